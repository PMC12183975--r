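#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' All randomness in the package flows from a single master seed through
#' named sub-seeds, so that any stage (per-ROI screening run, per-subject
#' simulation, bootstrap, ...) is reproducible in isolation and independent
#' of execution order. The derivation is a rolling polynomial hash of
#' `"<master>:<tag>"` modulo 2^31 - 1, so derived seeds always fit an R
#' integer.
#'
#' @param master integer master seed.
#' @param tag character tag naming the consumer of the seed.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "roi_7")
derive_seed <- function(master, tag) {
  s <- paste0(format(master, scientific = FALSE), ":", tag)
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# Short stable hex hash of an R object (via its canonical JSON), used to
# stamp generated cohorts and pipeline runs.
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                     null = "null", force = TRUE))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
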