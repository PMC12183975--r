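#' Specification of the shared convolutional backbone
#'
#' The backbone used by both the single-ROI network (SRNet) and every branch
#' of the multi-ROI network (MRNet): `n_conv_layers` same-padded 3x3x3
#' convolutions with ReLU activations, a stride-2 max-pool after every layer
#' but the last, and a global average pool after the last layer, producing a
#' feature vector of length `channels[n_conv_layers]`. The default follows
#' the reference architecture: five layers with channels 16, 32, 64, 64, 64,
#' so a 32^3 patch traverses the spatial chain 32 -> 16 -> 8 -> 4 -> 2 and
#' yields a 64-dimensional feature.
#'
#' Same padding is used throughout: it is the only convention under which
#' five 3x3x3 layers plus four stride-2 pools map a 32^3 patch onto the
#' stated 64-length global-average output without cropping.
#'
#' @param n_conv_layers number of convolutional layers.
#' @param channels integer vector of output channels per layer; its length
#'   must equal `n_conv_layers`.
#' @param kernel 3 odd positive integers, the convolution kernel size.
#' @return an object of class `backbone_spec`.
#' @export
backbone_spec <- function(n_conv_layers = 5L,
                          channels = c(16L, 32L, 64L, 64L, 64L),
                          kernel = c(3L, 3L, 3L)) {
  n_conv_layers <- as.integer(n_conv_layers)
  channels <- as.integer(channels)
  kernel <- as.integer(kernel)
  if (n_conv_layers < 1) stopf("n_conv_layers must be >= 1")
  if (length(channels) != n_conv_layers)
    stopf("length(channels) (%d) must equal n_conv_layers (%d)",
          length(channels), n_conv_layers)
  if (any(channels < 1)) stopf("all channels must be >= 1")
  if (length(kernel) != 3 || any(kernel < 1) || any(kernel %% 2 == 0))
    stopf("kernel must be 3 odd positive integers")
  structure(list(n_conv_layers = n_conv_layers, channels = channels,
                 kernel = kernel),
            class = "backbone_spec")
}

# minimum input edge length: the spatial dims must survive the pooling chain
min_patch_size <- function(spec) 2L^(spec$n_conv_layers - 1L)

check_patch_dims <- function(spec, dims) {
  need <- min_patch_size(spec)
  if (any(dims %% need != 0) || any(dims < need))
    stopf("patch dims %s do not survive %d stride-2 pools (must be multiples of %d)",
          paste(dims, collapse = "x"), spec$n_conv_layers - 1L, need)
  invisible(dims)
}

#' The spatial side-length chain of a patch through the backbone
#'
#' Pure arithmetic helper: the edge length of the activation entering each
#' conv layer, followed by the size entering the global average pool.
#'
#' @param spec a [backbone_spec()].
#' @param size input patch edge length.
#' @return integer vector of length `n_conv_layers + 1`.
#' @export
backbone_dims_chain <- function(spec, size) {
  check_patch_dims(spec, rep(size, 3))
  out <- integer(spec$n_conv_layers + 1L)
  d <- as.integer(size)
  for (l in seq_len(spec$n_conv_layers)) {
    out[l] <- d
    if (l < spec$n_conv_layers) d <- d %/% 2L
  }
  out[spec$n_conv_layers + 1L] <- d
  out
}

#' Allocate seeded backbone parameters
#'
#' He-normal weight initialization (SD `sqrt(2 / fan_in)`), zero biases.
#' Identical seeds give identical parameters.
#'
#' @param spec a [backbone_spec()].
#' @param init_seed integer seed.
#' @return an object of class `backbone_params` holding per-layer weight
#'   matrices (`c_out` x `kernel_volume * c_in`) and bias vectors.
#' @export
build_backbone <- function(spec = backbone_spec(), init_seed = 1L) {
  stopifnot(inherits(spec, "backbone_spec"))
  kk <- prod(spec$kernel)
  c_in <- c(1L, spec$channels[-spec$n_conv_layers])
  with_seed(init_seed, {
    conv_w <- vector("list", spec$n_conv_layers)
    conv_b <- vector("list", spec$n_conv_layers)
    for (l in seq_len(spec$n_conv_layers)) {
      fan_in <- kk * c_in[l]
      conv_w[[l]] <- matrix(rnorm(spec$channels[l] * fan_in, 0, sqrt(2 / fan_in)),
                            nrow = spec$channels[l], ncol = fan_in)
      conv_b[[l]] <- numeric(spec$channels[l])
    }
    structure(list(conv_w = conv_w, conv_b = conv_b, spec = spec,
                   init_seed = as.integer(init_seed)),
              class = "backbone_params")
  })
}

#' Number of trainable backbone parameters
#' @param params a `backbone_params` object.
#' @return integer count of weights plus biases.
#' @export
backbone_n_params <- function(params) {
  sum(vapply(params$conv_w, length, numeric(1))) +
    sum(vapply(params$conv_b, length, numeric(1)))
}

#' Forward a patch through the backbone
#'
#' @param params a `backbone_params` object.
#' @param patch a cubic patch whose edge length is a multiple of
#'   `2^(n_conv_layers - 1)` (32 for the default spec).
#' @param standardize standardize the patch (subtract mean, divide by SD)
#'   before the first convolution (default `TRUE`).
#' @return numeric feature vector of length `channels[n_conv_layers]`.
#' @export
backbone_forward <- function(params, patch, standardize = TRUE) {
  d <- dim(patch)
  if (length(d) != 3) stopf("patch must be a 3D array")
  check_patch_dims(params$spec, d)
  if (standardize) patch <- standardize_patch(patch)
  X <- matrix(as.numeric(patch), ncol = 1)
  f <- cpp_backbone_features(params$conv_w, params$conv_b, X,
                             as.integer(d), params$spec$kernel)
  as.numeric(f[1, ])
}

#' Binary cross-entropy loss
#'
#' `L = -[y log p + (1 - y) log(1 - p)]` with the probability clipped to
#' `[clip_eps, 1 - clip_eps]` for numerical safety. This is the training
#' objective of both SRNet and MRNet; the positive-class output probability
#' of the trained model is the Progressive Index.
#'
#' @param label 0/1 ground-truth label(s).
#' @param p predicted positive-class probability(ies).
#' @param clip_eps clipping bound (default `1e-7`).
#' @return non-negative loss value(s).
#' @export
cross_entropy <- function(label, p, clip_eps = 1e-7) {
  if (!all(label %in% c(0, 1))) stopf("label must be 0 or 1")
  p <- pmin(pmax(p, clip_eps), 1 - clip_eps)
  -(label * log(p) + (1 - label) * log(1 - p))
}
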