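#' Default pipeline configuration
#'
#' A complete, self-contained configuration for the seeded end-to-end
#' pipeline. By default the pipeline runs on a generated phantom cohort
#' (`synthetic$enabled = TRUE`); point `paths$manifest`/`paths$atlas` (and
#' optionally `paths$covariates`) at your own data to disable simulation.
#' All stage seeds are derived from `master_seed`.
#'
#' @return a nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    master_seed = 1L,
    output_dir = "roiprog_run",
    paths = list(atlas = NULL, manifest = NULL, covariates = NULL),
    synthetic = list(
      enabled = TRUE,
      shape = c(48L, 48L, 48L),
      n_rois = 30L,
      roi_radius = 4L,
      informative_labels = c(1L, 2L, 3L),
      intensity_shift = 0.5,
      erosion_fraction = 0.1,
      noise_sd = 0.2,
      n_per_group = list(pMCI = 50L, AD = 50L, sMCI = 50L, sNC = 50L)
    ),
    backbone = list(n_conv_layers = 5L,
                    channels = c(16L, 32L, 64L, 64L, 64L),
                    kernel = c(3L, 3L, 3L)),
    patch_size = 32L,
    standardize = TRUE,
    screen = list(candidate_labels = NULL, k = 10L,
                  contrast = "composite", n_splits = 1L),
    train = list(learning_rate = 1e-3, batch_size = 8L,
                 epochs_screen = 4L, epochs_mrnet = 8L,
                 validation_fraction = 0.2),
    stats = list(
      pi_scale = 100, n_boot = 500L,
      models = list(
        unadjusted = character(0),
        m1 = c("age", "gender", "education", "brain_size"),
        m2 = c("age", "gender", "education", "brain_size", "assoc_memory")
      ),
      combined_terms = c("age", "gender", "education", "assoc_memory")
    )
  )
}

# fields whose user value replaces the default wholesale (value maps and
# vectors; deep-merging them against the defaults would be surprising)
.atomic_config_fields <- c("n_per_group", "models", "combined_terms",
                           "informative_labels", "candidate_labels",
                           "channels", "shape", "kernel")

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (!nm %in% .atomic_config_fields &&
        is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else
      base[[nm]] <- override[[nm]]
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or accepts a list), fills unset fields from
#' [default_pipeline_config()], and validates the schema before any compute:
#' types, positivity, `k` against the candidate ROI count, and existence of
#' referenced input paths.
#'
#' @param config path to a YAML file, or a (possibly partial) config list.
#' @return the validated, completed config (class `pipeline_config`).
#' @export
pipeline_config <- function(config = list()) {
  if (inherits(config, "pipeline_config")) return(config)
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a YAML file path or a list")
  cfg <- merge_config(default_pipeline_config(), config)

  err <- function(field, msg) stopf("invalid config field '%s': %s", field, msg)
  if (!is.numeric(cfg$master_seed) || length(cfg$master_seed) != 1)
    err("master_seed", "must be a single integer")
  if (cfg$screen$k < 1) err("screen.k", "must be >= 1")
  if (!cfg$screen$contrast %in% c("composite", "ad_vs_nc"))
    err("screen.contrast", "must be 'composite' or 'ad_vs_nc'")
  if (cfg$patch_size < 1) err("patch_size", "must be positive")
  spec <- do.call(backbone_spec, cfg$backbone)  # validates the backbone block
  check_patch_dims(spec, rep(cfg$patch_size, 3))
  tr <- cfg$train
  if (tr$learning_rate <= 0 || tr$batch_size < 1 ||
      tr$epochs_screen < 1 || tr$epochs_mrnet < 1)
    err("train", "learning_rate/batch_size/epochs must be positive")
  if (tr$validation_fraction < 0 || tr$validation_fraction >= 1)
    err("train.validation_fraction", "must be in [0, 1)")

  n_candidates <- if (!is.null(cfg$screen$candidate_labels))
    length(cfg$screen$candidate_labels)
  else if (isTRUE(cfg$synthetic$enabled)) cfg$synthetic$n_rois
  else NA_integer_
  if (!is.na(n_candidates) && cfg$screen$k > n_candidates)
    err("screen.k", sprintf("k (%d) exceeds the candidate ROI count (%d)",
                            cfg$screen$k, n_candidates))
  if (isTRUE(cfg$synthetic$enabled)) {
    sy <- cfg$synthetic
    if (sy$n_rois < 1) err("synthetic.n_rois", "must be >= 1")
    if (length(sy$informative_labels) &&
        any(sy$informative_labels > sy$n_rois))
      err("synthetic.informative_labels", "labels exceed n_rois")
  } else {
    for (p in c("atlas", "manifest")) {
      if (is.null(cfg$paths[[p]]))
        err(paste0("paths.", p), "required when synthetic.enabled is false")
      if (!file.exists(cfg$paths[[p]]))
        err(paste0("paths.", p), paste("file not found:", cfg$paths[[p]]))
    }
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

read_atlas_file <- function(path) {
  a <- load_nifti_volume(path)
  a <- array(as.integer(round(a)), dim = dim(a))
  validate_atlas(a)
  a
}

# deterministic full-precision PI table serialization (stage contract: two
# runs with the same master seed are byte-identical)
write_pi_table <- function(table, path) {
  df <- data.frame(subject_id = table$subject_id, group = table$group,
                   label = table$label,
                   pi = ifelse(is.na(table$pi), "", sprintf("%.17g", table$pi)),
                   failed = table$failed, note = table$note,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a PI table written by the pipeline
#' @param path CSV path.
#' @return a `pi_table` data frame.
#' @export
read_pi_table <- function(path) {
  if (!file.exists(path)) stopf("PI table not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(subject_id = "character", group = "character",
                                note = "character"))
  df$pi <- suppressWarnings(as.numeric(df$pi))
  df$label <- suppressWarnings(as.integer(df$label))
  class(df) <- c("pi_table", "data.frame")
  df
}

pipeline_paths <- function(cfg) {
  out <- cfg$output_dir
  synth <- isTRUE(cfg$synthetic$enabled)
  list(
    out = out,
    cohort = file.path(out, "cohort"),
    atlas = if (synth) file.path(out, "cohort", "atlas.nii.gz") else cfg$paths$atlas,
    manifest = if (synth) file.path(out, "cohort", "manifest.csv") else cfg$paths$manifest,
    covariates = if (synth) file.path(out, "cohort", "covariates.csv") else cfg$paths$covariates,
    auc_table = file.path(out, "screen", "auc_table.csv"),
    ranking = file.path(out, "screen", "ranking.json"),
    model = file.path(out, "model", "mrnet.rds"),
    train_report = file.path(out, "model", "train_report.json"),
    pi_table = file.path(out, "pi_table.csv"),
    metrics = file.path(out, "metrics.json"),
    stats_dir = file.path(out, "stats"),
    log = file.path(out, "run_log.txt")
  )
}

log_line <- function(paths, msg) {
  dir.create(paths$out, recursive = TRUE, showWarnings = FALSE)
  cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg),
      file = paths$log, append = TRUE)
}

require_artifact <- function(path, produced_by) {
  if (is.null(path) || !file.exists(path))
    stopf("missing input artifact %s; run the '%s' stage first",
          path %||% "<unset>", produced_by)
  path
}

#' Run the end-to-end pipeline
#'
#' Executes one stage or the full chain
#' `simulate -> screen -> train -> score -> metrics -> stats`, writing each
#' stage's declared artifacts under `output_dir` together with a run log
#' carrying the config hash and stage seeds. Stages are restartable: each
#' one reads only the on-disk artifacts of its predecessors.
#'
#' @param config YAML path or config list, see [pipeline_config()].
#' @param stage one of `"simulate"`, `"screen"`, `"train"`, `"score"`,
#'   `"metrics"`, `"stats"`, `"all"`.
#' @param validate_only if TRUE, validate the config and return without
#'   computing.
#' @return (invisibly) the named list of artifact paths.
#' @export
run_pipeline <- function(config, stage = c("all", "simulate", "screen", "train",
                                           "score", "metrics", "stats"),
                         validate_only = FALSE) {
  stage <- match.arg(stage)
  cfg <- pipeline_config(config)
  paths <- pipeline_paths(cfg)
  if (validate_only) return(invisible(paths))
  dir.create(paths$out, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(unclass(cfg))
  log_line(paths, sprintf("run start: stage=%s config_hash=%s master_seed=%d",
                          stage, hash, as.integer(cfg$master_seed)))
  jsonlite::write_json(c(unclass(cfg), list(config_hash = hash)),
                       file.path(paths$out, "config_used.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")

  stages <- if (stage == "all") {
    c(if (isTRUE(cfg$synthetic$enabled)) "simulate",
      "screen", "train", "score", "metrics", "stats")
  } else stage
  spec <- do.call(backbone_spec, cfg$backbone)

  for (st in stages) {
    log_line(paths, paste("stage:", st))
    switch(st,
      simulate = {
        if (!isTRUE(cfg$synthetic$enabled))
          stopf("simulate stage requires synthetic.enabled = true")
        sy <- cfg$synthetic
        eff <- effect_spec(sy$informative_labels, sy$intensity_shift,
                           sy$erosion_fraction, sy$noise_sd)
        simulate_cohort(paths$cohort, shape = unlist(sy$shape),
                        n_rois = sy$n_rois, roi_radius = sy$roi_radius,
                        effect = eff, n_per_group = unlist(sy$n_per_group),
                        seed = derive_seed(cfg$master_seed, "simulate"))
      },
      screen = {
        manifest <- read_manifest(require_artifact(paths$manifest, "simulate"))
        atlas <- read_atlas_file(require_artifact(paths$atlas, "simulate"))
        tcfg <- train_config(learning_rate = cfg$train$learning_rate,
                             batch_size = cfg$train$batch_size,
                             epochs = cfg$train$epochs_screen,
                             seed = derive_seed(cfg$master_seed, "screen"),
                             validation_fraction = cfg$train$validation_fraction)
        tab <- screen_rois(manifest, atlas,
                           candidate_labels = cfg$screen$candidate_labels,
                           spec = spec, cfg = tcfg,
                           patch_size = cfg$patch_size,
                           standardize = cfg$standardize,
                           contrast = cfg$screen$contrast,
                           n_splits = cfg$screen$n_splits)
        dir.create(dirname(paths$auc_table), recursive = TRUE, showWarnings = FALSE)
        write.csv(tab, paths$auc_table, row.names = FALSE)
        rk <- rank_rois(tab, cfg$screen$k)
        jsonlite::write_json(list(ordered = rk$ordered, selected = rk$selected,
                                  k = rk$k),
                             paths$ranking, auto_unbox = TRUE, digits = NA)
      },
      train = {
        manifest <- read_manifest(require_artifact(paths$manifest, "simulate"))
        atlas <- read_atlas_file(require_artifact(paths$atlas, "simulate"))
        rk <- jsonlite::read_json(require_artifact(paths$ranking, "screen"),
                                  simplifyVector = TRUE)
        tcfg <- train_config(learning_rate = cfg$train$learning_rate,
                             batch_size = cfg$train$batch_size,
                             epochs = cfg$train$epochs_mrnet,
                             seed = derive_seed(cfg$master_seed, "train"),
                             validation_fraction = cfg$train$validation_fraction)
        model <- train_mrnet(manifest, atlas, as.integer(rk$selected),
                             spec = spec, cfg = tcfg,
                             patch_size = cfg$patch_size,
                             standardize = cfg$standardize,
                             contrast = cfg$screen$contrast)
        dir.create(dirname(paths$model), recursive = TRUE, showWarnings = FALSE)
        saveRDS(model, paths$model)
        jsonlite::write_json(model$report[c("train_loss", "val_loss", "val_auc",
                                            "n_train", "n_val")],
                             paths$train_report, auto_unbox = TRUE, digits = NA)
      },
      score = {
        manifest <- read_manifest(require_artifact(paths$manifest, "simulate"))
        atlas <- read_atlas_file(require_artifact(paths$atlas, "simulate"))
        model <- readRDS(require_artifact(paths$model, "train"))
        tab <- score_cohort(model, manifest, atlas)
        write_pi_table(tab, paths$pi_table)
      },
      metrics = {
        tab <- read_pi_table(require_artifact(paths$pi_table, "score"))
        tm <- threshold_metrics(tab)
        jsonlite::write_json(list(threshold = tm$threshold,
                                  sensitivity = tm$sensitivity,
                                  specificity = tm$specificity,
                                  auc = tm$auc, counts = as.list(tm$counts),
                                  n_known = tm$n_known, n_scored = tm$n_scored),
                             paths$metrics, auto_unbox = TRUE, digits = NA)
      },
      stats = {
        tab <- read_pi_table(require_artifact(paths$pi_table, "score"))
        cov <- read.csv(require_artifact(paths$covariates, "simulate"),
                        stringsAsFactors = FALSE)
        dir.create(paths$stats_dir, recursive = TRUE, showWarnings = FALSE)
        gs <- group_pi_summary(tab)
        seed_stats <- derive_seed(cfg$master_seed, "stats")
        d <- tab[!is.na(tab$label) & !is.na(tab$pi), , drop = FALSE]
        m <- match(d$subject_id, cov$subject_id)
        dd <- cbind(data.frame(label = d$label,
                               pi = d$pi * cfg$stats$pi_scale),
                    cov[m, setdiff(names(cov), "subject_id"), drop = FALSE])
        fits <- lapply(cfg$stats$models, function(terms)
          fit_logistic(dd, "label", c("pi", unlist(terms))))
        comb <- combined_model_eval(tab, cov,
                                    formula_terms = unlist(cfg$stats$combined_terms),
                                    n_boot = cfg$stats$n_boot,
                                    seed = seed_stats,
                                    pi_scale = cfg$stats$pi_scale)
        out <- list(
          group_summary = gs$group_summary,
          contrast = gs$contrast,
          pi_scale = cfg$stats$pi_scale,
          models = lapply(fits, function(f)
            list(formula = f$formula, converged = f$converged,
                 n_used = f$n_used, n_dropped = f$n_dropped, terms = f$terms)),
          combined = list(formula = comb$fit$formula,
                          auc = comb$roc$auc, ci95 = comb$roc$ci95,
                          terms = comb$fit$terms)
        )
        jsonlite::write_json(out, file.path(paths$stats_dir, "summary.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        roc_df <- data.frame(threshold = comb$roc$thresholds,
                             sensitivity = comb$roc$sensitivities,
                             specificity = comb$roc$specificities)
        write.csv(roc_df, file.path(paths$stats_dir, "roc_combined.csv"),
                  row.names = FALSE)
      })
    log_line(paths, paste("stage done:", st))
  }
  log_line(paths, "run complete")
  invisible(paths)
}
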