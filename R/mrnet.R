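#' Build an untrained multi-ROI network (MRNet)
#'
#' K parallel branches — one per selected ROI — share a single backbone
#' parameter set; their K feature vectors are concatenated into one
#' fully-connected layer with two logits and softmax output, so the FC input
#' length is K times that of a single-ROI network (640 for the default
#' 10-ROI, 64-feature configuration). The positive-class output probability
#' is the Progressive Index.
#'
#' @param selected_rois ordered vector of K distinct ROI labels; the order
#'   is part of the model contract (FC weights are order-sensitive) and is
#'   stored with the model.
#' @param spec a [backbone_spec()].
#' @param init_seed integer seed.
#' @param patch_size patch edge length the model expects (default 32).
#' @return an object of class `c("mrnet", "cnn_fit")`.
#' @export
build_mrnet <- function(selected_rois, spec = backbone_spec(), init_seed = 1L,
                        patch_size = 32L) {
  selected_rois <- as.integer(selected_rois)
  if (length(selected_rois) < 1) stopf("need at least one selected ROI")
  if (anyDuplicated(selected_rois)) stopf("selected_rois must be distinct")
  k <- length(selected_rois)
  backbone <- build_backbone(spec, derive_seed(init_seed, "backbone"))
  cl <- spec$channels[spec$n_conv_layers]
  fc <- with_seed(derive_seed(init_seed, "fc"), {
    list(w = matrix(rnorm(2 * k * cl, 0, sqrt(1 / (k * cl))), nrow = 2),
         b = numeric(2))
  })
  structure(list(conv_w = backbone$conv_w, conv_b = backbone$conv_b,
                 fc_w = fc$w, fc_b = fc$b, spec = spec, k = k,
                 dims = rep(as.integer(patch_size), 3),
                 selected_rois = selected_rois, standardize = TRUE,
                 report = NULL),
            class = c("mrnet", "cnn_fit"))
}

#' Extract the ordered ROI patch stack for one subject
#'
#' Patches are extracted at the centroid of each selected ROI, in the stored
#' selection order. Border ROIs are zero-padded per [extract_patch()].
#'
#' @param volume 3D image array (atlas space).
#' @param atlas 3D integer label array.
#' @param selected_rois ordered ROI labels (or a `roi_ranking`).
#' @param size patch edge length (default 32).
#' @param centroids optional precomputed centroid matrix (rows in selection
#'   order) to skip the atlas scan.
#' @return a `(size, size, size, K)` array with attribute `roi_labels`.
#' @export
subject_patches <- function(volume, atlas, selected_rois, size = 32L,
                            centroids = NULL) {
  if (inherits(selected_rois, "roi_ranking")) selected_rois <- selected_rois$selected
  selected_rois <- as.integer(selected_rois)
  k <- length(selected_rois)
  if (is.null(centroids)) {
    centroids <- t(vapply(selected_rois, function(l) roi_centroid(atlas, l),
                          integer(3)))
  }
  out <- array(0, dim = c(size, size, size, k))
  for (i in seq_len(k)) {
    out[, , , i] <- extract_patch(volume, centroids[i, ], size,
                                  roi_label = selected_rois[i])
  }
  attr(out, "roi_labels") <- selected_rois
  out
}

#' Train the MRNet for conversion prediction (step 2)
#'
#' Extracts the K selected centroid patches per labeled subject and trains
#' the parameter-shared MRNet with the cross-entropy objective on a
#' stratified split. Reproducible for a fixed `cfg$seed`.
#'
#' @param manifest subject manifest; only rows with label 0/1 are used.
#' @param atlas 3D integer label array.
#' @param ranking a `roi_ranking` (or a plain vector of ROI labels).
#' @param spec a [backbone_spec()].
#' @param cfg a [train_config()].
#' @param patch_size patch edge length (default 32).
#' @param standardize per-patch standardization (default TRUE).
#' @param contrast which manifest rows form the training contrast, see
#'   [screen_rois()].
#' @return a trained `mrnet` object with a training report.
#' @export
train_mrnet <- function(manifest, atlas, ranking, spec = backbone_spec(),
                        cfg = train_config(), patch_size = 32L,
                        standardize = TRUE,
                        contrast = c("composite", "ad_vs_nc")) {
  selected <- if (inherits(ranking, "roi_ranking")) ranking$selected else
    as.integer(ranking)
  ct <- contrast_rows(manifest, contrast)
  k <- length(selected)
  cents <- t(vapply(selected, function(l) roi_centroid(atlas, l), integer(3)))
  n <- nrow(ct$manifest)
  V <- patch_size^3
  X <- matrix(0, nrow = V, ncol = n * k)
  for (s in seq_len(n)) {
    vol <- load_nifti_volume(ct$manifest$image_path[s])
    for (i in seq_len(k)) {
      p <- extract_patch(vol, cents[i, ], patch_size)
      if (standardize) p <- standardize_patch(p)
      X[, (s - 1L) * k + i] <- as.numeric(p)
    }
  }
  fit <- fit_cnn(X, ct$y, k = k, dims = rep(as.integer(patch_size), 3),
                 spec = spec, cfg = cfg)
  fit$selected_rois <- selected
  fit$standardize <- standardize
  class(fit) <- c("mrnet", "cnn_fit")
  fit
}

#' Progressive Index of a subject
#'
#' The positive-class softmax probability of the MRNet for one subject's
#' ordered patch stack — a continuous score in `[0, 1]` interpreted as the
#' propensity to progress; deterministic given model and input.
#'
#' @param model a (trained) `mrnet` object.
#' @param patches a `(s, s, s, K)` array in the model's ROI order (K may be
#'   1 for a single-ROI model), or a `(s, s, s, K, n)` batch.
#' @return numeric PI value(s) in `[0, 1]`.
#' @export
progressive_index <- function(model, patches) {
  d <- dim(patches)
  if (length(d) == 3) {
    if (model$k != 1) stopf("model expects %d patches per subject, got 1", model$k)
    dim(patches) <- c(d, 1L, 1L)
  } else if (length(d) == 4) {
    # a 4D array is one subject's K-patch stack unless the model is
    # single-ROI, in which case it is a batch of n single patches
    if (model$k == 1) dim(patches) <- c(d[1:3], 1L, d[4])
    else if (d[4] == model$k) dim(patches) <- c(d, 1L)
    else stopf("model expects %d patches per subject, got %d", model$k, d[4])
  } else if (length(d) == 5 && d[4] != model$k) {
    stopf("model expects %d patches per subject, got %d", model$k, d[4])
  }
  predict.cnn_fit(model, patches)
}

#' Score a whole cohort with a trained MRNet
#'
#' One row per manifest subject, including unknown-label subjects (their PI
#' is computed; they are excluded from metrics downstream). A subject whose
#' image cannot be read or scored is marked failed with the error message
#' recorded, and scoring continues.
#'
#' @param model a trained `mrnet`.
#' @param manifest subject manifest.
#' @param atlas 3D integer label array.
#' @return a data frame of class `pi_table` with columns `subject_id`,
#'   `group`, `label`, `pi`, `failed`, `note`.
#' @export
score_cohort <- function(model, manifest, atlas) {
  size <- model$dims[1]
  cents <- t(vapply(model$selected_rois, function(l) roi_centroid(atlas, l),
                    integer(3)))
  n <- nrow(manifest)
  pi <- rep(NA_real_, n)
  failed <- logical(n)
  note <- character(n)
  for (s in seq_len(n)) {
    res <- tryCatch({
      vol <- load_nifti_volume(manifest$image_path[s])
      patches <- subject_patches(vol, atlas, model$selected_rois, size,
                                 centroids = cents)
      progressive_index(model, patches)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[s] <- TRUE
      note[s] <- conditionMessage(res)
    } else {
      pi[s] <- res
    }
  }
  out <- data.frame(subject_id = manifest$subject_id, group = manifest$group,
                    label = manifest$label, pi = pi, failed = failed,
                    note = note, stringsAsFactors = FALSE)
  class(out) <- c("pi_table", "data.frame")
  out
}

#' Classification metrics at a PI threshold
#'
#' Under the default `"overall_mean"` mode the threshold is the mean PI over
#' all scored rows — including unknown-label subjects, mirroring an
#' "overall average score" computed over the full validation cohort.
#' Subjects with `PI >= threshold` are classified positive (ties positive);
#' sensitivity, specificity and AUC are computed over known-label rows only.
#'
#' @param table a `pi_table`.
#' @param threshold_mode `"overall_mean"` or `"fixed"`.
#' @param value the threshold when `threshold_mode = "fixed"`.
#' @return an object of class `threshold_metrics`: threshold, sensitivity,
#'   specificity, AUC and the 2x2 counts.
#' @export
threshold_metrics <- function(table, threshold_mode = c("overall_mean", "fixed"),
                              value = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  ok <- !is.na(table$pi)
  if (!any(ok)) stopf("no scored subjects in the PI table")
  thr <- if (threshold_mode == "overall_mean") mean(table$pi[ok]) else {
    if (is.null(value)) stopf("threshold_mode 'fixed' requires a value")
    value
  }
  known <- ok & !is.na(table$label)
  y <- table$label[known]
  p <- table$pi[known]
  if (sum(y == 1) == 0 || sum(y == 0) == 0)
    stopf("metrics undefined: need known-label subjects of both classes")
  pred <- p >= thr
  tp <- sum(pred & y == 1); fn <- sum(!pred & y == 1)
  tn <- sum(!pred & y == 0); fp <- sum(pred & y == 0)
  structure(list(threshold = thr,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 auc = compute_auc(p, y),
                 counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 n_known = sum(known), n_scored = sum(ok)),
            class = "threshold_metrics")
}

#' @export
print.threshold_metrics <- function(x, ...) {
  cat(sprintf(
    "PI threshold %.4f: SEN %.4f, SPE %.4f, AUC %.4f (%d labeled / %d scored)\n",
    x$threshold, x$sensitivity, x$specificity, x$auc, x$n_known, x$n_scored))
  invisible(x)
}

#' Stage-sorted PI plot data
#'
#' Rows ordered by group (in the given order) and PI within group, with a
#' running subject index — the layout of a stage-sorted progression plot.
#'
#' @param table a `pi_table`.
#' @param group_order optional character vector fixing the group order.
#' @return a data frame with `index`, `group`, `subject_id`, `pi`.
#' @export
stage_plot_data <- function(table, group_order = NULL) {
  ok <- table[!is.na(table$pi), , drop = FALSE]
  groups <- group_order %||% sort(unique(ok$group))
  ok$group <- factor(ok$group, levels = groups)
  ok <- ok[order(ok$group, ok$pi), , drop = FALSE]
  data.frame(index = seq_len(nrow(ok)), group = as.character(ok$group),
             subject_id = ok$subject_id, pi = ok$pi, stringsAsFactors = FALSE)
}
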