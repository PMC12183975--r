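#' Area under the ROC curve (rank-sum formulation)
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative, with ties credited 0.5 — computed from the Wilcoxon
#' rank sum, which is exactly the all-pairs count.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels, at least one of each class.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' compute_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
compute_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels)) stopf("scores and labels must not contain NA")
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0/1")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("AUC undefined: need at least one of each class")
  r <- rank(scores)   # midranks credit ties 0.5
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# resolve the screening/training contrast on a manifest
contrast_rows <- function(manifest, contrast = c("composite", "ad_vs_nc")) {
  contrast <- match.arg(contrast)
  if (contrast == "composite") {
    keep <- !is.na(manifest$label)
    m <- manifest[keep, , drop = FALSE]
    y <- m$label
  } else {
    pos <- manifest$group == "AD"
    neg <- manifest$group %in% c("NC", "sNC")
    m <- manifest[pos | neg, , drop = FALSE]
    y <- as.integer(m$group == "AD")
  }
  if (nrow(m) == 0 || length(unique(y)) < 2)
    stopf("contrast '%s' leaves fewer than two classes in the manifest", contrast)
  list(manifest = m, y = as.integer(y))
}

# Load every subject once and extract the centroid patch of every candidate
# ROI; returns a list of (V x n) matrices keyed by ROI label.
cohort_roi_patches <- function(manifest, atlas, candidate_labels, patch_size,
                               standardize = TRUE) {
  roi_tab <- list_rois(atlas)
  missing <- setdiff(candidate_labels, roi_tab$label_id)
  if (length(missing))
    stopf("candidate label(s) not present in atlas: %s", paste(missing, collapse = ", "))
  cent <- roi_tab[match(candidate_labels, roi_tab$label_id), c("cx", "cy", "cz")]
  V <- patch_size^3
  n <- nrow(manifest)
  out <- lapply(seq_along(candidate_labels),
                function(i) matrix(0, nrow = V, ncol = n))
  names(out) <- as.character(candidate_labels)
  for (s in seq_len(n)) {
    vol <- load_nifti_volume(manifest$image_path[s])
    for (i in seq_along(candidate_labels)) {
      p <- extract_patch(vol, as.integer(cent[i, ]), patch_size)
      if (standardize) p <- standardize_patch(p)
      out[[i]][, s] <- as.numeric(p)
    }
  }
  out
}

#' Screen ROIs with single-ROI networks (step 1)
#'
#' Trains one SRNet per candidate ROI on the centroid patches of the
#' screening contrast and records its held-out validation AUC. Per-ROI seeds
#' are derived from `cfg$seed` and the ROI label, so the screen is
#' reproducible and its result does not depend on execution order.
#'
#' With `n_splits > 1` the recorded AUC is the mean validation AUC over that
#' many repeated stratified splits (different derived seeds); this stabilizes
#' the per-ROI estimate when the cohort is small.
#'
#' @param manifest subject manifest (see [read_manifest()]).
#' @param atlas 3D integer label array in the space of the images.
#' @param candidate_labels ROI labels to screen; default all nonzero labels.
#' @param spec a [backbone_spec()].
#' @param cfg a [train_config()].
#' @param patch_size patch edge length in voxels (default 32).
#' @param standardize per-patch standardization (default TRUE).
#' @param contrast `"composite"` (default: all labeled rows, the
#'   positive/negative composite) or `"ad_vs_nc"` (rows tagged `AD` vs
#'   `NC`/`sNC` only).
#' @param n_splits repeated hold-out splits per ROI (default 1).
#' @return a data frame of class `auc_table` with columns `label_id`,
#'   `name`, `auc`, `n_train`, `n_val`, `seed`.
#' @export
screen_rois <- function(manifest, atlas, candidate_labels = NULL,
                        spec = backbone_spec(), cfg = train_config(),
                        patch_size = 32L, standardize = TRUE,
                        contrast = c("composite", "ad_vs_nc"),
                        n_splits = 1L) {
  ct <- contrast_rows(manifest, contrast)
  roi_tab <- list_rois(atlas)
  if (is.null(candidate_labels)) candidate_labels <- roi_tab$label_id
  candidate_labels <- as.integer(candidate_labels)
  patch_list <- cohort_roi_patches(ct$manifest, atlas, candidate_labels,
                                   patch_size, standardize)
  dims <- rep(as.integer(patch_size), 3)
  rows <- lapply(seq_along(candidate_labels), function(i) {
    lab <- candidate_labels[i]
    roi_seed <- derive_seed(cfg$seed, paste0("roi_", lab))
    aucs <- numeric(n_splits)
    n_train <- n_val <- NA_integer_
    for (s in seq_len(n_splits)) {
      cfg_s <- cfg
      cfg_s$seed <- if (n_splits == 1) roi_seed else
        derive_seed(roi_seed, paste0("split_", s))
      fit <- fit_cnn(patch_list[[i]], ct$y, k = 1L, dims = dims,
                     spec = spec, cfg = cfg_s)
      aucs[s] <- fit$report$val_auc
      n_train <- fit$report$n_train
      n_val <- fit$report$n_val
    }
    data.frame(label_id = lab,
               name = roi_tab$name[match(lab, roi_tab$label_id)],
               auc = mean(aucs), n_train = n_train, n_val = n_val,
               seed = roi_seed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("auc_table", "data.frame")
  out
}

#' Rank screened ROIs and select the top K
#'
#' Deterministic ordering by descending AUC, ties broken by ascending label
#' id; the first `k` become the selected discriminative regions (the
#' reference pipeline keeps the top 10 of the 116 AAL parcels).
#'
#' @param table an `auc_table` from [screen_rois()] (any data frame with
#'   `label_id` and `auc` columns works).
#' @param k number of ROIs to select (default 10).
#' @return an object of class `roi_ranking` with elements `ordered`
#'   (all labels, best first), `selected` (first `k`), `k` and the reordered
#'   `auc_table`.
#' @export
rank_rois <- function(table, k = 10L) {
  k <- as.integer(k)
  if (k < 1) stopf("k must be >= 1")
  if (k > nrow(table)) stopf("k (%d) exceeds the number of screened ROIs (%d)",
                             k, nrow(table))
  ord <- order(-table$auc, table$label_id)
  tab <- table[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(ordered = as.integer(tab$label_id),
                 selected = as.integer(tab$label_id[seq_len(k)]),
                 k = k, auc_table = tab),
            class = "roi_ranking")
}

#' @export
print.roi_ranking <- function(x, ...) {
  cat(sprintf("ROI ranking: %d screened, top %d selected\n",
              length(x$ordered), x$k))
  print(utils::head(x$auc_table, x$k))
  invisible(x)
}
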