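#' Training hyperparameters
#'
#' The reference description leaves optimization unspecified; these defaults
#' are the package's engineering choices and every stochastic ingredient
#' (initialization, split, shuffling) draws a named sub-seed from `seed`.
#'
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size (subjects).
#' @param epochs number of passes over the training split.
#' @param seed master seed for this training run.
#' @param validation_fraction stratified per-class fraction held out to
#'   record the validation loss/AUC; set to 0 to train on everything.
#' @param optimizer gradient method; only `"adam"` is provided.
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabilizer.
#' @param clip_eps probability clipping bound inside the cross-entropy.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 8L, epochs = 20L,
                         seed = 1L, validation_fraction = 0.2,
                         optimizer = "adam", beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8, clip_eps = 1e-7) {
  optimizer <- match.arg(optimizer, "adam")
  if (learning_rate <= 0 || batch_size < 1 || epochs < 1)
    stopf("learning_rate, batch_size and epochs must be positive")
  if (validation_fraction < 0 || validation_fraction >= 1)
    stopf("validation_fraction must be in [0, 1)")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 validation_fraction = validation_fraction,
                 optimizer = optimizer, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, clip_eps = clip_eps),
            class = "train_config")
}

# column indices in a (V x n*k) patch matrix belonging to the given subjects
subject_cols <- function(subjects, k) {
  as.vector(vapply(subjects, function(s) (s - 1L) * k + seq_len(k),
                   integer(k)))
}

# Convert patches to the (V x n*k) matrix the C++ engine consumes.
# Accepts a 3D array (one patch), 4D (s,s,s,n; k = 1), 5D (s,s,s,k,n),
# or a list of such patches / per-subject patch stacks.
as_patch_matrix <- function(patches, standardize = TRUE) {
  if (is.list(patches)) {
    dims <- dim(patches[[1]])
    arr <- array(unlist(patches, use.names = FALSE),
                 dim = c(dims, length(patches)))
    return(as_patch_matrix(arr, standardize))
  }
  d <- dim(patches)
  if (length(d) == 3) d <- c(d, 1L, 1L)
  if (length(d) == 4) d <- c(d[1:3], 1L, d[4])
  if (length(d) != 5) stopf("patches must be a 3D/4D/5D array or a list")
  dims <- d[1:3]
  k <- d[4]
  n <- d[5]
  X <- matrix(as.numeric(patches), nrow = prod(dims), ncol = k * n)
  if (standardize) {
    X <- apply(X, 2, function(col) {
      s <- stats::sd(col)
      if (!is.finite(s) || s == 0) numeric(length(col)) else (col - mean(col)) / s
    })
  }
  list(X = X, dims = as.integer(dims), k = as.integer(k), n = as.integer(n))
}

# Core trainer shared by SRNet and MRNet: stratified split, seeded init,
# seeded shuffling, Adam + cross-entropy in C++, held-out AUC.
fit_cnn <- function(X, y, k, dims, spec, cfg) {
  n <- length(y)
  if (ncol(X) != n * k) stopf("patch matrix has %d columns, expected %d", ncol(X), n * k)
  if (!all(y %in% c(0, 1))) stopf("labels must be 0/1 (exclude unknown-label subjects upstream)")
  if (length(unique(y)) < 2) stopf("training data must contain both classes")
  check_patch_dims(spec, dims)

  pos <- which(y == 1)
  neg <- which(y == 0)
  n_val_pos <- floor(cfg$validation_fraction * length(pos))
  n_val_neg <- floor(cfg$validation_fraction * length(neg))
  if (n_val_pos >= length(pos) || n_val_neg >= length(neg))
    stopf("validation split would leave no training sample in one class")
  val_idx <- if (n_val_pos >= 1 && n_val_neg >= 1) {
    with_seed(derive_seed(cfg$seed, "split"),
              c(sample(pos, n_val_pos), sample(neg, n_val_neg)))
  } else integer(0)
  train_idx <- setdiff(seq_len(n), val_idx)
  if (length(unique(y[train_idx])) < 2)
    stopf("training split lost one class; lower validation_fraction")

  backbone <- build_backbone(spec, derive_seed(cfg$seed, "init"))
  cl <- spec$channels[spec$n_conv_layers]
  fc <- with_seed(derive_seed(cfg$seed, "fc"), {
    list(w = matrix(rnorm(2 * k * cl, 0, sqrt(1 / (k * cl))), nrow = 2),
         b = numeric(2))
  })
  perm <- with_seed(derive_seed(cfg$seed, "shuffle"),
                    vapply(seq_len(cfg$epochs),
                           function(e) sample.int(length(train_idx)),
                           integer(length(train_idx))))
  perm <- matrix(as.integer(perm), nrow = length(train_idx))

  Xtr <- X[, subject_cols(train_idx, k), drop = FALSE]
  Xval <- if (length(val_idx)) X[, subject_cols(val_idx, k), drop = FALSE] else
    matrix(numeric(0), nrow = nrow(X), ncol = 0)
  yval <- as.integer(y[val_idx])

  out <- cpp_cnn_train(backbone$conv_w, backbone$conv_b, fc$w, fc$b,
                       Xtr, as.integer(y[train_idx]), dims, as.integer(k),
                       spec$kernel, perm, cfg$batch_size, cfg$learning_rate,
                       cfg$beta1, cfg$beta2, cfg$adam_eps, cfg$clip_eps,
                       Xval, yval)

  val_auc <- NA_real_
  val_pi <- NULL
  if (length(val_idx)) {
    pr <- cpp_cnn_forward(out$conv_w, out$conv_b, out$fc_w, as.numeric(out$fc_b),
                          Xval, dims, as.integer(k), spec$kernel)
    val_pi <- pr$prob[, 2]
    val_auc <- compute_auc(val_pi, yval)
  }
  structure(list(conv_w = out$conv_w, conv_b = out$conv_b,
                 fc_w = out$fc_w, fc_b = as.numeric(out$fc_b),
                 spec = spec, k = as.integer(k), dims = dims, cfg = cfg,
                 report = list(train_loss = as.numeric(out$train_loss),
                               val_loss = as.numeric(out$val_loss),
                               val_auc = val_auc,
                               n_train = length(train_idx),
                               n_val = length(val_idx),
                               val_idx = val_idx, val_pi = val_pi)),
            class = "cnn_fit")
}

#' Train a patch classifier (backbone + softmax head)
#'
#' Generic trainer behind both SRNet (one patch per subject) and MRNet
#' (K parameter-shared branches): mini-batch Adam on the cross-entropy loss
#' over a stratified training split, fully reproducible for a fixed
#' `cfg$seed`.
#'
#' @param patches patches for all subjects: a `(s, s, s, n)` array (single
#'   ROI), a `(s, s, s, k, n)` array (k ROIs per subject), or a list.
#' @param labels 0/1 outcome per subject (both classes required).
#' @param spec a [backbone_spec()].
#' @param cfg a [train_config()].
#' @param standardize per-patch standardization before input (default TRUE).
#' @return an object of class `cnn_fit` with the trained parameters and a
#'   training report (per-epoch training/validation loss, validation AUC).
#' @export
train_classifier <- function(patches, labels, spec = backbone_spec(),
                             cfg = train_config(), standardize = TRUE) {
  pm <- as_patch_matrix(patches, standardize)
  if (pm$n != length(labels))
    stopf("got %d subjects of patches but %d labels", pm$n, length(labels))
  fit <- fit_cnn(pm$X, labels, pm$k, pm$dims, spec, cfg)
  fit$standardize <- standardize
  fit
}

#' Predict class probabilities from a trained classifier
#'
#' @param object a `cnn_fit` (or `mrnet`) object.
#' @param patches patches with the same per-subject layout used in training.
#' @param ... unused.
#' @return numeric vector of positive-class probabilities.
#' @export
predict.cnn_fit <- function(object, patches, ...) {
  pm <- as_patch_matrix(patches, object$standardize %||% TRUE)
  if (pm$k != object$k)
    stopf("model expects %d patch(es) per subject, got %d", object$k, pm$k)
  if (!all(pm$dims == object$dims))
    stopf("patch dims %s do not match the model's %s",
          paste(pm$dims, collapse = "x"), paste(object$dims, collapse = "x"))
  pr <- cpp_cnn_forward(object$conv_w, object$conv_b, object$fc_w,
                        object$fc_b, pm$X, object$dims, object$k,
                        object$spec$kernel)
  pr$prob[, 2]
}
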