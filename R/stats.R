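#' Per-group PI summary and progressive-vs-stable contrast
#'
#' Summarizes the Progressive Index by group tag and compares progressive
#' (label 1) against stable (label 0) subjects with a linear model of PI on
#' group. Unadjusted, the contrast is exactly the classical pooled-variance
#' two-sample t statistic; with covariates it is the Wald test of the group
#' coefficient in `pi ~ group + covariates`.
#'
#' @param table a `pi_table` (see [score_cohort()]).
#' @param covariates optional data frame keyed by `subject_id`.
#' @param adjust character vector of covariate columns to adjust for.
#' @return a list with `group_summary` (n/mean/sd per group tag) and
#'   `contrast` (estimate for progressive minus stable, statistic, df, p).
#' @export
group_pi_summary <- function(table, covariates = NULL, adjust = NULL) {
  ok <- table[!is.na(table$pi), , drop = FALSE]
  gs <- do.call(rbind, lapply(split(ok$pi, ok$group), function(v) {
    data.frame(n = length(v), mean = mean(v), sd = stats::sd(v))
  }))
  gs <- data.frame(group = rownames(gs), gs, row.names = NULL,
                   stringsAsFactors = FALSE)

  known <- ok[!is.na(ok$label), , drop = FALSE]
  if (any(table(known$label) < 2) || length(unique(known$label)) < 2)
    stopf("contrast needs at least 2 subjects in each of the stable and progressive groups")
  d <- data.frame(pi = known$pi,
                  progressive = factor(known$label, levels = c(0, 1)))
  terms <- "progressive"
  if (!is.null(adjust) && length(adjust)) {
    if (is.null(covariates)) stopf("covariates table required to adjust for %s",
                                   paste(adjust, collapse = ", "))
    miss <- setdiff(adjust, names(covariates))
    if (length(miss)) stopf("missing covariate column(s): %s",
                            paste(miss, collapse = ", "))
    m <- match(known$subject_id, covariates$subject_id)
    if (anyNA(m)) stopf("covariates missing for %d subject(s)", sum(is.na(m)))
    d <- cbind(d, covariates[m, adjust, drop = FALSE])
    terms <- c(terms, adjust)
  }
  fit <- lm(as.formula(paste("pi ~", paste(terms, collapse = " + "))), data = d)
  sfit <- suppressWarnings(summary(fit))
  sm <- sfit$coefficients
  row <- grep("^progressive1$", rownames(sm))
  est <- unname(sm[row, 1])
  stat <- unname(sm[row, 3])
  pval <- unname(sm[row, 4])
  if (!is.finite(stat) || sfit$sigma < 1e-10) {  # (near-)zero residual variance
    stat <- if (abs(est) < 1e-12) 0 else sign(est) * Inf
    pval <- if (abs(est) < 1e-12) 1 else 0
  }
  contrast <- list(estimate = est,
                   statistic = stat,
                   df = fit$df.residual,
                   p = pval,
                   adjusted_for = adjust %||% character(0),
                   n = nrow(d))
  list(group_summary = gs, contrast = contrast)
}

#' Covariate-adjusted binary logistic regression with odds ratios
#'
#' Maximum-likelihood logistic fit of a 0/1 outcome on the named predictor
#' columns, reporting per-term coefficients, Wald standard errors, odds
#' ratios (`exp(coef)`) with 95% Wald confidence intervals, and p-values.
#' Rows with missing values in the outcome or any predictor are dropped
#' (complete-case) and counted. Perfect separation is flagged as
#' non-converged.
#'
#' @param data data frame holding the outcome and predictors.
#' @param outcome name of the 0/1 outcome column.
#' @param terms character vector of predictor column names; empty fits an
#'   intercept-only model.
#' @return an object of class `logistic_fit`.
#' @export
fit_logistic <- function(data, outcome, terms = character(0)) {
  miss <- setdiff(c(outcome, terms), names(data))
  if (length(miss)) stopf("column(s) not found in data: %s",
                          paste(miss, collapse = ", "))
  use <- data[, c(outcome, terms), drop = FALSE]
  cc <- complete.cases(use)
  use <- use[cc, , drop = FALSE]
  y <- use[[outcome]]
  if (!all(y %in% c(0, 1))) stopf("outcome must be 0/1")
  if (length(unique(y)) < 2) stopf("outcome is constant; logistic model undefined")
  if (nrow(use) < length(terms) + 1)
    stopf("too few complete-case rows (%d) for %d predictors", nrow(use), length(terms))
  fml <- if (length(terms)) paste(outcome, "~", paste(terms, collapse = " + "))
         else paste(outcome, "~ 1")
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(as.formula(fml), data = use, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  # quasi-separation can also surface as numerically saturated probabilities
  if (length(terms) && (any(fitted(fit) > 1 - 1e-8) || any(fitted(fit) < 1e-8)))
    separation <- TRUE
  sm <- summary(fit)$coefficients
  z <- qnorm(0.975)
  tab <- data.frame(term = rownames(sm),
                    estimate = sm[, 1], std_error = sm[, 2],
                    odds_ratio = exp(sm[, 1]),
                    or_ci_lo = exp(sm[, 1] - z * sm[, 2]),
                    or_ci_hi = exp(sm[, 1] + z * sm[, 2]),
                    p = sm[, 4], row.names = NULL, stringsAsFactors = FALSE)
  structure(list(terms = tab, converged = fit$converged && !separation,
                 separation = separation,
                 n_used = nrow(use), n_dropped = sum(!cc),
                 fitted = unname(fitted(fit)), outcome = y,
                 formula = fml, model = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic model %s (n = %d, dropped %d)%s\n", x$formula,
              x$n_used, x$n_dropped,
              if (!x$converged) " [NOT CONVERGED / separation]" else ""))
  print(x$terms, digits = 4)
  invisible(x)
}

#' ROC curve and AUC with a stratified bootstrap confidence interval
#'
#' The point AUC is the rank-sum AUC of [compute_auc()] (so any strictly
#' monotone transform of the scores leaves it unchanged); the 95% CI is the
#' 2.5/97.5 percentile interval of AUCs over seeded bootstrap resamples
#' drawn within each class.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @param n_boot number of bootstrap resamples (default 2000).
#' @param seed integer seed for the resampling.
#' @return an object of class `roc_result` with the threshold/sensitivity/
#'   specificity staircase, `auc`, and `ci95`.
#' @export
roc_with_ci <- function(scores, labels, n_boot = 2000L, seed = 1L) {
  auc <- compute_auc(scores, labels)   # validates inputs
  if (n_boot < 1) stopf("n_boot must be >= 1")
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bp <- sample(pos, replace = TRUE)
      bn <- sample(neg, replace = TRUE)
      compute_auc(c(bp, bn), rep(c(1, 0), c(length(bp), length(bn))))
    }, numeric(1))
  })
  ci <- unname(quantile(boot, c(0.025, 0.975)))
  structure(list(thresholds = thr, sensitivities = sens, specificities = spec,
                 auc = auc, ci95 = ci, n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (95%% CI %.4f-%.4f, %d bootstrap resamples)\n",
              x$auc, x$ci95[1], x$ci95[2], x$n_boot))
  invisible(x)
}

#' Evaluate the PI combined with clinical covariates
#'
#' Fits `outcome ~ PI + clinical terms` by logistic regression on the
#' known-label rows of a PI table merged with a covariate table, then
#' computes the ROC/AUC of the in-sample fitted probabilities (apparent
#' performance, as typically reported for such combined models). PI enters
#' the model on a 0-100 scale by default (`pi_scale = 100`) so its per-unit
#' odds ratio refers to one PI percentage point.
#'
#' @param pi_table a `pi_table`.
#' @param covariates covariate data frame keyed by `subject_id`.
#' @param formula_terms character vector of covariate columns to combine
#'   with the PI.
#' @param n_boot,seed bootstrap settings for the ROC CI.
#' @param pi_scale multiplier applied to PI before it enters the model.
#' @return a list of class `combined_model_eval`: `fit` (a `logistic_fit`),
#'   `roc` (a `roc_result` of the fitted probabilities), and `pi_scale`.
#' @export
combined_model_eval <- function(pi_table, covariates,
                                formula_terms = character(0),
                                n_boot = 2000L, seed = 1L, pi_scale = 100) {
  known <- pi_table[!is.na(pi_table$label) & !is.na(pi_table$pi), , drop = FALSE]
  if (nrow(known) == 0) stopf("no labeled, scored subjects")
  m <- match(known$subject_id, covariates$subject_id)
  if (anyNA(m)) stopf("covariates missing for %d subject(s)", sum(is.na(m)))
  miss <- setdiff(formula_terms, names(covariates))
  if (length(miss)) stopf("column(s) not found in data: %s",
                          paste(miss, collapse = ", "))
  d <- cbind(data.frame(label = known$label, pi = known$pi * pi_scale),
             covariates[m, setdiff(names(covariates), "subject_id"), drop = FALSE])
  fit <- fit_logistic(d, "label", c("pi", formula_terms))
  roc <- roc_with_ci(fit$fitted, fit$outcome, n_boot = n_boot, seed = seed)
  structure(list(fit = fit, roc = roc, pi_scale = pi_scale),
            class = "combined_model_eval")
}

#' Partial Pearson correlation controlling for one covariate
#'
#' Correlates the residuals of `x` and `y` after linear regression of each
#' on the covariate; the p-value uses the t transform with `n - 3` degrees
#' of freedom.
#'
#' @param x,y numeric vectors.
#' @param covariate numeric vector (e.g. age).
#' @return a list with `estimate` (partial r), `p.value`, `n`.
#' @export
partial_pearson <- function(x, y, covariate) {
  n <- length(x)
  if (length(y) != n || length(covariate) != n) stopf("inputs differ in length")
  if (n < 4) stopf("need n >= 4 for a partial correlation")
  if (anyNA(c(x, y, covariate)) || !all(is.finite(c(x, y, covariate))))
    stopf("inputs must be finite and non-missing")
  rx <- resid(lm(x ~ covariate))
  ry <- resid(lm(y ~ covariate))
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12)
    stopf("partial correlation undefined: zero residual variance")
  r <- max(-1, min(1, stats::cor(rx, ry)))
  df <- n - 3
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt(df / (1 - r^2))
    2 * pt(-abs(t), df)
  }
  list(estimate = r, p.value = p, n = n)
}
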