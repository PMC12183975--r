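make_pi_table <- function(pi, label, group = "g",
                          id = sprintf("s%03d", seq_along(pi))) {
  tab <- data.frame(subject_id = id, group = group, label = label, pi = pi,
                    failed = FALSE, note = "")
  class(tab) <- c("pi_table", "data.frame")
  tab
}

test_that("the unadjusted group contrast equals the pooled two-sample t-test", {
  tab <- make_pi_table(c(0.1, 0.2, 0.3, 0.4), c(0, 0, 1, 1))
  gs <- group_pi_summary(tab)
  expect_equal(abs(gs$contrast$statistic), 2 * sqrt(2), tolerance = 1e-9)
  tt <- t.test(c(0.3, 0.4), c(0.1, 0.2), var.equal = TRUE)
  expect_equal(gs$contrast$p, tt$p.value, tolerance = 1e-9)
  expect_equal(gs$contrast$estimate, 0.2, tolerance = 1e-12)

  pis <- withr::with_seed(31, runif(40))
  labs <- rep(0:1, 20)
  gs2 <- group_pi_summary(make_pi_table(pis, labs))
  tt2 <- t.test(pis[labs == 1], pis[labs == 0], var.equal = TRUE)
  expect_equal(gs2$contrast$p, tt2$p.value, tolerance = 1e-9)
})

test_that("identical groups give a zero statistic with p = 1", {
  tab <- make_pi_table(rep(0.3, 6), rep(0:1, 3))
  gs <- group_pi_summary(tab)
  expect_equal(gs$contrast$statistic, 0)
  expect_equal(gs$contrast$p, 1)
})

test_that("an orthogonal covariate leaves the group effect unchanged", {
  pis <- withr::with_seed(5, runif(40))
  labs <- rep(0:1, each = 20)
  z <- rep(c(-1, 1), 20)            # balanced across groups -> orthogonal
  cov <- data.frame(subject_id = sprintf("s%03d", 1:40), z = z)
  tab <- make_pi_table(pis, labs)
  gs0 <- group_pi_summary(tab)
  gs1 <- group_pi_summary(tab, covariates = cov, adjust = "z")
  expect_equal(gs1$contrast$estimate, gs0$contrast$estimate, tolerance = 1e-8)
  expect_error(group_pi_summary(tab, covariates = cov, adjust = "missing_col"),
               "missing_col")
})

test_that("logistic fits reproduce closed-form 2x2 and intercept-only results", {
  d <- data.frame(y = rep(c(1, 0, 1, 0), c(30, 10, 10, 30)),
                  x = rep(c(1, 0), c(40, 40)))
  fit <- fit_logistic(d, "y", "x")
  or <- fit$terms$odds_ratio[fit$terms$term == "x"]
  expect_equal(or, 9.0, tolerance = 1e-6)
  expect_equal(log(or), fit$terms$estimate[fit$terms$term == "x"],
               tolerance = 1e-9)
  d0 <- data.frame(y = rep(c(1, 0), c(10, 30)))
  fit0 <- fit_logistic(d0, "y")
  expect_equal(fit0$terms$estimate[1], log(1 / 3), tolerance = 1e-8)
  expect_error(fit_logistic(data.frame(y = rep(1, 10)), "y"), "constant")
  expect_error(fit_logistic(d, "y", "nope"), "nope")
})

test_that("logistic coefficients match an independent convex-optimizer oracle", {
  negll <- function(beta, X, y) {
    eta <- X %*% beta
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  for (s in 1:20) {
    d <- withr::with_seed(400 + s, {
      n <- 60
      x1 <- rnorm(n)
      x2 <- rnorm(n)
      y <- rbinom(n, 1, plogis(-0.3 + 0.6 * x1 - 0.4 * x2))
      data.frame(y = y, x1 = x1, x2 = x2)
    })
    if (length(unique(d$y)) < 2) next
    fit <- fit_logistic(d, "y", c("x1", "x2"))
    X <- cbind(1, d$x1, d$x2)
    opt <- optim(c(0, 0, 0), negll, X = X, y = d$y, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    expect_equal(unname(fit$terms$estimate), unname(opt$par), tolerance = 1e-5)
  }
})

test_that("the logistic slope is recovered from simulated data", {
  d <- withr::with_seed(77, {
    x <- rnorm(2000)
    data.frame(y = rbinom(2000, 1, plogis(-1 + 0.8 * x)), x = x)
  })
  fit <- fit_logistic(d, "y", "x")
  expect_lt(abs(fit$terms$estimate[fit$terms$term == "x"] - 0.8), 0.15)
  expect_true(fit$converged)
})

test_that("perfect separation is flagged rather than reported as converged", {
  d <- data.frame(y = rep(0:1, each = 10), x = c(rnorm(10), rnorm(10) + 50))
  fit <- fit_logistic(d, "y", "x")
  expect_true(fit$separation)
  expect_false(fit$converged)
})

test_that("ROC point AUC is rank-based and the bootstrap CI behaves", {
  sc <- c(0.9, 0.8, 0.7, 0.1, 0.2, 0.3)
  y <- rep(c(1, 0), each = 3)
  r <- roc_with_ci(sc, y, n_boot = 200, seed = 5)
  expect_equal(r$auc, 1.0)
  # invariance under strictly monotone transforms
  sc2 <- withr::with_seed(9, rnorm(40))
  y2 <- rep(0:1, 20)
  expect_equal(roc_with_ci(exp(2 * sc2), y2, 10, 1)$auc,
               compute_auc(sc2, y2), tolerance = 1e-12)
  # coverage of the point estimate across seeded trials
  inside <- vapply(1:100, function(s) {
    dat <- withr::with_seed(6000 + s, {
      list(sc = c(rnorm(25, 0.8), rnorm(25)), y = rep(c(1, 0), each = 25))
    })
    r <- roc_with_ci(dat$sc, dat$y, n_boot = 300, seed = s)
    r$ci95[1] <= r$auc && r$auc <= r$ci95[2]
  }, logical(1))
  expect_gte(mean(inside), 0.99)
  expect_error(roc_with_ci(c(1, 2), c(1, 1), 10, 1), "undefined")
})

test_that("rank-sum AUC agrees with an established ROC implementation", {
  for (s in 1:10) {
    dat <- withr::with_seed(7000 + s, {
      list(sc = sample(seq(0, 1, 0.05), 40, replace = TRUE),
           y = c(0, 1, sample(0:1, 38, replace = TRUE)))
    })
    expect_equal(compute_auc(dat$sc, dat$y),
                 as.numeric(pROC::auc(pROC::roc(dat$y, dat$sc, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("combining PI with covariates never hurts in-sample AUC", {
  n <- 200
  base <- withr::with_seed(88, {
    pii <- runif(n)
    label <- rbinom(n, 1, plogis(-2 + 4 * pii))
    list(pi = pii, label = label,
         cov = data.frame(subject_id = sprintf("s%03d", 1:n),
                          age = rnorm(n, 72, 5), noise = rnorm(n)))
  })
  tab <- make_pi_table(base$pi, base$label)
  alone <- combined_model_eval(tab, base$cov, character(0), n_boot = 50, seed = 2)
  plus <- combined_model_eval(tab, base$cov, c("age", "noise"),
                              n_boot = 50, seed = 2)
  expect_gte(plus$roc$auc, alone$roc$auc - 1e-9)
  noise_only <- combined_model_eval(tab, base$cov, "noise", n_boot = 50, seed = 2)
  expect_lt(abs(noise_only$roc$auc - alone$roc$auc), 0.05)
  expect_error(combined_model_eval(tab, base$cov, "absent"), "absent")
})

test_that("partial correlation matches the textbook three-variable formula", {
  # hand dataset, n = 5
  x <- c(1.2, 0.8, 2.4, 3.1, 2.0)
  y <- c(0.9, 1.1, 2.2, 2.8, 2.1)
  z <- c(10, 12, 9, 14, 11)
  pp <- partial_pearson(x, y, z)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(pp$estimate, oracle, tolerance = 1e-10)
  expect_equal(pp$n, 5)

  w <- withr::with_seed(3, rnorm(30))
  expect_equal(partial_pearson(w, w, rnorm(30))$estimate, 1.0)
  # x purely driven by the covariate decorrelates after residualization
  dat <- withr::with_seed(12, {
    cv <- rnorm(50)
    list(x = 2 * cv + rnorm(50, 0, 1e-8), y = rnorm(50), cv = cv)
  })
  expect_lt(abs(partial_pearson(dat$x, dat$y, dat$cv)$estimate), 0.3)
  expect_error(partial_pearson(1:3, 1:3, 1:3), "n >= 4")
  expect_error(partial_pearson(c(1, 2, 3, 4), 2 * c(1, 2, 3, 4), c(1, 2, 3, 4)),
               "zero residual")
})
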