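test_that("backbone_spec validates layer/channel consistency", {
  spec <- backbone_spec()
  expect_equal(spec$n_conv_layers, 5L)
  expect_equal(spec$channels, c(16L, 32L, 64L, 64L, 64L))
  expect_error(backbone_spec(5, c(16, 32)), "must equal")
  expect_error(backbone_spec(2, c(4, 0)), ">= 1")
  expect_error(backbone_spec(2, c(4, 4), kernel = c(2, 3, 3)), "odd")
})

test_that("seeded initialization is reproducible and correctly shaped", {
  b1 <- build_backbone(micro_spec(), 42)
  b2 <- build_backbone(micro_spec(), 42)
  b3 <- build_backbone(micro_spec(), 43)
  expect_identical(b1$conv_w, b2$conv_w)
  expect_false(identical(b1$conv_w, b3$conv_w))
  expect_equal(dim(b1$conv_w[[1]]), c(2L, 27L))
  expect_equal(dim(b1$conv_w[[2]]), c(3L, 54L))
})

test_that("parameter counts match the closed-form oracle", {
  # default: kernel 27, input channel chain 1,16,32,64,64
  bb <- build_backbone(backbone_spec(), 1)
  cin <- c(1, 16, 32, 64, 64)
  cout <- c(16, 32, 64, 64, 64)
  expect_equal(backbone_n_params(bb), sum(27 * cin * cout + cout))
  mb <- build_backbone(micro_spec(), 1)
  expect_equal(backbone_n_params(mb), (27 * 1 * 2 + 2) + (27 * 2 * 3 + 3))
})

test_that("forward pass is deterministic and rejects undersized patches", {
  bb <- build_backbone(tiny_spec(), 5)
  p <- rand_volume(c(16, 16, 16), seed = 8)
  f1 <- backbone_forward(bb, p)
  f2 <- backbone_forward(bb, p)
  expect_identical(f1, f2)
  expect_length(f1, 4)
  expect_error(backbone_forward(bb, rand_volume(c(8, 8, 8), seed = 1)),
               "survive")
})

test_that("zero parameters map any patch to zero features", {
  bb <- build_backbone(tiny_spec(), 5)
  bb$conv_w <- lapply(bb$conv_w, function(w) w * 0)
  bb$conv_b <- lapply(bb$conv_b, function(b) b * 0)
  f <- backbone_forward(bb, rand_volume(c(16, 16, 16), seed = 8))
  expect_true(all(f == 0))
})

test_that("standardization makes features invariant to constant shifts", {
  bb <- build_backbone(tiny_spec(), 5)
  p <- rand_volume(c(16, 16, 16), seed = 8)
  expect_equal(backbone_forward(bb, p, standardize = TRUE),
               backbone_forward(bb, p + 3.7, standardize = TRUE),
               tolerance = 1e-12)
})

test_that("cross-entropy matches its closed form and validates labels", {
  expect_lt(cross_entropy(1, 1.0), 1e-6)
  expect_equal(cross_entropy(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(cross_entropy(0, 0.5), log(2), tolerance = 1e-12)
  expect_error(cross_entropy(2, 0.5), "label")
  # brute-force agreement on a grid
  for (y in c(0, 1)) for (p in seq(0.05, 0.95, by = 0.09)) {
    expect_equal(cross_entropy(y, p),
                 -(y * log(p) + (1 - y) * log(1 - p)), tolerance = 1e-9)
  }
})

test_that("the softmax head returns complementary class probabilities", {
  spec <- micro_spec()
  bb <- build_backbone(spec, 3)
  fc_w <- withr::with_seed(4, matrix(rnorm(2 * 2 * 3, 0, 2), 2))
  X <- withr::with_seed(5, matrix(rnorm(64 * 20), 64, 20))
  pr <- roiprog:::cpp_cnn_forward(bb$conv_w, bb$conv_b, fc_w, c(0.3, -0.2),
                                  X, c(4L, 4L, 4L), 2L, spec$kernel)
  expect_true(all(abs(rowSums(pr$prob) - 1) < 1e-6))
})

test_that("analytic gradients agree with finite differences", {
  spec <- micro_spec()
  bb <- build_backbone(spec, 11)
  fc_w <- withr::with_seed(12, matrix(rnorm(12, 0, 0.5), 2))
  fc_b <- c(0.1, -0.2)
  X <- withr::with_seed(13, matrix(rnorm(64 * 8), 64, 8))
  y <- rep(c(0L, 1L), 2)
  g <- roiprog:::cpp_cnn_loss_grad(bb$conv_w, bb$conv_b, fc_w, fc_b, X, y,
                                   c(4L, 4L, 4L), 2L, spec$kernel, 1e-7)
  lossfun <- function(cw, cb, fw, fb) {
    roiprog:::cpp_cnn_loss_grad(cw, cb, fw, fb, X, y, c(4L, 4L, 4L), 2L,
                                spec$kernel, 1e-7)$loss
  }
  eps <- 1e-6
  idx <- withr::with_seed(14, lapply(1:2, function(l)
    sample(length(bb$conv_w[[l]]), 5)))
  for (l in 1:2) {
    for (i in idx[[l]]) {
      cw <- bb$conv_w
      cw[[l]][i] <- cw[[l]][i] + eps
      fd <- (lossfun(cw, bb$conv_b, fc_w, fc_b) - g$loss) / eps
      expect_equal(fd, g$d_conv_w[[l]][i], tolerance = 1e-4)
    }
  }
  for (i in seq_along(fc_w)) {
    fw <- fc_w
    fw[i] <- fw[i] + eps
    fd <- (lossfun(bb$conv_w, bb$conv_b, fw, fc_b) - g$loss) / eps
    expect_equal(fd, g$d_fc_w[i], tolerance = 1e-4)
  }
})

test_that("training reduces the loss on separable data and reproduces itself", {
  n <- 24
  patches <- rand_volume(c(16, 16, 16, n), seed = 31, sd = 0.1)
  y <- rep(0:1, each = n / 2)
  for (i in which(y == 1)) patches[5:12, 5:12, 5:12, i] <-
      patches[5:12, 5:12, 5:12, i] - 0.8
  cfg <- train_config(epochs = 8, seed = 3, batch_size = 4)
  fit1 <- train_classifier(patches, y, tiny_spec(), cfg)
  expect_lt(tail(fit1$report$train_loss, 1), fit1$report$train_loss[1])
  expect_true(all(is.finite(fit1$report$train_loss)))
  expect_true(all(fit1$report$train_loss >= 0))
  fit2 <- train_classifier(patches, y, tiny_spec(), cfg)
  expect_identical(fit1$conv_w, fit2$conv_w)
  expect_identical(fit1$fc_w, fit2$fc_w)
  expect_identical(fit1$report$train_loss, fit2$report$train_loss)
  expect_error(train_classifier(patches, rep(1, n), tiny_spec(), cfg),
               "both classes")
})
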