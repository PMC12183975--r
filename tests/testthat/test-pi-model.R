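test_that("MRNet construction shares one backbone across K branches", {
  m <- build_mrnet(1:10, backbone_spec(), 1)
  expect_equal(dim(m$fc_w), c(2L, 640L))          # 10 x 64 concatenated
  expect_equal(m$k, 10L)
  m1 <- build_mrnet(5L, backbone_spec(), 1, patch_size = 32)
  expect_equal(dim(m1$fc_w), c(2L, 64L))          # degenerate K=1 = SRNet shape
  expect_error(build_mrnet(c(1, 1, 2), backbone_spec(), 1), "distinct")

  # identical patches fed to two branches produce identical branch features
  spec <- tiny_spec()
  m2 <- build_mrnet(c(3L, 7L), spec, 9, patch_size = 16)
  p <- rand_volume(c(16, 16, 16), seed = 2)
  X <- cbind(as.numeric(p), as.numeric(p))
  pr <- roiprog:::cpp_cnn_forward(m2$conv_w, m2$conv_b, m2$fc_w, m2$fc_b,
                                  X, c(16L, 16L, 16L), 2L, spec$kernel,
                                  return_features = TRUE)
  cl <- spec$channels[5]
  expect_equal(pr$features[1, 1:cl], pr$features[1, (cl + 1):(2 * cl)])
  # perturbing the shared backbone changes every branch's features
  m3 <- m2
  m3$conv_w[[1]] <- m3$conv_w[[1]] + 0.05
  pr3 <- roiprog:::cpp_cnn_forward(m3$conv_w, m3$conv_b, m3$fc_w, m3$fc_b,
                                   X, c(16L, 16L, 16L), 2L, spec$kernel,
                                   return_features = TRUE)
  expect_false(isTRUE(all.equal(pr$features[1, 1:cl], pr3$features[1, 1:cl])))
  expect_false(isTRUE(all.equal(pr$features[1, (cl + 1):(2 * cl)],
                                pr3$features[1, (cl + 1):(2 * cl)])))
})

test_that("subject_patches extracts the stored ROI order deterministically", {
  atlas <- make_phantom_atlas(c(32, 32, 32), 6, 3, seed = 3)
  vol <- simulate_subject(atlas, 0, effect_spec(integer(), 0, 0, 0.1), seed = 4)
  ps <- subject_patches(vol, atlas, c(5L, 2L, 4L), size = 16)
  expect_equal(dim(ps), c(16, 16, 16, 3))
  expect_equal(attr(ps, "roi_labels"), c(5L, 2L, 4L))
  expect_identical(ps, subject_patches(vol, atlas, c(5L, 2L, 4L), size = 16))
  expect_error(subject_patches(vol, atlas, c(5L, 99L), size = 16), "not present")
  # a patch centered near the border carries the zero padding of extract_patch
  border_atlas <- array(0L, c(32, 32, 32))
  border_atlas[1:2, 15:16, 15:16] <- 9L
  pb <- subject_patches(vol, border_atlas, 9L, size = 16)
  expect_equal(dim(pb), c(16, 16, 16, 1))
  expect_true(all(pb[1:7, , , 1] == 0))   # window overhangs x < 0
})

test_that("the Progressive Index is a symmetric, bounded probability", {
  m <- build_mrnet(c(1L, 2L), micro_spec(), 5, patch_size = 4)
  m$fc_w <- m$fc_w * 0
  m$fc_b <- c(0, 0)
  p <- withr::with_seed(6, array(rnorm(4^3 * 2), c(4, 4, 4, 2)))
  expect_equal(progressive_index(m, p), 0.5)
  m2 <- build_mrnet(c(1L, 2L), micro_spec(), 5, patch_size = 4)
  for (s in 1:50) {
    ps <- withr::with_seed(600 + s, array(rnorm(4^3 * 2, 0, 3), c(4, 4, 4, 2)))
    pi <- progressive_index(m2, ps)
    expect_gte(pi, 0)
    expect_lte(pi, 1)
  }
  expect_error(progressive_index(m2, withr::with_seed(1, array(rnorm(4^3 * 3),
                                                               c(4, 4, 4, 3)))),
               "expects 2")
})

test_that("MRNet training separates a planted cohort and reproduces itself", {
  d <- tempfile("mrnet")
  co <- make_small_cohort(d, seed = 17, n_per_class = 16L)
  atlas <- load_atlas(co$atlas_path, c(32, 32, 32))
  cfg <- train_config(epochs = 14, seed = 21, batch_size = 4,
                      validation_fraction = 0.25)
  fit <- train_mrnet(co$manifest, atlas, c(1L, 3L, 5L), spec = tiny_spec(),
                     cfg = cfg, patch_size = 16L)
  expect_equal(fit$selected_rois, c(1L, 3L, 5L))
  expect_gte(fit$report$val_auc, 0.7)
  fit2 <- train_mrnet(co$manifest, atlas, c(1L, 3L, 5L), spec = tiny_spec(),
                      cfg = cfg, patch_size = 16L)
  expect_identical(fit$conv_w, fit2$conv_w)
  expect_identical(fit$fc_w, fit2$fc_w)

  pt <- score_cohort(fit, co$manifest, atlas)
  expect_equal(nrow(pt), nrow(co$manifest))
  expect_true(all(pt$pi >= 0 & pt$pi <= 1, na.rm = TRUE))
  expect_false(any(pt$failed))
  expect_gt(mean(pt$pi[pt$label == 1]), mean(pt$pi[pt$label == 0]))
  expect_identical(pt, score_cohort(fit, co$manifest, atlas))

  # a corrupt image fails its row only, the cohort run continues
  m_bad <- co$manifest
  m_bad$image_path[2] <- tempfile(fileext = ".nii")
  pt_bad <- score_cohort(fit, m_bad, atlas)
  expect_true(pt_bad$failed[2])
  expect_true(is.na(pt_bad$pi[2]))
  expect_false(any(pt_bad$failed[-2]))
  unlink(d, recursive = TRUE)
})

test_that("threshold metrics follow the overall-mean rule with ties positive", {
  tab <- data.frame(subject_id = letters[1:4], group = "g",
                    label = c(0, 0, 1, 1), pi = c(0.2, 0.3, 0.6, 0.7),
                    failed = FALSE, note = "")
  class(tab) <- c("pi_table", "data.frame")
  tm <- threshold_metrics(tab)
  expect_equal(tm$threshold, 0.45)
  expect_equal(tm$sensitivity, 1.0)
  expect_equal(tm$specificity, 1.0)
  expect_equal(unname(tm$counts), c(2L, 0L, 2L, 0L))
  expect_equal(tm$auc, compute_auc(tab$pi, tab$label))

  # unknown-label rows enter the threshold but not the counts
  tab2 <- rbind(tab, data.frame(subject_id = "e", group = "r", label = NA,
                                pi = 1.0, failed = FALSE, note = ""))
  class(tab2) <- c("pi_table", "data.frame")
  tm2 <- threshold_metrics(tab2)
  expect_equal(tm2$threshold, mean(c(0.2, 0.3, 0.6, 0.7, 1.0)))
  expect_equal(sum(tm2$counts), 4)

  # all-equal PI classifies everyone positive under the >= rule
  tab3 <- tab
  tab3$pi <- 0.4
  tm3 <- threshold_metrics(tab3)
  expect_equal(tm3$sensitivity, 1.0)
  expect_equal(tm3$specificity, 0.0)

  tab4 <- tab
  tab4$label <- NA
  expect_error(threshold_metrics(tab4), "both classes")

  tm5 <- threshold_metrics(tab, threshold_mode = "fixed", value = 0.65)
  expect_equal(tm5$sensitivity, 0.5)
})

test_that("stage plot data sorts subjects by group then PI", {
  tab <- data.frame(subject_id = letters[1:6], group = c("pNC", "sNC", "pNC",
                                                         "sNC", "rNC", "rNC"),
                    label = c(1, 0, 1, 0, NA, NA),
                    pi = c(0.9, 0.1, 0.5, 0.2, 0.4, 0.3),
                    failed = FALSE, note = "")
  sp <- stage_plot_data(tab, group_order = c("sNC", "pNC", "rNC"))
  expect_equal(sp$index, 1:6)
  expect_equal(sp$subject_id, c("b", "d", "c", "a", "f", "e"))
})
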