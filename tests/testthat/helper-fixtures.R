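# Shared fixtures: everything is generated programmatically at test time.

# micro backbone for architecture/math checks (2 layers -> 4^3 patches)
micro_spec <- function() backbone_spec(2L, c(2L, 3L))

# small fast backbone for functional tests (5 layers -> 16^3 patches)
tiny_spec <- function() backbone_spec(5L, c(2L, 4L, 4L, 4L, 4L))

# a small planted-signal cohort on disk; label 1 subjects have a darker ROI 1
make_small_cohort <- function(dir, seed = 7L, n_per_class = 12L,
                              shift = 0.6, noise = 0.2) {
  simulate_cohort(dir, shape = c(32L, 32L, 32L), n_rois = 6L, roi_radius = 3L,
                  effect = effect_spec(1L, intensity_shift = shift,
                                       erosion_fraction = 0, noise_sd = noise),
                  n_per_group = c(pMCI = n_per_class, sMCI = n_per_class),
                  seed = seed)
}

load_atlas <- function(path, shape) {
  array(as.integer(round(load_nifti_volume(path))), shape)
}

# deterministic random 3D array
rand_volume <- function(shape, seed = 1, sd = 1) {
  withr::with_seed(seed, array(rnorm(prod(shape), 0, sd), dim = shape))
}

# minimal end-to-end pipeline configuration (18 subjects, 6 ROIs)
tiny_config <- function(dir, seed = 42L) {
  list(
    master_seed = seed,
    output_dir = dir,
    synthetic = list(shape = c(32L, 32L, 32L), n_rois = 6L, roi_radius = 3L,
                     informative_labels = c(1L, 2L), intensity_shift = 0.5,
                     erosion_fraction = 0, noise_sd = 0.2,
                     n_per_group = list(pNC = 4L, sNC = 4L, pSCD = 4L,
                                        sSCD = 4L, rNC = 2L)),
    backbone = list(n_conv_layers = 5L, channels = c(2L, 4L, 4L, 4L, 4L),
                    kernel = c(3L, 3L, 3L)),
    patch_size = 16L,
    screen = list(k = 3L, n_splits = 1L),
    train = list(epochs_screen = 2L, epochs_mrnet = 2L, batch_size = 4L,
                 learning_rate = 1e-3, validation_fraction = 0.25),
    stats = list(n_boot = 50L,
                 models = list(unadjusted = character(0),
                               m1 = c("age", "gender", "education")),
                 combined_terms = c("age", "gender", "education",
                                    "assoc_memory"))
  )
}

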