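#' Specify the planted class effect of a phantom cohort
#'
#' Describes how the progressive (positive) class differs from the stable
#' (negative) class inside a chosen set of "informative" ROIs. Atrophy is
#' emulated as an intensity decrease plus erosion of the ROI boundary; both
#' are expressed relative to the fixed base intensities of the phantom
#' (background 0.2, ROI tissue 1.0), so effect sizes are comparable across
#' simulations.
#'
#' @param informative_labels integer label ids carrying the class signal.
#' @param intensity_shift intensity subtracted inside informative ROIs for
#'   positive subjects (signal units).
#' @param erosion_fraction fraction in `[0, 1)` of each informative ROI's
#'   outermost voxels (by distance from its centroid) reset to background
#'   for positive subjects — an atrophy proxy.
#' @param noise_sd standard deviation of additive Gaussian voxel noise.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(informative_labels = integer(),
                        intensity_shift = 0,
                        erosion_fraction = 0,
                        noise_sd = 0) {
  if (erosion_fraction < 0 || erosion_fraction >= 1)
    stopf("erosion_fraction must be in [0, 1)")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if ((intensity_shift != 0 || erosion_fraction > 0) &&
      length(informative_labels) == 0)
    stopf("informative_labels must be nonempty when an effect is specified")
  structure(list(informative_labels = as.integer(informative_labels),
                 intensity_shift = intensity_shift,
                 erosion_fraction = erosion_fraction,
                 noise_sd = noise_sd),
            class = "effect_spec")
}

#' Generate a phantom ROI atlas of non-overlapping spheres
#'
#' Places `n_rois` spheres of radius `roi_radius` uniformly at random inside
#' the volume (fully inside the bounds, pairwise disjoint with at least a
#' one-voxel gap), labeled `1..n_rois`. Deterministic for a fixed seed.
#'
#' @param shape integer vector of 3 volume dimensions (voxels).
#' @param n_rois number of spherical ROIs.
#' @param roi_radius sphere radius in voxels.
#' @param seed integer seed.
#' @param max_tries rejection-sampling budget; exceeding it raises a
#'   capacity error (the requested packing is infeasible or too dense).
#' @return a 3D integer label array.
#' @export
make_phantom_atlas <- function(shape, n_rois, roi_radius, seed,
                               max_tries = 1000L * n_rois) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 1)) stopf("shape must be 3 positive integers")
  if (n_rois < 1) stopf("n_rois must be >= 1")
  span <- shape - 2L * roi_radius
  if (any(span < 1))
    stopf("cannot place spheres of radius %d inside volume %s",
          roi_radius, paste(shape, collapse = "x"))
  centers <- with_seed(seed, {
    acc <- matrix(0L, 0, 3)
    tries <- 0L
    min_d2 <- (2 * roi_radius + 1)^2
    while (nrow(acc) < n_rois && tries < max_tries) {
      tries <- tries + 1L
      cand <- c(sample.int(span[1], 1L), sample.int(span[2], 1L),
                sample.int(span[3], 1L)) + roi_radius - 1L  # 0-based
      if (nrow(acc) == 0 ||
          all(rowSums((acc - matrix(cand, nrow(acc), 3, byrow = TRUE))^2) >= min_d2))
        acc <- rbind(acc, cand)
    }
    acc
  })
  if (nrow(centers) < n_rois)
    stopf("could not place %d non-overlapping spheres of radius %d in %s (capacity)",
          n_rois, roi_radius, paste(shape, collapse = "x"))
  # sphere stencil (0-based offsets)
  r <- roi_radius
  offs <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  offs <- offs[rowSums(offs^2) <= r^2, , drop = FALSE]
  atlas <- array(0L, dim = shape)
  for (i in seq_len(n_rois)) {
    vox <- offs + matrix(centers[i, ], nrow(offs), 3, byrow = TRUE)
    lin <- 1L + vox[, 1] + shape[1] * (vox[, 2] + shape[2] * vox[, 3])
    atlas[lin] <- i
  }
  atlas
}

#' Simulate one phantom subject
#'
#' Builds a volume with background intensity 0.2 and ROI tissue intensity
#' 1.0. For a positive subject (`label = 1`), each informative ROI has its
#' intensity reduced by `intensity_shift` and its outermost
#' `erosion_fraction` of voxels (ranked by distance from the ROI centroid,
#' ties broken by voxel index) reset to background. Gaussian noise is added
#' last. Deterministic for a fixed seed.
#'
#' @param atlas 3D integer label array.
#' @param label 0 (stable) or 1 (progressive).
#' @param effect an [effect_spec()].
#' @param seed integer seed (consumed by the noise draw).
#' @return a 3D numeric array.
#' @export
simulate_subject <- function(atlas, label, effect = effect_spec(), seed = 1L) {
  validate_atlas(atlas)
  if (!label %in% c(0, 1)) stopf("label must be 0 or 1")
  vol <- array(0.2, dim = dim(atlas))
  vol[atlas > 0] <- 1.0
  if (label == 1) {
    for (lab in effect$informative_labels) {
      idx <- which(atlas == lab)
      if (length(idx) == 0) stopf("informative label %d not present in atlas", lab)
      vol[idx] <- vol[idx] - effect$intensity_shift
      if (effect$erosion_fraction > 0) {
        cen <- roi_centroid(atlas, lab)
        coords <- arrayInd(idx, dim(atlas)) - 1L
        d2 <- rowSums((coords - matrix(cen, length(idx), 3, byrow = TRUE))^2)
        n_erode <- floor(effect$erosion_fraction * length(idx))
        if (n_erode > 0) {
          ord <- order(-d2, idx)
          vol[idx[ord[seq_len(n_erode)]]] <- 0.2
        }
      }
    }
  }
  if (effect$noise_sd > 0) {
    vol <- vol + with_seed(seed, array(rnorm(length(vol), 0, effect$noise_sd),
                                       dim = dim(vol)))
  }
  vol
}

# group tag -> outcome label: p*/AD -> 1, s* -> 0, anything else (r*, plain
# NC/SCD) -> NA (unknown outcome at follow-up)
group_label <- function(group) {
  ifelse(group == "AD" | startsWith(group, "p"), 1L,
         ifelse(startsWith(group, "s"), 0L, NA_integer_))
}

#' Simulate a labeled phantom cohort on disk
#'
#' Generates a phantom atlas plus one NIfTI volume per subject and writes a
#' manifest CSV, a synthetic covariate CSV, and a JSON sidecar recording the
#' full configuration and seed. Group tags reuse the cohort vocabulary of
#' longitudinal aging studies (`sNC`/`pNC`/`rNC`, `sSCD`/`pSCD`/`rSCD`,
#' `AD`/`sMCI`/`pMCI`): a leading `p` (or `AD`) marks progressive subjects
#' (label 1), a leading `s` stable subjects (label 0), and `r*` subjects with
#' unknown outcome (label NA). Unknown-outcome subjects are generated from
#' the stable model; their label is withheld from the manifest.
#'
#' Per-subject seeds are derived from the master seed, so regeneration with
#' the same configuration is byte-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param shape,n_rois,roi_radius atlas geometry, see [make_phantom_atlas()].
#' @param effect an [effect_spec()].
#' @param n_per_group named integer vector of subjects per group tag,
#'   e.g. `c(AD = 20, sMCI = 20)`.
#' @param seed master integer seed.
#' @param atlas optional precomputed label array to reuse (e.g. to generate
#'   independent train and test cohorts on the same template); by default a
#'   fresh phantom atlas is drawn from the master seed.
#' @param datatype on-disk NIfTI datatype for the volumes.
#' @param covariates if `TRUE` (default), also writes `covariates.csv` with
#'   synthetic age, gender, education, brain-size and associative-memory
#'   columns (memory is depressed in progressive subjects so the
#'   covariate-adjusted models have signal to find).
#' @return (invisibly) a list with the manifest data frame and the paths of
#'   all written artifacts.
#' @export
simulate_cohort <- function(out_dir, shape, n_rois, roi_radius,
                            effect = effect_spec(), n_per_group, seed,
                            atlas = NULL, datatype = "float",
                            covariates = TRUE) {
  if (is.null(names(n_per_group)) || any(names(n_per_group) == ""))
    stopf("n_per_group must be a named vector of group tags")
  dir.create(file.path(out_dir, "volumes"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(file.path(out_dir, "volumes")))
    stopf("cannot create output directory: %s", out_dir)
  if (is.null(atlas)) {
    atlas <- make_phantom_atlas(shape, n_rois, roi_radius,
                                seed = derive_seed(seed, "atlas"))
  } else {
    validate_atlas(atlas)
    if (!all(dim(atlas) == shape)) stopf("supplied atlas does not match shape")
  }
  atlas_path <- file.path(out_dir, "atlas.nii.gz")
  write_nifti_volume(atlas, atlas_path, datatype = "int16")

  rows <- list()
  for (g in names(n_per_group)) {
    for (i in seq_len(n_per_group[[g]])) {
      sid <- sprintf("%s_%03d", g, i)
      lab <- group_label(g)
      gen_lab <- if (is.na(lab)) 0L else lab   # unknowns drawn as stable
      vol <- simulate_subject(atlas, gen_lab, effect,
                              seed = derive_seed(seed, paste0("subject_", sid)))
      vpath <- file.path("volumes", paste0(sid, ".nii.gz"))
      write_nifti_volume(vol, file.path(out_dir, vpath), datatype = datatype)
      rows[[sid]] <- data.frame(subject_id = sid, image_path = vpath,
                                group = g, label = lab,
                                stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  manifest_path <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE, na = "")

  cov_path <- NULL
  if (covariates) {
    cov <- with_seed(derive_seed(seed, "covariates"), {
      n <- nrow(manifest)
      lab <- ifelse(is.na(manifest$label), 0L, manifest$label)
      data.frame(
        subject_id = manifest$subject_id,
        age = round(rnorm(n, 72, 5), 1),
        gender = sample(0:1, n, replace = TRUE),
        education = pmax(0, round(rnorm(n, 12, 3))),
        brain_size = round(rnorm(n, 1400, 80), 1),
        assoc_memory = round(rnorm(n, 10 - 2 * lab, 2), 2),
        stringsAsFactors = FALSE
      )
    })
    cov_path <- file.path(out_dir, "covariates.csv")
    write.csv(cov, cov_path, row.names = FALSE, quote = FALSE)
  }

  config <- list(shape = as.integer(shape), n_rois = n_rois,
                 roi_radius = roi_radius, effect = unclass(effect),
                 n_per_group = as.list(n_per_group), seed = seed,
                 datatype = datatype)
  sidecar <- c(config, list(config_hash = config_hash(config)))
  jsonlite::write_json(sidecar, file.path(out_dir, "cohort_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(manifest = read_manifest(manifest_path),
                 atlas_path = atlas_path,
                 manifest_path = manifest_path,
                 covariates_path = cov_path,
                 config_hash = sidecar$config_hash))
}
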