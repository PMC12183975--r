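#' Read a 3D NIfTI volume
#'
#' Loads a NIfTI file (`.nii` or `.nii.gz`) into a plain 3D numeric array.
#' The voxel size (mm) from the header is kept as the `"voxel_size"`
#' attribute; it is metadata only, all geometry in this package is expressed
#' in voxel indices. Images are assumed to be skull-stripped and spatially
#' normalized to the atlas space upstream.
#'
#' Voxel coordinates throughout the package are 0-based, matching the NIfTI
#' voxel-index convention.
#'
#' @param path path to a NIfTI file containing a 3D image.
#' @return a 3D numeric array with attribute `voxel_size`.
#' @export
load_nifti_volume <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path))
    stopf("cannot read NIfTI file: %s", as.character(path)[1])
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3)
    stopf("expected a 3D image, got %d dimensions: %s", length(dim(a)), path)
  vx <- RNifti::pixdim(img)
  storage.mode(a) <- "double"
  a <- array(a, dim = dim(a))  # strip niftiImage attributes
  attr(a, "voxel_size") <- as.numeric(vx[seq_len(3)])
  a
}

#' Write a 3D volume to NIfTI
#'
#' @param volume 3D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size voxel dimensions in mm (defaults to the array's
#'   `voxel_size` attribute, else 1 mm isotropic).
#' @param datatype on-disk datatype, e.g. `"float"` (default) or `"double"`.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(volume, path,
                               voxel_size = attr(volume, "voxel_size") %||% c(1, 1, 1),
                               datatype = "float") {
  if (length(dim(volume)) != 3) stopf("volume must be a 3D array")
  img <- RNifti::asNifti(array(as.numeric(volume), dim = dim(volume)))
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

validate_atlas <- function(atlas) {
  if (length(dim(atlas)) != 3) stopf("atlas must be a 3D array")
  if (any(atlas < 0) || any(atlas != round(atlas)))
    stopf("atlas labels must be non-negative integers")
  invisible(atlas)
}

#' List the ROIs present in a label atlas
#'
#' Returns one row per distinct nonzero label, sorted by ascending label id,
#' with the voxel count and the integer centroid (0-based voxel indices,
#' per-axis mean rounded half-to-even).
#'
#' @param atlas 3D integer label array; 0 is background.
#' @param lookup optional name table: a data frame with columns `label_id`
#'   and `name` (see [aal116_lookup()]). Labels without an entry are named
#'   `"roi_<id>"`.
#' @return a data frame with columns `label_id`, `name`, `voxel_count`,
#'   `cx`, `cy`, `cz`.
#' @export
list_rois <- function(atlas, lookup = NULL) {
  validate_atlas(atlas)
  idx <- which(atlas != 0)
  if (length(idx) == 0) {
    return(data.frame(label_id = integer(0), name = character(0),
                      voxel_count = integer(0), cx = integer(0),
                      cy = integer(0), cz = integer(0),
                      stringsAsFactors = FALSE))
  }
  labs <- as.integer(atlas[idx])
  coords <- arrayInd(idx, dim(atlas)) - 1L   # 0-based
  sums <- rowsum(coords, labs)               # rows sorted by label
  counts <- as.integer(rowsum(rep(1L, length(labs)), labs))
  ids <- as.integer(rownames(sums))
  cent <- round(sums / counts)               # round half-to-even per axis
  nm <- paste0("roi_", ids)
  if (!is.null(lookup)) {
    m <- match(ids, lookup$label_id)
    nm[!is.na(m)] <- as.character(lookup$name[m[!is.na(m)]])
  }
  data.frame(label_id = ids, name = nm, voxel_count = counts,
             cx = as.integer(cent[, 1]), cy = as.integer(cent[, 2]),
             cz = as.integer(cent[, 3]), stringsAsFactors = FALSE)
}

#' Centroid of one ROI in voxel coordinates
#'
#' The per-axis arithmetic mean of all 0-based voxel indices carrying
#' `label_id`, rounded half-to-even to integers.
#'
#' @param atlas 3D integer label array.
#' @param label_id positive integer label present in the atlas.
#' @return integer vector of 3 voxel indices (0-based).
#' @export
roi_centroid <- function(atlas, label_id) {
  validate_atlas(atlas)
  idx <- which(atlas == label_id)
  if (length(idx) == 0) stopf("label %s not present in atlas", label_id)
  coords <- arrayInd(idx, dim(atlas)) - 1L
  as.integer(round(colMeans(coords)))
}

#' Extract a cubic patch around a voxel
#'
#' Returns the half-open window `[c - floor(size/2), c + ceiling(size/2))`
#' along each axis (0-based center `c`), so an even patch size (the default
#' network input is 32) has a well-defined center voxel. Voxels outside the
#' volume are zero-filled, so centroids near the border are valid.
#'
#' @param volume 3D numeric array.
#' @param center integer vector of 3 voxel indices (0-based); may lie
#'   anywhere, including outside the volume.
#' @param size positive integer edge length in voxels.
#' @param roi_label optional integer label recorded on the patch.
#' @return a `size^3` array with attributes `center`, `size`, `roi_label`.
#' @export
extract_patch <- function(volume, center, size, roi_label = NA_integer_) {
  if (length(dim(volume)) != 3) stopf("volume must be a 3D array")
  if (!is.numeric(size) || length(size) != 1 || size < 1 || size != round(size))
    stopf("patch size must be a positive integer")
  size <- as.integer(size)
  center <- as.integer(round(center))
  if (length(center) != 3) stopf("center must have 3 coordinates")
  h <- size %/% 2L
  start0 <- center - h               # inclusive, 0-based
  end0 <- start0 + size - 1L
  d <- dim(volume)
  out <- array(0, dim = c(size, size, size))
  lo <- pmax(start0, 0L)
  hi <- pmin(end0, d - 1L)
  if (all(lo <= hi)) {
    out[(lo[1] - start0[1] + 1L):(hi[1] - start0[1] + 1L),
        (lo[2] - start0[2] + 1L):(hi[2] - start0[2] + 1L),
        (lo[3] - start0[3] + 1L):(hi[3] - start0[3] + 1L)] <-
      volume[(lo[1] + 1L):(hi[1] + 1L),
             (lo[2] + 1L):(hi[2] + 1L),
             (lo[3] + 1L):(hi[3] + 1L)]
  }
  attr(out, "center") <- center
  attr(out, "size") <- size
  attr(out, "roi_label") <- as.integer(roi_label)
  out
}

#' Per-patch intensity standardization
#'
#' Subtracts the patch mean and divides by the patch standard deviation;
#' a constant patch maps to all zeros. Applied (by default) to every patch
#' just before it enters a network.
#'
#' @param patch numeric array.
#' @return array of the same shape.
#' @export
standardize_patch <- function(patch) {
  m <- mean(patch)
  s <- stats::sd(patch)
  out <- if (!is.finite(s) || s == 0) array(0, dim = dim(patch)) else (patch - m) / s
  attributes(out) <- attributes(patch)
  out
}

#' The AAL-116 region name lookup
#'
#' The standard 116-region Automated Anatomical Labeling nomenclature
#' (90 cerebral + 26 cerebellar/vermis parcels), shipped as documentation
#' for user-supplied AAL-space label volumes. The table maps label ids to
#' names only; it is not a registration resource.
#'
#' @return a data frame with columns `label_id` and `name` (116 rows).
#' @export
aal116_lookup <- function() {
  path <- system.file("extdata", "aal116.tsv", package = "roiprog", mustWork = TRUE)
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a subject manifest
#'
#' The manifest is a CSV with columns `subject_id`, `image_path`, `group`
#' and `label` (0 = stable/negative, 1 = progressive/positive, empty/NA =
#' unknown outcome).
#'
#' @param path CSV path.
#' @param base_dir optional directory against which relative image paths are
#'   resolved (defaults to the manifest's directory).
#' @return a data frame.
#' @export
read_manifest <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "image_path", "group", "label")
  miss <- setdiff(need, names(m))
  if (length(miss)) stopf("manifest is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(m$subject_id)) stopf("manifest subject_ids must be unique")
  m$label <- suppressWarnings(as.integer(m$label))
  rel <- !is.na(m$image_path) & !grepl("^(/|[A-Za-z]:)", m$image_path)
  m$image_path[rel] <- file.path(base_dir, m$image_path[rel])
  m
}
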