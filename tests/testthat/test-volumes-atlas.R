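test_that("NIfTI volumes survive a read-write-read round trip", {
  vol <- rand_volume(c(8, 8, 8), seed = 11)
  attr(vol, "voxel_size") <- c(1.5, 1.5, 2)
  p1 <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(vol, p1, datatype = "double")
  v1 <- load_nifti_volume(p1)
  expect_identical(dim(v1), c(8L, 8L, 8L))
  expect_equal(as.numeric(v1), as.numeric(vol), tolerance = 0)
  expect_equal(attr(v1, "voxel_size"), c(1.5, 1.5, 2))
  # at stored (float32) precision the second round trip is value-identical
  p2 <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(vol, p2, datatype = "float")
  v2 <- load_nifti_volume(p2)
  p3 <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(v2, p3, datatype = "float")
  expect_identical(as.numeric(load_nifti_volume(p3)), as.numeric(v2))
  file.remove(p1, p2, p3)
})

test_that("volume loading rejects missing files and non-3D images", {
  expect_error(load_nifti_volume(tempfile(fileext = ".nii")), "cannot read")
  p4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, c(8, 8, 8, 2))), p4)
  expect_error(load_nifti_volume(p4), "3D")
  file.remove(p4)
})

test_that("an all-ones fixture reads back as identity", {
  p <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(array(1, c(8, 8, 8)), p, datatype = "double")
  v <- load_nifti_volume(p)
  expect_true(all(v == 1))
  file.remove(p)
})

test_that("list_rois enumerates exactly the distinct nonzero labels", {
  a <- array(0L, c(6, 6, 6))
  a[1, 1, 1] <- 1L; a[3, 3, 3] <- 2L; a[5:6, 5, 5] <- 5L
  tab <- list_rois(a)
  expect_equal(tab$label_id, c(1L, 2L, 5L))
  expect_equal(tab$voxel_count, c(1L, 1L, 2L))
  expect_equal(tab$name, c("roi_1", "roi_2", "roi_5"))
  expect_equal(nrow(list_rois(array(0L, c(4, 4, 4)))), 0)
  # brute-force voxel-scan agreement on random atlases
  for (s in 1:5) {
    ra <- withr::with_seed(s, array(sample(0:6, 6^3, replace = TRUE), c(6, 6, 6)))
    tab <- list_rois(ra)
    cnt <- table(ra[ra != 0])
    expect_equal(tab$label_id, as.integer(names(cnt)))
    expect_equal(tab$voxel_count, as.integer(cnt))
  }
})

test_that("the shipped AAL-116 lookup names a full one-voxel-per-label atlas", {
  lk <- aal116_lookup()
  expect_equal(nrow(lk), 116)
  expect_equal(lk$label_id, 1:116)
  a <- array(0L, c(5, 5, 5))
  a[seq_len(116)] <- 1:116
  tab <- list_rois(a, lookup = lk)
  expect_equal(nrow(tab), 116)
  expect_equal(tab$name[37], "Hippocampus_L")
  expect_equal(tab$name[116], "Vermis_10")
})

test_that("roi_centroid averages 0-based voxel indices with half-to-even rounding", {
  a <- array(0L, c(8, 8, 8))
  a[6, 7, 8] <- 3L                         # 0-based (5, 6, 7)
  expect_equal(roi_centroid(a, 3), c(5L, 6L, 7L))
  b <- array(0L, c(8, 8, 8))
  b[1, 1, 1] <- 1L; b[3, 1, 1] <- 1L       # 0-based x in {0, 2}
  expect_equal(roi_centroid(b, 1), c(1L, 0L, 0L))
  d <- array(0L, c(8, 8, 8))
  d[1, 1, 1] <- 1L; d[2, 1, 1] <- 1L       # mean 0.5 -> rounds to even 0
  expect_equal(roi_centroid(d, 1), c(0L, 0L, 0L))
  expect_error(roi_centroid(d, 9), "not present")
})

test_that("centroids stay inside each label's bounding box", {
  for (s in 1:4) {
    atlas <- make_phantom_atlas(c(24, 24, 24), 4, 3, seed = 100 + s)
    for (lab in 1:4) {
      cen <- roi_centroid(atlas, lab)
      coords <- arrayInd(which(atlas == lab), dim(atlas)) - 1L
      expect_true(all(cen >= apply(coords, 2, min)))
      expect_true(all(cen <= apply(coords, 2, max)))
    }
  }
})

test_that("extract_patch uses half-open centered windows with zero padding", {
  vol <- array(1, c(8, 8, 8))
  p <- extract_patch(vol, c(4, 4, 4), 4)
  expect_equal(dim(p), c(4, 4, 4))
  expect_equal(sum(p), 64)
  # window [-2, 2)^3 at the origin overlaps 2^3 in-bounds voxels
  p0 <- extract_patch(vol, c(0, 0, 0), 4)
  expect_equal(sum(p0), 8)
  expect_error(extract_patch(vol, c(4, 4, 4), 0), "positive")
  expect_error(extract_patch(vol, c(4, 4, 4), -2), "positive")
})

test_that("extract_patch is translation-consistent in the interior", {
  vol <- rand_volume(c(16, 16, 16), seed = 21)
  shifted <- array(0, c(16, 16, 16))
  shifted[4:16, , ] <- vol[1:13, , ]       # content shifted by +3 in x
  a <- extract_patch(vol, c(6, 8, 8), 6)
  b <- extract_patch(shifted, c(9, 8, 8), 6)
  expect_equal(as.numeric(a), as.numeric(b))
})

test_that("per-patch standardization centers, scales, and zeroes constants", {
  p <- extract_patch(rand_volume(c(16, 16, 16), seed = 3), c(8, 8, 8), 4)
  s <- standardize_patch(p)
  expect_equal(mean(s), 0, tolerance = 1e-12)
  expect_equal(stats::sd(as.numeric(s)), 1, tolerance = 1e-12)
  expect_true(all(standardize_patch(array(2.5, c(4, 4, 4))) == 0))
})

test_that("manifests round-trip with relative paths and unique ids", {
  d <- tempfile("man")
  dir.create(d)
  write.csv(data.frame(subject_id = c("a", "b"), image_path = c("x.nii", "y.nii"),
                       group = c("pNC", "sNC"), label = c(1, 0)),
            file.path(d, "manifest.csv"), row.names = FALSE)
  m <- read_manifest(file.path(d, "manifest.csv"))
  expect_equal(m$image_path, file.path(d, c("x.nii", "y.nii")))
  write.csv(data.frame(subject_id = c("a", "a"), image_path = "x.nii",
                       group = "pNC", label = 1),
            file.path(d, "dup.csv"), row.names = FALSE)
  expect_error(read_manifest(file.path(d, "dup.csv")), "unique")
  unlink(d, recursive = TRUE)
})
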