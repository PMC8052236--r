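test_that("ct_volume enforces its invariants", {
  v <- array(0, c(4, 4, 4))
  expect_s3_class(ct_volume(v, c(0.5, 0.5, 0.625)), "ct_volume")
  expect_error(ct_volume(v, c(0.5, -1, 0.5)), "positive")
  expect_error(ct_volume(v, c(0.5, Inf, 0.5)), "positive")
  bad_aff <- diag(4); bad_aff[1, 1] <- 2  # column norm != spacing
  expect_error(ct_volume(v, c(0.5, 0.5, 0.5), bad_aff), "column norms")
  expect_error(ct_volume(matrix(0, 2, 2), c(1, 1, 1)), "3D")
})

test_that("NIfTI round-trip preserves values, spacing and affine", {
  set.seed(11)
  v <- array(round(stats::rnorm(6 * 5 * 4, 500, 300), 2), c(6, 5, 4))
  A <- diag(c(0.5, 0.5, 0.625, 1)); A[1:3, 4] <- c(-10, 3, 7.5)
  vol <- ct_volume(v, c(0.5, 0.5, 0.625), A)
  for (ext in c(".nii", ".nii.gz")) {
    path <- tempfile(fileext = ext)
    write_nifti(vol, path)
    back <- read_nifti(path)
    expect_equal(back$values, v, tolerance = 1e-4)  # float32 storage
    expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
    expect_equal(back$affine, A, tolerance = 1e-5)
    unlink(path)
  }
})

test_that("NIfTI output agrees with an independent reader (nibabel)", {
  v <- array(seq(-1000, 3000, length.out = 5 * 4 * 3), c(5, 4, 3))
  vol <- ct_volume(v, c(0.7, 0.7, 0.625))
  path <- tempfile(fileext = ".nii")
  write_nifti(vol, path)
  script <- paste(
    "import nibabel, sys, json",
    sprintf("img = nibabel.load('%s')", path),
    "d = img.get_fdata()",
    "print(json.dumps({'shape': list(d.shape),",
    "  'sum': float(d.sum()), 'zoom': [float(z) for z in",
    "  img.header.get_zooms()]}))", sep = "\n")
  out <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                  stdout = TRUE, stderr = FALSE))
  res <- jsonlite::fromJSON(out[length(out)])
  expect_equal(res$shape, c(5L, 4L, 3L))
  expect_equal(res$sum, sum(v), tolerance = 1e-5)
  expect_equal(res$zoom, c(0.7, 0.7, 0.625), tolerance = 1e-6)
  unlink(path)
})

test_that("load_ct reads a DICOM series with rescale and geometry", {
  dir <- tempfile("dcm")
  dir.create(dir)
  nx <- 6L; ny <- 5L
  mk_px <- function(k) matrix(1000L + k, nx, ny)  # stored values
  for (k in 1:3)
    write_dicom_slice(file.path(dir, sprintf("s%d.dcm", k)), mk_px(k),
                      ipp = c(0, 0, (k - 1) * 1.25),
                      pixel_spacing = c(0.8, 0.7))
  vol <- load_ct(dir)
  # stored 1000+k, slope 1, intercept -1024 -> HU
  expect_equal(vol$values[1, 1, 1], 1001 - 1024)
  expect_equal(vol$values[1, 1, 3], 1003 - 1024)
  # PixelSpacing = (row, col) -> x spacing is the column spacing 0.7
  expect_equal(vol$spacing, c(0.7, 0.8, 1.25), tolerance = 1e-9)
  expect_equal(dim(vol$values), c(nx, ny, 3L))
})

test_that("DICOM error paths: multi-series, non-monotonic slices, missing", {
  dir <- tempfile("dcm2"); dir.create(dir)
  px <- matrix(10L, 4, 4)
  write_dicom_slice(file.path(dir, "a.dcm"), px, c(0, 0, 0),
                    series_uid = "1.1")
  write_dicom_slice(file.path(dir, "b.dcm"), px, c(0, 0, 1.25),
                    series_uid = "2.2")
  expect_error(read_dicom_series(dir), "multiple DICOM series.*1\\.1")

  dir2 <- tempfile("dcm3"); dir.create(dir2)
  write_dicom_slice(file.path(dir2, "a.dcm"), px, c(0, 0, 0))
  write_dicom_slice(file.path(dir2, "b.dcm"), px, c(0, 0, 0))  # duplicate z
  expect_error(read_dicom_series(dir2), "non-monotonic")

  expect_error(load_ct(tempfile("nope")), "not found")
})

test_that("resampling: identity, constants, grid-extent arithmetic", {
  set.seed(3)
  v <- array(stats::rnorm(12 * 11 * 10, 100, 400), c(12, 11, 10))
  vol <- ct_volume(v, c(0.5, 0.5, 0.5))
  iso <- resample_isotropic(vol, 0.5)
  expect_equal(dim(iso$values), dim(v))
  expect_lt(max(abs(iso$values - v)), 1e-6)

  const <- ct_volume(array(700, c(9, 10, 11)), c(0.9, 0.66, 0.625))
  out <- resample_isotropic(const, 0.5)
  expect_lt(max(abs(out$values - 700)), 1e-6)

  big <- ct_volume(array(0, c(40, 40, 40)), c(1, 1, 1))
  expect_equal(dim(resample_isotropic(big, 0.5)$values), c(80L, 80L, 80L))
  expect_error(resample_isotropic(big, -1), "positive")
  expect_error(resample_isotropic(big, 0), "positive")
})

test_that("resampling preserves a bright point's world-space centroid", {
  v <- array(0, c(21, 19, 17))
  v[14, 9, 6] <- 1000
  vol <- ct_volume(v, c(0.9, 0.7, 0.625))
  iso <- resample_isotropic(vol, 0.5, clamp_range = c(0, 4000))
  w <- iso$values / sum(iso$values)
  co <- arrayInd(seq_along(w), dim(iso$values)) - 1
  cen_vox <- colSums(co * as.vector(w))
  cen_mm <- voxel_to_world(iso, matrix(cen_vox, 1))
  truth <- voxel_to_world(vol, matrix(c(13, 8, 5), 1))
  expect_lt(max(abs(cen_mm - truth)), 0.5)  # within one output voxel
})

test_that("load + resample is deterministic (bit-identical reruns)", {
  set.seed(4)
  v <- array(stats::rnorm(10 * 10 * 8, 0, 500), c(10, 10, 8))
  path <- tempfile(fileext = ".nii.gz")
  write_nifti(ct_volume(v, c(0.8, 0.8, 0.625)), path)
  r1 <- resample_isotropic(load_ct(path), 0.5)
  r2 <- resample_isotropic(load_ct(path), 0.5)
  expect_identical(r1$values, r2$values)
  expect_identical(r1$affine, r2$affine)
  unlink(path)
})

test_that("canonical reorientation yields a positive near-diagonal affine", {
  v <- array(seq_len(4 * 5 * 6), c(4, 5, 6))
  A <- matrix(0, 4, 4); A[4, 4] <- 1
  A[1:3, 1] <- c(0, 0.5, 0)        # axis 1 points along world y
  A[1:3, 2] <- c(0, 0, -0.7)       # axis 2 points along -z
  A[1:3, 3] <- c(0.625, 0, 0)      # axis 3 along x
  A[1:3, 4] <- c(5, 6, 7)
  path <- tempfile(fileext = ".nii")
  write_nifti(structure(list(values = v, spacing = c(0.5, 0.7, 0.625),
                             affine = A), class = "ct_volume"), path)
  vol <- load_ct(path)
  L <- vol$affine[1:3, 1:3]
  expect_true(all(diag(L) > 0))
  expect_lt(max(abs(L - diag(diag(L)))), 1e-6)
  # world content unchanged: value at a fixed world point is preserved
  expect_equal(sort(as.vector(vol$values)), sort(as.vector(v)))
  unlink(path)
})
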