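test_that("NIfTI write/read round-trips values and grid bit-exactly", {
  set.seed(7)
  arr <- array(round(rnorm(16 * 12 * 6, 400, 50)), c(16L, 12L, 6L))
  vol <- ImageVolume(arr, spacing = c(0.9375, 0.9375, 5), origin = c(-10, 4, 2))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(vol, path)
  back <- readVolume(path)
  expect_identical(imgData(back), imgData(vol))
  expect_equal(imgAffine(back), imgAffine(vol), tolerance = 1e-6)
  expect_equal(voxelSpacing(back), c(0.9375, 0.9375, 5), tolerance = 1e-6)
})

test_that("reorientation to the canonical frame preserves intensities and world positions", {
  set.seed(8)
  arr <- array(rnorm(10 * 8 * 6), c(10L, 8L, 6L))
  # flipped, permuted grid: x <- -j, y <- i, z <- -k style affine
  aff <- matrix(c(0, 2, 0, 0,
                  -1, 0, 0, 0,
                  0, 0, -3, 0,
                  5, -4, 20, 1), 4, 4)
  out <- gliovol:::reorientCanonical(arr, aff)
  lin <- out$affine[1:3, 1:3]
  expect_true(all(diag(lin) > 0))
  expect_true(all(abs(lin[upper.tri(lin) | lower.tri(lin)]) < 1e-12))
  expect_equal(sort(as.vector(out$data)), sort(as.vector(arr)))
  # voxel (2,3,4) of the original must map to the same world point
  w <- aff %*% c(2, 3, 4, 1)
  idx <- solve(out$affine, w)[1:3]
  expect_equal(out$data[idx[1] + 1, idx[2] + 1, idx[3] + 1], arr[3, 4, 5])
})

test_that("voxel volume is the product of the spacings", {
  mk <- function(sp) ImageVolume(array(0, c(2, 2, 2)), spacing = sp)
  expect_equal(voxelVolume(mk(c(1, 1, 1))), 1.0)
  expect_equal(voxelVolume(mk(c(0.5, 0.5, 2.0))), 0.5)
  expect_equal(voxelVolume(mk(c(0.9375, 0.9375, 5.0))), 0.9375^2 * 5)
  expect_equal(voxelVolume(c(0.9375, 0.9375, 5.0)), 0.9375 * 0.9375 * 5.0)
  expect_error(voxelVolume(c(1, -1, 1)))
})

test_that("a fabricated DICOM series reads back as the source array", {
  set.seed(9)
  arr <- array(sample.int(2000, 16 * 16 * 6, replace = TRUE), c(16L, 16L, 6L))
  storage.mode(arr) <- "double"
  vol <- ImageVolume(arr, spacing = c(1, 1, 5))
  dir <- withr::local_tempdir()
  writeDicomSeries(vol, dir)
  back <- readVolume(dir, format = "dicom")
  expect_equal(voxelSpacing(back), c(1, 1, 5), tolerance = 1e-6)
  expect_identical(dim(back), dim(arr))
  expect_equal(imgData(back), arr)
})

test_that("a DICOM series with a missing middle slice errors and names the gap", {
  arr <- array(seq_len(8 * 8 * 5), c(8L, 8L, 5L))
  storage.mode(arr) <- "double"
  dir <- withr::local_tempdir()
  writeDicomSeries(ImageVolume(arr, spacing = c(1, 1, 2)), dir)
  file.remove(file.path(dir, "slice_0003.dcm"))
  expect_error(readDicomSeries(dir), "missing slice")
})

test_that("non-integer DICOM intensities survive the rescale round-trip", {
  set.seed(10)
  arr <- array(rnorm(8 * 8 * 4, 100, 20), c(8L, 8L, 4L))
  dir <- withr::local_tempdir()
  writeDicomSeries(ImageVolume(arr, spacing = c(2, 2, 3)), dir)
  back <- readVolume(dir)
  expect_equal(imgData(back), arr, tolerance = 1e-2)
})

test_that("missing inputs are rejected with the offending path", {
  expect_error(readVolume("/nonexistent/vol.nii.gz"), "nonexistent")
  expect_error(writeVolume(array(0, c(2, 2, 2)), tempfile()), "reference")
})
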