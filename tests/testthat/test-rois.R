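refGrid <- function(dims = c(24L, 24L, 6L), spacing = c(1, 1, 1)) {
  ImageVolume(array(0, dims), spacing = spacing)
}

squareVerts <- function(x0, y0, side) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side), c(x0, y0 + side))
}

test_that("an axis-aligned 10 mm square rasterizes to 100 voxels per slice", {
  ref <- refGrid()
  verts <- squareVerts(2.5, 3.5, 10)
  roi1 <- rasterizePolygons(PolygonSet(list(list(index = 2, vertices = verts))),
                            ref)
  expect_equal(voxelCount(roi1), 100L)
  expect_equal(roiMask(roi1)[, , 2],
               oracleRasterizeSlice(verts, dim(ref)[1:2], c(1, 1)))
  # per-slice additivity: same square on two adjacent slices
  roi2 <- rasterizePolygons(PolygonSet(list(
    list(index = 2, vertices = verts),
    list(index = 3, vertices = verts))), ref)
  expect_equal(voxelCount(roi2), 200L)
})

test_that("rasterization matches the brute-force oracle on an irregular polygon", {
  ref <- refGrid()
  set.seed(15)
  ang <- sort(runif(7, 0, 2 * pi))
  verts <- cbind(11 + 8 * cos(ang), 12 + 9 * sin(ang))
  roi <- rasterizePolygons(PolygonSet(list(list(index = 4, vertices = verts))),
                           ref)
  expect_equal(roiMask(roi)[, , 4],
               oracleRasterizeSlice(verts, dim(ref)[1:2], c(1, 1)))
})

test_that("rasterization is independent of vertex ordering", {
  ref <- refGrid()
  verts <- squareVerts(5.2, 6.8, 7.5)
  cw <- rasterizePolygons(PolygonSet(list(list(index = 1, vertices = verts))),
                          ref)
  ccw <- rasterizePolygons(PolygonSet(list(
    list(index = 1, vertices = verts[4:1, ]))), ref)
  expect_identical(roiMask(cw), roiMask(ccw))
})

test_that("a polygon covering no voxel center is an error", {
  ref <- refGrid()
  verts <- rbind(c(4.3, 4.4), c(4.7, 4.4), c(4.5, 4.7))  # between centers
  expect_error(
    rasterizePolygons(PolygonSet(list(list(index = 1, vertices = verts))),
                      ref),
    "zero voxels")
})

test_that("polygon JSON round-trips through writePolygonSet/readRoi", {
  ref <- refGrid()
  verts <- squareVerts(2.5, 3.5, 10)
  ps <- PolygonSet(list(list(index = 2, vertices = verts)), role = "tumor")
  path <- withr::local_tempfile(fileext = ".json")
  writePolygonSet(ps, path)
  roi <- readRoi(path, ref)
  expect_equal(roiRole(roi), "tumor")
  expect_identical(roiMask(roi), roiMask(rasterizePolygons(ps, ref)))
})

test_that("ROI transfer through the identity returns the identical mask", {
  ph <- fxNoiseless()
  roi <- ph$truth@rois$tumor
  out <- transferRoi(roi, rigidTransform(), ph$post)
  expect_identical(roiMask(out), roiMask(roi))
  expect_equal(roiSource(out), "transferred")
})

test_that("integer-voxel ROI transfer equals the index-shift oracle", {
  ref <- refGrid(c(20L, 20L, 8L))
  mask <- array(FALSE, dim(ref))
  mask[5:12, 6:14, 3:6] <- TRUE
  roi <- roiFromMask(mask, ref, "tumor")
  out <- transferRoi(roi, rigidTransform(translation = c(3, 0, 1)), ref)
  oracle <- array(FALSE, dim(ref))
  oracle[8:15, 6:14, 4:7] <- TRUE
  expect_identical(roiMask(out), oracle)
})

test_that("transfer then inverse transfer keeps Dice >= 0.9 for a large blob", {
  ph <- fxNoiseless()
  roi <- ph$truth@rois$tumor
  expect_gte(voxelCount(roi), 1000L)
  t <- rigidTransform(rotation = c(0, 0, 4), translation = c(2.4, -1.7, 1.2),
                      center = gliovol:::worldCenter(ph$post))
  there <- transferRoi(roi, t, ph$post)
  back <- transferRoi(there, invertTransform(t), ph$post)
  expect_gte(oracleDice(roiMask(back), roiMask(roi)), 0.9)
})

test_that("nested outlines rasterize to nested masks", {
  ref <- refGrid()
  inner <- rasterizePolygons(PolygonSet(list(
    list(index = 3, vertices = squareVerts(6.5, 6.5, 6)))), ref)
  outer <- rasterizePolygons(PolygonSet(list(
    list(index = 3, vertices = squareVerts(4.5, 4.5, 12)))), ref)
  expect_true(all(roiMask(outer)[roiMask(inner)]))
  expect_gt(voxelCount(outer), voxelCount(inner))
})

test_that("tumor/normal overlap and undersized normal regions are rejected", {
  ref <- refGrid(c(16L, 16L, 8L))
  m <- array(FALSE, dim(ref)); m[2:13, 2:13, 2:7] <- TRUE
  tumor <- roiFromMask(m, ref, "tumor")
  normalOverlap <- roiFromMask(m, ref, "normal")
  expect_error(gliovol:::validateRoiSet(tumor, normalOverlap), "overlap")
  small <- array(FALSE, dim(ref)); small[15:16, 15:16, 1:8] <- TRUE
  expect_error(
    gliovol:::validateRoiSet(tumor, roiFromMask(small, ref, "normal")),
    "at least 100")
  mid <- array(FALSE, dim(ref)); mid[14:16, 1:16, 1:8] <- TRUE  # 384 voxels
  expect_warning(
    gliovol:::validateRoiSet(tumor, roiFromMask(mid, ref, "normal")),
    "unstable")
})
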