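test_that("the same spec and seed reproduce bit-identical volumes", {
  spec <- phantomSpec(noise = "rician", sigma = 2, seed = 42L)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(imgData(a$pre), imgData(b$pre))
  expect_identical(imgData(a$post), imgData(b$post))
  c <- generatePhantom(phantomSpec(noise = "rician", sigma = 2, seed = 43L))
  expect_false(identical(imgData(c$post), imgData(a$post)))
  expect_identical(c$truth@enhancingCount, a$truth@enhancingCount)
})

test_that("the noiseless construction equation holds voxel by voxel", {
  ph <- generatePhantom(phantomSpec(noise = "none", rimContrast = 100,
                                    offset = 7))
  diffMap <- imgData(ph$post) - imgData(ph$pre)
  rim <- ph$truth@enhancingMask & roiMask(ph$truth@rois$tumor)
  expect_true(all(diffMap[rim] == 107))
  parenchyma <- roiMask(ph$truth@rois$normal)
  expect_true(all(diffMap[parenchyma] == 7))
  expect_gte(min(diffMap), 0)
  expect_true(all(diffMap[ph$truth@cavityMask] == 7))
})

test_that("phantom regions are pairwise disjoint and truth is self-consistent", {
  for (spec in c(phantomScenario("rim_baseline"),
                 phantomScenario("meningeal_rim"),
                 phantomScenario("subacute_blood"))) {
    ph <- generatePhantom(spec)
    r <- ph$truth@rois
    expect_false(any(roiMask(r$tumor) & roiMask(r$normal)))
    expect_false(any(roiMask(r$tumorGenerous) & roiMask(r$normal)))
    expect_false(any(roiMask(r$tumor) & roiMask(r$mucosa)))
    expect_equal(ph$truth@enhancingCount,
                 sum(ph$truth@enhancingMask & roiMask(r$tumor)))
  }
})

test_that("cavity collapse shrinks the cavity extents but grows the rim", {
  specs <- phantomScenario("cavity_collapse")
  expect_length(specs, 2L)
  t1 <- generatePhantom(specs[[1]])
  t2 <- generatePhantom(specs[[2]])
  expect_gt(t2$truth@enhancingCount, t1$truth@enhancingCount)
  bbox <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    apply(idx, 2, function(v) diff(range(v)))
  }
  lesion1 <- t1$truth@cavityMask | t1$truth@enhancingMask
  lesion2 <- t2$truth@cavityMask | t2$truth@enhancingMask
  expect_true(all(bbox(lesion2)[1:2] < bbox(lesion1)[1:2]))
})

test_that("the subacute blood scenario brightens the cavity on the right scans", {
  specs <- phantomScenario("subacute_blood")
  both <- generatePhantom(specs[[1]])
  postOnly <- generatePhantom(specs[[2]])
  cav <- both$truth@cavityMask
  par <- specs[[1]]@parenchyma
  expect_true(all(imgData(both$pre)[cav] > par))
  expect_true(all(imgData(both$post)[cav] > par))
  expect_equal(sum(both$truth@enhancingMask & cav), 0L)
  expect_true(all(imgData(postOnly$pre)[cav] < par))
  expect_true(all(postOnly$truth@enhancingMask[cav]))
})

test_that("the serial series fixes the trajectory across seeds", {
  s1 <- phantomScenario("serial_series", seed = 1L)
  s2 <- phantomScenario("serial_series", seed = 2L)
  expect_length(s1, 8L)
  traj1 <- vapply(s1, function(s) generatePhantom(s)$truth@enhancingCount,
                  integer(1))
  traj2 <- vapply(s2, function(s) generatePhantom(s)$truth@enhancingCount,
                  integer(1))
  expect_identical(traj1, traj2)
  expect_gt(length(unique(sign(diff(traj1)))), 1L)  # non-monotonic by design
})

test_that("unknown scenario names list the valid ones", {
  expect_error(phantomScenario("no_such"), "rim_baseline")
})

test_that("phantom fixture directories are written deterministically", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writePhantomFixture("cavity_collapse", d1, seed = 7L)
  writePhantomFixture("cavity_collapse", d2, seed = 7L)
  expect_setequal(list.files(d1, recursive = TRUE),
                  list.files(d2, recursive = TRUE))
  expect_true(file.exists(file.path(d1, "truth.json")))
  expect_length(list.dirs(d1, recursive = FALSE), 3L)  # 2 timepoints + atlas
  expect_identical(readLines(file.path(d1, "truth.json")),
                   readLines(file.path(d2, "truth.json")))
  a <- readVolume(file.path(d1, "timepoint_01", "pre.nii.gz"))
  b <- readVolume(file.path(d2, "timepoint_01", "pre.nii.gz"))
  expect_identical(imgData(a), imgData(b))
})
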