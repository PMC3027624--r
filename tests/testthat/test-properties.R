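# Invariance properties of the measurement: the mode correction absorbs
# additive brightness changes, the mucosa-referenced threshold makes the
# measurement scale-equivariant, and volumes are monotone in the threshold
# fraction and in the tumor region.

test_that("adding a constant to either scan leaves the enhancement mask unchanged", {
  fx <- fxNoiselessResult()
  ph <- fx$ph
  r <- ph$truth@rois
  for (delta in c(-30, 50)) {
    postShift <- ImageVolume(imgData(ph$post) + delta,
                             affine = imgAffine(ph$post))
    resPost <- quantifyEnhancement(ph$pre, postShift, r$tumor, r$normal,
                                   r$mucosa)
    expect_identical(enhancementMask(resPost), enhancementMask(fx$res))
    preShift <- ImageVolume(imgData(ph$pre) + delta,
                            affine = imgAffine(ph$pre))
    resPre <- quantifyEnhancement(preShift, ph$post, r$tumor, r$normal,
                                  r$mucosa)
    expect_identical(enhancementMask(resPre), enhancementMask(fx$res))
  }
})

test_that("scaling both scans by k scales correction and threshold by k, mask unchanged", {
  fx <- fxNoiselessResult()
  ph <- fx$ph
  r <- ph$truth@rois
  k <- 2
  preK <- ImageVolume(imgData(ph$pre) * k, affine = imgAffine(ph$pre))
  postK <- ImageVolume(imgData(ph$post) * k, affine = imgAffine(ph$post))
  resK <- quantifyEnhancement(preK, postK, r$tumor, r$normal, r$mucosa)
  expect_equal(resK@correction@value, k * fx$res@correction@value)
  expect_equal(thresholdValue(resK), k * thresholdValue(fx$res))
  expect_identical(enhancementMask(resK), enhancementMask(fx$res))
})

test_that("raising the threshold fraction can only shrink the volume", {
  ph <- fxNoiseless()
  r <- ph$truth@rois
  noisy <- generatePhantom(phantomSpec(noise = "rician", sigma = 2,
                                       seed = 21L))
  for (p in list(list(ph = ph, rois = r),
                 list(ph = noisy, rois = noisy$truth@rois))) {
    v25 <- quantifyEnhancement(p$ph$pre, p$ph$post, p$rois$tumor,
                               p$rois$normal, p$rois$mucosa,
                               config = analysisConfig(thresholdFraction = 0.25))
    v40 <- quantifyEnhancement(p$ph$pre, p$ph$post, p$rois$tumor,
                               p$rois$normal, p$rois$mucosa,
                               config = analysisConfig(thresholdFraction = 0.40))
    expect_lte(voxelCount(v40), voxelCount(v25))
    expect_true(all(roiMask(p$rois$tumor)[enhancementMask(v25)]))
  }
})

test_that("a tumor region that contains another cannot measure less", {
  ph <- generatePhantom(phantomScenario("meningeal_rim", seed = 5L)[[1]])
  r <- ph$truth@rois
  expect_true(all(roiMask(r$tumorGenerous)[roiMask(r$tumor)]))
  narrow <- quantifyEnhancement(ph$pre, ph$post, r$tumor, r$normal, r$mucosa)
  generous <- quantifyEnhancement(ph$pre, ph$post, r$tumorGenerous, r$normal,
                                  r$mucosa)
  expect_lte(voxelCount(narrow), voxelCount(generous))
  # the generous region picks up the meningeal enhancement
  expect_gt(voxelCount(generous), voxelCount(narrow))
})
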