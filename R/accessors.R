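#' @rdname ImageVolume-class
#' @export
setMethod("imgData", "ImageVolume", function(x) x@data)

#' @rdname ImageVolume-class
#' @export
setMethod("imgAffine", "ImageVolume", function(x) x@affine)

#' @rdname ImageVolume-class
#' @export
setMethod("voxelSpacing", "ImageVolume",
          function(x) sqrt(colSums(x@affine[1:3, 1:3]^2)))

#' @describeIn ImageVolume-class grid shape.
#' @export
setMethod("dim", "ImageVolume", function(x) dim(x@data))

#' Volume of one voxel
#'
#' The product of the three voxel spacings, in mm^3; converts supra-threshold
#' voxel counts to volumes.
#'
#' @param x an [ImageVolume-class] (or numeric spacing vector of length 3)
#' @return voxel volume in mm^3.
#' @examples
#' vol <- ImageVolume(array(0, c(4, 4, 4)), spacing = c(0.5, 0.5, 2))
#' voxelVolume(vol)  # 0.5 mm^3
#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "ImageVolume",
          function(x) prod(voxelSpacing(x)))

#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "numeric", function(x) {
  stopifnot(length(x) == 3L, all(x > 0))
  prod(x)
})

#' @rdname RegionOfInterest-class
#' @export
setMethod("roiMask", "RegionOfInterest", function(x) x@mask)

#' @rdname RegionOfInterest-class
#' @export
setMethod("roiRole", "RegionOfInterest", function(x) x@role)

#' @rdname RegionOfInterest-class
#' @export
setMethod("roiSource", "RegionOfInterest", function(x) x@source)

#' @rdname RegionOfInterest-class
#' @export
setMethod("voxelCount", "RegionOfInterest",
          function(x) sum(x@mask, na.rm = TRUE))

#' @rdname EnhancingVolumeResult-class
#' @export
setMethod("voxelCount", "EnhancingVolumeResult", function(x) x@voxelCount)

#' @rdname EnhancingVolumeResult-class
#' @export
setMethod("volumeCm3", "EnhancingVolumeResult", function(x) x@volumeCm3)

#' @rdname EnhancingVolumeResult-class
#' @export
setMethod("enhancementMask", "EnhancingVolumeResult", function(x) x@mask)

#' @rdname EnhancementThreshold-class
#' @export
setMethod("thresholdValue", "EnhancementThreshold", function(x) x@value)

#' @rdname EnhancementThreshold-class
#' @export
setMethod("thresholdValue", "EnhancingVolumeResult",
          function(x) x@threshold@value)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  sp <- voxelSpacing(object)
  cat(sprintf("ImageVolume: %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], sp[1], sp[2], sp[3]))
  rng <- range(object@data, na.rm = TRUE)
  cat(sprintf("  intensity range [%.4g, %.4g], %d out-of-field voxel(s)\n",
              rng[1], rng[2], sum(is.na(object@data))))
})

setMethod("show", "RegionOfInterest", function(object) {
  cat(sprintf("RegionOfInterest (%s, %s): %d voxels on a %s grid\n",
              object@role, object@source, voxelCount(object),
              paste(dim(object@mask), collapse = " x ")))
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: rotation (%.3f, %.3f, %.3f) deg, translation (%.3f, %.3f, %.3f) mm\n",
              object@rotation[1], object@rotation[2], object@rotation[3],
              object@translation[1], object@translation[2],
              object@translation[3]))
  cat(sprintf("  center (%.2f, %.2f, %.2f) mm\n", object@center[1],
              object@center[2], object@center[3]))
})

setMethod("show", "AffineTransform", function(object) {
  cat("AffineTransform (3x4, mm):\n")
  print(round(object@matrix, 4))
})

setMethod("show", "EnhancementThreshold", function(object) {
  cat(sprintf("EnhancementThreshold: %.4g (= %.0f%% of remaining max %.4g; top %.0f%% of %d mucosa voxels excluded)\n",
              object@value, 100 * object@thresholdFraction,
              object@remainingMax, 100 * object@exclusionFraction,
              object@nMucosaVoxels))
})

setMethod("show", "CorrectionFactor", function(object) {
  cat(sprintf("CorrectionFactor: %.4g (mode of %d normal-region subtraction values, bin width %.4g)\n",
              object@value, object@nVoxels, object@binWidth))
})

setMethod("show", "EnhancingVolumeResult", function(object) {
  cat(sprintf("EnhancingVolumeResult: %d voxels = %.4g cm^3\n",
              object@voxelCount, object@volumeCm3))
  show(object@threshold)
  show(object@correction)
})

setMethod("show", "AtlasBundle", function(object) {
  cat(sprintf("AtlasBundle: template %s, mucosa label %d voxels\n",
              paste(dim(object@template@data), collapse = " x "),
              sum(object@mucosaLabel)))
  if (nzchar(object@metadata)) cat(" ", object@metadata, "\n")
})

setMethod("show", "DiameterMeasurement", function(object) {
  cat(sprintf("DiameterMeasurement: %.3g cm x %.3g cm = %.3g cm^2 (slice %d)\n",
              object@longestDiameter, object@perpendicularDiameter,
              object@product, object@sliceIndex))
})
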