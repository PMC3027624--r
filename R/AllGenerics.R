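#' @rdname ImageVolume-class
#' @param object,x an object
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname ImageVolume-class
#' @export
setGeneric("imgAffine", function(x) standardGeneric("imgAffine"))

#' @rdname ImageVolume-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxelVolume
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname RegionOfInterest-class
#' @export
setGeneric("roiMask", function(x) standardGeneric("roiMask"))

#' @rdname RegionOfInterest-class
#' @export
setGeneric("roiRole", function(x) standardGeneric("roiRole"))

#' @rdname RegionOfInterest-class
#' @export
setGeneric("roiSource", function(x) standardGeneric("roiSource"))

#' @rdname RegionOfInterest-class
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))

#' @rdname EnhancingVolumeResult-class
#' @export
setGeneric("volumeCm3", function(x) standardGeneric("volumeCm3"))

#' @rdname EnhancingVolumeResult-class
#' @export
setGeneric("enhancementMask", function(x) standardGeneric("enhancementMask"))

#' @rdname EnhancementThreshold-class
#' @export
setGeneric("thresholdValue", function(x) standardGeneric("thresholdValue"))

#' Invert a spatial transform
#' @param t a [RigidTransform-class] or [AffineTransform-class]
#' @return a transform of the same class mapping fixed-world back to
#'   moving-world.
#' @export
setGeneric("invertTransform", function(t) standardGeneric("invertTransform"))

#' Apply a spatial transform to world-coordinate points
#' @param t a [RigidTransform-class] or [AffineTransform-class]
#' @param pts n x 3 matrix of world mm points
#' @return n x 3 matrix of mapped points.
#' @export
setGeneric("transformPoints",
           function(t, pts) standardGeneric("transformPoints"))

#' Transform as homogeneous matrix
#' @param t a transform
#' @return 4x4 homogeneous matrix acting on world coordinates.
#' @export
setGeneric("transformMatrix", function(t) standardGeneric("transformMatrix"))
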