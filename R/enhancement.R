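# The central computation: voxelwise subtraction, mode-based brightness
# correction from normal parenchyma, mucosa-referenced enhancement threshold,
# and supra-threshold volume inside the tumor region.

#' Voxelwise subtraction of fused pre from post
#'
#' @param post post-contrast [ImageVolume-class].
#' @param preResampled pre-contrast volume already resampled onto the post
#'   grid (see [resampleVolume()]); its \code{NA} fill voxels are excluded
#'   from the valid mask.
#' @return a [SubtractionMap-class] on the post grid.
#' @export
subtractVolumes <- function(post, preResampled) {
  if (!sameGrid(post, preResampled))
    stop("subtraction requires identical grids; resample the pre image first")
  valid <- !is.na(post@data) & !is.na(preResampled@data)
  data <- post@data - preResampled@data
  data[!valid] <- NA_real_
  new("SubtractionMap", data = data, validMask = valid, affine = post@affine)
}

# Fixed-width histogram mode with bins centered on integer multiples of
# binWidth; ties broken toward the lowest bin center.
histogramMode <- function(values, binWidth) {
  bins <- round(values / binWidth)
  tab <- table(bins)
  top <- names(tab)[tab == max(tab)]
  min(as.numeric(top)) * binWidth
}

#' Mode of normal-parenchyma subtraction values (the correction factor)
#'
#' MRI pixel values are not standardized, so serial scans differ by a global
#' brightness offset. The mode of subtraction values inside the user-drawn
#' normal-parenchyma region estimates that offset and is subtracted from all
#' subsequent tumor and mucosa values.
#'
#' @param sub a [SubtractionMap-class].
#' @param normal a [RegionOfInterest-class] with role \code{"normal"}.
#' @param binWidth histogram bin width in native intensity units; the default
#'   1 suits integer-valued MRI data (reduce for float data on another scale).
#' @return a [CorrectionFactor-class].
#' @export
correctionFactor <- function(sub, normal, binWidth = 1) {
  stopifnot(is(sub, "SubtractionMap"), is(normal, "RegionOfInterest"))
  if (roiRole(normal) != "normal")
    stop("correction factor requires a region with role 'normal'")
  if (!sameGrid(sub@affine, normal@refAffine) ||
      !identical(dim(sub@data), dim(normal@mask)))
    stop("normal region is not on the subtraction grid")
  vals <- sub@data[normal@mask & sub@validMask]
  if (length(vals) < 100L)
    stop("only ", length(vals),
         " valid normal-region voxels; at least 100 are required")
  new("CorrectionFactor", value = histogramMode(vals, binWidth),
      binWidth = binWidth, nVoxels = length(vals))
}

#' Corrected subtraction values within a region
#'
#' Subtracts the correction factor from each valid in-region subtraction
#' value. Negative corrected values are retained (no clamping); they simply
#' never exceed a positive threshold.
#'
#' @param sub a [SubtractionMap-class].
#' @param roi a [RegionOfInterest-class] on the same grid.
#' @param correction a [CorrectionFactor-class].
#' @return numeric vector of corrected per-voxel values (intensity units).
#' @export
applyCorrection <- function(sub, roi, correction) {
  stopifnot(is(sub, "SubtractionMap"), is(roi, "RegionOfInterest"),
            is(correction, "CorrectionFactor"))
  sel <- roi@mask & sub@validMask
  if (!any(sel))
    stop("region does not intersect the valid subtraction field")
  sub@data[sel] - correction@value
}

#' Enhancement threshold from corrected mucosa values
#'
#' The top \code{exclusionFraction} of the corrected nasal-mucosa values --
#' the \code{ceiling(exclusionFraction * n)} largest, an order-statistic trim
#' by voxel count -- are excluded to avoid error from outliers, and the
#' threshold is \code{thresholdFraction} times the remaining maximum.
#'
#' @param correctedMucosa numeric vector of corrected mucosa values.
#' @param exclusionFraction fraction of values trimmed from the top
#'   (default 0.05).
#' @param thresholdFraction fraction of the remaining maximum used as the
#'   cut-off (default 0.25; 0.40 is the common alternative setting).
#' @return an [EnhancementThreshold-class].
#' @examples
#' enhancementThreshold(1:100)                            # 0.25 * 95 = 23.75
#' enhancementThreshold(1:100, thresholdFraction = 0.40)  # 0.40 * 95 = 38
#' @export
enhancementThreshold <- function(correctedMucosa, exclusionFraction = 0.05,
                                 thresholdFraction = 0.25) {
  vals <- correctedMucosa[!is.na(correctedMucosa)]
  n <- length(vals)
  if (n == 0L) stop("no corrected mucosa values supplied")
  k <- ceiling(exclusionFraction * n)
  if (k >= n)
    stop("exclusion fraction removes all ", n, " mucosa values")
  sorted <- sort(vals, decreasing = TRUE)
  remainingMax <- if (k > 0) sorted[k + 1L] else sorted[1L]
  if (remainingMax <= 0)
    stop("mucosa shows no net enhancement (remaining maximum <= 0)")
  new("EnhancementThreshold", value = thresholdFraction * remainingMax,
      thresholdFraction = thresholdFraction,
      exclusionFraction = exclusionFraction, remainingMax = remainingMax,
      nMucosaVoxels = n)
}

#' Supra-threshold enhancing volume within the tumor region
#'
#' A tumor-region voxel is enhancing iff its corrected subtraction value is
#' strictly greater than the threshold (configurable to \code{>=}). The count
#' is converted to cm^3 via the voxel volume.
#'
#' @param sub a [SubtractionMap-class].
#' @param tumor a [RegionOfInterest-class] with role \code{"tumor"}.
#' @param correction a [CorrectionFactor-class].
#' @param threshold an [EnhancementThreshold-class].
#' @param voxelVolumeMm3 voxel volume in mm^3 (see [voxelVolume()]).
#' @param strict use strict \code{>} at the cut-off (default) or \code{>=}.
#' @return an [EnhancingVolumeResult-class]. Zero enhancing voxels is a valid
#'   result.
#' @export
enhancingVolume <- function(sub, tumor, correction, threshold,
                            voxelVolumeMm3, strict = TRUE) {
  stopifnot(is(tumor, "RegionOfInterest"))
  if (roiRole(tumor) != "tumor")
    stop("enhancing volume requires a region with role 'tumor'")
  stopifnot(threshold@value > 0, voxelVolumeMm3 > 0)
  sel <- tumor@mask & sub@validMask
  corrected <- sub@data - correction@value
  above <- if (strict) corrected > threshold@value
           else corrected >= threshold@value
  mask <- sel & !is.na(above) & above
  count <- sum(mask)
  new("EnhancingVolumeResult", voxelCount = as.integer(count),
      volumeCm3 = count * voxelVolumeMm3 / 1000, mask = mask,
      threshold = threshold, correction = correction)
}

#' Full enhancing-tumor volume pipeline
#'
#' Composes the whole measurement: rigid fusion of pre onto the post grid,
#' voxelwise subtraction, normal-parenchyma mode correction, mucosa detection
#' (atlas) or manual mucosa override, threshold derivation, and
#' supra-threshold counting inside the tumor region. Deterministic for fixed
#' inputs.
#'
#' @param pre,post pre-/post-contrast [ImageVolume-class] volumes.
#' @param tumor,normal [RegionOfInterest-class] regions on the post grid.
#' @param mucosa an [AtlasBundle-class] (automatic detection) or a
#'   [RegionOfInterest-class] with role \code{"mucosa"} (manual override).
#' @param config an [analysisConfig()] list of tunable parameters.
#' @return an [EnhancingVolumeResult-class].
#' @seealso [runMeasure()] for the file-based front end.
#' @export
quantifyEnhancement <- function(pre, post, tumor, normal, mucosa,
                                config = analysisConfig()) {
  validateRoiSet(tumor, normal)
  fusion <- tryCatch(
    registerRigid(pre, post, searchRange = config$registration$searchRange,
                  maxit = config$registration$maxit),
    error = function(e) stop("fusion stage: ", conditionMessage(e),
                             call. = FALSE))
  preFused <- resampleVolume(pre, fusion, post, interp = "linear")
  sub <- subtractVolumes(post, preFused)
  correction <- tryCatch(
    correctionFactor(sub, normal, binWidth = config$binWidth),
    error = function(e) stop("correction stage: ", conditionMessage(e),
                             call. = FALSE))
  mucosaRoi <- detectMucosa(post, mucosa)
  if (any(mucosaRoi@mask & tumor@mask))
    stop("mucosa stage: detected mucosa region intersects the tumor region")
  correctedMucosa <- applyCorrection(sub, mucosaRoi, correction)
  threshold <- tryCatch(
    enhancementThreshold(correctedMucosa,
                         exclusionFraction = config$exclusionFraction,
                         thresholdFraction = config$thresholdFraction),
    error = function(e) stop("threshold stage: ", conditionMessage(e),
                             call. = FALSE))
  enhancingVolume(sub, tumor, correction, threshold,
                  voxelVolume(post), strict = config$strictGreater)
}
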