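#' @import methods
NULL

#' ImageVolume: a 3D scalar MRI volume
#'
#' Holds the voxel data of one scalar volume (pre-contrast, post-contrast, or
#' a derived map) together with the 4x4 affine mapping 0-based voxel indices
#' to world coordinates in millimetres. All volumes are reoriented to a fixed
#' right-handed RAS convention on load, so that grids, regions of interest and
#' the atlas can be compared voxel-for-voxel. Intensities are kept in native
#' scanner units (after DICOM rescale slope/intercept); the analysis
#' self-normalizes via the normal-parenchyma mode correction, so no further
#' intensity scaling is applied.
#'
#' @slot data numeric 3D array of intensities (arbitrary MRI units). May
#'   contain \code{NA} at out-of-field voxels created by resampling.
#' @slot affine 4x4 numeric matrix, 0-based voxel index (i,j,k,1) to world mm.
#'   A voxel's world position is the position of its center.
#'
#' @seealso [readVolume()], [writeVolume()], [voxelVolume()]
#' @export
setClass("ImageVolume",
  representation(data = "array", affine = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    else if (any(dim(object@data) < 1L))
      msg <- c(msg, "all data dimensions must be >= 1")
    if (!all(dim(object@affine) == c(4L, 4L)))
      msg <- c(msg, "affine must be a 4x4 matrix")
    else {
      if (abs(det(object@affine)) < 1e-12)
        msg <- c(msg, "affine must be invertible")
      sp <- sqrt(colSums(object@affine[1:3, 1:3]^2))
      if (any(!is.finite(sp)) || any(sp <= 0))
        msg <- c(msg, "voxel spacing components must be strictly positive")
    }
    if (length(msg)) msg else TRUE
  })

#' RigidTransform: a 6-DOF spatial mapping
#'
#' Maps world coordinates of a moving image into world coordinates of a fixed
#' image: \code{x_fixed = R (x_moving - center) + center + translation}, with
#' \code{R} built from extrinsic rotations about the x, y and z world axes (in
#' that order), angles in degrees. Used for pre-to-post fusion,
#' baseline-to-follow-up mapping, and as the rigid part of atlas mapping.
#'
#' @slot rotation numeric(3), rotation angles about x, y, z in degrees.
#' @slot translation numeric(3), offsets in mm.
#' @slot center numeric(3), center of rotation in world mm.
#' @export
setClass("RigidTransform",
  representation(rotation = "numeric", translation = "numeric",
                 center = "numeric"),
  prototype(rotation = c(0, 0, 0), translation = c(0, 0, 0),
            center = c(0, 0, 0)),
  validity = function(object) {
    if (length(object@rotation) != 3L || length(object@translation) != 3L ||
        length(object@center) != 3L)
      return("rotation, translation and center must each have length 3")
    if (!all(is.finite(c(object@rotation, object@translation, object@center))))
      return("transform parameters must be finite")
    TRUE
  })

#' AffineTransform: a general linear spatial mapping
#'
#' A 3x4 matrix (linear part plus translation, mm) mapping moving-world to
#' fixed-world coordinates. Used for atlas-to-patient mapping, where a small
#' amount of scaling may be needed on top of pose.
#'
#' @slot matrix numeric 3x4 matrix; the 3x3 linear part must be invertible.
#' @export
setClass("AffineTransform",
  representation(matrix = "matrix"),
  validity = function(object) {
    if (!all(dim(object@matrix) == c(3L, 4L)))
      return("matrix must be 3x4")
    if (abs(det(object@matrix[, 1:3])) < 1e-12)
      return("linear part must be invertible")
    TRUE
  })

#' RegionOfInterest: a binary mask with a role
#'
#' A binary mask on the grid of a named reference volume. Roles are
#' \code{"tumor"} (the grossly outlined tumor region), \code{"normal"}
#' (normal brain parenchyma used for the mode correction; must avoid vessels,
#' ventricles and CSF spaces) and \code{"mucosa"} (the nasal-mucosa reference
#' used to set the enhancement threshold). Tumor and normal regions must not
#' overlap: the correction factor has to come from uninvolved tissue.
#'
#' @slot mask logical 3D array.
#' @slot role one of \code{"tumor"}, \code{"normal"}, \code{"mucosa"}.
#' @slot source one of \code{"drawn"}, \code{"transferred"}, \code{"atlas"}.
#' @slot refAffine the affine of the reference grid the mask lives on.
#' @export
setClass("RegionOfInterest",
  representation(mask = "array", role = "character", source = "character",
                 refAffine = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
      msg <- c(msg, "mask must be a logical 3D array")
    else if (sum(object@mask, na.rm = TRUE) < 1L)
      msg <- c(msg, "mask must contain at least one voxel")
    if (!object@role %in% c("tumor", "normal", "mucosa"))
      msg <- c(msg, "role must be one of tumor, normal, mucosa")
    if (!object@source %in% c("drawn", "transferred", "atlas"))
      msg <- c(msg, "source must be one of drawn, transferred, atlas")
    if (!all(dim(object@refAffine) == c(4L, 4L)))
      msg <- c(msg, "refAffine must be a 4x4 matrix")
    if (length(msg)) msg else TRUE
  })

#' PolygonSet: per-slice closed polygons of a hand outline
#'
#' The storage form of a gross hand outline: for each axial slice, one or more
#' closed polygons with vertices in world mm (x, y). Rasterization uses the
#' even-odd rule on voxel centers.
#'
#' @slot role the role the rasterized region will carry.
#' @slot slices list of lists with elements \code{index} (1-based slice) and
#'   \code{vertices} (n x 2 matrix of x, y world mm).
#' @export
setClass("PolygonSet",
  representation(role = "character", slices = "list"),
  validity = function(object) {
    for (s in object@slices) {
      if (is.null(s$index) || is.null(s$vertices))
        return("each slice needs 'index' and 'vertices'")
      v <- s$vertices
      if (!is.matrix(v) || ncol(v) != 2L || nrow(v) < 3L)
        return("each polygon needs >= 3 vertices as an n x 2 matrix")
    }
    TRUE
  })

#' SubtractionMap: post minus fused pre
#'
#' The voxelwise difference between the post-contrast volume and the
#' pre-contrast volume resampled onto the post grid. Out-of-field voxels
#' introduced by resampling are excluded from every downstream statistic via
#' \code{validMask}.
#'
#' @slot data numeric 3D array, post - pre, intensity units.
#' @slot validMask logical 3D array; TRUE where both images are in-field.
#' @slot affine the post-contrast grid affine.
#' @export
setClass("SubtractionMap",
  representation(data = "array", validMask = "array", affine = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@data), dim(object@validMask)))
      return("data and validMask dimensions differ")
    if (!is.logical(object@validMask))
      return("validMask must be logical")
    TRUE
  })

#' CorrectionFactor: the normal-parenchyma subtraction mode
#'
#' The mode of subtraction values inside the normal-parenchyma region,
#' estimated with a fixed-width histogram (bins centered on integer multiples
#' of \code{binWidth}, ties broken toward the lowest bin). Subtracting it from
#' tumor and mucosa subtraction values absorbs global inter-scan brightness
#' offsets, compensating for the lack of standardized pixel values in MRI.
#'
#' @slot value the mode, intensity units.
#' @slot binWidth histogram bin width, intensity units.
#' @slot nVoxels number of valid normal-region voxels used (>= 100 enforced).
#' @export
setClass("CorrectionFactor",
  representation(value = "numeric", binWidth = "numeric",
                 nVoxels = "integer"),
  validity = function(object) {
    if (object@nVoxels < 100L)
      return("correction factor requires >= 100 normal-region voxels")
    if (!is.finite(object@value) || object@binWidth <= 0)
      return("value must be finite and binWidth positive")
    TRUE
  })

#' EnhancementThreshold: mucosa-referenced enhancement cut-off
#'
#' Derived from corrected nasal-mucosa subtraction values: the top
#' \code{exclusionFraction} of values (by voxel count, default 5%) are
#' excluded to avoid error from outliers, and the threshold is
#' \code{thresholdFraction} (default 25%) of the remaining maximum.
#'
#' @slot value the cut-off, intensity units (> 0).
#' @slot thresholdFraction unitless, in (0, 1).
#' @slot exclusionFraction unitless, in [0, 1).
#' @slot remainingMax maximum corrected mucosa value after the trim.
#' @slot nMucosaVoxels number of corrected mucosa values used.
#' @export
setClass("EnhancementThreshold",
  representation(value = "numeric", thresholdFraction = "numeric",
                 exclusionFraction = "numeric", remainingMax = "numeric",
                 nMucosaVoxels = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@thresholdFraction <= 0 || object@thresholdFraction >= 1)
      msg <- c(msg, "thresholdFraction must be in (0, 1)")
    if (object@exclusionFraction < 0 || object@exclusionFraction >= 1)
      msg <- c(msg, "exclusionFraction must be in [0, 1)")
    if (!isTRUE(all.equal(object@value,
                          object@thresholdFraction * object@remainingMax)))
      msg <- c(msg, "value must equal thresholdFraction * remainingMax")
    if (object@value <= 0)
      msg <- c(msg, "threshold must be positive (mucosa shows no net enhancement)")
    if (length(msg)) msg else TRUE
  })

#' EnhancingVolumeResult: the volumetric measurement
#'
#' The number of tumor-region voxels whose corrected subtraction value lies
#' above the enhancement cut-off, the corresponding volume in cubic
#' centimetres, the binary enhancement mask (a subset of the tumor region),
#' and the provenance of threshold and correction.
#'
#' @slot voxelCount integer count of enhancing voxels.
#' @slot volumeCm3 enhancing volume, cm^3.
#' @slot mask logical 3D array, the enhancing voxels.
#' @slot threshold the [EnhancementThreshold-class] used.
#' @slot correction the [CorrectionFactor-class] used.
#' @export
setClass("EnhancingVolumeResult",
  representation(voxelCount = "integer", volumeCm3 = "numeric",
                 mask = "array", threshold = "EnhancementThreshold",
                 correction = "CorrectionFactor"),
  validity = function(object) {
    if (object@voxelCount < 0L) return("voxelCount must be >= 0")
    if (sum(object@mask, na.rm = TRUE) != object@voxelCount)
      return("mask voxel count must match voxelCount")
    TRUE
  })

#' AtlasBundle: template volume plus mucosa label
#'
#' The packaged anatomic atlas used to locate the nasal mucosa automatically:
#' a template volume and a binary mucosa label on the template grid. The
#' template is affine-registered to the patient's post-contrast scan and the
#' label is propagated with nearest-neighbour interpolation.
#'
#' @slot template an [ImageVolume-class].
#' @slot mucosaLabel logical 3D array on the template grid.
#' @slot metadata free-text provenance.
#' @export
setClass("AtlasBundle",
  representation(template = "ImageVolume", mucosaLabel = "array",
                 metadata = "character"),
  validity = function(object) {
    if (!identical(dim(object@mucosaLabel), dim(object@template@data)))
      return("mucosaLabel grid must match template grid")
    if (sum(object@mucosaLabel, na.rm = TRUE) < 1L)
      return("mucosa label must contain at least one voxel")
    TRUE
  })

#' DiameterMeasurement: RECIST/Macdonald diameters of a lesion mask
#'
#' The longest in-plane diameter (maximum pairwise distance between in-mask
#' voxel centers on the slice where that maximum is attained), the
#' perpendicular diameter (extent of the same slice's voxel centers projected
#' onto the direction orthogonal to the longest-diameter axis), and their
#' product.
#'
#' @slot longestDiameter cm.
#' @slot perpendicularDiameter cm.
#' @slot product cm^2.
#' @slot sliceIndex 1-based axial slice on which the measurement was made.
#' @slot endpoints 2x2 matrix of world-mm (x, y) endpoints of the longest
#'   diameter.
#' @export
setClass("DiameterMeasurement",
  representation(longestDiameter = "numeric",
                 perpendicularDiameter = "numeric", product = "numeric",
                 sliceIndex = "integer", endpoints = "matrix"),
  validity = function(object) {
    if (object@perpendicularDiameter > object@longestDiameter + 1e-9)
      return("perpendicular diameter cannot exceed longest diameter")
    if (object@longestDiameter < 0 || object@perpendicularDiameter < 0)
      return("diameters must be >= 0")
    if (!isTRUE(all.equal(object@product,
                          object@longestDiameter * object@perpendicularDiameter,
                          tolerance = 1e-6)))
      return("product must equal longestDiameter * perpendicularDiameter")
    TRUE
  })

#' PhantomSpec: parameters of a synthetic ground-truth phantom
#'
#' Describes one synthetic pre/post scan pair: a head ellipsoid of uniform
#' parenchyma, a dark resection cavity with an enhancing rim of configurable
#' thickness and contrast, optional intrinsically bright "subacute blood"
#' filling the cavity (added to both scans, or to the post scan only for the
#' counterfactual), optional thin meningeal enhancement near the cavity, a
#' strongly enhancing nasal-mucosa slab in inferior slices, a global additive
#' pre-to-post brightness offset, and Rician or Gaussian noise.
#'
#' @slot dim integer(3) grid shape.
#' @slot spacing numeric(3) voxel spacing, mm.
#' @slot parenchyma baseline parenchyma intensity.
#' @slot offset global additive offset applied to the post scan.
#' @slot shift numeric(3) rigid world shift (mm) of all geometry, used to pose
#'   follow-up timepoints.
#' @slot cavityCenter,cavityRadii cavity ellipsoid, voxel units of the
#'   unshifted grid (center) and mm (radii).
#' @slot cavityIntensity intensity inside the cavity on the pre scan.
#' @slot rimThickness rim shell thickness, mm (0 disables the rim).
#' @slot rimContrast post-contrast intensity added within the rim shell.
#' @slot roiRadii semi-axes (mm) of the gross tumor outline around the cavity
#'   center; \code{NA} (default) uses cavity radii + rim thickness + 2 mm.
#'   Fixed explicitly in the serial scenario so the baseline outline contains
#'   the rim at every timepoint.
#' @slot bloodIntensity intensity added inside the cavity ("subacute blood").
#' @slot bloodMode \code{"both"} (added to pre and post: true blood) or
#'   \code{"post"} (added to post only: enhancement filling the cavity).
#' @slot meningesContrast post-contrast intensity added along a thin meningeal
#'   arc adjacent to the cavity (0 disables it).
#' @slot mucosaContrast post-contrast intensity added inside the mucosa slab.
#' @slot noise \code{"none"}, \code{"rician"} or \code{"gaussian"}.
#' @slot sigma noise standard deviation, intensity units.
#' @slot seed integer seed; all randomness flows from it.
#' @export
setClass("PhantomSpec",
  representation(dim = "integer", spacing = "numeric", parenchyma = "numeric",
                 offset = "numeric", shift = "numeric",
                 cavityCenter = "numeric", cavityRadii = "numeric",
                 cavityIntensity = "numeric", rimThickness = "numeric",
                 rimContrast = "numeric", roiRadii = "numeric",
                 bloodIntensity = "numeric",
                 bloodMode = "character", meningesContrast = "numeric",
                 mucosaContrast = "numeric", noise = "character",
                 sigma = "numeric", seed = "integer"),
  prototype(dim = c(64L, 64L, 44L), spacing = c(1, 1, 1), parenchyma = 400,
            offset = 7, shift = c(0, 0, 0), cavityCenter = c(40, 32, 26),
            cavityRadii = c(9, 8, 7), cavityIntensity = 120,
            rimThickness = 2, rimContrast = 100,
            roiRadii = c(NA_real_, NA_real_, NA_real_), bloodIntensity = 0,
            bloodMode = "both", meningesContrast = 0, mucosaContrast = 160,
            noise = "none", sigma = 0, seed = 1L),
  validity = function(object) {
    msg <- character()
    if (length(object@dim) != 3L || any(object@dim < 16L))
      msg <- c(msg, "dim must be three entries, each >= 16")
    if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
    if (!object@noise %in% c("none", "rician", "gaussian"))
      msg <- c(msg, "noise must be none, rician or gaussian")
    if (!object@bloodMode %in% c("both", "post"))
      msg <- c(msg, "bloodMode must be 'both' or 'post'")
    if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' PhantomTruth: exact ground truth of a generated phantom
#'
#' @slot enhancingMask logical array: voxels whose noiseless post - pre
#'   exceeds the global offset by construction (rim, meninges, mucosa,
#'   post-only blood).
#' @slot enhancingCount integer: true enhancing voxels inside the (narrow)
#'   tumor region.
#' @slot cavityMask,bloodMask,meningesMask logical arrays.
#' @slot rois named list of [RegionOfInterest-class]: \code{tumor},
#'   \code{tumorGenerous}, \code{normal}, \code{mucosa}.
#' @slot offset the applied global pre-to-post offset.
#' @export
setClass("PhantomTruth",
  representation(enhancingMask = "array", enhancingCount = "integer",
                 cavityMask = "array", bloodMask = "array",
                 meningesMask = "array", rois = "list", offset = "numeric"))
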