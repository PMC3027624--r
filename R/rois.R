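#' Construct a PolygonSet
#'
#' @param slices list of per-slice outlines, each a list with \code{index}
#'   (1-based axial slice) and \code{vertices} (n x 2 matrix of x, y world mm,
#'   closed implicitly).
#' @param role role the rasterized region will carry.
#' @return a [PolygonSet-class].
#' @export
PolygonSet <- function(slices, role = "tumor") {
  slices <- lapply(slices, function(s) {
    s$vertices <- matrix(as.numeric(s$vertices), ncol = 2)
    s$index <- as.integer(s$index)
    s
  })
  new("PolygonSet", role = role, slices = slices)
}

# Even-odd (ray crossing) point-in-polygon test, vectorized over points.
# Orientation-independent: clockwise and counter-clockwise outlines give the
# same result.
pointsInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py))
    if (any(crosses)) {
      xint <- (vx[j] - vx[i]) * (py[crosses] - vy[i]) /
        (vy[j] - vy[i]) + vx[i]
      hit <- px[crosses] < xint
      inside[crosses] <- xor(inside[crosses], hit)
    }
    j <- i
  }
  inside
}

#' Rasterize per-slice polygons onto a reference grid
#'
#' A voxel is included iff its center lies inside a polygon of its slice
#' (even-odd rule). Deterministic and independent of vertex ordering.
#'
#' @param polys a [PolygonSet-class].
#' @param reference [ImageVolume-class] supplying the grid.
#' @param source provenance label for the resulting region.
#' @return a [RegionOfInterest-class].
#' @export
rasterizePolygons <- function(polys, reference, source = "drawn") {
  aff <- reference@affine
  d <- dim(reference@data)
  mask <- array(FALSE, d)
  xs <- aff[1, 1] * (seq_len(d[1]) - 1) + aff[1, 4]
  ys <- aff[2, 2] * (seq_len(d[2]) - 1) + aff[2, 4]
  px <- rep(xs, times = d[2])
  py <- rep(ys, each = d[1])
  for (s in polys@slices) {
    k <- s$index
    if (k < 1L || k > d[3])
      stop("polygon slice index ", k, " outside the reference field of view")
    inside <- pointsInPolygon(px, py, s$vertices[, 1], s$vertices[, 2])
    mask[, , k] <- mask[, , k] | matrix(inside, d[1], d[2])
  }
  if (!any(mask)) stop("ROI rasterized to zero voxels")
  new("RegionOfInterest", mask = mask, role = polys@role, source = source,
      refAffine = aff)
}

#' Wrap a binary mask as a RegionOfInterest
#'
#' @param mask logical (or 0/1 numeric) 3D array on the reference grid.
#' @param reference [ImageVolume-class] the mask lives on.
#' @param role region role.
#' @param source provenance label.
#' @return a [RegionOfInterest-class].
#' @export
roiFromMask <- function(mask, reference, role, source = "drawn") {
  if (!is.logical(mask)) mask <- mask != 0
  if (!identical(dim(mask), dim(reference@data)))
    stop("mask grid does not match the reference image grid")
  new("RegionOfInterest", mask = mask, role = role, source = source,
      refAffine = reference@affine)
}

#' Read a region of interest from file
#'
#' Accepts either the per-slice polygon JSON dialect (keys \code{role},
#' \code{slices[{index, vertices[[x, y], ...]}]}) or a binary NIfTI mask on
#' the reference grid.
#'
#' @param path .json outline or .nii/.nii.gz mask.
#' @param reference [ImageVolume-class] supplying the grid.
#' @param role region role; for JSON files the file's role is used unless
#'   given here.
#' @return a [RegionOfInterest-class].
#' @export
readRoi <- function(path, reference, role = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    spec <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(role)) role <- spec$role
    slices <- lapply(spec$slices, function(s)
      list(index = s$index,
           vertices = do.call(rbind, lapply(s$vertices, unlist))))
    rasterizePolygons(PolygonSet(slices, role = role), reference)
  } else {
    mask <- readMask(path, reference)
    if (is.null(role)) stop("a mask file needs an explicit role")
    roiFromMask(mask, reference, role = role)
  }
}

#' Write a PolygonSet as JSON
#'
#' @param polys a [PolygonSet-class].
#' @param path output .json path.
#' @param reference optional reference-image identifier recorded in the file.
#' @return \code{path}, invisibly.
#' @export
writePolygonSet <- function(polys, path, reference = "") {
  obj <- list(role = polys@role, reference = reference,
              slices = lapply(polys@slices, function(s)
                list(index = s$index,
                     vertices = lapply(seq_len(nrow(s$vertices)), function(i)
                       as.numeric(s$vertices[i, ])))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Transfer a region of interest to another scan
#'
#' Maps the mask through a rigid transform onto the target grid with
#' nearest-neighbour interpolation. This is how the tumor region outlined on
#' the baseline scan is reused on fused follow-up scans, removing the
#' re-outlining variability between timepoints.
#'
#' @param roi a [RegionOfInterest-class].
#' @param t transform mapping the ROI's reference world to the target world.
#' @param target [ImageVolume-class] target grid.
#' @return a [RegionOfInterest-class] with \code{source = "transferred"}.
#' @export
transferRoi <- function(roi, t, target) {
  mask <- resampleMaskArray(roi@mask, roi@refAffine, t, target)
  if (!any(mask))
    stop("transferred ROI is empty on the target grid")
  new("RegionOfInterest", mask = mask, role = roi@role,
      source = "transferred", refAffine = target@affine)
}

# Enforce role exclusivity and normal-region size for one analysis.
validateRoiSet <- function(tumor, normal, mucosa = NULL) {
  stopifnot(roiRole(tumor) == "tumor", roiRole(normal) == "normal")
  if (any(tumor@mask & normal@mask))
    stop("tumor and normal regions overlap; the correction factor must come from uninvolved tissue")
  if (!is.null(mucosa)) {
    stopifnot(roiRole(mucosa) == "mucosa")
    if (any(tumor@mask & mucosa@mask))
      stop("mucosa region intersects the tumor region")
  }
  nv <- voxelCount(normal)
  if (nv < 100L)
    stop("normal region has ", nv, " voxels; at least 100 are required")
  if (nv < 1000L)
    warning("normal region has only ", nv,
            " voxels; the mode estimate may be unstable")
  invisible(TRUE)
}
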