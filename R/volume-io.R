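#' Construct an ImageVolume
#'
#' @param data numeric 3D array.
#' @param spacing numeric(3) voxel spacing in mm (ignored when \code{affine}
#'   is given).
#' @param affine optional 4x4 voxel-index(0-based)-to-world-mm matrix.
#' @param origin world position of voxel (0,0,0), used with \code{spacing}.
#' @return an [ImageVolume-class].
#' @examples
#' vol <- ImageVolume(array(rnorm(8 * 8 * 4), c(8, 8, 4)), spacing = c(1, 1, 5))
#' voxelSpacing(vol)
#' @export
ImageVolume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                        origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array")
  storage.mode(data) <- "double"
  if (is.null(affine)) {
    stopifnot(length(spacing) == 3L, all(spacing > 0))
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- origin
  }
  new("ImageVolume", data = data, affine = affine)
}

# TRUE when two volumes share the same grid (shape + affine).
sameGrid <- function(a, b, tol = 1e-6) {
  affA <- if (is(a, "ImageVolume")) a@affine else a
  affB <- if (is(b, "ImageVolume")) b@affine else b
  dimA <- if (is(a, "ImageVolume")) dim(a@data) else NULL
  dimB <- if (is(b, "ImageVolume")) dim(b@data) else NULL
  ok <- max(abs(affA - affB)) < tol
  if (!is.null(dimA) && !is.null(dimB)) ok <- ok && identical(dimA, dimB)
  ok
}

# Reorient an axis-aligned volume so the affine's linear part has a positive
# diagonal (the canonical right-handed frame). Works for any affine whose
# linear part is a signed permutation times positive scales; preserves the
# multiset of intensities exactly.
reorientCanonical <- function(data, affine) {
  lin <- affine[1:3, 1:3]
  perm <- integer(3)
  for (ax in 1:3) {
    perm[ax] <- which.max(abs(lin[ax, ]))
  }
  if (length(unique(perm)) != 3L)
    stop("cannot determine a unique axis permutation; oblique volumes are not supported")
  # permute data axes so data axis perm[ax] becomes output axis ax
  data <- aperm(data, perm)
  lin <- lin[, perm, drop = FALSE]
  trans <- affine[1:3, 4]
  for (ax in 1:3) {
    if (lin[ax, ax] < 0) {
      idx <- rev(seq_len(dim(data)[ax]))
      data <- switch(ax, data[idx, , , drop = FALSE],
                     data[, idx, , drop = FALSE],
                     data[, , idx, drop = FALSE])
      # new origin is the old last voxel along this axis
      trans <- trans + lin[, ax] * (dim(data)[ax] - 1)
      lin[, ax] <- -lin[, ax]
    }
  }
  aff <- diag(4)
  aff[1:3, 1:3] <- lin
  aff[1:3, 4] <- trans
  list(data = data, affine = aff)
}

#' Read a medical image volume
#'
#' Reads a NIfTI file or a DICOM series directory and reorients it to the
#' canonical internal frame (right-handed, RAS-like: affine linear part with a
#' positive diagonal). Intensities are unmodified beyond the DICOM rescale
#' slope/intercept.
#'
#' @param path a .nii/.nii.gz file or a directory of DICOM slices.
#' @param format \code{"auto"} (by path type), \code{"nifti"} or
#'   \code{"dicom"}.
#' @return an [ImageVolume-class].
#' @seealso [writeVolume()], [writeDicomSeries()]
#' @export
readVolume <- function(path, format = c("auto", "nifti", "dicom")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("input path does not exist: ", path)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom" else "nifti"
  if (format == "dicom") return(readDicomSeries(path))
  img <- RNifti::readNifti(path)
  if (!identical(RNifti::orientation(img), "RAS"))
    RNifti::orientation(img) <- "RAS"
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  out <- reorientCanonical(arr, aff)
  ImageVolume(out$data, affine = out$affine)
}

#' Write a volume or mask as NIfTI
#'
#' @param vol an [ImageVolume-class], or a logical/numeric 3D array with
#'   \code{reference} giving the grid.
#' @param path output .nii or .nii.gz path.
#' @param reference an [ImageVolume-class] supplying the affine when
#'   \code{vol} is a bare array.
#' @param datatype NIfTI storage type; the default \code{"double"} round-trips
#'   intensities bit-exactly, use \code{"uint8"} for masks.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path, reference = NULL, datatype = "double") {
  if (is(vol, "ImageVolume")) {
    arr <- vol@data
    aff <- vol@affine
  } else {
    if (is.null(reference))
      stop("a bare array needs a reference volume for its grid")
    arr <- vol
    storage.mode(arr) <- "double"
    aff <- if (is(reference, "ImageVolume")) reference@affine else reference
  }
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# Read a binary mask volume on (and checked against) a reference grid.
readMask <- function(path, reference, tol = 1e-4) {
  vol <- readVolume(path)
  if (!sameGrid(vol, reference, tol = tol))
    stop("mask grid does not match the reference image grid: ", path)
  vol@data != 0
}

# World coordinates of all voxel centers of a grid (n x 3), 0-based indexing.
gridWorldCoords <- function(affine, dims) {
  idx <- as.matrix(expand.grid(i = seq_len(dims[1]) - 1,
                               j = seq_len(dims[2]) - 1,
                               k = seq_len(dims[3]) - 1))
  t(affine[1:3, 1:3] %*% t(idx) + affine[1:3, 4])
}
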