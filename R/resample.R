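#' Resample a volume onto a reference grid through a transform
#'
#' Realizes the fusion: the output has the reference's grid, and each
#' reference voxel takes the value of the moving volume at the back-projected
#' location \code{t^-1(x)}. Out-of-field voxels are filled with the sentinel
#' \code{NA} and excluded from all downstream statistics. When the transform
#' is the identity and the grids already coincide, the input is returned
#' unchanged (no interpolation is applied).
#'
#' @param vol moving [ImageVolume-class].
#' @param t a [RigidTransform-class] or [AffineTransform-class] mapping
#'   moving-world to fixed-world.
#' @param reference [ImageVolume-class] supplying the output grid.
#' @param interp \code{"linear"} for intensity images (default),
#'   \code{"nearest"} for masks/labels.
#' @return an [ImageVolume-class] on the reference grid.
#' @export
resampleVolume <- function(vol, t, reference, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  if (isIdentityTransform(t) && sameGrid(vol, reference))
    return(vol)
  map <- solve(vol@affine) %*% solve(transformMatrix(t)) %*% reference@affine
  out <- .resampleKernel(vol@data, dim(vol@data), map, dim(reference@data),
                         if (interp == "nearest") 0L else 1L)
  ImageVolume(out, affine = reference@affine)
}

# Resample a logical mask with nearest-neighbour interpolation; out-of-field
# voxels become FALSE.
resampleMaskArray <- function(mask, maskAffine, t, reference) {
  m <- mask
  storage.mode(m) <- "double"
  map <- solve(maskAffine) %*% solve(transformMatrix(t)) %*% reference@affine
  out <- .resampleKernel(m, dim(m), map, dim(reference@data), 0L)
  res <- !is.na(out) & out > 0.5
  dim(res) <- dim(reference@data)
  res
}

# Downsample a volume by integer strides (for multi-resolution registration).
decimateVolume <- function(vol, stride) {
  if (all(stride == 1L)) return(vol)
  d <- dim(vol@data)
  ix <- seq(1L, d[1], by = stride[1])
  iy <- seq(1L, d[2], by = stride[2])
  iz <- seq(1L, d[3], by = stride[3])
  arr <- vol@data[ix, iy, iz, drop = FALSE]
  aff <- vol@affine
  aff[1:3, 1] <- aff[1:3, 1] * stride[1]
  aff[1:3, 2] <- aff[1:3, 2] * stride[2]
  aff[1:3, 3] <- aff[1:3, 3] * stride[3]
  ImageVolume(arr, affine = aff)
}
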