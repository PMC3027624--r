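# Conventional 1D (RECIST) and 2D (Macdonald) measurements from binary lesion
# masks, for side-by-side comparison with the volumetric result. Diameters are
# measured across the full in-plane lesion extent -- including any enclosed
# cavity -- the way a reader's calipers would span it.

# Per-slice in-mask voxel centers as an n x 2 matrix of world mm.
.sliceCenters <- function(mask2d, spacing) {
  idx <- which(mask2d, arr.ind = TRUE)
  cbind((idx[, 1] - 1) * spacing[1], (idx[, 2] - 1) * spacing[2])
}

# Longest pairwise distance between points (mm) plus its endpoints. Uses the
# convex hull: the diameter of a point set is attained on its hull.
.maxPairDist <- function(pts) {
  if (nrow(pts) == 1L)
    return(list(d = 0, a = pts[1, ], b = pts[1, ]))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  dmat <- as.matrix(stats::dist(hp))
  im <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
  list(d = max(dmat), a = hp[im[1], ], b = hp[im[2], ])
}

#' RECIST longest diameter of a lesion mask
#'
#' The maximum pairwise Euclidean distance between in-mask voxel centers
#' within an axial slice, in cm. For a 3D mask the slice with the largest
#' per-slice maximum is reported.
#'
#' @param mask logical 2D slice or 3D mask.
#' @param spacing in-plane spacing (dx, dy) in mm.
#' @return longest diameter in cm.
#' @export
recistLongestDiameter <- function(mask, spacing) {
  macdonaldMeasurement(mask, spacing)@longestDiameter
}

#' Macdonald bidimensional measurement of a lesion mask
#'
#' Longest in-plane diameter as in [recistLongestDiameter()]; the
#' perpendicular diameter is the extent of the same slice's voxel centers
#' projected onto the direction orthogonal to the longest-diameter axis; the
#' product is in cm^2. Measured on the slice with the largest longest
#' diameter.
#'
#' @param mask logical 2D slice or 3D mask.
#' @param spacing in-plane spacing (dx, dy) in mm.
#' @return a [DiameterMeasurement-class].
#' @export
macdonaldMeasurement <- function(mask, spacing) {
  stopifnot(length(spacing) >= 2, all(spacing[1:2] > 0))
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  if (!any(mask, na.rm = TRUE)) stop("lesion mask is empty")
  mask[is.na(mask)] <- FALSE
  bestSlice <- 0L; best <- NULL
  for (k in seq_len(dim(mask)[3])) {
    if (!any(mask[, , k])) next
    pts <- .sliceCenters(mask[, , k], spacing)
    mp <- .maxPairDist(pts)
    if (is.null(best) || mp$d > best$d) {
      best <- mp; best$pts <- pts; bestSlice <- k
    }
  }
  longest <- best$d / 10
  if (best$d < 1e-12) {
    perp <- 0
  } else {
    u <- (best$b - best$a) / best$d
    v <- c(-u[2], u[1])
    proj <- best$pts %*% v
    perp <- (max(proj) - min(proj)) / 10
  }
  new("DiameterMeasurement", longestDiameter = longest,
      perpendicularDiameter = perp, product = longest * perp,
      sliceIndex = bestSlice, endpoints = rbind(best$a, best$b))
}

#' Bidimensional product of two diameters
#'
#' The Macdonald-style product of the longest diameter and its perpendicular,
#' rounded for reporting to 3 significant figures (4.3 cm x 3.2 cm reports as
#' 13.8 cm^2).
#'
#' @param d1,d2 diameters in cm, both >= 0.
#' @return product in cm^2, 3 significant figures.
#' @examples
#' bidimensionalProduct(4.3, 3.2)  # 13.8
#' bidimensionalProduct(3.7, 1.7)  # 6.29
#' @export
bidimensionalProduct <- function(d1, d2) {
  if (d1 < 0 || d2 < 0) stop("diameters must be >= 0")
  signif(d1 * d2, 3)
}
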