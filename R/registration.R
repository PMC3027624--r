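# Intensity-based registration.
#
# Same-subject, same-modality pairs (pre vs post contrast T1, baseline vs
# follow-up) differ mainly by pose plus a global brightness change and a
# sparse set of enhancing voxels, so the similarity objective is negative
# normalized cross-correlation over the in-field overlap: invariant to global
# linear intensity changes and piecewise-smooth in the transform parameters,
# which a derivative-free simplex optimizer needs. Optimization is
# multi-resolution (decimated grids first) with a deterministic coarse
# translation grid search for initialization; there is no randomness, so
# repeated runs give identical transforms.

negNCC <- function(fixedVals, movingVals, minOverlapFrac = 0.2) {
  ok <- !is.na(movingVals) & !is.na(fixedVals)
  n <- sum(ok)
  if (n < minOverlapFrac * length(fixedVals) || n < 32L) return(1e6)
  f <- fixedVals[ok]; m <- movingVals[ok]
  sf <- stats::sd(f); sm <- stats::sd(m)
  if (sf < 1e-12 || sm < 1e-12) return(1e6)
  -stats::cor(f, m)
}

# Evaluate the similarity of moving mapped by parameters p onto fixedL.
.rigidObjective <- function(p, moving, fixedL, center) {
  t <- rigidTransform(rotation = p[1:3], translation = p[4:6],
                      center = center)
  map <- solve(moving@affine) %*% solve(transformMatrix(t)) %*% fixedL@affine
  mv <- .resampleKernel(moving@data, dim(moving@data), map, dim(fixedL@data), 1L)
  negNCC(as.vector(fixedL@data), as.vector(mv))
}

.registrationLevels <- function(dims) {
  strides <- c(4L, 2L, 1L)
  strides[vapply(strides, function(s) all(dims %/% s >= 8L), logical(1))]
}

worldCenter <- function(vol) {
  as.numeric(vol@affine[1:3, 1:3] %*% ((dim(vol@data) - 1) / 2) +
               vol@affine[1:3, 4])
}

#' Rigid registration of two volumes
#'
#' Estimates the 6-DOF transform mapping moving-world onto fixed-world by
#' maximizing normalized cross-correlation, coarse-to-fine. Transforms whose
#' magnitude falls below 0.1 mm / 0.1 degree are snapped to the exact
#' identity, so already-aligned pairs are fused without interpolation loss.
#'
#' @param moving,fixed [ImageVolume-class] objects with substantial world
#'   overlap.
#' @param searchRange half-width (mm) of the coarse translation grid search.
#' @param maxit iteration budget per resolution level (coarse to fine).
#' @return a [RigidTransform-class] (rotation center at the fixed volume's
#'   world center).
#' @examples
#' \donttest{
#' ph <- generatePhantom(phantomSpec(noise = "none"))
#' t <- registerRigid(ph$post, ph$post)   # identity
#' }
#' @export
registerRigid <- function(moving, fixed, searchRange = 8,
                          maxit = c(400L, 200L, 120L)) {
  center <- worldCenter(fixed)
  strides <- .registrationLevels(dim(fixed@data))
  maxit <- rep_len(maxit, length(strides))
  p <- rep(0, 6)

  # deterministic coarse translation search at the coarsest level
  coarse <- decimateVolume(fixed, rep(strides[1], 3))
  offs <- seq(-searchRange, searchRange, by = searchRange / 2)
  best <- .rigidObjective(p, moving, coarse, center)
  for (ox in offs) for (oy in offs) for (oz in offs) {
    cand <- c(0, 0, 0, ox, oy, oz)
    v <- .rigidObjective(cand, moving, coarse, center)
    if (v < best - 1e-12) { best <- v; p <- cand }
  }
  # greedy per-axis rotation search so small rotations start in-basin
  for (ax in 1:3) {
    for (ang in c(-6, -4, -2, 2, 4, 6)) {
      cand <- p; cand[ax] <- ang
      v <- .rigidObjective(cand, moving, coarse, center)
      if (v < best - 1e-12) { best <- v; p <- cand }
    }
  }

  conv <- 0L
  value <- best
  for (li in seq_along(strides)) {
    fixedL <- decimateVolume(fixed, rep(strides[li], 3))
    valPrev <- Inf
    for (run in 1:2) {  # restart the simplex once per level for precision
      fit <- stats::optim(p, .rigidObjective, moving = moving, fixedL = fixedL,
                          center = center, method = "Nelder-Mead",
                          control = list(maxit = maxit[li], reltol = 1e-9))
      p <- fit$par
      conv <- fit$convergence
      valPrev <- value
      value <- fit$value
    }
  }
  if (value >= 1e6)
    stop(sprintf("rigid registration failed to find overlap (final metric %g)",
                 value))
  if (conv != 0L && valPrev - value > 1e-5)
    warning(sprintf("rigid optimizer stopped at the iteration limit while still improving (final metric %.6f)",
                    value))
  if (max(abs(p[1:3])) < 0.1 && max(abs(p[4:6])) < 0.1)
    p <- rep(0, 6)
  rigidTransform(rotation = p[1:3], translation = p[4:6], center = center)
}

.affineObjective <- function(p, moving, fixedL, center) {
  t <- .affineFromParams(p, center)
  map <- solve(moving@affine) %*% solve(transformMatrix(t)) %*% fixedL@affine
  mv <- .resampleKernel(moving@data, dim(moving@data), map, dim(fixedL@data), 1L)
  negNCC(as.vector(fixedL@data), as.vector(mv))
}

# 9-parameter affine: rotations (deg), translations (mm), log-scales,
# applied about `center`.
.affineFromParams <- function(p, center) {
  R <- rotationMatrix3(p[1:3]) %*% diag(exp(p[7:9]))
  m <- cbind(R, center + p[4:6] - R %*% center)
  affineTransform(m)
}

#' Affine registration (atlas to patient)
#'
#' Nine degrees of freedom (pose plus per-axis scale) estimated the same way
#' as [registerRigid()]; enough to map the packaged atlas template onto a
#' patient scan, where head size may differ.
#'
#' @inheritParams registerRigid
#' @return an [AffineTransform-class].
#' @export
registerAffine <- function(moving, fixed, searchRange = 8,
                           maxit = c(500L, 300L, 150L)) {
  center <- worldCenter(fixed)
  strides <- .registrationLevels(dim(fixed@data))
  maxit <- rep_len(maxit, length(strides))
  p <- rep(0, 9)

  coarse <- decimateVolume(fixed, rep(strides[1], 3))
  offs <- seq(-searchRange, searchRange, by = searchRange / 2)
  best <- .affineObjective(p, moving, coarse, center)
  for (ox in offs) for (oy in offs) for (oz in offs) {
    cand <- c(0, 0, 0, ox, oy, oz, 0, 0, 0)
    v <- .affineObjective(cand, moving, coarse, center)
    if (v < best - 1e-12) { best <- v; p <- cand }
  }
  for (ax in 1:3) {
    for (ang in c(-6, -4, -2, 2, 4, 6)) {
      cand <- p; cand[ax] <- ang
      v <- .affineObjective(cand, moving, coarse, center)
      if (v < best - 1e-12) { best <- v; p <- cand }
    }
  }

  value <- best
  for (li in seq_along(strides)) {
    fixedL <- decimateVolume(fixed, rep(strides[li], 3))
    for (run in 1:2) {
      fit <- stats::optim(p, .affineObjective, moving = moving,
                          fixedL = fixedL, center = center,
                          method = "Nelder-Mead",
                          control = list(maxit = maxit[li], reltol = 1e-9))
      p <- fit$par
      value <- fit$value
    }
  }
  if (value >= 1e6)
    stop(sprintf("affine registration failed to find overlap (final metric %g)",
                 value))
  if (max(abs(p[1:3])) < 0.1 && max(abs(p[4:6])) < 0.1 &&
      max(abs(p[7:9])) < 1e-3)
    return(affineTransform(diag(4)))
  .affineFromParams(p, center)
}
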