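#' Construct a rigid transform
#'
#' @param rotation angles about the world x, y, z axes in degrees, applied in
#'   that order (extrinsic).
#' @param translation offsets in mm.
#' @param center rotation center in world mm.
#' @return a [RigidTransform-class].
#' @examples
#' t <- rigidTransform(rotation = c(0, 0, 3), translation = c(3, -2, 1))
#' transformPoints(t, cbind(10, 0, 0))
#' @export
rigidTransform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  new("RigidTransform", rotation = as.numeric(rotation),
      translation = as.numeric(translation), center = as.numeric(center))
}

#' Construct an affine transform
#'
#' @param matrix 3x4 matrix (linear part and translation, mm), or a 4x4
#'   homogeneous matrix whose last row is (0,0,0,1).
#' @return an [AffineTransform-class].
#' @export
affineTransform <- function(matrix) {
  if (all(dim(matrix) == c(4L, 4L))) matrix <- matrix[1:3, , drop = FALSE]
  new("AffineTransform", matrix = matrix)
}

# 3x3 rotation from degrees about x, y, z (applied in that order).
rotationMatrix3 <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' @rdname transformMatrix
#' @export
setMethod("transformMatrix", "RigidTransform", function(t) {
  R <- rotationMatrix3(t@rotation)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- t@center + t@translation - R %*% t@center
  m
})

#' @rdname transformMatrix
#' @export
setMethod("transformMatrix", "AffineTransform", function(t) {
  m <- diag(4)
  m[1:3, ] <- t@matrix
  m
})

#' @rdname invertTransform
#' @export
setMethod("invertTransform", "RigidTransform", function(t) {
  m <- solve(transformMatrix(t))
  # recover angles from the inverse rotation matrix (R^T); keep the same
  # center so composition with the original is identity by construction
  R <- m[1:3, 1:3]
  ry <- asin(pmin(pmax(-R[3, 1], -1), 1))
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal lock
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  rot <- c(rx, ry, rz) * 180 / pi
  trans <- m[1:3, 4] - t@center + R %*% t@center
  rigidTransform(rotation = rot, translation = as.numeric(trans),
                 center = t@center)
})

#' @rdname invertTransform
#' @export
setMethod("invertTransform", "AffineTransform", function(t) {
  affineTransform(solve(transformMatrix(t)))
})

#' @rdname transformPoints
#' @export
setMethod("transformPoints", "RigidTransform", function(t, pts) {
  m <- transformMatrix(t)
  pts <- matrix(pts, ncol = 3)
  t(m[1:3, 1:3] %*% t(pts) + m[1:3, 4])
})

#' @rdname transformPoints
#' @export
setMethod("transformPoints", "AffineTransform", function(t, pts) {
  m <- transformMatrix(t)
  pts <- matrix(pts, ncol = 3)
  t(m[1:3, 1:3] %*% t(pts) + m[1:3, 4])
})

#' Compose two transforms
#'
#' @param outer,inner transforms; the result applies \code{inner} first.
#' @return an [AffineTransform-class] equal to \code{outer(inner(x))} (a
#'   [RigidTransform-class] composition is still rigid but is returned in
#'   matrix form).
#' @export
composeTransforms <- function(outer, inner) {
  affineTransform(transformMatrix(outer) %*% transformMatrix(inner))
}

# Is this transform the identity to within tight tolerance?
isIdentityTransform <- function(t, tol = 1e-6) {
  max(abs(transformMatrix(t) - diag(4))) < tol
}

#' Serialize a transform to a plain-text file
#'
#' Key/value text: rotation in degrees, translation and center in mm (rigid),
#' or the 3x4 matrix row by row (affine).
#'
#' @param t a [RigidTransform-class] or [AffineTransform-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeTransform <- function(t, path) {
  if (is(t, "RigidTransform")) {
    lines <- c("type: rigid",
               sprintf("rotation_deg: %.10g %.10g %.10g", t@rotation[1],
                       t@rotation[2], t@rotation[3]),
               sprintf("translation_mm: %.10g %.10g %.10g", t@translation[1],
                       t@translation[2], t@translation[3]),
               sprintf("center_mm: %.10g %.10g %.10g", t@center[1],
                       t@center[2], t@center[3]))
  } else if (is(t, "AffineTransform")) {
    lines <- c("type: affine",
               vapply(1:3, function(i)
                 sprintf("row%d: %.10g %.10g %.10g %.10g", i,
                         t@matrix[i, 1], t@matrix[i, 2], t@matrix[i, 3],
                         t@matrix[i, 4]), character(1)))
  } else stop("unsupported transform type")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ":\\s*")
  vals <- stats::setNames(lapply(kv, function(p)
    if (p[1] == "type") p[2] else as.numeric(strsplit(p[2], "\\s+")[[1]])),
    vapply(kv, `[`, character(1), 1))
  if (vals$type == "rigid") {
    rigidTransform(rotation = vals$rotation_deg,
                   translation = vals$translation_mm, center = vals$center_mm)
  } else {
    affineTransform(rbind(vals$row1, vals$row2, vals$row3))
  }
}
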