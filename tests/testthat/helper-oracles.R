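# Independent brute-force oracles used to freeze expected values. These stay
# deliberately naive (double loops, O(n^2) scans) and share no code with the
# package internals they check.

# Crossing-number point-in-polygon, one point at a time.
oraclePointInPolygon <- function(px, py, verts) {
  n <- nrow(verts)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- verts[i, 1]; yi <- verts[i, 2]
    xj <- verts[j, 1]; yj <- verts[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Rasterization oracle: test every voxel center of a slice against a polygon.
oracleRasterizeSlice <- function(verts, dims, spacing) {
  mask <- matrix(FALSE, dims[1], dims[2])
  for (i in seq_len(dims[1])) {
    for (j in seq_len(dims[2])) {
      mask[i, j] <- oraclePointInPolygon((i - 1) * spacing[1],
                                         (j - 1) * spacing[2], verts)
    }
  }
  mask
}

# O(n^2) longest pairwise distance between in-mask voxel centers (mm).
oracleMaxPairDist <- function(mask2d, spacing) {
  idx <- which(mask2d, arr.ind = TRUE)
  pts <- cbind((idx[, 1] - 1) * spacing[1], (idx[, 2] - 1) * spacing[2])
  best <- 0
  pair <- c(1L, 1L)
  n <- nrow(pts)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      d <- sqrt(sum((pts[a, ] - pts[b, ])^2))
      if (d > best) { best <- d; pair <- c(a, b) }
    }
  }
  list(d = best, a = pts[pair[1], ], b = pts[pair[2], ], pts = pts)
}

# Projection-extent perpendicular diameter for the oracle pair (mm).
oraclePerpExtent <- function(or) {
  if (or$d == 0) return(0)
  u <- (or$b - or$a) / or$d
  v <- c(-u[2], u[1])
  proj <- or$pts %*% v
  max(proj) - min(proj)
}

# Histogram-mode oracle: count values per bin center (integer multiples of w)
# by explicit loop; ties toward the lowest center.
oracleHistMode <- function(values, w) {
  centers <- sort(unique(round(values / w) * w))
  counts <- vapply(centers, function(ctr)
    sum(round(values / w) * w == ctr), numeric(1))
  centers[which(counts == max(counts))[1]]
}

# Order-statistic threshold oracle: drop the ceil(ef*n) largest, take the max
# of the rest, multiply by tf.
oracleThreshold <- function(values, ef, tf) {
  n <- length(values)
  k <- ceiling(ef * n)
  kept <- sort(values)[seq_len(n - k)]
  tf * max(kept)
}

oracleDice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
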