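# Internal geometric primitives shared by the simulator and the probes.
# Segment sets are stored as plain matrices with columns
#   x1 y1 z1 x2 y2 z2 r1 r2 [cell]
# (radii in micrometres; the optional cell column tags the parent cell).

SEG_COLS <- c("x1", "y1", "z1", "x2", "y2", "z2", "r1", "r2")

empty_segments <- function(cell = FALSE) {
  cols <- if (cell) c(SEG_COLS, "cell") else SEG_COLS
  matrix(numeric(0), ncol = length(cols), dimnames = list(NULL, cols))
}

#' Segment lengths
#'
#' Euclidean lengths of the rows of a segment matrix (columns
#' `x1 y1 z1 x2 y2 z2 r1 r2`, the package's curve representation).
#'
#' @param segs segment matrix.
#' @return Numeric vector of lengths, um.
#' @export
seg_lengths <- function(segs) {
  if (nrow(segs) == 0) return(numeric(0))
  sqrt((segs[, 4] - segs[, 1])^2 + (segs[, 5] - segs[, 2])^2 +
         (segs[, 6] - segs[, 3])^2)
}

polyline_to_segments <- function(points, radius, cell = NA_real_) {
  n <- nrow(points)
  if (n < 2) return(empty_segments(cell = !is.na(cell)))
  i <- seq_len(n - 1)
  out <- cbind(points[i, 1], points[i, 2], points[i, 3],
               points[i + 1, 1], points[i + 1, 2], points[i + 1, 3],
               radius[i], radius[i + 1])
  colnames(out) <- SEG_COLS
  if (!is.na(cell)) out <- cbind(out, cell = cell)
  out
}

# Parametric clip of segments to an axis-aligned box [lo, hi] (closed; the
# boundary has measure zero for length).  Returns clipped segment matrix.
clip_segments_box <- function(segs, lo, hi) {
  if (nrow(segs) == 0) return(segs)
  t0 <- rep(0, nrow(segs))
  t1 <- rep(1, nrow(segs))
  for (ax in 1:3) {
    p <- segs[, ax]
    q <- segs[, ax + 3]
    d <- q - p
    deg <- abs(d) < 1e-300
    # degenerate along this axis: keep iff inside slab
    inside <- p >= lo[ax] & p <= hi[ax]
    ta <- ifelse(deg, ifelse(inside, 0, 1), (lo[ax] - p) / d)
    tb <- ifelse(deg, ifelse(inside, 1, 0), (hi[ax] - p) / d)
    tmin <- pmin(ta, tb)
    tmax <- pmax(ta, tb)
    t0 <- pmax(t0, tmin)
    t1 <- pmin(t1, tmax)
  }
  keep <- which(t1 > t0)
  if (length(keep) == 0) return(segs[0, , drop = FALSE])
  s <- segs[keep, , drop = FALSE]
  a0 <- t0[keep]
  a1 <- t1[keep]
  out <- s
  for (ax in 1:3) {
    d <- s[, ax + 3] - s[, ax]
    out[, ax]     <- s[, ax] + a0 * d
    out[, ax + 3] <- s[, ax] + a1 * d
  }
  dr <- s[, 8] - s[, 7]
  out[, 7] <- s[, 7] + a0 * dr
  out[, 8] <- s[, 7] + a1 * dr
  out
}

#' Clip segments to a z slab
#'
#' @param segs segment matrix.
#' @param z0,z1 slab bounds, um.
#' @return Clipped segment matrix (radii interpolated).
#' @export
clip_segments_z <- function(segs, z0, z1) {
  if (nrow(segs) == 0) return(segs)
  clip_segments_box(segs, c(-Inf, -Inf, z0), c(Inf, Inf, z1))
}

# Anisotropic rescale of z about `base` (section collapse model).
shrink_segments_z <- function(segs, factor, base = 0) {
  if (nrow(segs) > 0) {
    segs[, 3] <- base + (segs[, 3] - base) * factor
    segs[, 6] <- base + (segs[, 6] - base) * factor
  }
  segs
}

# Wrap segments into [0, dims] with periodic boundary conditions: every
# periodic copy of a segment that intersects the block is clipped and kept.
# Used by the simulator so that length density is exactly stationary (no
# edge deficit from arbors leaving the block).
wrap_segments <- function(segs, dims) {
  if (nrow(segs) == 0) return(segs)
  out <- vector("list", 0)
  kx <- cbind(floor(pmin(segs[, 1], segs[, 4]) / dims[1]),
              floor(pmax(segs[, 1], segs[, 4]) / dims[1]))
  ky <- cbind(floor(pmin(segs[, 2], segs[, 5]) / dims[2]),
              floor(pmax(segs[, 2], segs[, 5]) / dims[2]))
  kz <- cbind(floor(pmin(segs[, 3], segs[, 6]) / dims[3]),
              floor(pmax(segs[, 3], segs[, 6]) / dims[3]))
  key <- paste(kx[, 1], kx[, 2], ky[, 1], ky[, 2], kz[, 1], kz[, 2])
  for (grp in split(seq_len(nrow(segs)), key)) {
    i1 <- grp[1]
    sub <- segs[grp, , drop = FALSE]
    for (ix in kx[i1, 1]:kx[i1, 2]) for (iy in ky[i1, 1]:ky[i1, 2])
      for (iz in kz[i1, 1]:kz[i1, 2]) {
        shifted <- sub
        shifted[, c(1, 4)] <- shifted[, c(1, 4)] - ix * dims[1]
        shifted[, c(2, 5)] <- shifted[, c(2, 5)] - iy * dims[2]
        shifted[, c(3, 6)] <- shifted[, c(3, 6)] - iz * dims[3]
        clipped <- clip_segments_box(shifted, c(0, 0, 0), dims)
        if (nrow(clipped)) out[[length(out) + 1L]] <- clipped
      }
  }
  if (!length(out)) return(segs[0, , drop = FALSE])
  do.call(rbind, out)
}

rotation_y <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), 0, sin(a),
           0, 1, 0,
           -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
}

# Uniform random 3D rotation matrix (QR of a Gaussian matrix, sign-fixed).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

# von Mises-Fisher sample on the sphere about unit vector mu.
rvmf <- function(n, mu, kappa) {
  mu <- mu / sqrt(sum(mu^2))
  if (kappa <= 0) {
    v <- matrix(rnorm(3 * n), n, 3)
    return(v / sqrt(rowSums(v^2)))
  }
  u <- runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  # orthonormal frame around mu
  a <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * mu) * mu
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(mu[2] * e1[3] - mu[3] * e1[2],
          mu[3] * e1[1] - mu[1] * e1[3],
          mu[1] * e1[2] - mu[2] * e1[1])
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  out <- outer(w, mu) + outer(s * cos(phi), e1) + outer(s * sin(phi), e2)
  out / sqrt(rowSums(out^2))
}

#' Project 3D segments onto a rotated vertical view
#'
#' Rotates by `angle_deg` about a vertical (y-parallel) axis through
#' `(center[1], center[2])` in the x-z plane and projects along the
#' viewing (z) axis.
#'
#' @param segs segment matrix.
#' @param angle_deg rotation angle, degrees.
#' @param center x and z of the rotation axis.
#' @return 2D segment matrix (`x1 y1 x2 y2`).
#' @export
project_segments <- function(segs, angle_deg, center = c(0, 0)) {
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  if (nrow(segs) == 0)
    return(matrix(numeric(0), ncol = 4,
                  dimnames = list(NULL, c("x1", "y1", "x2", "y2"))))
  px <- function(x, z) (x - center[1]) * ca + (z - center[2]) * sa + center[1]
  cbind(x1 = px(segs[, 1], segs[, 3]), y1 = segs[, 2],
        x2 = px(segs[, 4], segs[, 6]), y2 = segs[, 5])
}

seg_lengths_2d <- function(segs2) {
  if (nrow(segs2) == 0) return(numeric(0))
  sqrt((segs2[, 3] - segs2[, 1])^2 + (segs2[, 4] - segs2[, 2])^2)
}

# Crossing tests use a half-open orientation rule (zero cross-product is
# treated as the non-negative side) so grazing contacts resolve
# deterministically.
cross2 <- function(ax, ay, bx, by) ax * by - ay * bx

# Vectorised proper-crossing test for paired rows (same length).
crossing_test <- function(p1x, p1y, p2x, p2y, q1x, q1y, q2x, q2y) {
  d1 <- cross2(p2x - p1x, p2y - p1y, q1x - p1x, q1y - p1y)
  d2 <- cross2(p2x - p1x, p2y - p1y, q2x - p1x, q2y - p1y)
  d3 <- cross2(q2x - q1x, q2y - q1y, p1x - q1x, p1y - q1y)
  d4 <- cross2(q2x - q1x, q2y - q1y, p2x - q1x, p2y - q1y)
  ((d1 < 0) != (d2 < 0)) & ((d3 < 0) != (d4 < 0))
}

# Shoelace area of an ordered planar polygon given 2D coordinates.
polygon_area_2d <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

polygon_centroid_2d <- function(poly) colMeans(poly)

# Horizontal-line crossings with a closed polygon; returns sorted x values.
polygon_line_crossings <- function(poly, y) {
  n <- nrow(poly)
  i2 <- c(2:n, 1)
  y1 <- poly[, 2]; y2 <- poly[i2, 2]
  hit <- (y1 < y) != (y2 < y)   # half-open: vertex on the line counts once
  if (!any(hit)) return(numeric(0))
  t <- (y - y1[hit]) / (y2[hit] - y1[hit])
  sort(poly[hit, 1] + t * (poly[i2, 1][hit] - poly[hit, 1]))
}
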