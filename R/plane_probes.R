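# Length density by isotropic virtual planes: families of parallel test
# planes with uniformly random 3D orientation swept through a sampling box;
# curve-plane intersections estimate length via L_V = 2 SumQ / Sum a(plane).

#' Uniform random directions on the hemisphere
#'
#' Area-weighted uniform directions (polar-angle density proportional to
#' sin theta), returned as unit vectors with non-negative z.
#'
#' @param n number of directions.
#' @param seed optional integer seed.
#' @return `n x 3` matrix of unit vectors.
#' @export
isotropic_direction <- function(n = 1, seed = NULL) {
  with_seed(seed, {
    z <- runif(n)                 # cos(theta) uniform on (0, 1): hemisphere
    phi <- runif(n, 0, 2 * pi)
    s <- sqrt(pmax(0, 1 - z^2))
    cbind(s * cos(phi), s * sin(phi), z)
  })
}

# Systematic uniform random (SUR) design over orientation space: cos(theta)
# stratified into n bands with a common random phase, azimuths on a
# golden-angle sequence with a random start.  Each row is marginally
# isotropic; jointly they cover the hemisphere evenly, which is how the
# package schedules "a new isotropic orientation per field".
plane_probe_orientations <- function(n, seed = NULL) {
  with_seed(seed, {
    i <- seq_len(n)
    z <- (i - 1 + runif(1)) / n
    golden <- (sqrt(5) - 1) / 2
    phi <- 2 * pi * ((i * golden + runif(1)) %% 1)
    s <- sqrt(pmax(0, 1 - z^2))
    cbind(s * cos(phi), s * sin(phi), z)
  })
}

#' Plane-probe configuration
#'
#' @param d spacing between consecutive parallel planes, um (default 20).
#' @param box_dims sampling-box extents `(x, y, z)`, um.
#' @param p_box number of corner points representing the box in the
#'   corner-point form of the estimator (default 4, the four topmost
#'   corners).
#' @return Object of class `plane_probe_config`.
#' @export
plane_probe_config <- function(d = 20, box_dims = c(60, 60, 12), p_box = 4) {
  if (d <= 0) stop("d must be positive")
  if (any(box_dims <= 0)) stop("box_dims must be positive")
  structure(list(d = d, box_dims = as.numeric(box_dims), p_box = p_box),
            class = "plane_probe_config")
}

box_corners <- function(origin, dims) {
  g <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  sweep(g %*% diag(dims), 2, origin, `+`)
}

#' Generate a family of virtual planes through a box
#'
#' Parallel planes `normal . x = offset_k` with isotropic random normal,
#' spacing `d`, and a uniformly random phase in `[0, d)`.
#'
#' @param box list with `origin` and `dims` (um).
#' @param config a [plane_probe_config()].
#' @param normal optional fixed unit normal (otherwise isotropic random).
#' @param seed optional integer seed.
#' @return Object of class `plane_set`: `normal`, `offsets`, `d`, `box`.
#' @export
make_virtual_planes <- function(box, config = plane_probe_config(),
                                normal = NULL, seed = NULL) {
  with_seed(seed, {
    if (is.null(normal)) normal <- as.numeric(isotropic_direction(1))
    normal <- normal / sqrt(sum(normal^2))
    s <- box_corners(box$origin, box$dims) %*% normal
    smin <- min(s); smax <- max(s)
    phase <- runif(1) * config$d
    offsets <- if (smin + phase <= smax)
      seq(smin + phase, smax, by = config$d) else numeric(0)
    structure(list(normal = normal, offsets = offsets, d = config$d,
                   smin = smin, phase = phase, box = box),
              class = "plane_set")
  })
}

#' Clip a plane to a box: intersection polygon and its area
#'
#' Exact convex polygon of the intersection of `normal . x = offset` with
#' an axis-aligned box; an empty intersection has area 0.
#'
#' @param normal unit normal.
#' @param offset plane offset (signed distance times `|normal|`).
#' @param box list with `origin`, `dims`.
#' @return List `polygon` (m x 3 matrix, ordered) and `area` (um^2).
#' @export
clip_plane_to_box <- function(normal, offset, box) {
  corners <- box_corners(box$origin, box$dims)
  edges <- rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8),
                 c(1, 3), c(2, 4), c(5, 7), c(6, 8),
                 c(1, 5), c(2, 6), c(3, 7), c(4, 8))
  s <- as.numeric(corners %*% normal) - offset
  pts <- matrix(numeric(0), 0, 3)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    if ((s[i] < 0) != (s[j] < 0) || s[i] == 0 || s[j] == 0) {
      if (s[i] == s[j]) next
      t <- s[i] / (s[i] - s[j])
      if (t >= 0 && t <= 1)
        pts <- rbind(pts, corners[i, ] + t * (corners[j, ] - corners[i, ]))
    }
  }
  if (nrow(pts) >= 2) pts <- unique(round(pts, 9))
  if (nrow(pts) < 3) return(list(polygon = pts, area = 0))
  # order around centroid in the plane's 2D frame
  a <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * normal) * normal
  u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  ctr <- colMeans(pts)
  rel <- sweep(pts, 2, ctr)
  ang <- atan2(rel %*% v, rel %*% u)
  ord <- order(ang)
  poly <- pts[ord, , drop = FALSE]
  list(polygon = poly,
       area = polygon_area_2d(as.numeric(poly %*% u), as.numeric(poly %*% v)))
}

plane_set_areas <- function(planes) {
  vapply(planes$offsets, function(o)
    clip_plane_to_box(planes$normal, o, planes$box)$area, numeric(1))
}

#' Count curve-plane intersections inside the box
#'
#' Counts transversal crossings of polyline segments with each plane of the
#' family, keeping only crossing points inside the (half-open) box.
#' Tangential touches are resolved by attributing each endpoint to a
#' half-open signed-distance interval, so a vertex exactly on a plane
#' belongs to the non-negative side.
#'
#' @param planes a [make_virtual_planes()] plane set.
#' @param segments segment matrix (see the simulator) or a
#'   `tissue_section`.
#' @return List `sum_Q` (total), `per_plane` (integer vector aligned with
#'   `planes$offsets`).
#' @export
count_plane_curve_intersections <- function(planes, segments) {
  if (inherits(segments, "tissue_section")) segments <- segments$segments
  n_pl <- length(planes$offsets)
  per <- integer(n_pl)
  if (nrow(segments) == 0 || n_pl == 0)
    return(list(sum_Q = 0L, per_plane = per))
  zero <- seg_lengths(segments) == 0
  if (any(zero)) {
    warning("skipping ", sum(zero), " zero-length segment(s)")
    segments <- segments[!zero, , drop = FALSE]
    if (nrow(segments) == 0) return(list(sum_Q = 0L, per_plane = per))
  }
  nrm <- planes$normal
  base <- planes$smin + planes$phase
  s1 <- segments[, 1:3, drop = FALSE] %*% nrm
  s2 <- segments[, 4:6, drop = FALSE] %*% nrm
  f1 <- floor((s1 - base) / planes$d)
  f2 <- floor((s2 - base) / planes$d)
  cross_n <- abs(f2 - f1)
  idx <- which(cross_n > 0)
  if (length(idx) == 0) return(list(sum_Q = 0L, per_plane = per))
  lo <- planes$box$origin
  hi <- planes$box$origin + planes$box$dims
  for (i in idx) {
    kk <- (min(f1[i], f2[i]) + 1):max(f1[i], f2[i])
    offs <- base + kk * planes$d
    t <- (offs - s1[i]) / (s2[i] - s1[i])
    px <- segments[i, 1] + t * (segments[i, 4] - segments[i, 1])
    py <- segments[i, 2] + t * (segments[i, 5] - segments[i, 2])
    pz <- segments[i, 3] + t * (segments[i, 6] - segments[i, 3])
    inside <- px >= lo[1] & px < hi[1] & py >= lo[2] & py < hi[2] &
      pz >= lo[3] & pz < hi[3]
    # plane index within the family: offsets[k] = base + (k0 + k - 1) d
    if (any(inside)) {
      pos <- round((offs[inside] - planes$offsets[1]) / planes$d) + 1L
      ok <- pos >= 1 & pos <= n_pl
      pos <- pos[ok]
      if (length(pos)) per[pos] <- per[pos] + 1L
    }
  }
  list(sum_Q = sum(per), per_plane = per)
}

#' Length density from plane-probe counts
#'
#' `L_V = 2 SumQ / Sum a(plane)` in um/um^3.  The corner-point form
#' `L_V = 2 (p_box / a_plane) SumQ / Sum p_ref` is used when boxes only
#' partially overlap the reference region, with `p_box` corner points per
#' box and `Sum p_ref` the corners hitting the reference space.
#'
#' @param sum_Q total intersection count.
#' @param sum_area total sampled plane area, um^2 (analytic form).
#' @param p_box,sum_p_ref,a_plane corner-point form inputs; supply either
#'   `sum_area` or all three of these.
#' @return Length density, um/um^3 (multiply by 1e6 for mm/mm^3).
#' @export
estimate_Lv_virtual_planes <- function(sum_Q, sum_area = NULL,
                                       p_box = NULL, sum_p_ref = NULL,
                                       a_plane = NULL) {
  if (!is.null(sum_area)) {
    if (sum_area <= 0) {
      if (sum_Q == 0) return(0)
      stop("zero sampled plane area with non-zero counts: undefined estimate")
    }
    return(2 * sum_Q / sum_area)
  }
  if (is.null(p_box) || is.null(sum_p_ref) || is.null(a_plane))
    stop("supply sum_area or the corner-point terms")
  if (sum_p_ref <= 0) stop("no box corners hit the reference space")
  2 * (p_box / a_plane) * sum_Q / sum_p_ref
}

#' Virtual-plane length density estimate over repeated probe placements
#'
#' Runs `n_placements` independent plane families through the box (one SUR
#' orientation schedule, fresh random phase each), pools counts and
#' analytically clipped plane areas, and returns the pooled estimator
#' together with per-placement values.
#'
#' @param segments segment matrix, `tissue_section`, or `tissue_block`
#'   (whose full extent is then the box).
#' @param box list `origin`, `dims`; defaults to the block extent.
#' @param n_placements number of probe placements.
#' @param config a [plane_probe_config()]; `box_dims` is ignored here in
#'   favour of `box`.
#' @param seed integer seed.
#' @return Object of class `plane_probe_result`: `sum_Q`, `sum_area`,
#'   `lv_um2`, `lv_mm_mm3`, `per_placement` (data frame).
#' @export
lv_planes <- function(segments, box = NULL, n_placements = 1,
                      config = plane_probe_config(), seed = NULL) {
  if (inherits(segments, "tissue_block")) {
    if (is.null(box)) box <- list(origin = c(0, 0, 0), dims = segments$dims)
    segments <- segments$segments
  }
  if (inherits(segments, "tissue_section")) {
    if (is.null(box))
      box <- list(origin = c(0, 0, 0),
                  dims = c(segments$xy_dims, segments$t_measured))
    segments <- segments$segments
  }
  if (is.null(box)) stop("box required for raw segment input")
  with_seed(seed, {
    normals <- plane_probe_orientations(n_placements)
    rows <- lapply(seq_len(n_placements), function(i) {
      planes <- make_virtual_planes(box, config, normal = normals[i, ])
      cnt <- count_plane_curve_intersections(planes, segments)
      area <- sum(plane_set_areas(planes))
      data.frame(placement = i, sum_Q = cnt$sum_Q, area = area,
                 lv = if (area > 0) 2 * cnt$sum_Q / area else NA_real_)
    })
    per <- do.call(rbind, rows)
    sum_Q <- sum(per$sum_Q)
    sum_area <- sum(per$area)
    lv <- estimate_Lv_virtual_planes(sum_Q, sum_area)
    structure(list(sum_Q = sum_Q, sum_area = sum_area,
                   lv_um2 = lv, lv_mm_mm3 = um2_inv_to_mm_per_mm3(lv),
                   d = config$d, box = box, per_placement = per),
              class = "plane_probe_result")
  })
}

#' @export
print.plane_probe_result <- function(x, ...) {
  cat("Isotropic virtual planes estimate\n")
  cat(sprintf("  SumQ = %d over %d placement(s), Sum a(plane) = %.0f um^2\n",
              x$sum_Q, nrow(x$per_placement), x$sum_area))
  cat(sprintf("  L_V = %.4g um/um^3 (%.0f mm/mm^3), d = %g um\n",
              x$lv_um2, x$lv_mm_mm3, x$d))
  invisible(x)
}
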