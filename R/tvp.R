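# Curve length from total vertical projections (TVP): a thin sub-stack is
# projected at several rotation angles about the vertical (y) axis and the
# intersections of a cycloid test system with the projected curves give
#   L = 2 (a/l) (1/M) mean(I_j).
# The cycloid minor axis is perpendicular to the vertical axis (the
# length-from-projections convention, opposite to surface-area cycloids):
# its tangent density is proportional to cos(angle from vertical), which is
# exactly the weighting a vertical design requires.

#' TVP configuration
#'
#' @param a_over_l grid constant: test-system area per unit cycloid arc
#'   length, um^2/um.
#' @param M linear magnification of the projections (1 when coordinates are
#'   already calibrated in um).
#' @param angles projection angles in degrees, evenly spaced in `[0, 180)`.
#' @param depth sub-stack depth, um (small to limit masking overlap).
#' @param point_spacing spacing of the area-counting point grid, um.
#' @return Object of class `tvp_config`.
#' @export
tvp_config <- function(a_over_l = 20, M = 1,
                       angles = c(0, 36, 72, 108, 144),
                       depth = 4, point_spacing = 15) {
  if (a_over_l <= 0) stop("a_over_l must be positive")
  if (length(angles) > 1) {
    gaps <- diff(sort(angles %% 180))
    if (max(gaps) - min(gaps) > 1e-6)
      warning("projection angles are not evenly spaced in [0, 180)")
  }
  structure(list(a_over_l = a_over_l, M = M, angles = angles %% 180,
                 n = length(angles), depth = depth,
                 point_spacing = point_spacing),
            class = "tvp_config")
}

#' Cycloid test grid
#'
#' Tiles the window with continuous vertical "snakes" of cycloid arcs
#' (`x = r (1 - cos t)`, `y = r (t - sin t)`), minor axis (the `2r` span)
#' horizontal, at uniformly random phase offsets.  The grid constant is
#' `a/l = pi * sx / 4` where `sx` is the column spacing, so `sx` is derived
#' from the requested `a_over_l`.  `orientation = "rotated"` rotates the
#' whole system 90 degrees (the wrong convention for vertical designs; kept
#' for the orientation stress test).
#'
#' @param a_over_l grid constant, um^2/um.
#' @param window list `xlim`, `ylim` (um).
#' @param r cycloid generating-circle radius, um; arc height is `2 pi r`.
#' @param chord maximum chord length used to polygonise arcs, um.
#' @param orientation `"vertical"` (default) or `"rotated"`.
#' @param seed optional integer seed for the random phase.
#' @return Object of class `cycloid_grid`: `chords` (m x 4), `snake` (run
#'   id per chord, in path order), `a_over_l`, `arc_length` (total in
#'   window).
#' @export
cycloid_grid <- function(a_over_l, window, r = a_over_l,
                         chord = r / 5, orientation = c("vertical", "rotated"),
                         seed = NULL) {
  orientation <- match.arg(orientation)
  with_seed(seed, {
    sx <- 4 * a_over_l / pi
    sy <- 2 * pi * r
    ox <- runif(1, 0, sx)
    oy <- runif(1, 0, sy)
    wx <- window$xlim; wy <- window$ylim
    pad <- 2 * r + chord
    dt <- max(1e-3, chord / (2 * r))
    t <- seq(0, 2 * pi, by = dt)
    if (t[length(t)] < 2 * pi) t <- c(t, 2 * pi)
    ux <- r * (1 - cos(t))
    uy <- r * (t - sin(t))
    cols <- seq(floor((wx[1] - ox - pad) / sx), ceiling((wx[2] - ox) / sx))
    rows <- seq(floor((wy[1] - oy - sy) / sy), ceiling((wy[2] - oy) / sy))
    chunks <- list()
    snake <- integer(0)
    id <- 0L
    for (j in cols) {
      id <- id + 1L
      x0 <- ox + j * sx
      for (k in rows) {
        y0 <- oy + k * sy
        px <- x0 + ux
        py <- y0 + uy
        m <- length(t) - 1
        ch <- cbind(px[1:m], py[1:m], px[2:(m + 1)], py[2:(m + 1)])
        # keep a one-period margin below/left of the window so the grid can
        # later be re-placed by translation (shift_cycloid_grid)
        keep <- pmax(ch[, 1], ch[, 3]) >= wx[1] - sx - chord &
          pmin(ch[, 1], ch[, 3]) <= wx[2] + chord &
          pmax(ch[, 2], ch[, 4]) >= wy[1] - sy - chord &
          pmin(ch[, 2], ch[, 4]) <= wy[2] + chord
        if (any(keep)) {
          chunks[[length(chunks) + 1L]] <- ch[keep, , drop = FALSE]
          snake <- c(snake, rep(id, sum(keep)))
        }
      }
    }
    chords <- if (length(chunks)) do.call(rbind, chunks)
    else matrix(numeric(0), 0, 4)
    colnames(chords) <- c("x1", "y1", "x2", "y2")
    if (orientation == "rotated") {
      cx <- mean(wx); cy <- mean(wy)
      rot <- cbind(cx + (chords[, 2] - cy), cy - (chords[, 1] - cx),
                   cx + (chords[, 4] - cy), cy - (chords[, 3] - cx))
      colnames(rot) <- colnames(chords)
      chords <- rot
    }
    # total arc length restricted to the window (chords clipped in 2D)
    arc_in <- clip_segments_box(
      cbind(chords[, 1], chords[, 2], 0, chords[, 3], chords[, 4], 0, 0, 0),
      c(wx[1], wy[1], -1), c(wx[2], wy[2], 1))
    structure(list(chords = chords, snake = snake, a_over_l = a_over_l,
                   r = r, sx = sx, sy = sy, window = window,
                   orientation = orientation,
                   arc_length = sum(seg_lengths(arc_in))),
              class = "cycloid_grid")
  })
}

#' Re-randomise a cycloid grid's placement
#'
#' Translates an existing grid by a fresh uniform phase within one tiling
#' period, which is equivalent to (and much cheaper than) regenerating it.
#' The generated chords carry a one-period margin, so coverage of the
#' window is preserved.
#'
#' @param grid a [cycloid_grid()].
#' @param seed optional integer seed.
#' @return A translated `cycloid_grid`.
#' @export
shift_cycloid_grid <- function(grid, seed = NULL) {
  with_seed(seed, {
    u <- runif(1, 0, grid$sx)
    v <- runif(1, 0, grid$sy)
    if (grid$orientation == "rotated") { tmp <- u; u <- v; v <- tmp }
    grid$chords[, c(1, 3)] <- grid$chords[, c(1, 3)] + u
    grid$chords[, c(2, 4)] <- grid$chords[, c(2, 4)] + v
    grid
  })
}

#' @export
print.cycloid_grid <- function(x, ...) {
  cat(sprintf(
    "Cycloid grid: a/l = %g um, r = %g um, %d chords, %.0f um arc in window\n",
    x$a_over_l, x$r, nrow(x$chords), x$arc_length))
  invisible(x)
}

# Candidate pre-filter on chord bounding intervals, then exact crossing
# test.  Bins are built only when the scene is large enough to amortise.
count_crossings_binned <- function(segs2, chords, restrict_window = NULL) {
  if (nrow(segs2) == 0 || nrow(chords) == 0) return(0L)
  cxlo <- pmin(chords[, 1], chords[, 3])
  cxhi <- pmax(chords[, 1], chords[, 3])
  cylo <- pmin(chords[, 2], chords[, 4])
  cyhi <- pmax(chords[, 2], chords[, 4])
  inwin <- if (!is.null(restrict_window)) {
    mx <- (chords[, 1] + chords[, 3]) / 2
    my <- (chords[, 2] + chords[, 4]) / 2
    mx >= restrict_window$xlim[1] & mx < restrict_window$xlim[2] &
      my >= restrict_window$ylim[1] & my < restrict_window$ylim[2]
  } else rep(TRUE, nrow(chords))
  test_seg <- function(i, cand) {
    if (!length(cand)) return(0L)
    hit <- crossing_test(segs2[i, 1], segs2[i, 2], segs2[i, 3], segs2[i, 4],
                         chords[cand, 1], chords[cand, 2],
                         chords[cand, 3], chords[cand, 4]) & inwin[cand]
    sum(hit)
  }
  total <- 0L
  if (nrow(segs2) < 64) {
    for (i in seq_len(nrow(segs2))) {
      sxlo <- min(segs2[i, 1], segs2[i, 3])
      sxhi <- max(segs2[i, 1], segs2[i, 3])
      sylo <- min(segs2[i, 2], segs2[i, 4])
      syhi <- max(segs2[i, 2], segs2[i, 4])
      cand <- which(cxhi >= sxlo & cxlo <= sxhi & cyhi >= sylo & cylo <= syhi)
      total <- total + test_seg(i, cand)
    }
  } else {
    bw <- max(1, max(cxhi - cxlo) * 4)
    cb_lo <- floor(cxlo / bw)
    cb_hi <- floor(cxhi / bw)
    dup <- cb_lo == cb_hi   # chords span at most 2 bins (bw > chord span)
    keys <- c(cb_lo, cb_hi[!dup])
    idx <- c(seq_len(nrow(chords)), which(!dup))
    bins <- split(idx, keys)
    for (i in seq_len(nrow(segs2))) {
      b_lo <- floor(min(segs2[i, 1], segs2[i, 3]) / bw)
      b_hi <- floor(max(segs2[i, 1], segs2[i, 3]) / bw)
      cand <- unique(unlist(bins[as.character(b_lo:b_hi)], use.names = FALSE))
      total <- total + test_seg(i, cand)
    }
  }
  as.integer(total)
}

#' Count cycloid intersections with projected polylines (geometric mode)
#'
#' Exact crossing count between the cycloid chords and 2D projected
#' segments.  Distinct processes overlapping at the same crossing point
#' count separately (each segment-chord crossing is one hit).
#'
#' @param segs2 projected 2D segments (m x 4: x1, y1, x2, y2).
#' @param grid a [cycloid_grid()].
#' @return Integer intersection count `I_j`.
#' @export
count_cycloid_intersections_geometric <- function(segs2, grid) {
  count_crossings_binned(segs2, grid$chords, restrict_window = grid$window)
}

#' Count cycloid intersections on a skeleton image (image mode)
#'
#' Walks the cycloid path over the skeleton raster and counts connected
#' crossing events: one hit per maximal run of skeleton pixels under the
#' path (a thick process crossed at its central spine counts once).
#'
#' @param skeleton a `skeleton_image` (see
#'   [binarize_and_skeletonize()]) or a logical matrix indexed `[x, y]`.
#' @param grid a [cycloid_grid()] in the image's physical coordinates.
#' @param pixel_size pixel size in um (taken from the skeleton object when
#'   available).
#' @param origin physical position of pixel (1, 1)'s lower corner.
#' @return Integer intersection count.
#' @export
count_cycloid_intersections_image <- function(skeleton, grid,
                                              pixel_size = NULL,
                                              origin = c(0, 0)) {
  if (inherits(skeleton, "skeleton_image")) {
    pixel_size <- skeleton$pixel_size
    img <- skeleton$skeleton
  } else img <- skeleton
  if (is.null(pixel_size)) stop("pixel_size required")
  if (nrow(grid$chords) == 0 || !any(img)) return(0L)
  step <- pixel_size / 2
  hits <- logical(0)
  ord <- order(grid$snake, seq_along(grid$snake))
  chords <- grid$chords[ord, , drop = FALSE]
  snake <- grid$snake[ord]
  nx <- dim(img)[1]; ny <- dim(img)[2]
  samp_chord <- function(ch) {
    len <- sqrt((ch[3] - ch[1])^2 + (ch[4] - ch[2])^2)
    k <- max(1L, ceiling(len / step))
    t <- (seq_len(k) - 0.5) / k
    cbind(ch[1] + t * (ch[3] - ch[1]), ch[2] + t * (ch[4] - ch[2]))
  }
  pts <- do.call(rbind, lapply(seq_len(nrow(chords)), function(i)
    cbind(samp_chord(chords[i, ]), snake[i])))
  ix <- floor((pts[, 1] - origin[1]) / pixel_size) + 1L
  iy <- floor((pts[, 2] - origin[2]) / pixel_size) + 1L
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  on <- logical(nrow(pts))
  on[ok] <- img[cbind(ix[ok], iy[ok])]
  # bridge 1-pixel gaps so a crossing of a diagonal 1-pixel skeleton,
  # whose corner the sampled path can slip through, stays one event
  snake_id <- pts[, 3]
  n <- length(on)
  gap_ok <- on
  if (n > 4) {
    bridged <- (c(on[-1], FALSE) | c(on[-(1:2)], FALSE, FALSE)) &
      (c(FALSE, on[-n]) | c(FALSE, FALSE, on[-((n - 1):n)]))
    same <- snake_id == c(snake_id[1], snake_id[-n]) &
      snake_id == c(snake_id[-1], snake_id[n])
    gap_ok <- on | (bridged & same)
  }
  run_start <- gap_ok & !c(FALSE, gap_ok[-n])
  new_snake <- c(TRUE, diff(snake_id) != 0)
  run_start[new_snake] <- gap_ok[new_snake]
  as.integer(sum(run_start))
}

#' TVP length estimate from per-angle intersection counts
#'
#' `L = 2 (a/l) (1/M) mean(I_j)`.
#'
#' @param I_j integer intersection counts, one per projection angle.
#' @param config a [tvp_config()].
#' @return Estimated length, um.
#' @export
estimate_length_tvp <- function(I_j, config) {
  if (length(I_j) < 1) stop("need at least one projection count")
  2 * config$a_over_l * (1 / config$M) * mean(I_j)
}

#' Point grid for area/volume estimation
#'
#' @param spacing point spacing, um; area per point is `spacing^2`.
#' @param window list `xlim`, `ylim`.
#' @param seed optional integer seed for the random offset.
#' @return Object of class `point_grid`: `points` (m x 2), `spacing`,
#'   `area_per_point`.
#' @export
point_grid <- function(spacing, window, seed = NULL) {
  with_seed(seed, {
    ox <- runif(1, 0, spacing); oy <- runif(1, 0, spacing)
    xs <- seq(window$xlim[1] - spacing + ox, window$xlim[2], by = spacing)
    ys <- seq(window$ylim[1] - spacing + oy, window$ylim[2], by = spacing)
    xs <- xs[xs >= window$xlim[1] & xs < window$xlim[2]]
    ys <- ys[ys >= window$ylim[1] & ys < window$ylim[2]]
    pts <- as.matrix(expand.grid(x = xs, y = ys))
    structure(list(points = pts, spacing = spacing,
                   area_per_point = spacing^2, window = window),
              class = "point_grid")
  })
}

#' Reference volume by point counting
#'
#' `V_ref = (points hitting the region) * (area per point) * depth` on the
#' 0-degree projection.
#'
#' @param region region mask: a function `f(x, y) -> logical`, a logical
#'   matrix indexed `[x, y]` with `pixel_size`/`origin`, or `TRUE` for a
#'   full-frame region.
#' @param grid a [point_grid()].
#' @param depth sub-stack depth, um.
#' @param pixel_size,origin raster calibration when `region` is a matrix.
#' @return Volume in um^3.
#' @export
point_count_volume <- function(region, grid, depth,
                               pixel_size = NULL, origin = c(0, 0)) {
  pts <- grid$points
  hit <- if (isTRUE(region)) rep(TRUE, nrow(pts))
  else if (is.function(region)) region(pts[, 1], pts[, 2])
  else {
    if (is.null(pixel_size)) stop("pixel_size required for a mask region")
    ix <- floor((pts[, 1] - origin[1]) / pixel_size) + 1L
    iy <- floor((pts[, 2] - origin[2]) / pixel_size) + 1L
    ok <- ix >= 1 & ix <= dim(region)[1] & iy >= 1 & iy <= dim(region)[2]
    out <- logical(nrow(pts))
    out[ok] <- region[cbind(ix[ok], iy[ok])]
    out
  }
  sum(hit) * grid$area_per_point * depth
}

#' Length density from a TVP length estimate
#'
#' `L_V = L / (V_ref * shrinkage)` where `shrinkage` is the volume
#' correction factor `t_cut / t_measured` (1 when no correction applies).
#'
#' @param L_hat estimated length, um.
#' @param V_ref reference volume, um^3 (> 0).
#' @param shrinkage volume correction factor (>= 1 for collapsed sections).
#' @return Length density, um/um^3.
#' @export
estimate_Lv_tvp <- function(L_hat, V_ref, shrinkage = 1) {
  if (V_ref <= 0) stop("zero reference volume: length density undefined")
  L_hat / (V_ref * shrinkage)
}

#' Full TVP estimate on a 3D curve set (geometric mode)
#'
#' Clips the curves to a sub-stack of `config$depth` below `z_top`,
#' projects at each configured angle about the vertical (y) axis, counts
#' cycloid intersections with an independently placed grid per angle, and
#' assembles length and length density (reference volume by point counting
#' over the window).
#'
#' @param segments 3D segment matrix or `tissue_section`.
#' @param window list `xlim`, `ylim` of the analysis frame, um.
#' @param config a [tvp_config()].
#' @param z_top top of the sub-stack (defaults to the maximum segment z).
#' @param shrinkage volume correction factor passed to [estimate_Lv_tvp()].
#' @param seed integer seed (grid and point offsets).
#' @return Object of class `tvp_result`: `I_j`, `L_hat_um`, `V_ref_um3`,
#'   `lv_um2`, `lv_mm_mm3`.
#' @export
tvp_estimate <- function(segments, window, config = tvp_config(),
                         z_top = NULL, shrinkage = 1, seed = NULL) {
  if (inherits(segments, "tissue_section")) {
    if (is.null(z_top)) z_top <- segments$t_measured
    segments <- segments$segments
  }
  if (is.null(z_top)) z_top <- if (nrow(segments)) max(segments[, c(3, 6)]) else 0
  with_seed(seed, {
    sub <- clip_segments_z(segments, z_top - config$depth, z_top)
    # rotate about the frame's central vertical axis so every projection
    # stays inside the counting window (padded by the sub-stack depth)
    center <- c(mean(window$xlim), z_top - config$depth / 2)
    gwin <- list(xlim = window$xlim + c(-1, 1) * (config$depth + 1),
                 ylim = window$ylim)
    I_j <- vapply(config$angles, function(a) {
      segs2 <- project_segments(sub, a, center = center)
      grid <- cycloid_grid(config$a_over_l, gwin)
      count_cycloid_intersections_geometric(segs2, grid)
    }, integer(1))
    L_hat <- estimate_length_tvp(I_j, config)
    pg <- point_grid(config$point_spacing, window)
    V_ref <- point_count_volume(TRUE, pg, config$depth)
    lv <- estimate_Lv_tvp(L_hat, V_ref, shrinkage)
    structure(list(I_j = I_j, angles = config$angles, L_hat_um = L_hat,
                   V_ref_um3 = V_ref, lv_um2 = lv,
                   lv_mm_mm3 = um2_inv_to_mm_per_mm3(lv)),
              class = "tvp_result")
  })
}

#' @export
print.tvp_result <- function(x, ...) {
  cat("Total vertical projection estimate\n")
  cat("  I_j:", paste(x$I_j, collapse = ", "),
      "at angles", paste(x$angles, collapse = ", "), "deg\n")
  cat(sprintf("  L = %.1f um, V_ref = %.0f um^3, L_V = %.0f mm/mm^3\n",
              x$L_hat_um, x$V_ref_um3, x$lv_mm_mm3))
  invisible(x)
}
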