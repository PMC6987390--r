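# Optical disector counting with systematic uniform random sampling,
# SumQ-weighted thickness shrinkage correction, and the coefficient of
# error of systematic random samples.

#' Systematic uniform random sampling boxes over a region
#'
#' Places disector boxes on a systematic grid with uniformly random start
#' such that the boxes cover approximately `fraction` of the region's area.
#'
#' @param region_dims `(x, y)` extents of the region, um.
#' @param fraction target area fraction in `(0, 1]`.
#' @param box_xy box footprint `(bx, by)`, um.
#' @param inside if `TRUE`, keep only boxes lying fully inside the region;
#'   by default boundary boxes are kept and their in-region overlap area is
#'   recorded, so the realised fraction matches the target (and
#'   `fraction = 1` tiles the whole region).
#' @param seed optional integer seed.
#' @return Object of class `disector_boxes`: `origins` (m x 2), `box_xy`,
#'   `overlap_area` (in-region footprint per box, um^2), `fraction`,
#'   `realized_fraction`.
#' @export
systematic_sample_boxes <- function(region_dims, fraction, box_xy,
                                    inside = FALSE, seed = NULL) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (any(box_xy > region_dims)) stop("box larger than region")
  with_seed(seed, {
    s <- box_xy / sqrt(fraction)
    off <- c(runif(1, 0, s[1]), runif(1, 0, s[2]))
    xs <- seq(off[1] - s[1], region_dims[1], by = s[1])
    ys <- seq(off[2] - s[2], region_dims[2], by = s[2])
    if (inside) {
      xs <- xs[xs >= 0 & xs + box_xy[1] <= region_dims[1]]
      ys <- ys[ys >= 0 & ys + box_xy[2] <= region_dims[2]]
    } else {
      xs <- xs[xs + box_xy[1] > 0 & xs < region_dims[1]]
      ys <- ys[ys + box_xy[2] > 0 & ys < region_dims[2]]
    }
    origins <- as.matrix(expand.grid(x = xs, y = ys))
    ox <- pmin(origins[, 1] + box_xy[1], region_dims[1]) -
      pmax(origins[, 1], 0)
    oy <- pmin(origins[, 2] + box_xy[2], region_dims[2]) -
      pmax(origins[, 2], 0)
    overlap <- ox * oy
    structure(list(origins = origins, box_xy = box_xy,
                   overlap_area = overlap, fraction = fraction,
                   region_dims = region_dims,
                   realized_fraction = sum(overlap) / prod(region_dims)),
              class = "disector_boxes")
  })
}

#' Optical disector counts
#'
#' Counts cell reference points (soma centroids) falling in each disector
#' box under the half-open inclusion rule: low faces included, high faces
#' excluded, in all three axes.  Tiling a volume with disectors therefore
#' counts every cell exactly once.
#'
#' @param boxes a [systematic_sample_boxes()] object (or an m x 2 origin
#'   matrix).
#' @param points n x 3 matrix of reference points in section coordinates.
#' @param z0 low z face of the disector, um.
#' @param height disector height, um.
#' @param box_xy box footprint when `boxes` is a plain matrix.
#' @return List `sum_Q` (total), `per_box` (integer vector).
#' @export
disector_count <- function(boxes, points, z0, height, box_xy = NULL) {
  if (inherits(boxes, "disector_boxes")) {
    origins <- boxes$origins
    box_xy <- boxes$box_xy
  } else origins <- boxes
  if (is.null(box_xy)) stop("box_xy required")
  per <- integer(nrow(origins))
  if (nrow(points) > 0 && nrow(origins) > 0) {
    inz <- points[, 3] >= z0 & points[, 3] < z0 + height
    pts <- points[inz, , drop = FALSE]
    if (nrow(pts) > 0)
      for (b in seq_len(nrow(origins))) {
        o <- origins[b, ]
        per[b] <- sum(pts[, 1] >= o[1] & pts[, 1] < o[1] + box_xy[1] &
                        pts[, 2] >= o[2] & pts[, 2] < o[2] + box_xy[2])
      }
  }
  list(sum_Q = sum(per), per_box = per)
}

#' SumQ-weighted mean section thickness
#'
#' `t_bar_Q = sum(q_i t_i) / sum(q_i)`; the thickness at spots that
#' collected more cells weighs more, which matches the volume actually
#' sampled.  Falls back to the unweighted mean (with a warning) when all
#' counts are zero.
#'
#' @param q per-spot disector counts.
#' @param t per-spot measured thicknesses, um.
#' @return Weighted mean thickness, um.
#' @export
q_weighted_thickness <- function(q, t) {
  if (length(q) != length(t)) stop("q and t must have equal length")
  if (sum(q) <= 0) {
    warning("all counts zero; using unweighted mean thickness")
    return(mean(t))
  }
  sum(q * t) / sum(q)
}

#' Numerical density with z-shrinkage correction
#'
#' `N_V = SumQ / (V_sampled * t_cut / t_bar_Q)`: the sampled volume is
#' measured in the collapsed (post-processing) section, so it is inflated
#' back by `t_cut / t_bar_Q` to refer the density to the cut-section
#' volume.
#'
#' @param sum_Q total disector count.
#' @param sampled_volume_um3 total sampled (measured) volume, um^3.
#' @param t_bar_Q SumQ-weighted measured thickness, um (`NULL` for no
#'   correction).
#' @param t_cut nominal cut thickness, um.
#' @return Numerical density in 1/um^3 (multiply by 1e9 for cells/mm^3).
#' @export
estimate_Nv <- function(sum_Q, sampled_volume_um3, t_bar_Q = NULL,
                        t_cut = NULL) {
  if (sampled_volume_um3 <= 0) stop("sampled volume must be positive")
  corr <- if (!is.null(t_bar_Q) && !is.null(t_cut)) t_cut / t_bar_Q else 1
  sum_Q / (sampled_volume_um3 * corr)
}

#' Mean process length per cell
#'
#' `L_N = L_V / N_V`; with `L_V` in um/um^3 and `N_V` in 1/um^3 the result
#' is um per cell (equivalently mm/mm^3 over cells/mm^3 gives mm/cell).
#'
#' @param L_V length density.
#' @param N_V numerical density (> 0 unless `L_V` is 0).
#' @return Length per cell.
#' @export
length_per_cell <- function(L_V, N_V) {
  if (L_V == 0) return(0)
  if (N_V <= 0) stop("N_V must be positive")
  L_V / N_V
}

#' Coefficient of error of a systematic random sample
#'
#' Covariogram-based CE for per-section values `f_i`:
#' `A = sum f_i^2`, `B = sum f_i f_(i+1)`, `C = sum f_i f_(i+2)`,
#' `VarSRS = (3 (A - noise) - 4 B + C) / 240` for smoothness class
#' `m = 1` (divisor 12 for `m = 0`), and
#' `CE = sqrt(noise + VarSRS) / sum(f_i)`.  For counts the noise (nugget)
#' term defaults to `sum(f_i)` (Poisson).  With fewer than 3 sections the
#' covariogram is undefined and the noise-only CE is returned with a
#' warning; a single section with total count Q gives `1 / sqrt(Q)`.
#'
#' @param f per-section values (counts), in section order.
#' @param m smoothness class, 0 or 1 (default 1, the standard choice for
#'   count data).
#' @param noise nugget variance (defaults to `sum(f)`).
#' @return Object of class `ce_result`: `ce`, `A`, `B`, `C`, `var_srs`,
#'   `noise`, `m`.
#' @export
ce_systematic <- function(f, m = 1, noise = sum(f)) {
  if (!m %in% c(0, 1)) stop("m must be 0 or 1")
  total <- sum(f)
  if (total <= 0) stop("cannot compute a CE for an all-zero sample")
  k <- length(f)
  if (k < 3) {
    warning("fewer than 3 sections: noise-only CE")
    return(structure(list(ce = sqrt(noise) / total, A = NA, B = NA, C = NA,
                          var_srs = 0, noise = noise, m = m),
                     class = "ce_result"))
  }
  A <- sum(f * f)
  B <- sum(f[-k] * f[-1])
  C <- sum(f[seq_len(k - 2)] * f[-(1:2)])
  div <- if (m == 1) 240 else 12
  var_srs <- max(0, (3 * (A - noise) - 4 * B + C) / div)
  structure(list(ce = sqrt(noise + var_srs) / total,
                 A = A, B = B, C = C, var_srs = var_srs, noise = noise,
                 m = m),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("CE (systematic sample, m = %d): %.1f%%\n", x$m, 100 * x$ce))
  invisible(x)
}

#' Optical disector numerical density over sections
#'
#' Runs SUR disector sampling on each section, records per-spot counts and
#' thicknesses (thickness measured at every `thickness_period`-th spot, as
#' in up-and-down focusing at every third spot), forms the SumQ-weighted
#' thickness, and returns the shrinkage-corrected density with its CE.
#'
#' @param sections list of `tissue_section` objects.
#' @param fraction sampled area fraction (default 0.40, the intensity used
#'   for scarce cell bodies).
#' @param box_xy disector footprint `(bx, by)`, um.
#' @param height disector height, um; default leaves `guard_z` um guards
#'   above and below within the measured section.
#' @param guard_z z guard, um.
#' @param thickness_period measure thickness at every n-th spot.
#' @param seed integer seed.
#' @return Object of class `disector_result`: `sum_Q`, `nv_um3`,
#'   `nv_per_mm3`, `nv_uncorrected_um3`, `t_bar_Q`, `t_cut`, `ce`
#'   (per-section counts CE), `per_section`.
#' @export
nv_disector <- function(sections, fraction = 0.40, box_xy = c(50, 50),
                        height = NULL, guard_z = 2, thickness_period = 3,
                        seed = NULL) {
  with_seed(seed, {
    q_all <- numeric(0)
    t_all <- numeric(0)
    f_sec <- numeric(length(sections))
    vol <- 0
    for (si in seq_along(sections)) {
      sec <- sections[[si]]
      h <- if (is.null(height)) max(sec$t_measured - 2 * guard_z,
                                    sec$t_measured / 2) else height
      z0 <- (sec$t_measured - h) / 2
      boxes <- systematic_sample_boxes(sec$xy_dims, fraction, box_xy)
      cnt <- disector_count(boxes, sec$cell_centers, z0, h)
      f_sec[si] <- cnt$sum_Q
      vol <- vol + sum(boxes$overlap_area) * h
      q_all <- c(q_all, cnt$per_box)
      t_all <- c(t_all, rep(sec$t_measured, length(cnt$per_box)))
    }
    spots <- seq(1, length(q_all), by = thickness_period)
    t_bar <- if (sum(q_all[spots]) > 0)
      q_weighted_thickness(q_all[spots], t_all[spots])
    else mean(t_all[spots])
    t_cut <- sections[[1]]$t_cut
    nv <- estimate_Nv(sum(f_sec), vol, t_bar, t_cut)
    ce <- if (sum(f_sec) > 0) ce_systematic(f_sec)$ce else NA_real_
    structure(list(sum_Q = sum(f_sec), sampled_volume_um3 = vol,
                   nv_um3 = nv, nv_per_mm3 = um3_inv_to_per_mm3(nv),
                   nv_uncorrected_um3 = estimate_Nv(sum(f_sec), vol),
                   t_bar_Q = t_bar, t_cut = t_cut, ce = ce,
                   fraction = fraction, per_section = f_sec),
              class = "disector_result")
  })
}

#' @export
print.disector_result <- function(x, ...) {
  cat("Optical disector estimate\n")
  cat(sprintf("  SumQ- = %d at sampling fraction %.0f%%\n",
              x$sum_Q, 100 * x$fraction))
  cat(sprintf("  t_bar_Q = %.2f um vs t_cut = %g um\n", x$t_bar_Q, x$t_cut))
  cat(sprintf("  N_V = %.0f cells/mm^3 (CE %.1f%%)\n", x$nv_per_mm3,
              100 * x$ce))
  invisible(x)
}
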