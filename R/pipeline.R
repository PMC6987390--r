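# End-to-end experiment runner: simulate -> section -> (detect) ->
# estimate -> report, for both regimes and both labelling modalities.

#' Virtual-plane length density over sampled sections
#'
#' Places SUR sampling boxes on each section (area fraction `fraction`,
#' footprint `box_dims[1:2]`, height `box_dims[3]` centred in the measured
#' thickness), sweeps an isotropic plane family through every box (one SUR
#' orientation schedule across boxes), and pools counts and clipped plane
#' areas into `L_V = 2 SumQ / (Sum a(plane) * t_cut / t_bar)`.
#'
#' @param sections list of `tissue_section`s.
#' @param fraction sampled area fraction (default 0.10).
#' @param box_dims box `(x, y, z)`, um.
#' @param d plane spacing, um.
#' @param correct_shrinkage correct the sampled volume back to cut-section
#'   scale (default TRUE).
#' @param seed integer seed.
#' @return A `plane_probe_result` with additional `per_section` counts and
#'   `ce` (systematic-sample CE of the per-section counts).
#' @export
lv_planes_sections <- function(sections, fraction = 0.10,
                               box_dims = c(60, 60, 12), d = 20,
                               correct_shrinkage = TRUE, seed = NULL) {
  cfg <- plane_probe_config(d = d, box_dims = box_dims)
  with_seed(seed, {
    f_sec <- numeric(length(sections))
    sum_area <- 0
    boxes_all <- list()
    for (si in seq_along(sections)) {
      sec <- sections[[si]]
      grid <- systematic_sample_boxes(sec$xy_dims, fraction, box_dims[1:2],
                                      inside = TRUE)
      z0 <- (sec$t_measured - box_dims[3]) / 2
      if (z0 < 0) stop("box higher than the measured section")
      boxes_all[[si]] <- grid$origins
      attr(boxes_all[[si]], "z0") <- z0
    }
    n_boxes <- sum(vapply(boxes_all, nrow, integer(1)))
    normals <- plane_probe_orientations(n_boxes)
    bi <- 0L
    for (si in seq_along(sections)) {
      sec <- sections[[si]]
      z0 <- attr(boxes_all[[si]], "z0")
      for (b in seq_len(nrow(boxes_all[[si]]))) {
        bi <- bi + 1L
        box <- list(origin = c(boxes_all[[si]][b, ], z0),
                    dims = box_dims)
        planes <- make_virtual_planes(box, cfg, normal = normals[bi, ])
        cnt <- count_plane_curve_intersections(planes, sec$segments)
        f_sec[si] <- f_sec[si] + cnt$sum_Q
        sum_area <- sum_area + sum(plane_set_areas(planes))
      }
    }
    sum_Q <- sum(f_sec)
    shrink <- if (correct_shrinkage)
      sections[[1]]$t_cut / sections[[1]]$t_measured else 1
    lv <- estimate_Lv_virtual_planes(sum_Q, sum_area * shrink)
    ce <- if (sum_Q > 0 && length(f_sec) >= 1) ce_systematic(f_sec)$ce
    else NA_real_
    structure(list(sum_Q = sum_Q, sum_area = sum_area,
                   lv_um2 = lv, lv_mm_mm3 = um2_inv_to_mm_per_mm3(lv),
                   d = d, box = box_dims, per_section = f_sec, ce = ce),
              class = "plane_probe_result")
  })
}

#' TVP length density over sampled sections
#'
#' Runs the cycloid/TVP estimator ([tvp_estimate()]) on the top sub-stack
#' of each section and pools per-section length and reference volume.
#'
#' @param sections list of `tissue_section`s.
#' @param config a [tvp_config()].
#' @param correct_shrinkage as in [lv_planes_sections()].
#' @param seed integer seed.
#' @return List with `lv_um2`, `lv_mm_mm3`, `I_total`, `ce` (CE of
#'   per-section total counts), `per_section`.
#' @export
lv_tvp_sections <- function(sections, config = tvp_config(),
                            correct_shrinkage = TRUE, seed = NULL) {
  with_seed(seed, {
    L_sum <- 0; V_sum <- 0
    f_sec <- numeric(length(sections))
    for (si in seq_along(sections)) {
      sec <- sections[[si]]
      win <- list(xlim = c(0, sec$xy_dims[1]), ylim = c(0, sec$xy_dims[2]))
      res <- tvp_estimate(sec, win, config)
      f_sec[si] <- sum(res$I_j)
      L_sum <- L_sum + res$L_hat_um
      V_sum <- V_sum + res$V_ref_um3
    }
    shrink <- if (correct_shrinkage)
      sections[[1]]$t_cut / sections[[1]]$t_measured else 1
    lv <- estimate_Lv_tvp(L_sum, V_sum, shrink)
    ce <- if (sum(f_sec) > 0) ce_systematic(f_sec)$ce else NA_real_
    list(lv_um2 = lv, lv_mm_mm3 = um2_inv_to_mm_per_mm3(lv),
         I_total = sum(f_sec), ce = ce, per_section = f_sec)
  })
}

#' Experiment configuration
#'
#' Defaults model the study design at desk scale: per "brain-stem side"
#' one tissue block, serial 40-um sections, virtual-plane sampling at 10%
#' of the area and optical-disector sampling at 40%, TVP on 4-um
#' sub-stacks, DAB-like and IF-like detection.
#'
#' @param n_control,n_deaff number of sides (blocks) per group.
#' @param dims block dims, um.
#' @param thickness,period,z_shrinkage sectioning parameters.
#' @param plane_fraction,plane_box,plane_d virtual-plane sampling.
#' @param disector_fraction,disector_box optical-disector sampling.
#' @param tvp a [tvp_config()].
#' @param control,deaff condition parameter sets ([mg_condition()]).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(n_control = 3, n_deaff = 3,
                              dims = c(260, 260, 160),
                              thickness = 40, period = 1, z_shrinkage = 1,
                              plane_fraction = 0.10,
                              plane_box = c(60, 60, 12), plane_d = 20,
                              disector_fraction = 0.40,
                              disector_box = c(50, 50),
                              tvp = tvp_config(a_over_l = 8),
                              control = mg_condition("control"),
                              deaff = mg_condition("deaff")) {
  structure(as.list(environment()), class = "experiment_config")
}

#' Run a full simulated experiment
#'
#' Simulates `n_control` control and `n_deaff` deafferented sides, cuts
#' sections, applies the DAB and IF detection models, and estimates L_V
#' (virtual planes and TVP), N_V (optical disector) and L_N per side with
#' CEs.  One master seed fans out deterministically to per-stage child
#' seeds.
#'
#' @param config an [experiment_config()].
#' @param seed master integer seed.
#' @return Object of class `density_report`: `rows` (one line per side x
#'   stain x length method) and `sides` (per-side ground truth).
#' @export
run_experiment <- function(config = experiment_config(), seed = 1) {
  groups <- c(rep("control", config$n_control), rep("deaff", config$n_deaff))
  rows <- list()
  sides <- list()
  for (i in seq_along(groups)) {
    side_seed <- seed * 1000L + i
    cond <- if (groups[i] == "control") config$control else config$deaff
    block <- build_tissue(cond, config$dims, seed = side_seed)
    sections <- cut_sections(block, config$thickness, config$period,
                             config$z_shrinkage, seed = side_seed + 500L)
    nv <- nv_disector(sections, config$disector_fraction,
                      config$disector_box, seed = side_seed + 600L)
    gt <- block$ground_truth
    sides[[i]] <- data.frame(
      side = i, group = groups[i],
      truth_nv_per_mm3 = um3_inv_to_per_mm3(gt$nv_um3),
      truth_lv_mm_mm3 = um2_inv_to_mm_per_mm3(gt$lv_um2),
      truth_ln_um = gt$length_per_cell_um)
    for (stain in c("DAB", "IF")) {
      model <- modality_model(stain)
      stained <- lapply(seq_along(sections), function(si) {
        sec <- sections[[si]]
        sec$segments <- apply_modality(sec$segments, model,
                                       seed = side_seed + 700L + si)
        sec
      })
      pl <- lv_planes_sections(stained, config$plane_fraction,
                               config$plane_box, config$plane_d,
                               seed = side_seed + 800L)
      tv <- lv_tvp_sections(stained, config$tvp, seed = side_seed + 900L)
      for (method in c("planes", "tvp")) {
        lv_um2 <- if (method == "planes") pl$lv_um2 else tv$lv_um2
        ce_lv <- if (method == "planes") pl$ce else tv$ce
        rows[[length(rows) + 1L]] <- data.frame(
          side = i, group = groups[i], stain = stain, method = method,
          lv_mm_mm3 = um2_inv_to_mm_per_mm3(lv_um2),
          nv_per_mm3 = nv$nv_per_mm3,
          ln_um = NA_real_, ce_lv = ce_lv, ce_nv = nv$ce)
      }
    }
  }
  rows <- do.call(rbind, rows)
  # L_N directly as L_V / N_V in the um system (exact consistency)
  rows$ln_um <- vapply(seq_len(nrow(rows)), function(r)
    length_per_cell(rows$lv_mm_mm3[r] / 1e6, rows$nv_per_mm3[r] / 1e9),
    numeric(1))
  structure(list(rows = rows, sides = do.call(rbind, sides),
                 config = config, seed = seed),
            class = "density_report")
}

#' @export
print.density_report <- function(x, ...) {
  cat("Simulated stereology experiment (seed", x$seed, ")\n")
  agg <- stats::aggregate(cbind(lv_mm_mm3, nv_per_mm3, ln_um) ~
                            group + stain + method, data = x$rows, mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' @export
summary.density_report <- function(object, ...) {
  rows <- object$rows
  m <- function(group, stain, method, col)
    mean(rows[rows$group == group & rows$stain == stain &
                rows$method == method, col])
  per_stain_lv_fold <- vapply(c("DAB", "IF"), function(s)
    m("deaff", s, "planes", "lv_mm_mm3") / m("control", s, "planes", "lv_mm_mm3"),
    numeric(1))
  nv_fold <- m("deaff", "IF", "planes", "nv_per_mm3") /
    m("control", "IF", "planes", "nv_per_mm3")
  ln_pct <- 100 * m("deaff", "IF", "planes", "ln_um") /
    m("control", "IF", "planes", "ln_um")
  deficit <- function(group) {
    per_side <- sapply(unique(rows$side[rows$group == group]), function(sd) {
      r <- rows[rows$side == sd & rows$method == "planes", ]
      100 * (r$lv_mm_mm3[r$stain == "IF"] - r$lv_mm_mm3[r$stain == "DAB"]) /
        r$lv_mm_mm3[r$stain == "IF"]
    })
    mean(per_side)
  }
  out <- list(nv_fold = nv_fold,
              lv_fold = mean(per_stain_lv_fold),
              lv_fold_by_stain = per_stain_lv_fold,
              ln_percent_of_control = ln_pct,
              dab_deficit_control_pct = deficit("control"),
              dab_deficit_deaff_pct = deficit("deaff"),
              mean_ce_lv = mean(rows$ce_lv, na.rm = TRUE),
              mean_ce_nv = mean(rows$ce_nv, na.rm = TRUE))
  class(out) <- "summary.density_report"
  out
}

#' @export
print.summary.density_report <- function(x, ...) {
  cat(sprintf("N_V fold change (deaff/control): %.2f\n", x$nv_fold))
  cat(sprintf("L_V fold change (mean of stains): %.2f (DAB %.2f, IF %.2f)\n",
              x$lv_fold, x$lv_fold_by_stain[1], x$lv_fold_by_stain[2]))
  cat(sprintf("L_N deafferented as %% of control: %.0f%%\n",
              x$ln_percent_of_control))
  cat(sprintf("DAB detection deficit (L_V, control sides): %.1f%%\n",
              x$dab_deficit_control_pct))
  cat(sprintf("mean CE: L_V %.1f%%, N_V %.1f%%\n",
              100 * x$mean_ce_lv, 100 * x$mean_ce_nv))
  invisible(x)
}

#' Group comparisons on a density report
#'
#' Delegates to the standard statistical routines: Mann-Whitney U
#' (unpaired sides), Wilcoxon signed rank (paired), Student's t, or the
#' two-sample Kolmogorov-Smirnov D test, with each side as the sampling
#' unit.
#'
#' @param report a [run_experiment()] report, or a list
#'   `list(x =, y =)` of numeric vectors.
#' @param parameter `"lv"`, `"nv"` or `"ln"`.
#' @param stain,method row filters.
#' @param test test name.
#' @return The `htest` object, with a `stars` attribute using the usual
#'   0.05 / 0.01 / 0.001 tiers.
#' @export
compare_groups <- function(report, parameter = c("lv", "nv", "ln"),
                           stain = "IF", method = "planes",
                           test = c("mann-whitney", "wilcoxon", "t", "ks")) {
  test <- match.arg(test)
  if (inherits(report, "density_report")) {
    parameter <- match.arg(parameter)
    col <- c(lv = "lv_mm_mm3", nv = "nv_per_mm3", ln = "ln_um")[[parameter]]
    rows <- report$rows[report$rows$stain == stain &
                          report$rows$method == method, ]
    x <- rows[rows$group == "deaff", col]
    y <- rows[rows$group == "control", col]
  } else {
    x <- report$x; y <- report$y
  }
  if (length(x) < 2 || length(y) < 2)
    stop("need at least two sampling units per group")
  ht <- switch(test,
    "mann-whitney" = wilcox.test(x, y, exact = TRUE),
    "wilcoxon" = {
      if (length(x) != length(y)) stop("paired test needs equal-length sides")
      wilcox.test(x, y, paired = TRUE, exact = TRUE)
    },
    "t" = t.test(x, y),
    "ks" = ks.test(x, y))
  p <- ht$p.value
  attr(ht, "stars") <- if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "n.s."
  ht
}

#' Write a density report to CSV
#'
#' @param report a `density_report`.
#' @param path output file.
#' @return Invisibly, the rows written.
#' @export
write_report_csv <- function(report, path) {
  write.csv(report$rows, path, row.names = FALSE)
  invisible(report$rows)
}
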