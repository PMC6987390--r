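# Synthetic 3D microglia tissue with exact ground-truth morphometry.

#' Condition parameters for the tissue simulator
#'
#' Bundles the generating parameters of one experimental regime.  The two
#' built-in regimes emulate mouse Sp5C microglia: `"control"` matches the
#' published control morphometry (numerical density about 1.03e4 cells/mm^3,
#' about 817 um of processes per cell, soma volumes 149 +/- 74 um^3, about
#' 4 primary processes), and `"deaff"` the peak deafferentation reaction
#' (cell density x5, process length density x2.5, hence half the process
#' length per cell, soma volumes 249 +/- 118 um^3, about 9 primary
#' processes).
#'
#' @param name `"control"`, `"deaff"`, or any label when parameters are
#'   supplied explicitly.
#' @param nv_per_mm3 soma (cell body) numerical density, cells/mm^3.
#' @param length_per_cell_um target mean total process length per cell, um.
#' @param soma_mean_um3,soma_sd_um3 mean and SD of the lognormal soma-volume
#'   distribution, um^3.
#' @param primaries_mean mean number of primary processes per cell.
#' @param primaries_shape gamma shape of the (rounded) primary-count
#'   distribution; larger is narrower.
#' @param seg_len_mean_um mean inter-branch segment length before
#'   calibration, um.
#' @param branch_prob probability that a segment bifurcates at its tip.
#' @param max_order maximum centrifugal branch order.
#' @param step_um polyline step used when growing tortuous segments, um.
#' @param kappa von Mises-Fisher concentration of step directions (higher is
#'   straighter).
#' @param branch_kappa concentration of daughter directions about the parent
#'   tip direction.
#' @param len_taper multiplicative segment-length decay per branch order.
#' @param radius_primary_um process radius at the soma, um.
#' @param radius_taper multiplicative radius decay per branch order.
#' @param radius_min_um radius floor, um.
#' @param axis_ratio_sdlog lognormal sd of soma axis ratios (0 = spheres).
#' @param orient_bias optional anisotropy in `[0, 1)`: fraction of primary
#'   directions re-drawn parallel to the horizontal (x-z) plane, emulating
#'   the superficial-lamina orientation bias.  Default off.
#' @param calibrate if `TRUE` (default) arbor coordinates are rescaled about
#'   each soma so the realised mean per-cell length matches
#'   `length_per_cell_um` exactly.
#' @return An object of class `mg_condition` (a named list).
#' @export
mg_condition <- function(name = c("control", "deaff"),
                         nv_per_mm3 = NULL,
                         length_per_cell_um = NULL,
                         soma_mean_um3 = NULL, soma_sd_um3 = NULL,
                         primaries_mean = NULL, primaries_shape = 8,
                         seg_len_mean_um = NULL, branch_prob = NULL,
                         max_order = 4, step_um = 3,
                         kappa = 12, branch_kappa = 4,
                         len_taper = 0.8,
                         radius_primary_um = NULL, radius_taper = 0.7,
                         radius_min_um = 0.1,
                         axis_ratio_sdlog = 0.12,
                         orient_bias = 0, calibrate = TRUE) {
  name <- if (length(name) > 1) match.arg(name) else name
  defaults <- switch(name,
    control = list(nv_per_mm3 = 10311, length_per_cell_um = 817,
                   soma_mean_um3 = 149, soma_sd_um3 = 74,
                   primaries_mean = 4.1, seg_len_mean_um = 15,
                   branch_prob = 0.55, radius_primary_um = 0.5),
    deaff   = list(nv_per_mm3 = 51555, length_per_cell_um = 408.5,
                   soma_mean_um3 = 249, soma_sd_um3 = 118,
                   primaries_mean = 9.0, seg_len_mean_um = 10,
                   branch_prob = 0.5, radius_primary_um = 0.8),
    list())
  pick <- function(x, key) if (is.null(x)) defaults[[key]] else x
  cond <- list(
    name = name,
    nv_per_mm3 = pick(nv_per_mm3, "nv_per_mm3"),
    length_per_cell_um = pick(length_per_cell_um, "length_per_cell_um"),
    soma_mean_um3 = pick(soma_mean_um3, "soma_mean_um3"),
    soma_sd_um3 = pick(soma_sd_um3, "soma_sd_um3"),
    primaries_mean = pick(primaries_mean, "primaries_mean"),
    primaries_shape = primaries_shape,
    seg_len_mean_um = pick(seg_len_mean_um, "seg_len_mean_um"),
    branch_prob = pick(branch_prob, "branch_prob"),
    max_order = max_order, step_um = step_um,
    kappa = kappa, branch_kappa = branch_kappa, len_taper = len_taper,
    radius_primary_um = pick(radius_primary_um, "radius_primary_um"),
    radius_taper = radius_taper, radius_min_um = radius_min_um,
    axis_ratio_sdlog = axis_ratio_sdlog,
    orient_bias = orient_bias, calibrate = calibrate)
  if (any(vapply(cond, is.null, logical(1))))
    stop("incomplete condition parameters for '", name, "'")
  if (cond$nv_per_mm3 < 0) stop("density must be non-negative")
  structure(cond, class = "mg_condition")
}

#' Read condition parameters from a YAML config file
#'
#' Keys mirror the arguments of [mg_condition()]; unknown keys are an error.
#'
#' @param path path to a YAML file.
#' @return An `mg_condition` object.
#' @export
read_condition_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(mg_condition))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown condition keys: ", paste(bad, collapse = ", "))
  do.call(mg_condition, cfg)
}

#' Ellipsoidal soma model
#'
#' @param center 3D centre, um.
#' @param semi_axes the three semi-axes, um (all positive).
#' @param orientation 3x3 rotation matrix (columns = body axes).
#' @return Object of class `soma_model` with a derived `volume` field,
#'   `volume = 4/3 pi a b c`.
#' @export
soma_model <- function(center, semi_axes, orientation = diag(3)) {
  if (any(semi_axes <= 0)) stop("semi_axes must be positive")
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 orientation = orientation,
                 volume = 4 / 3 * pi * prod(semi_axes)),
            class = "soma_model")
}

#' Branched process arbor
#'
#' A tree of polyline segments.  `parent = 0` marks primary processes rooted
#' on the soma surface; otherwise `parent` indexes the segment whose tip the
#' child continues from.
#'
#' @param segments list of `list(parent, points, radius)` entries, `points`
#'   an n x 3 matrix and `radius` a length-n vector (um).
#' @return Object of class `process_arbor` with `primary_count`.
#' @export
process_arbor <- function(segments) {
  parents <- vapply(segments, function(s) s$parent, numeric(1))
  if (length(segments) && any(parents >= seq_along(segments)))
    stop("segments must be listed parents-first (tree order)")
  structure(list(segments = segments,
                 primary_count = sum(parents == 0)),
            class = "process_arbor")
}

#' Total length of an arbor
#'
#' Exact sum of inter-vertex Euclidean distances over all segments.
#'
#' @param arbor a [process_arbor()].
#' @return Length in um.
#' @export
arbor_total_length <- function(arbor) {
  sum(vapply(arbor$segments, function(s) {
    d <- diff(s$points)
    sum(sqrt(rowSums(d^2)))
  }, numeric(1)))
}

#' Number of primary processes
#'
#' Counts segments attached directly to the soma surface (ground-truth
#' mode; registered per cell alongside the rotator in a real workflow).
#'
#' @param arbor a [process_arbor()].
#' @return Integer count (0 for an "ameboid", process-free profile).
#' @export
primary_process_count <- function(arbor) arbor$primary_count

# grow one arbor; returns list(segments = arbor segment list)
grow_arbor <- function(center, soma, cond) {
  segs <- list()
  n_prim <- max(1L, as.integer(round(
    rgamma(1, shape = cond$primaries_shape,
           rate = cond$primaries_shape / cond$primaries_mean))))
  A <- soma$orientation %*% diag(soma$semi_axes)
  grow_one <- function(start, dir, order, parent) {
    len <- rexp(1, 1 / (cond$seg_len_mean_um * cond$len_taper^(order - 1)))
    len <- max(len, cond$step_um / 2)
    k <- max(2L, ceiling(len / cond$step_um))
    step <- len / k
    pts <- matrix(0, k + 1, 3)
    pts[1, ] <- start
    d <- dir
    for (i in seq_len(k)) {
      d <- as.numeric(rvmf(1, d, cond$kappa))
      pts[i + 1, ] <- pts[i, ] + step * d
    }
    r0 <- max(cond$radius_min_um,
              cond$radius_primary_um * cond$radius_taper^(order - 1))
    r1 <- max(cond$radius_min_um, r0 * cond$radius_taper)
    seg <- list(parent = parent, points = pts,
                radius = seq(r0, r1, length.out = k + 1))
    segs[[length(segs) + 1L]] <<- seg
    idx <- length(segs)
    if (order < cond$max_order && runif(1) < cond$branch_prob) {
      tip <- pts[k + 1, ]
      tip_dir <- d
      for (b in 1:2) {
        child_dir <- as.numeric(rvmf(1, tip_dir, cond$branch_kappa))
        grow_one(tip, child_dir, order + 1L, idx)
      }
    }
  }
  for (p in seq_len(n_prim)) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    if (cond$orient_bias > 0 && runif(1) < cond$orient_bias) {
      a <- runif(1, 0, 2 * pi)            # parallel to the x-z plane
      u <- c(cos(a), 0, sin(a))
    }
    root <- center + as.numeric(A %*% u)
    dir <- root - center
    dir <- dir / sqrt(sum(dir^2))
    grow_one(root, dir, 1L, 0L)
  }
  segs
}

#' Simulate a tissue block
#'
#' Soma centres follow a homogeneous Poisson process at the condition's
#' intensity; soma volumes are lognormal matched to the condition's
#' mean/SD; arbors are grown by recursive binary branching with tortuous
#' (von Mises-Fisher) polyline segments and then rescaled once about each
#' soma so the realised mean per-cell length matches the configured target.
#' Exact ground truth (counts, densities, per-cell lengths and volumes) is
#' recorded on the object.
#'
#' The block has periodic (toroidal) boundary conditions: arbor geometry
#' leaving the block re-enters on the opposite face, so length density is
#' exactly stationary everywhere and the block ground truth
#' `L_V = sum(arbor lengths) / volume` holds with no edge deficit.
#'
#' @param condition an [mg_condition()] or a regime name.
#' @param dims block extents `(x, y, z)` in um (all positive).
#' @param seed integer seed; the block is bit-reproducible given
#'   `condition`, `dims`, `seed`.
#' @param grow_arbors set `FALSE` for soma-only blocks (fast counting
#'   studies).
#' @return Object of class `tissue_block`: fields `dims`, `condition`,
#'   `cells` (list of `soma`/`arbor` pairs), `segments` (pooled segment
#'   matrix with a `cell` column, wrapped to the block), and `ground_truth`
#'   with `n_cells`, `nv_um3`, `lv_um2` (total length per unit volume),
#'   `total_length_um`, `length_per_cell_um`, `soma_volumes_um3`,
#'   `primary_counts`.
#' @export
build_tissue <- function(condition = "control", dims = c(300, 300, 80),
                         seed = NULL, grow_arbors = TRUE) {
  if (is.character(condition)) condition <- mg_condition(condition)
  if (any(dims <= 0)) stop("dims must be positive")
  with_seed(seed, {
    vol <- prod(dims)
    lambda_um <- condition$nv_per_mm3 / 1e9
    n <- rpois(1, lambda_um * vol)
    cells <- vector("list", n)
    if (n > 0) {
      centers <- cbind(runif(n, 0, dims[1]), runif(n, 0, dims[2]),
                       runif(n, 0, dims[3]))
      sdlog2 <- log(1 + (condition$soma_sd_um3 / condition$soma_mean_um3)^2)
      vols <- rlnorm(n, meanlog = log(condition$soma_mean_um3) - sdlog2 / 2,
                     sdlog = sqrt(sdlog2))
      for (i in seq_len(n)) {
        q <- exp(rnorm(2, 0, condition$axis_ratio_sdlog))
        s <- (3 * vols[i] / (4 * pi * q[1] * q[2]))^(1 / 3)
        soma <- soma_model(centers[i, ], c(s, s * q[1], s * q[2]),
                           random_rotation())
        arbor <- if (grow_arbors)
          process_arbor(grow_arbor(centers[i, ], soma, condition))
        else process_arbor(list())
        cells[[i]] <- list(soma = soma, arbor = arbor)
      }
      if (grow_arbors && condition$calibrate && n > 0) {
        lens <- vapply(cells, function(c) arbor_total_length(c$arbor),
                       numeric(1))
        realized <- mean(lens)
        if (realized > 0) {
          f <- condition$length_per_cell_um / realized
          # common rescale about each soma centre: matches the target mean
          # exactly while preserving relative between-cell variability
          for (i in seq_len(n)) {
            ctr <- cells[[i]]$soma$center
            cells[[i]]$arbor$segments <- lapply(
              cells[[i]]$arbor$segments, function(s) {
                s$points <- t(ctr + f * (t(s$points) - ctr))
                s
              })
          }
        }
      }
    }
    segs <- do.call(rbind, c(list(empty_segments(cell = TRUE)),
      lapply(seq_len(n), function(i) {
        do.call(rbind, c(list(empty_segments(cell = TRUE)),
          lapply(cells[[i]]$arbor$segments, function(s)
            polyline_to_segments(s$points, s$radius, cell = i))))
      })))
    # periodic boundary conditions: arbor geometry leaving the block wraps
    # around, so length density is exactly stationary across the block and
    # the clipped total equals the sum of arbor lengths
    segs <- wrap_segments(segs, dims)
    total_len <- sum(seg_lengths(segs))
    per_cell <- if (n > 0)
      vapply(cells, function(c) arbor_total_length(c$arbor), numeric(1))
    else numeric(0)
    structure(list(
      dims = dims, condition = condition, seed = seed, cells = cells,
      segments = segs,
      ground_truth = list(
        n_cells = n,
        nv_um3 = n / vol,
        lv_um2 = total_len / vol,
        total_length_um = total_len,
        length_per_cell_um = if (n > 0) mean(per_cell) else 0,
        per_cell_length_um = per_cell,
        soma_volumes_um3 = vapply(cells, function(c) c$soma$volume,
                                  numeric(1)),
        primary_counts = vapply(cells, function(c) c$arbor$primary_count,
                                integer(1)))),
      class = "tissue_block")
  })
}

#' @export
print.tissue_block <- function(x, ...) {
  gt <- x$ground_truth
  cat("Synthetic tissue block (", x$condition$name, ")\n", sep = "")
  cat(sprintf("  dims: %g x %g x %g um, %d cells\n",
              x$dims[1], x$dims[2], x$dims[3], gt$n_cells))
  cat(sprintf("  ground truth: N_V = %.0f /mm^3, L_V = %.0f mm/mm^3, L_N = %.1f um\n",
              um3_inv_to_per_mm3(gt$nv_um3), um2_inv_to_mm_per_mm3(gt$lv_um2),
              gt$length_per_cell_um))
  invisible(x)
}

#' Cut a block into sampled sections
#'
#' Clips geometry to slabs `[k t, (k+1) t)` of nominal thickness `t`,
#' keeping every `period`-th slab with a random start, then rescales
#' z-coordinates by `z_shrinkage` (the post-processing collapse of the cut
#' section).  The nominal cut thickness is retained as metadata for the
#' shrinkage correction downstream.
#'
#' @param block a [build_tissue()] block.
#' @param thickness nominal cut thickness, um.
#' @param period sampling period (every `period`-th section is kept).
#' @param z_shrinkage in `(0, 1]`: measured thickness / cut thickness.
#' @param seed integer seed for the random sampling start.
#' @return List of `tissue_section` objects, each with `xy_dims`,
#'   `t_cut`, `t_measured`, `z_shrinkage`, `segments` (clipped, z rebased to
#'   0 and shrunken), `cell_centers` (soma centroids assigned by centroid
#'   rule, same coordinates), `somas`, `arbors`, and `truth_length_um`
#'   (clipped length before shrinkage).
#' @export
cut_sections <- function(block, thickness = 40, period = 5,
                         z_shrinkage = 1, seed = NULL) {
  if (period < 1) stop("period must be >= 1")
  if (z_shrinkage <= 0 || z_shrinkage > 1)
    stop("z_shrinkage must be in (0, 1]")
  if (thickness > block$dims[3]) stop("thickness exceeds block z extent")
  with_seed(seed, {
    n_slab <- floor(block$dims[3] / thickness)
    start <- if (period > 1) sample.int(period, 1) - 1L else 0L
    ks <- seq(start, n_slab - 1L, by = period)
    lapply(ks, function(k) {
      z0 <- k * thickness
      z1 <- z0 + thickness
      segs <- clip_segments_z(block$segments, z0, z1)
      truth_len <- sum(seg_lengths(segs))
      if (nrow(segs) > 0) {
        segs[, 3] <- (segs[, 3] - z0) * z_shrinkage
        segs[, 6] <- (segs[, 6] - z0) * z_shrinkage
      }
      keep <- which(vapply(block$cells, function(c)
        c$soma$center[3] >= z0 && c$soma$center[3] < z1, logical(1)))
      centers <- if (length(keep))
        t(vapply(block$cells[keep], function(c) {
          p <- c$soma$center
          c(p[1], p[2], (p[3] - z0) * z_shrinkage)
        }, numeric(3)))
      else matrix(numeric(0), ncol = 3)
      structure(list(
        xy_dims = block$dims[1:2],
        t_cut = thickness,
        t_measured = thickness * z_shrinkage,
        z_shrinkage = z_shrinkage,
        slab_index = k,
        segments = segs,
        cell_centers = centers,
        somas = lapply(block$cells[keep], `[[`, "soma"),
        arbors = lapply(block$cells[keep], `[[`, "arbor"),
        truth_length_um = truth_len),
        class = "tissue_section")
    })
  })
}

#' @export
print.tissue_section <- function(x, ...) {
  cat(sprintf(
    "Tissue section: %g x %g um, t_cut %g um (measured %g um), %d cells, %d segments\n",
    x$xy_dims[1], x$xy_dims[2], x$t_cut, x$t_measured,
    nrow(x$cell_centers), nrow(x$segments)))
  invisible(x)
}

#' Export ground truth as JSON and per-cell CSV
#'
#' @param block a `tissue_block`.
#' @param json_path,csv_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the ground-truth list.
#' @export
export_ground_truth <- function(block, json_path = NULL, csv_path = NULL) {
  gt <- block$ground_truth
  if (!is.null(json_path)) {
    meta <- list(dims_um = block$dims, condition = block$condition$name,
                 seed = block$seed,
                 n_cells = gt$n_cells, nv_per_mm3 = um3_inv_to_per_mm3(gt$nv_um3),
                 lv_mm_per_mm3 = um2_inv_to_mm_per_mm3(gt$lv_um2),
                 total_length_um = gt$total_length_um,
                 soma_volumes_um3 = gt$soma_volumes_um3,
                 per_cell_length_um = gt$per_cell_length_um)
    jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    df <- data.frame(cell = seq_len(gt$n_cells),
                     soma_volume_um3 = gt$soma_volumes_um3,
                     process_length_um = gt$per_cell_length_um,
                     primary_processes = gt$primary_counts)
    write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(gt)
}

#' Write a block's geometry as SWC-like text
#'
#' One line per vertex: `id type parent x y z radius` (type 1 = soma
#' centroid, 3 = process vertex), the usual reconstruction interchange
#' layout.
#'
#' @param block a `tissue_block`.
#' @param path output file.
#' @return Invisibly, the number of lines written.
#' @export
write_swc <- function(block, path) {
  lines <- character(0)
  id <- 0L
  for (ci in seq_along(block$cells)) {
    cell <- block$cells[[ci]]
    id <- id + 1L
    soma_id <- id
    ctr <- cell$soma$center
    lines <- c(lines, sprintf("%d 1 -1 %.4f %.4f %.4f %.4f", soma_id,
                              ctr[1], ctr[2], ctr[3],
                              mean(cell$soma$semi_axes)))
    tip_ids <- integer(length(cell$arbor$segments))
    for (si in seq_along(cell$arbor$segments)) {
      s <- cell$arbor$segments[[si]]
      parent_id <- if (s$parent == 0) soma_id else tip_ids[s$parent]
      for (vi in seq_len(nrow(s$points))) {
        if (vi == 1) next  # first vertex coincides with the parent tip/root
        id <- id + 1L
        lines <- c(lines, sprintf("%d 3 %d %.4f %.4f %.4f %.4f", id,
                                  parent_id, s$points[vi, 1], s$points[vi, 2],
                                  s$points[vi, 3], s$radius[vi]))
        parent_id <- id
      }
      tip_ids[si] <- parent_id
    }
  }
  writeLines(lines, path)
  invisible(length(lines))
}
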