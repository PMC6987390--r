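test_that("isotropic directions are uniform on the hemisphere", {
  d <- isotropic_direction(1e5, seed = 1)
  expect_equal(dim(d), c(1e5, 3))
  expect_true(all(abs(rowSums(d^2) - 1) < 1e-12))
  # mean z of area-weighted hemisphere directions is 1/2
  expect_lt(abs(mean(d[, 3]) - 0.5), 0.005)
  # polar angle density proportional to sin(theta)
  theta <- acos(d[, 3])
  ks <- suppressWarnings(ks.test(theta, function(q) 1 - cos(q)))
  expect_gt(ks$p.value, 0.01)
  expect_identical(isotropic_direction(3, seed = 7),
                   isotropic_direction(3, seed = 7))
})

test_that("axis-aligned plane families have the expected count", {
  box <- unit_box(c(100, 100, 100))
  cfg <- plane_probe_config(d = 20)
  for (s in 1:20) {
    pl <- make_virtual_planes(box, cfg, normal = c(0, 0, 1), seed = s)
    expect_length(pl$offsets, 5)   # 100 / 20
  }
})

test_that("plane family obeys the Cavalieri identity", {
  box <- unit_box(c(100, 100, 100))
  cfg <- plane_probe_config(d = 20)
  set.seed(4)
  vols <- replicate(300, {
    pl <- make_virtual_planes(box, cfg)
    sum(stereoglia:::plane_set_areas(pl)) * cfg$d
  })
  expect_lt(abs(mean(vols) - 1e6) / 1e6, 0.01)
})

test_that("plane-box clipping is exact", {
  box <- unit_box(c(100, 100, 100))
  expect_equal(clip_plane_to_box(c(0, 0, 1), 50, box)$area, 1e4)
  expect_equal(clip_plane_to_box(c(0, 0, 1), 150, box)$area, 0)
  # hexagonal section of the main diagonal plane
  n <- rep(1, 3) / sqrt(3)
  expect_equal(clip_plane_to_box(n, 50 * sqrt(3), box)$area,
               3 * sqrt(3) / 2 * (50 * sqrt(2))^2, tolerance = 1e-9)
  # Monte-Carlo area oracle over random planes (aggregate)
  set.seed(8)
  npl <- 60
  tot_analytic <- 0
  tot_mc <- 0
  pts <- matrix(runif(3 * 4e4, 0, 100), ncol = 3)
  for (i in seq_len(npl)) {
    nrm <- as.numeric(isotropic_direction(1))
    off <- sum(nrm * runif(3, 0, 100))   # plane through a random box point
    tot_analytic <- tot_analytic + clip_plane_to_box(nrm, off, box)$area
    # slab MC: points within eps/2 of the plane approximate area * eps
    eps <- 2
    s <- abs(pts %*% nrm - off)
    tot_mc <- tot_mc + sum(s < eps / 2) / nrow(pts) * 1e6 / eps
  }
  expect_lt(abs(tot_mc - tot_analytic) / tot_analytic, 0.02)
})

test_that("intersection counting satisfies the L/(2d) identity", {
  box <- unit_box(c(100, 100, 100))
  cfg <- plane_probe_config(d = 20)
  seg <- one_seg(c(10, 10, 10), c(90, 90, 90))
  L <- seg_lengths(seg)
  set.seed(3)
  qs <- replicate(2500, {
    pl <- make_virtual_planes(box, cfg)
    count_plane_curve_intersections(pl, seg)$sum_Q
  })
  expect_lt(abs(mean(qs) - L / (2 * cfg$d)) / (L / (2 * cfg$d)), 0.05)
  # a curve entirely outside the box contributes nothing
  far <- one_seg(c(500, 500, 500), c(600, 600, 600))
  pl <- make_virtual_planes(box, cfg, seed = 1)
  expect_equal(count_plane_curve_intersections(pl, far)$sum_Q, 0L)
  # a single transversal crossing counts once
  pl0 <- make_virtual_planes(box, plane_probe_config(d = 200),
                             normal = c(0, 0, 1), seed = 2)
  cross <- one_seg(c(50, 50, pl0$offsets[1] - 1), c(50, 50, pl0$offsets[1] + 1))
  expect_equal(count_plane_curve_intersections(pl0, cross)$sum_Q, 1L)
  # zero-length segments are skipped with a warning
  degen <- rbind(seg, one_seg(c(5, 5, 5), c(5, 5, 5)))
  expect_warning(count_plane_curve_intersections(pl, degen), "zero-length")
})

test_that("estimator equals a marching oracle on small instances", {
  box <- unit_box(c(60, 60, 60))
  cfg <- plane_probe_config(d = 12)
  set.seed(10)
  for (k in 1:10) {
    segs <- random_segments_in_box(3, 30, c(60, 60, 60))
    pl <- make_virtual_planes(box, cfg)
    got <- count_plane_curve_intersections(pl, segs)$sum_Q
    # marching oracle: walk each segment in tiny steps, count cell changes
    oracle <- 0L
    base <- pl$smin + pl$phase
    for (i in seq_len(nrow(segs))) {
      t <- seq(0, 1, length.out = 4001)
      p <- outer(1 - t, segs[i, 1:3]) + outer(t, segs[i, 4:6])
      s <- p %*% pl$normal
      cells <- floor((s - base) / cfg$d)
      dc <- abs(diff(cells))
      ch <- which(dc != 0)
      if (length(ch)) {
        mid <- (p[ch, , drop = FALSE] + p[ch + 1, , drop = FALSE]) / 2
        inside <- mid[, 1] >= 0 & mid[, 1] < 60 & mid[, 2] >= 0 &
          mid[, 2] < 60 & mid[, 3] >= 0 & mid[, 3] < 60
        oracle <- oracle + sum(dc[ch] * inside)
      }
    }
    expect_lte(abs(got - oracle), 1)
  }
})

test_that("length density is recovered, including fully anisotropic curves", {
  dims <- c(100, 100, 100)
  box <- unit_box(dims)
  cfg <- plane_probe_config(d = 20)
  set.seed(21)
  iso <- random_segments_in_box(62, 80, dims)
  ani <- random_segments_in_box(62, 80, dims, direction = c(1, 0, 0))
  for (segs in list(iso, ani)) {
    truth <- sum(seg_lengths(segs)) / prod(dims)
    res <- lv_planes(segs, box = box, n_placements = 150, config = cfg,
                     seed = 31)
    per <- res$per_placement$lv
    sem <- sd(per) / sqrt(length(per))
    expect_lt(abs(mean(per) - truth), 2 * sem + 0.03 * truth)
    expect_lt(abs(res$lv_um2 - truth) / truth, 0.03)
  }
})

test_that("doubling d halves the expected count, not the estimate", {
  dims <- c(100, 100, 100)
  box <- unit_box(dims)
  set.seed(22)
  segs <- random_segments_in_box(50, 80, dims)
  truth <- sum(seg_lengths(segs)) / prod(dims)
  r20 <- lv_planes(segs, box, n_placements = 120,
                   config = plane_probe_config(d = 20), seed = 5)
  r40 <- lv_planes(segs, box, n_placements = 120,
                   config = plane_probe_config(d = 40), seed = 6)
  expect_lt(abs(r40$sum_Q / r20$sum_Q - 0.5), 0.08)
  expect_lt(abs(r20$lv_um2 - truth) / truth, 0.04)
  expect_lt(abs(r40$lv_um2 - truth) / truth, 0.04)
})

test_that("estimator forms and degenerate cases behave as specified", {
  expect_equal(estimate_Lv_virtual_planes(0, 0), 0)
  expect_error(estimate_Lv_virtual_planes(5, 0), "undefined")
  expect_equal(estimate_Lv_virtual_planes(10, 4000), 2 * 10 / 4000)
  # corner-point form
  expect_equal(estimate_Lv_virtual_planes(10, p_box = 4, sum_p_ref = 40,
                                          a_plane = 900),
               2 * 4 / 900 * 10 / 40)
  expect_error(estimate_Lv_virtual_planes(10, p_box = 4, sum_p_ref = 0,
                                          a_plane = 900), "corner")
})
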