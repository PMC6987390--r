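test_that("cycloid grids have the stated grid constant and arc geometry", {
  win <- list(xlim = c(0, 100), ylim = c(0, 100))
  g <- cycloid_grid(100, win, seed = 1)
  # a/l = 100 um: about 100 um of arc per 1e4 um^2 window
  expect_lt(abs(g$arc_length - 100) / 100, 0.35)
  # aggregate over several windows converges on the definition
  arcs <- vapply(1:40, function(s)
    cycloid_grid(20, list(xlim = c(0, 180), ylim = c(0, 180)),
                 seed = s)$arc_length, numeric(1))
  expect_lt(abs(mean(arcs) - 180 * 180 / 20) / (180 * 180 / 20), 0.02)
  # arc length of one half-period equals 4 r (closed form)
  r <- 7
  quad <- integrate(function(t) 2 * r * sin(t / 2), 0, pi,
                    rel.tol = 1e-10)$value
  expect_equal(quad, 4 * r, tolerance = 1e-6)
  expect_identical(cycloid_grid(20, win, seed = 5)$chords,
                   cycloid_grid(20, win, seed = 5)$chords)
})

test_that("geometric intersection counts match an exact pairwise oracle", {
  win <- list(xlim = c(0, 60), ylim = c(0, 60))
  set.seed(14)
  for (k in 1:20) {
    g <- cycloid_grid(15, win)
    segs3 <- random_segments_in_box(4, 40, c(60, 60, 1))
    s2 <- project_segments(segs3, 0)
    got <- count_cycloid_intersections_geometric(s2, g)
    ch <- g$chords
    mid_in <- (ch[, 1] + ch[, 3]) / 2 >= 0 & (ch[, 1] + ch[, 3]) / 2 < 60 &
      (ch[, 2] + ch[, 4]) / 2 >= 0 & (ch[, 2] + ch[, 4]) / 2 < 60
    oracle <- 0L
    for (i in seq_len(nrow(s2))) for (j in which(mid_in)) {
      if (oracle_seg_cross(s2[i, 1:2], s2[i, 3:4], ch[j, 1:2], ch[j, 3:4]))
        oracle <- oracle + 1L
    }
    expect_lte(abs(got - oracle), 1)
  }
  # empty projection
  expect_equal(count_cycloid_intersections_geometric(
    project_segments(stereoglia:::empty_segments(), 0),
    cycloid_grid(15, win, seed = 2)), 0L)
})

test_that("the TVP estimator is unbiased for vertical and horizontal lines", {
  cfg <- tvp_config(a_over_l = 5)
  win <- list(xlim = c(-120, 120), ylim = c(-20, 220))
  tmpl <- cycloid_grid(5, win, seed = 99)
  run <- function(seg3, tm, n) {
    est <- replicate(n, {
      I <- vapply(cfg$angles, function(a)
        count_cycloid_intersections_geometric(
          project_segments(seg3, a), shift_cycloid_grid(tm)), integer(1))
      estimate_length_tvp(I, cfg)
    })
    mean(est)
  }
  set.seed(51)
  segv <- one_seg(c(0.4, 0, 0), c(0.4, 200, 0))
  segh <- one_seg(c(-100, 100.3, 0), c(100, 100.3, 0))
  expect_lt(abs(run(segv, tmpl, 250) - 200) / 200, 0.03)
  expect_lt(abs(run(segh, tmpl, 150) - 200) / 200, 0.05)
  # a 90-degree-rotated grid (surface-area convention) fails badly on
  # horizontal structures: guards the orientation convention
  tmpl_r <- cycloid_grid(5, win, orientation = "rotated", seed = 99)
  expect_lt(run(segh, tmpl_r, 100), 0.7 * 200)
  # trivial cases
  expect_equal(estimate_length_tvp(c(0, 0, 0, 0, 0), cfg), 0)
  expect_equal(estimate_length_tvp(rep(10, 5), tvp_config(a_over_l = 2)),
               2 * 2 * 10)
  expect_error(estimate_length_tvp(integer(0), cfg), "projection")
})

test_that("image-mode counting can only lose hits relative to geometric", {
  set.seed(61)
  cond <- mg_condition("deaff")
  b <- build_tissue(cond, c(60, 60, 40), seed = 62)
  sub <- clip_segments_z(b$segments, 36, 40)
  win <- list(xlim = c(0, 60), ylim = c(0, 60))
  stack <- render_stack(sub, window = win, z_range = c(36, 40),
                        voxel_size = c(0.4, 0.4, 0.5))
  proj <- rotate_and_project(stack, 0)
  sk <- binarize_and_skeletonize(proj, threshold = 0.05)
  s2 <- project_segments(sub, 0)
  n_geo <- 0L; n_img <- 0L
  for (s in 63:70) {
    g <- cycloid_grid(8, win, seed = s)
    n_geo <- n_geo + count_cycloid_intersections_geometric(s2, g)
    n_img <- n_img + count_cycloid_intersections_image(sk, g,
                                                       origin = proj$origin)
  }
  expect_gt(n_geo, 40)
  expect_lte(n_img, n_geo * 1.05)
  # empty skeleton counts nothing
  empty <- matrix(FALSE, 10, 10)
  expect_equal(count_cycloid_intersections_image(empty, g, pixel_size = 1),
               0L)
})

test_that("point counting estimates areas and volumes", {
  win <- list(xlim = c(0, 183), ylim = c(0, 183))
  # full frame, depth 4 um: mean over random offsets equals area x depth
  vols <- vapply(1:200, function(s)
    point_count_volume(TRUE, point_grid(15, win, seed = s), 4), numeric(1))
  expect_lt(abs(mean(vols) - 183 * 183 * 4), 15^2 * 4)
  # empty region
  expect_equal(point_count_volume(function(x, y) rep(FALSE, length(x)),
                                  point_grid(15, win, seed = 1), 4), 0)
  # blob mask: point-count area within the classical error bound
  px <- 0.5
  n <- 183 / px
  xs <- (seq_len(n) - 0.5) * px
  mask <- outer(xs, xs, function(x, y) (x - 90)^2 + (y - 90)^2 < 50^2)
  pg <- point_grid(10, win, seed = 3)
  a_pts <- point_count_volume(mask, pg, 1, pixel_size = px) # depth 1 = area
  a_pix <- sum(mask) * px^2
  expect_lt(abs(a_pts - a_pix), 2 * 10 * (2 * pi * 50))
})

test_that("length density assembles from length and reference volume", {
  expect_equal(estimate_Lv_tvp(500, 1e5), 5e-3)
  expect_equal(um2_inv_to_mm_per_mm3(estimate_Lv_tvp(500, 1e5)), 5000)
  expect_equal(estimate_Lv_tvp(500, 1e5, shrinkage = 1),
               estimate_Lv_tvp(500, 1e5))
  expect_equal(estimate_Lv_tvp(500, 1e5, shrinkage = 2), 2.5e-3)
  expect_error(estimate_Lv_tvp(500, 0), "reference volume")
})

test_that("full TVP estimate recovers arbor scene length", {
  b <- build_tissue("deaff", c(150, 150, 60), seed = 71)
  secs <- cut_sections(b, 40, 1, 1, seed = 72)
  sec <- secs[[1]]
  truth <- sum(seg_lengths(clip_segments_z(sec$segments,
                                           sec$t_measured - 4,
                                           sec$t_measured)))
  cfg <- tvp_config(a_over_l = 6)
  win <- list(xlim = c(0, 150), ylim = c(0, 150))
  set.seed(73)
  ests <- replicate(40, tvp_estimate(sec, win, cfg)$L_hat_um)
  expect_lt(abs(mean(ests) - truth) / truth, 0.05)
})
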