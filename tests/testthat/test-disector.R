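test_that("systematic boxes realise the target area fraction", {
  # expectation over random starts matches the target to within one box;
  # single draws fluctuate by a few boxes through boundary overlap
  a10 <- vapply(1:20, function(s)
    sum(systematic_sample_boxes(c(1000, 1000), 0.10, c(60, 60),
                                seed = s)$overlap_area), numeric(1))
  expect_lt(abs(mean(a10) - 1e5), 60 * 60)
  expect_true(all(abs(a10 - 1e5) < 1e5 * 0.15))
  # quadrupling the fraction quadruples the sampled area
  a40 <- vapply(1:20, function(s)
    sum(systematic_sample_boxes(c(1000, 1000), 0.40, c(60, 60),
                                seed = s)$overlap_area), numeric(1))
  expect_lt(abs(mean(a40) / mean(a10) - 4), 0.1)
  # full fraction tiles the region completely
  g1 <- systematic_sample_boxes(c(500, 500), 1, c(50, 50), seed = 4)
  expect_equal(g1$realized_fraction, 1)
  expect_error(systematic_sample_boxes(c(100, 100), 0, c(10, 10)),
               "fraction")
  expect_error(systematic_sample_boxes(c(40, 40), 0.5, c(60, 60)),
               "larger")
})

test_that("disector counting applies the half-open inclusion rule", {
  boxes <- matrix(c(0, 0), 1, 2)
  # low faces count, high faces do not
  pts <- rbind(c(0, 0, 0),      # on all low faces: counted
               c(10, 5, 5),     # on high x face: excluded
               c(5, 10, 5),     # on high y face: excluded
               c(5, 5, 10),     # on high z face: excluded
               c(5, 5, 5))      # interior: counted
  cnt <- disector_count(boxes, pts, z0 = 0, height = 10, box_xy = c(10, 10))
  expect_equal(cnt$sum_Q, 2L)
  # tiling a volume counts every cell exactly once
  set.seed(5)
  cells <- cbind(runif(400, 0, 500), runif(400, 0, 500), runif(400, 0, 20))
  tiles <- systematic_sample_boxes(c(500, 500), 1, c(50, 50), seed = 6)
  cnt2 <- disector_count(tiles, cells, z0 = 0, height = 20)
  expect_equal(cnt2$sum_Q, 400L)
  # translating the grid by a full period leaves counts over interior
  # points unchanged (the partition of the central area is identical)
  inner <- cells[cells[, 1] > 80 & cells[, 1] < 420 &
                   cells[, 2] > 80 & cells[, 2] < 420, , drop = FALSE]
  grid_a <- as.matrix(expand.grid(seq(0, 450, 75), seq(0, 450, 75)))
  grid_b <- as.matrix(expand.grid(seq(-75, 450, 75), seq(-75, 450, 75)))
  ca <- disector_count(grid_a, inner, 0, 20, box_xy = c(75, 75))
  cb <- disector_count(grid_b, inner, 0, 20, box_xy = c(75, 75))
  expect_equal(ca$sum_Q, cb$sum_Q)
  expect_equal(ca$sum_Q, nrow(inner))
})

test_that("SumQ-weighted thickness is the count-weighted mean", {
  expect_equal(q_weighted_thickness(c(1, 1), c(10, 20)), 15)
  expect_equal(q_weighted_thickness(c(3, 1), c(10, 20)), 12.5)
  expect_equal(q_weighted_thickness(c(7, 2, 11), rep(13.7, 3)), 13.7)
  expect_warning(t0 <- q_weighted_thickness(c(0, 0), c(10, 20)), "zero")
  expect_equal(t0, 15)
  expect_error(q_weighted_thickness(1:3, 1:2), "equal length")
})

test_that("the N_V estimator corrects for z shrinkage in the right direction", {
  expect_equal(estimate_Nv(100, 1e6), 1e-4)
  expect_equal(estimate_Nv(100, 1e6, t_bar_Q = 40, t_cut = 40), 1e-4)
  # collapsed sections: measured volume is inflated back
  expect_equal(estimate_Nv(100, 1e6, t_bar_Q = 20, t_cut = 40), 5e-5)
  expect_error(estimate_Nv(100, 0), "positive")
})

test_that("shrunken sections recover the generating intensity", {
  lam <- 2e4
  b <- build_tissue(mg_condition("control", nv_per_mm3 = lam),
                    dims = c(800, 800, 240), seed = 7, grow_arbors = FALSE)
  secs <- cut_sections(b, 40, 1, z_shrinkage = 0.5, seed = 8)
  res <- nv_disector(secs, fraction = 0.5, box_xy = c(60, 60), seed = 9)
  realized <- um3_inv_to_per_mm3(b$ground_truth$nv_um3)
  expect_lt(abs(res$nv_per_mm3 - realized) / realized, 0.08)
  # without the correction the density is about twice too high
  uncorr <- um3_inv_to_per_mm3(res$nv_uncorrected_um3)
  expect_lt(abs(uncorr / res$nv_per_mm3 - 2), 1e-9)
  expect_equal(res$t_bar_Q, 20)
  expect_equal(res$t_cut, 40)
})

test_that("length per cell is the density ratio", {
  # reference-scale example: 5779 mm/mm^3 over 10311 cells/mm^3
  expect_equal(1000 * length_per_cell(5779, 10311), 560.5, tolerance = 0.05)
  expect_equal(length_per_cell(0, 10311), 0)
  expect_error(length_per_cell(5, 0), "positive")
})

test_that("the systematic-sample CE has its analytic limits", {
  # single section: Poisson noise only, CE = 1/sqrt(Q)
  expect_warning(ce1 <- ce_systematic(100), "fewer than 3")
  expect_equal(ce1$ce, 0.1)
  # constant profile: the covariogram term is dominated by noise and the
  # CE approaches 1/sqrt(sum f) as sections accumulate
  f <- rep(50, 10)
  ce <- ce_systematic(f)
  expect_lte(ce$var_srs, ce$noise)
  expect_lt(abs(ce$ce - 1 / sqrt(sum(f))) / (1 / sqrt(sum(f))), 0.05)
  # m = 0 uses the rougher divisor
  ce0 <- ce_systematic(f, m = 0)
  expect_gte(ce0$ce, ce$ce)
  expect_error(ce_systematic(rep(0, 5)), "all-zero")
  expect_error(ce_systematic(f, m = 2), "m must be")
})

test_that("predicted CE tracks the empirical CV of systematic samples", {
  # smooth sectional profile sampled by k systematic sections
  g <- function(x) 400 * exp(-((x - 0.45) / 0.25)^2)
  k <- 8
  set.seed(12)
  totals <- numeric(500)
  ces <- numeric(500)
  for (r in 1:500) {
    u <- runif(1) / k
    x <- u + (0:(k - 1)) / k
    f <- rpois(k, g(x) / k)
    totals[r] <- sum(f)
    ces[r] <- ce_systematic(f)$ce
  }
  cv <- sd(totals) / mean(totals)
  expect_lt(mean(ces) / cv, 1.5)
  expect_gt(mean(ces) / cv, 1 / 1.5)
})

test_that("CE falls as the sampling fraction rises", {
  b <- build_tissue(mg_condition("control", nv_per_mm3 = 3e4),
                    dims = c(600, 600, 160), seed = 13, grow_arbors = FALSE)
  secs <- cut_sections(b, 40, 1, seed = 14)
  ce_lo <- mean(vapply(1:8, function(s)
    nv_disector(secs, fraction = 0.1, seed = s)$ce, numeric(1)))
  ce_hi <- mean(vapply(1:8, function(s)
    nv_disector(secs, fraction = 0.6, seed = s)$ce, numeric(1)))
  expect_lt(ce_hi, ce_lo)
})
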