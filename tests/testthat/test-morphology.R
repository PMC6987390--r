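test_that("soma volume follows the ellipsoid formula and rejects bad axes", {
  s <- soma_model(c(0, 0, 0), c(2, 3, 4))
  expect_equal(s$volume, 4 / 3 * pi * 24, tolerance = 1e-9)
  expect_error(soma_model(c(0, 0, 0), c(1, -1, 1)), "positive")
})

test_that("arbor length is the exact sum of polyline lengths", {
  a1 <- process_arbor(list(list(parent = 0,
                                points = rbind(c(0, 0, 0), c(0, 0, 100)),
                                radius = c(0.5, 0.3))))
  expect_equal(arbor_total_length(a1), 100)
  a2 <- process_arbor(list(
    list(parent = 0, points = rbind(c(0, 0, 0), c(60, 0, 0)),
         radius = c(0.5, 0.4)),
    list(parent = 1, points = rbind(c(60, 0, 0), c(60, 40, 0)),
         radius = c(0.4, 0.3))))
  expect_equal(arbor_total_length(a2), 100)
  expect_equal(primary_process_count(a2), 1)
  expect_equal(primary_process_count(process_arbor(list())), 0)
})

test_that("soma counts follow the homogeneous Poisson model", {
  # empty block at zero intensity
  b0 <- build_tissue(mg_condition("control", nv_per_mm3 = 0),
                     dims = c(100, 100, 100), seed = 1)
  expect_equal(b0$ground_truth$n_cells, 0)
  expect_equal(b0$ground_truth$lv_um2, 0)
  expect_equal(b0$ground_truth$nv_um3, 0)
  # 500 replicate soma-only blocks at lambda = 5e4 / mm^3
  lam <- 5e4
  dims <- c(100, 100, 100)
  expected <- lam / 1e9 * prod(dims)
  counts <- vapply(1:500, function(s)
    build_tissue(mg_condition("deaff", nv_per_mm3 = lam), dims,
                 seed = s, grow_arbors = FALSE)$ground_truth$n_cells,
    numeric(1))
  se <- sqrt(expected / 500)
  expect_lt(abs(mean(counts) - expected), 2 * se)
  expect_lt(abs(mean(counts) - expected) / expected, 0.02)
})

test_that("blocks are bit-reproducible for a fixed seed", {
  b1 <- build_tissue("control", c(120, 120, 80), seed = 42)
  b2 <- build_tissue("control", c(120, 120, 80), seed = 42)
  expect_identical(b1$segments, b2$segments)
  expect_identical(b1$ground_truth, b2$ground_truth)
  b3 <- build_tissue("control", c(120, 120, 80), seed = 43)
  expect_false(identical(b1$segments, b3$segments))
})

test_that("arbor calibration hits the configured per-cell length target", {
  cond <- mg_condition("control", length_per_cell_um = 560)
  b <- build_tissue(cond, c(400, 400, 120), seed = 9)
  expect_gt(b$ground_truth$n_cells, 50)
  expect_lt(abs(b$ground_truth$length_per_cell_um - 560) / 560, 0.05)
})

test_that("regimes reproduce the configured primary-process means", {
  nb <- build_tissue("control", c(500, 500, 100), seed = 3)
  db <- build_tissue("deaff", c(260, 260, 80), seed = 4)
  pc <- nb$ground_truth$primary_counts
  pd <- db$ground_truth$primary_counts
  expect_lt(abs(mean(pc) - 4.1), 3 * sd(pc) / sqrt(length(pc)) + 0.1)
  expect_lt(abs(mean(pd) - 9.0), 3 * sd(pd) / sqrt(length(pd)) + 0.1)
})

test_that("soma volumes match the configured lognormal moments", {
  b <- build_tissue("deaff", c(300, 300, 100), seed = 8, grow_arbors = FALSE)
  v <- b$ground_truth$soma_volumes_um3
  expect_gt(length(v), 300)
  expect_lt(abs(mean(v) - 249) / 249, 0.15)
  expect_lt(abs(sd(v) - 118) / 118, 0.3)
})

test_that("sectioning samples every period-th slab and clips exactly", {
  b <- build_tissue(mg_condition("control", nv_per_mm3 = 2e4),
                    dims = c(150, 150, 400), seed = 11)
  secs <- cut_sections(b, thickness = 40, period = 5, seed = 2)
  expect_length(secs, 2)
  expect_equal(secs[[1]]$t_cut, 40)
  # identity shrinkage leaves geometry unchanged within the slab
  all_secs <- cut_sections(b, thickness = 40, period = 1, z_shrinkage = 1)
  total <- sum(vapply(all_secs, function(s) s$truth_length_um, numeric(1)))
  expect_equal(total, b$ground_truth$total_length_um,
               tolerance = 1e-6)
  expect_error(cut_sections(b, period = 0), "period")
  expect_error(cut_sections(b, thickness = 500), "thickness")
  expect_error(cut_sections(b, z_shrinkage = 0), "z_shrinkage")
})

test_that("z-shrinkage rescales the optical axis anisotropically", {
  # a z-parallel segment's measured length halves at z_shrinkage 0.5
  b <- build_tissue(mg_condition("control", nv_per_mm3 = 0),
                    dims = c(50, 50, 40), seed = 1)
  b$segments <- seg_mat(c(25, 25, 5, 25, 25, 35, 0.3, 0.3))
  s1 <- cut_sections(b, thickness = 40, period = 1, z_shrinkage = 1)[[1]]
  s5 <- cut_sections(b, thickness = 40, period = 1, z_shrinkage = 0.5)[[1]]
  expect_equal(sum(seg_lengths(s1$segments)), 30)
  expect_equal(sum(seg_lengths(s5$segments)), 15)
  expect_equal(s5$t_measured, 20)
  expect_equal(s5$t_cut, 40)
})

test_that("ground truth and SWC exports round-trip the block", {
  b <- build_tissue("control", c(100, 100, 60), seed = 5)
  json <- tempfile(fileext = ".json")
  csv <- tempfile(fileext = ".csv")
  swc <- tempfile(fileext = ".swc")
  export_ground_truth(b, json, csv)
  write_swc(b, swc)
  meta <- jsonlite::read_json(json)
  expect_equal(meta$n_cells, b$ground_truth$n_cells)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), b$ground_truth$n_cells)
  lines <- readLines(swc)
  expect_gt(length(lines), b$ground_truth$n_cells)
  # parsable numeric table with parent references
  parsed <- read.table(text = lines)
  expect_equal(ncol(parsed), 7)
  expect_true(all(parsed$V3 < parsed$V1))
})

test_that("condition configs read from YAML and reject unknown keys", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("name: custom", "nv_per_mm3: 12000",
               "length_per_cell_um: 500", "soma_mean_um3: 150",
               "soma_sd_um3: 60", "primaries_mean: 5",
               "seg_len_mean_um: 12", "branch_prob: 0.5",
               "radius_primary_um: 0.5"), path)
  cond <- read_condition_config(path)
  expect_s3_class(cond, "mg_condition")
  expect_equal(cond$nv_per_mm3, 12000)
  writeLines(c("name: x", "bogus: 1"), path)
  expect_error(read_condition_config(path), "unknown")
})
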