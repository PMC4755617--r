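test_that("a single-size scan reproduces edi() and scales cell counts with r^2", {
  spec <- synthetic_tumor_spec(2, regions_per_level = 30,
                               cells_per_region = 100)
  cm <- simulate_cellmap(spec, seed = 61)
  scan <- scale_scan(cm, sizes = 200, seed = 61)
  direct <- edi(cm, region_size = 200, seed = 61 + 1001L)  # scan's seed offset
  expect_equal(scan$edi, direct$edi)
  expect_equal(scan$n_regions, direct$profile$n)

  # uniform density: cells/region at 200 um ~ 4x that at 100 um
  scan2 <- scale_scan(cm, sizes = c(100, 200), min_cells = 1, seed = 61)
  ratio <- scan2$mean_cells_per_region[scan2$region_size == 200] /
    scan2$mean_cells_per_region[scan2$region_size == 100]
  expect_equal(ratio, 4, tolerance = 0.25)

  expect_error(scale_scan(cm, sizes = c(200, -1)),
               class = "ecodiv_parameter_error")
})

test_that("a homogeneous tumor scores EDI 1 at every feasible size", {
  spec <- synthetic_tumor_spec(1, regions_per_level = 60,
                               cells_per_region = 120)
  cm <- simulate_cellmap(spec, seed = 62)
  scan <- suppressWarnings(
    scale_scan(cm, sizes = c(166, 200, 250), seed = 62))
  expect_true(all(scan$edi == 1L, na.rm = TRUE))
  # infeasible sizes are flagged NA, not fatal
  scan_big <- suppressWarnings(scale_scan(cm, sizes = 5000, seed = 62))
  expect_true(is.na(scan_big$edi))
})

test_that("bootstrap instability is near zero for clean profiles and grows with overlap", {
  d_tight <- withr::with_seed(70, rnorm(500, 0.5, 0.02))
  inst_tight <- clustering_instability(d_tight, n_boot = 30, seed = 70)
  ks <- attr(inst_tight, "k_values")
  expect_gte(mean(ks == 1L), 0.95)
  expect_lt(inst_tight, 0.25)

  # heavily overlapping components look like one cluster (modal K = 1)
  # while well-separated ones keep their modal K = 2 across resamples;
  # bootstrap ties can transiently inflate K in either regime
  d_overlap <- withr::with_seed(71, c(rnorm(150, 0.50, 0.10),
                                      rnorm(150, 0.53, 0.10)))
  d_sep <- withr::with_seed(71, c(rnorm(150, 0.2, 0.03),
                                  rnorm(150, 0.9, 0.03)))
  inst_o <- clustering_instability(d_overlap, n_boot = 30, seed = 72)
  inst_s <- clustering_instability(d_sep, n_boot = 30, seed = 72)
  modal <- function(x) as.integer(names(which.max(table(x))))
  expect_equal(modal(attr(inst_o, "k_values")), 1L)
  expect_equal(modal(attr(inst_s, "k_values")), 2L)
  # reproducible given the seed schedule
  expect_equal(as.numeric(inst_o),
               as.numeric(clustering_instability(d_overlap, n_boot = 30,
                                                 seed = 72)))
  expect_error(clustering_instability(d_sep, n_boot = 1),
               class = "ecodiv_parameter_error")
})

test_that("cross-scale correlations are symmetric with unit diagonal", {
  scan <- structure(data.frame(
    tumor = rep(c("a", "b", "c", "d"), each = 2),
    region_size = rep(c(166, 200), 4),
    n_regions = 50L, mean_cells_per_region = 100,
    edi = c(1, 1, 3, 3, 5, 5, 2, 2), instability = NA_real_),
    class = c("scale_scan", "data.frame"))
  cc <- cross_scale_correlation(scan)
  expect_equal(cc, t(cc))
  expect_equal(diag(cc), c("166" = 1, "200" = 1))
  expect_equal(cc["166", "200"], 1)  # identical EDI vectors
  expect_error(cross_scale_correlation(scan[scan$tumor == "a", ]),
               class = "ecodiv_parameter_error")
})

test_that("subsampling agreement is exact at full data and reproducible", {
  spec <- synthetic_tumor_spec(3, regions_per_level = 30,
                               cells_per_region = 100)
  cm <- simulate_cellmap(spec, seed = 63)
  st <- region_subsample_stability(cm, fractions = c(1, 0.9), n_repeats = 10,
                                   seed = 63)
  expect_equal(st$agreement[st$fraction == 1], 1)
  expect_true(st$agreement[st$fraction == 0.9] >= 0 &&
                st$agreement[st$fraction == 0.9] <= 1)
  st2 <- region_subsample_stability(cm, fractions = c(1, 0.9), n_repeats = 10,
                                    seed = 63)
  expect_identical(st, st2)

  # single repeat is a deterministic 0/1 agreement
  st3 <- region_subsample_stability(cm, fractions = 0.8, n_repeats = 1,
                                    seed = 64)
  expect_true(st3$agreement %in% c(0, 1))

  # fractions leaving too few regions are flagged, not fatal
  prof <- regional_diversity(tile_regions(cm, 200), min_cells = 10)
  st4 <- region_subsample_stability(prof, fractions = 0.05, n_repeats = 5,
                                    seed = 65)
  expect_true(is.na(st4$agreement))
  expect_error(region_subsample_stability(prof, fractions = 1.2),
               class = "ecodiv_parameter_error")
})
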