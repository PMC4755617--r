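test_that("BIC selection picks the generating component count", {
  # one tight component -> K = 1 in nearly all seeds
  hits <- sapply(1:20, function(s) {
    d <- withr::with_seed(s, rnorm(200, 0.5, 0.1))
    select_k(d, seed = s)$edi
  })
  expect_gte(mean(hits == 1L), 0.95)

  # two components 10 pooled SDs apart -> K = 2
  hits2 <- sapply(1:10, function(s) {
    d <- withr::with_seed(100 + s, c(rnorm(100, 0.3, 0.04),
                                     rnorm(100, 0.9, 0.04)))
    select_k(d, seed = s)$edi
  })
  expect_true(all(hits2 == 2L))
})

test_that("K values beyond the sample size are skipped", {
  sel <- select_k(c(0.1, 0.5, 0.9), seed = 1)
  expect_equal(sel$bic_table$K, 1:3)
  expect_error(select_k(numeric(0)), class = "ecodiv_empty_profile_error")
})

test_that("edi() scores synthetic habitat mosaics at their ground truth", {
  spec1 <- synthetic_tumor_spec(1, regions_per_level = 40,
                                cells_per_region = 100)
  cm1 <- simulate_cellmap(spec1, seed = 21)
  f1 <- suppressWarnings(edi(cm1, seed = 21))
  expect_equal(f1$edi, 1L)

  spec5 <- synthetic_tumor_spec(5)
  cm5 <- simulate_cellmap(spec5, seed = 22)
  f5 <- edi(cm5, seed = 22)
  expect_equal(f5$edi, 5L)
  expect_equal(expected_edi(spec5), 5L)

  # EDI is always within the searched range
  expect_true(all(f5$bic_table$K %in% 1:5))
  # one label per retained region, ordered k1 < ... < kK by mean diversity
  expect_equal(length(f5$region_labels), f5$profile$n)
  lab_means <- tapply(f5$profile$d, f5$region_labels, mean)
  expect_true(all(diff(lab_means) > 0))
  # cluster means track the habitat entropies
  expect_equal(unname(coef(f5)[, "mean"]),
               sort(attr(cm5, "habitat_shannon")), tolerance = 0.08)
})

test_that("sections are pooled: duplicated sections agree on separated data", {
  spec <- synthetic_tumor_spec(3, regions_per_level = 30,
                               cells_per_region = 100)
  cm <- simulate_cellmap(spec, seed = 31)
  f1 <- edi(cm, seed = 31)
  f2 <- edi(list(cm, cm), seed = 31)
  expect_equal(f2$profile$n, 2L * f1$profile$n)
  expect_equal(f2$edi, f1$edi)
})

test_that("too few regions is an explicit error", {
  cm <- cell_map(runif(30, 0, 190), runif(30, 0, 190),
                 sample(cell_classes(), 30, replace = TRUE))
  expect_error(edi(cm, region_size = 200, min_cells = 1),
               class = "ecodiv_insufficient_data_error")
})

test_that("Q-Q diagnostic validates a correct fit and flags degeneracy", {
  f <- fit_gmm(withr::with_seed(3, c(rnorm(100, 0.4, 0.12),
                                     rnorm(100, 0.85, 0.12))), 2, seed = 3)
  d_self <- withr::with_seed(4, ecodiv:::rgmm1(1000, f))
  expect_gt(qq_diagnostic(f, d_self), 0.99)
  expect_warning(r <- qq_diagnostic(f, rep(0.5, 10)), "constant")
  expect_true(is.na(r))
  expect_error(qq_diagnostic(f, c(0.1, 0.2)), class = "ecodiv_domain_error")
  # Pearson correlation is invariant under affine rescaling of both sides
  d <- withr::with_seed(5, ecodiv:::rgmm1(200, f))
  f_scaled <- f
  f_scaled$mean <- 2 * f$mean + 1
  f_scaled$variance <- 4 * f$variance
  expect_equal(qq_diagnostic(f, d), qq_diagnostic(f_scaled, 2 * d + 1),
               tolerance = 1e-6)
})

test_that("edi objects support the standard model-object verbs", {
  spec <- synthetic_tumor_spec(2, regions_per_level = 30,
                               cells_per_region = 100)
  f <- edi(simulate_cellmap(spec, seed = 41), seed = 41)

  expect_output(print(f), "EDI = 2")
  expect_output(print(summary(f)), "BIC over K")
  expect_equal(dim(coef(f)), c(2L, 3L))
  expect_equal(unname(attr(logLik(f), "df")), 5L)
  expect_equal(as.character(predict(f, c(0, 10))), c("k1", "k2"))
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(f$profile$n, 3L))
  expect_equal(length(residuals(f)), f$profile$n)
  expect_lt(abs(mean(residuals(f))), 0.3)   # roughly standard normal
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
})

test_that("identical input and seed give bit-identical results", {
  spec <- synthetic_tumor_spec(3, regions_per_level = 25,
                               cells_per_region = 80)
  cm <- simulate_cellmap(spec, seed = 51)
  f1 <- edi(cm, seed = 51)
  f2 <- edi(cm, seed = 51)
  expect_identical(f1$bic_table, f2$bic_table)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$region_labels, f2$region_labels)
})

test_that("EDI-high means score 5 exactly", {
  expect_equal(as.character(dichotomize_edi(c(5, 4, 1, 5))),
               c("high", "low", "low", "high"))
  expect_error(dichotomize_edi(0), class = "ecodiv_domain_error")
  expect_error(dichotomize_edi(6), class = "ecodiv_domain_error")
})
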