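test_that("KM curves start at 1, are non-increasing, and scale with time", {
  co <- validate_cohort(simulate_cohort(300, hr_edi = 2, seed = 80))
  grp <- dichotomize_edi(co$edi_score)
  km <- km_logrank(co$survival_months, co$event, grp)
  expect_s3_class(km$fit, "survfit")
  expect_true(all(km$fit$surv <= 1))
  for (s in split(km$fit$surv, rep(seq_along(km$fit$strata), km$fit$strata)))
    expect_true(all(diff(s) <= 1e-12))
  expect_true(km$p >= 0 && km$p <= 1)

  # doubling all event times (no censoring) doubles the KM median
  t0 <- withr::with_seed(81, rexp(400, 0.02))
  km_a <- km_logrank(c(t0, 2 * t0), rep(1, 800), rep(c("a", "b"), each = 400))
  med <- summary(km_a$fit)$table[, "median"]
  expect_equal(unname(med[2] / med[1]), 2, tolerance = 1e-8)

  # degenerate cases
  expect_warning(km0 <- km_logrank(c(1, 2, 3, 4), rep(0, 4),
                                   c("a", "a", "b", "b")), "no events")
  expect_true(is.na(km0$p))
  expect_error(suppressWarnings(km_logrank(1:4, rep(1, 4), rep("a", 4))),
               class = "ecodiv_parameter_error")
})

test_that("Cox fits recover a known hazard ratio and flag rank deficiency", {
  co <- validate_cohort(simulate_cohort(1000, hr_edi = 2, censoring = 0.3,
                                        seed = 82))
  co$edi_group <- dichotomize_edi(co$edi_score)
  fit <- cox_fit(co, "edi_group")
  expect_true(fit$hr > 1.6 && fit$hr < 2.5)
  expect_true(fit$lower < 2 && fit$upper > 2)   # CI covers the truth here
  expect_lt(fit$p, 0.01)

  # multivariate form returns one row per covariate
  fit2 <- cox_fit(co, c("edi_group", "node", "size_cat"))
  expect_equal(nrow(fit2), 3L)

  # duplicated covariate -> aliased design flagged
  co$edi_copy <- co$edi_group
  expect_error(cox_fit(co, c("edi_group", "edi_copy")),
               class = "ecodiv_fit_error")
  expect_error(cox_fit(transform(co, event = 0), "edi_group"),
               class = "ecodiv_validation_error")
})

test_that("EDI + TP53 defines the three-level prognostic grouping", {
  co <- data.frame(edi_score = c(5, 1, 1, 5, 3),
                   tp53 = c("MUT", "WT", "MUT", "WT", NA))
  expect_message(out <- combine_edi_tp53(co), "1 row")
  expect_equal(as.character(out$combined_group),
               c("adverse", "favorable", "intermediate", "intermediate"))
  expect_equal(out$edi_tp53, c(2, 0, 1, 1))
})

test_that("Fisher enrichment matches exhaustive hypergeometric enumeration", {
  # diagonal table: closed form 2 / choose(20, 10)
  expect_equal(fisher_enum_p(10, 0, 0, 10), 2 / choose(20, 10))

  # every 2x2 table with N <= 40 drawn at random agrees with fisher.test
  withr::with_seed(90, {
    for (i in 1:200) {
      n <- sample(4:40, 1)
      a <- sample(0:n, 1); b <- sample(0:(n - a), 1)
      c_ <- sample(0:(n - a - b), 1); d_ <- n - a - b - c_
      if ((a + c_) == 0 || (b + d_) == 0 || (a + b) == 0 || (c_ + d_) == 0) next
      expect_equal(
        stats::fisher.test(matrix(c(a, b, c_, d_), 2))$p.value,
        fisher_enum_p(a, b, c_, d_), tolerance = 1e-9)
    }
  })

  # planted loss block is recovered with small adjusted p
  groups <- rep(c("low", "high"), each = 250)
  cna <- simulate_cna(100, 500, groups, block_genes = 1:10,
                      direction = "loss", odds = 20, seed = 91)
  enr <- fisher_enrichment(cna, groups)
  losses <- enr[enr$direction == "loss", ]
  top10 <- losses$gene[order(losses$p_adj)][1:10]
  expect_gte(length(intersect(top10, sprintf("gene%04d", 1:10))), 8)

  # degenerate gene: all zero calls -> p = 1, flagged
  cna0 <- matrix(0L, 2, 10)
  enr0 <- fisher_enrichment(cna0, rep(c("low", "high"), 5))
  expect_true(all(enr0$p == 1) && all(enr0$degenerate))
})

test_that("EDI-high tumors show the reported ER-negative enrichment pattern", {
  # ER-positive / ER-negative counts by EDI group in a validation cohort:
  # low 353/99, high 40/22
  tab <- matrix(c(353, 99, 40, 22), nrow = 2,
                dimnames = list(er = c("pos", "neg"), edi = c("low", "high")))
  p <- stats::fisher.test(tab)$p.value
  expect_equal(p, fisher_enum_p(353, 99, 40, 22), tolerance = 1e-9)
  expect_lt(p, 0.05)
  # the high group is depleted of ER-positive tumors (odds ratio > 1 for
  # ER-neg given high)
  expect_gt((22 / 40) / (99 / 353), 1)
})

test_that("q-values control the null and rank a planted signal first", {
  withr::with_seed(92, {
    p_null <- runif(2000)
    q <- qvalues(p_null)
    expect_true(all(q >= 0 & q <= 1))
    expect_lte(mean(q < 0.05), 0.02)
    # q-values are monotone in p
    o <- order(p_null)
    expect_true(all(diff(q[o]) >= -1e-12))
  })

  scores <- rep(1:5, each = 20)
  expr <- withr::with_seed(93, matrix(rnorm(100 * 100), nrow = 100))
  expr[1, ] <- -scores + withr::with_seed(94, rnorm(100, 0, 0.01))
  expr[2, ] <- scores             # exact linear gene
  rownames(expr) <- sprintf("g%03d", 1:100)
  res <- expression_correlation(expr, scores)
  expect_equal(res$r[res$gene == "g002"], 1, tolerance = 1e-12)
  expect_equal(res$r[res$gene == "g001"], -1, tolerance = 1e-3)
  # the planted genes share the minimum q (the exact gene ties at p = 0)
  expect_equal(res$q[res$gene == "g001"], min(res$q))

  # constant genes are excluded with a count
  expr[3, ] <- 7
  res2 <- expression_correlation(expr, scores)
  expect_equal(attr(res2, "n_excluded"), 1L)
  expect_error(expression_correlation(expr[, 1:2], scores[1:2]),
               class = "ecodiv_parameter_error")
})

test_that("genomic instability is the aberrant fraction of the genome", {
  segs <- data.frame(length = c(50, 30, 20), aberrant = c(FALSE, FALSE, FALSE))
  expect_equal(genomic_instability(segs), 0)
  segs$aberrant <- TRUE
  expect_equal(genomic_instability(segs), 1)
  segs$aberrant <- c(TRUE, FALSE, TRUE)
  expect_equal(genomic_instability(segs), 0.7)
  expect_error(genomic_instability(data.frame(length = -1, aberrant = TRUE)),
               class = "ecodiv_domain_error")
})
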