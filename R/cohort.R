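# Cohort-level analyses downstream of the index: survival stratification,
# the combined EDI + TP53 grouping, copy-number enrichment and an
# expression-correlation screen with tail-area FDR control.

#' Kaplan-Meier curves and log-rank test between groups
#'
#' Product-limit survival estimates per group and the log-rank chi-square
#' test of differences among groups. Empty groups are dropped with a
#' warning; at least two non-empty groups must remain. With no events in
#' any group the test is undefined and the p-value is NA (flagged).
#'
#' @param times survival times in months (already administratively capped;
#'   see [validate_cohort()]).
#' @param events 0/1 event indicators.
#' @param groups group labels.
#' @return List of class `"km_logrank"`: `fit` (a [survival::survfit()]
#'   object), `p` (log-rank p), `chisq`, `n_groups`.
#' @export
km_logrank <- function(times, events, groups) {
  groups <- factor(groups)
  keep_levels <- levels(groups)[table(groups) > 0L]
  if (length(keep_levels) < length(levels(groups)))
    warning("dropping empty group(s): ",
            paste(setdiff(levels(groups), keep_levels), collapse = ", "))
  groups <- factor(as.character(groups), levels = keep_levels)
  if (nlevels(groups) < 2)
    stop_ecodiv("need at least 2 non-empty groups", "ecodiv_parameter_error")
  df <- data.frame(time = times, event = events, group = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  if (sum(events) == 0) {
    warning("no events in any group: log-rank test undefined")
    return(structure(list(fit = fit, p = NA_real_, chisq = NA_real_,
                          n_groups = nlevels(groups)), class = "km_logrank"))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- stats::pchisq(sd$chisq, df = nlevels(groups) - 1, lower.tail = FALSE)
  structure(list(fit = fit, p = p, chisq = sd$chisq,
                 n_groups = nlevels(groups)), class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("Log-rank test over %d groups: chisq = %.3f, p = %.4g\n",
              x$n_groups, x$chisq, x$p))
  invisible(x)
}

#' Cox proportional-hazards fit over cohort covariates
#'
#' Partial-likelihood estimation (Efron tie handling) of hazard ratios for
#' one covariate (univariate) or several (multivariate), with 95%
#' confidence intervals and Wald p-values. Rank-deficient designs
#' (e.g. duplicated covariates) are flagged as an error.
#'
#' @param cohort a validated cohort data.frame ([validate_cohort()]) with
#'   `survival_months` and `event` columns.
#' @param covariates character vector of covariate column names.
#' @return A data.frame (one row per coefficient): `term`, `hr`, `lower`,
#'   `upper`, `p`, with the `coxph` fit attached as attribute `"fit"`.
#' @export
cox_fit <- function(cohort, covariates) {
  stopifnot(length(covariates) >= 1L, all(covariates %in% names(cohort)))
  if (sum(cohort$event) == 0)
    stop_ecodiv("no events in cohort", "ecodiv_validation_error")
  fml <- stats::as.formula(paste(
    "survival::Surv(survival_months, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = cohort, ties = "efron")
  if (any(is.na(stats::coef(fit))))
    stop_ecodiv("rank-deficient design: aliased covariate(s)",
                "ecodiv_fit_error")
  s <- summary(fit)
  out <- data.frame(term = rownames(s$coefficients),
                    hr = s$conf.int[, "exp(coef)"],
                    lower = s$conf.int[, "lower .95"],
                    upper = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}

#' Combined EDI + TP53 three-group stratification
#'
#' Tumors with low EDI and wild-type TP53 are `favorable`; high EDI (score
#' 5) with mutant TP53 are `adverse`; all others `intermediate`. The
#' ordinal coding 0/1/2 (column `edi_tp53`) enters Cox models as a single
#' covariate. Rows with missing TP53 are excluded (count reported via a
#' message).
#'
#' @param cohort data.frame with `edi_score` (or `edi_group`) and `tp53`.
#' @return The cohort with `edi_group`, `combined_group` (factor
#'   favorable < intermediate < adverse) and numeric `edi_tp53` columns.
#' @export
combine_edi_tp53 <- function(cohort) {
  if (!"edi_group" %in% names(cohort)) {
    stopifnot("edi_score" %in% names(cohort))
    cohort$edi_group <- dichotomize_edi(cohort$edi_score)
  }
  stopifnot("tp53" %in% names(cohort))
  miss <- is.na(cohort$tp53)
  if (any(miss)) {
    message(sum(miss), " row(s) excluded for missing TP53 status")
    cohort <- cohort[!miss, , drop = FALSE]
  }
  high <- cohort$edi_group == "high"
  mut <- cohort$tp53 == "MUT"
  grp <- ifelse(high & mut, "adverse",
                ifelse(!high & !mut, "favorable", "intermediate"))
  cohort$combined_group <- factor(grp, levels = c("favorable", "intermediate",
                                                  "adverse"))
  cohort$edi_tp53 <- as.numeric(cohort$combined_group) - 1
  cohort
}

#' Copy-number enrichment in the EDI-high group
#'
#' For every gene and each direction (gain: call > 0; loss: call < 0),
#' tests the 2x2 table of group (low/high) by aberration (present/absent)
#' with the two-sided Fisher exact test (sum of tables with probability at
#' most that observed), and reports Benjamini-Hochberg adjusted p-values
#' per direction alongside the raw p. Genes with no variation in a
#' direction get p = 1 and are flagged.
#'
#' @param cna integer matrix of calls in `{-2,-1,0,1,2}`, genes x samples.
#' @param groups labels aligned with the matrix columns, levels low/high.
#' @return A data.frame: `gene`, `direction`, the 2x2 counts
#'   `high_ab`, `high_no`, `low_ab`, `low_no`, `odds_ratio`, `p`, `p_adj`,
#'   `degenerate` flag.
#' @export
fisher_enrichment <- function(cna, groups) {
  stopifnot(is.matrix(cna), ncol(cna) == length(groups))
  if (!all(cna %in% -2:2))
    stop_ecodiv("copy-number calls must be in {-2,...,2}", "ecodiv_domain_error")
  groups <- as.character(groups)
  if (!all(groups %in% c("low", "high")))
    stop_ecodiv("groups must be 'low'/'high'", "ecodiv_domain_error")
  hi <- groups == "high"
  genes <- if (is.null(rownames(cna))) sprintf("gene%04d", seq_len(nrow(cna)))
           else rownames(cna)
  res <- list()
  for (dir in c("gain", "loss")) {
    ab <- if (dir == "gain") cna > 0 else cna < 0
    a <- rowSums(ab[, hi, drop = FALSE]);  b <- sum(hi) - a
    c_ <- rowSums(ab[, !hi, drop = FALSE]); d_ <- sum(!hi) - c_
    p <- numeric(nrow(cna)); or <- numeric(nrow(cna)); degen <- logical(nrow(cna))
    for (g in seq_len(nrow(cna))) {
      tab <- matrix(c(a[g], b[g], c_[g], d_[g]), 2)
      if (a[g] + c_[g] == 0 || b[g] + d_[g] == 0) {  # no variation
        p[g] <- 1; or[g] <- NA_real_; degen[g] <- TRUE
      } else {
        ft <- stats::fisher.test(tab)
        p[g] <- ft$p.value; or[g] <- unname(ft$estimate)
      }
    }
    res[[dir]] <- data.frame(gene = genes, direction = dir,
                             high_ab = a, high_no = b,
                             low_ab = c_, low_no = d_,
                             odds_ratio = or, p = p,
                             p_adj = stats::p.adjust(p, "BH"),
                             degenerate = degen,
                             row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- rbind(res$gain, res$loss)
  rownames(out) <- NULL
  out
}

#' Storey-type q-values (tail-area false discovery rate)
#'
#' Estimates the null proportion pi0 by the smoother method -- `pi0(lambda)
#' = mean(p > lambda) / (1 - lambda)` over a lambda grid 0.05..0.95,
#' smoothed with a cubic spline and evaluated at the largest lambda -- and
#' converts p-values to monotone q-values `q_(i) = min_{j>=i} pi0 * n *
#' p_(j) / j`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param lambda grid for the pi0 smoother.
#' @return q-values in the original order, with `pi0` as an attribute.
#' @export
qvalues <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_ecodiv("p-values must lie in [0, 1]", "ecodiv_domain_error")
  n <- length(p)
  pi0 <- if (n >= 100) {
    pl <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    sp <- stats::smooth.spline(lambda, pl, df = 3)
    max(min(stats::predict(sp, max(lambda))$y, 1), 0)
  } else 1
  if (pi0 <= 0) pi0 <- 1 / n  # degenerate: all p tiny
  o <- order(p)
  q <- pi0 * n * p[o] / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n); out[o] <- q
  attr(out, "pi0") <- pi0
  out
}

#' Expression-correlation screen against EDI scores
#'
#' Per-gene Pearson correlation of expression with the integer EDI score,
#' t-test p-values, and Storey-type tail-area q-values. Constant genes are
#' excluded and counted.
#'
#' @param expr numeric matrix, genes x samples.
#' @param edi_scores integer scores aligned with the columns.
#' @return A data.frame `gene`, `r`, `p`, `q`, with attribute
#'   `"n_excluded"` (constant genes).
#' @export
expression_correlation <- function(expr, edi_scores) {
  stopifnot(is.matrix(expr), ncol(expr) == length(edi_scores))
  n <- ncol(expr)
  if (n < 3) stop_ecodiv("need at least 3 samples", "ecodiv_parameter_error")
  if (stats::sd(edi_scores) == 0)
    stop_ecodiv("EDI scores are constant across samples", "ecodiv_domain_error")
  v <- apply(expr, 1L, stats::sd)
  keep <- v > 0
  genes <- if (is.null(rownames(expr))) sprintf("gene%04d", seq_len(nrow(expr)))
           else rownames(expr)
  expr <- expr[keep, , drop = FALSE]
  r <- as.numeric(stats::cor(t(expr), edi_scores))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  q <- qvalues(p)
  out <- data.frame(gene = genes[keep], r = r, p = p, q = as.numeric(q),
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!keep)
  attr(out, "pi0") <- attr(q, "pi0")
  out
}

#' Genomic instability fraction
#'
#' The proportion of the genome called aberrant: total aberrant segment
#' length divided by total segment length.
#'
#' @param segments data.frame with columns `length` (> = 0) and `aberrant`
#'   (logical or 0/1).
#' @return Fraction in `[0, 1]`.
#' @export
genomic_instability <- function(segments) {
  stopifnot(is.data.frame(segments),
            all(c("length", "aberrant") %in% names(segments)))
  if (any(segments$length < 0))
    stop_ecodiv("segment lengths must be non-negative", "ecodiv_domain_error")
  total <- sum(segments$length)
  if (total <= 0)
    stop_ecodiv("total genome length must be positive", "ecodiv_domain_error")
  sum(segments$length[as.logical(segments$aberrant)]) / total
}
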