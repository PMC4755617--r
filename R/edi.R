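#' Control parameters for EDI fitting
#'
#' Collects the tuning parameters of the mixture fit and selection in one
#' place. Defaults follow the method's standard operating point: 200 um
#' regions, at least 10 cells per region, K searched over 1-5.
#'
#' @param k_max largest number of mixture components considered (default 5).
#' @param n_restarts EM restarts per K (default 10).
#' @param max_iter maximum EM iterations (default 500).
#' @param tol EM log-likelihood tolerance (default 1e-8).
#' @param variance_floor component variance floor in nats^2 (default 1e-4).
#' @param min_regions minimum retained regions required to score a tumor
#'   (default 5).
#' @return A list of class `"edi_control"`.
#' @export
edi_control <- function(k_max = 5, n_restarts = 10, max_iter = 500,
                        tol = 1e-8, variance_floor = 1e-4, min_regions = 5) {
  stopifnot(k_max >= 1, n_restarts >= 1, max_iter >= 1, tol > 0,
            variance_floor > 0, min_regions >= 1)
  structure(list(k_max = as.integer(k_max), n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), tol = tol,
                 variance_floor = variance_floor,
                 min_regions = as.integer(min_regions)),
            class = "edi_control")
}

#' Select the number of diversity clusters by BIC
#'
#' Fits mixtures with `K = 1, ..., k_max` components to the regional
#' Shannon scores and picks the `K` minimizing the BIC; ties go to the
#' smaller `K`. Values of `K` exceeding the number of regions are skipped.
#' The selected `K` is the tumor's ecosystem diversity index.
#'
#' @param d numeric vector of regional Shannon scores or a
#'   `"diversity_profile"`.
#' @param control an [edi_control()] list.
#' @param seed optional integer seed for the EM restarts.
#' @return A list: `edi` (selected K), `bic_table` (data.frame K/BIC/
#'   loglik/converged), `fits` (all `"gmm1"` fits), `best_fit`.
#' @export
select_k <- function(d, control = edi_control(), seed = NULL) {
  if (inherits(d, "diversity_profile")) d <- d$d
  d <- as.numeric(d)
  if (length(d) == 0L)
    stop_ecodiv("empty diversity profile", "ecodiv_empty_profile_error")
  ks <- seq_len(control$k_max)
  ks <- ks[ks <= length(d)]
  fits <- lapply(ks, function(k)
    fit_gmm(d, k, n_restarts = control$n_restarts,
            max_iter = control$max_iter, tol = control$tol,
            variance_floor = control$variance_floor,
            seed = if (is.null(seed)) NULL else seed + k))
  bic <- vapply(fits, bic_gmm, numeric(1))
  tab <- data.frame(K = ks, bic = bic,
                    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
                    converged = vapply(fits, function(f) f$converged, logical(1)))
  best <- which.min(bic)   # first minimum = smallest K on ties
  list(edi = ks[best], bic_table = tab, fits = fits, best_fit = fits[[best]])
}

#' Ecosystem diversity index of a tumor
#'
#' End-to-end scoring of microenvironmental spatial heterogeneity from
#' classified cell positions. Each section is tiled into square regions of
#' side `region_size`; regions with at least `min_cells` cells are scored
#' with the Shannon index over cancer / lymphocyte / stromal proportions;
#' regions from all sections are pooled into one score vector `D`; Gaussian
#' mixtures with `K = 1..k_max` components are fitted to `D` and the
#' BIC-selected `K` is the EDI score. A score of 1 means the local
#' diversity is spatially homogeneous; 5 means five distinct diversity
#' levels coexist, the most heterogeneous class.
#'
#' @param x a [cell_map()], a list of cell maps (sections of one tumor), or
#'   a precomputed `"diversity_profile"`.
#' @param region_size square region side in micrometres (default 200).
#' @param min_cells minimum cells per scored region (default 10).
#' @param control an [edi_control()] list.
#' @param seed optional integer seed (EM restarts).
#' @param ... ignored.
#' @return An object of class `"edi"`: `edi` (integer score), `bic_table`,
#'   `best_fit`, all per-K `fits`, the `profile`, `region_labels` (MAP
#'   cluster per retained region, factor `k1 < k2 < ...` ordered by
#'   ascending cluster mean diversity), `qq_correlation` (goodness-of-fit,
#'   see [qq_diagnostic()]), and the effective `config`.
#' @examples
#' spec <- synthetic_tumor_spec(2, regions_per_level = 20,
#'                              cells_per_region = 60)
#' cm <- simulate_cellmap(spec, seed = 7)
#' fit <- edi(cm, seed = 7)
#' fit$edi
#' @export
edi <- function(x, region_size = 200, min_cells = 10,
                control = edi_control(), seed = NULL, ...) {
  profile <- if (inherits(x, "diversity_profile")) x else {
    maps <- if (inherits(x, "cell_map")) list(x) else x
    stopifnot(length(maps) >= 1L, all(vapply(maps, inherits, TRUE, "cell_map")))
    grids <- lapply(maps, tile_regions, region_size = region_size)
    regional_diversity(grids, min_cells = min_cells)
  }
  if (profile$n < control$min_regions)
    stop_ecodiv(sprintf("only %d retained regions; at least %d required",
                        profile$n, control$min_regions),
                "ecodiv_insufficient_data_error")
  sel <- select_k(profile, control = control, seed = seed)
  labels <- factor(paste0("k", map_labels(profile$d, sel$best_fit)),
                   levels = paste0("k", seq_len(sel$best_fit$k)))
  qq <- tryCatch(qq_diagnostic(sel$best_fit, profile),
                 error = function(e) NA_real_)
  structure(list(edi = sel$edi, bic_table = sel$bic_table,
                 best_fit = sel$best_fit, fits = sel$fits,
                 profile = profile, region_labels = labels,
                 qq_correlation = qq,
                 config = list(region_size = profile$region_size,
                               min_cells = profile$min_cells,
                               control = control, seed = seed),
                 tumor_id = profile$tumor_id),
            class = "edi")
}

#' Mixture goodness-of-fit by quantile-quantile correlation
#'
#' Pearson correlation between the sorted regional scores and the fitted
#' mixture's theoretical quantiles at plotting positions `(i - 0.5) / n`
#' (quantiles by monotone numerical inversion of the mixture CDF). Values
#' near 1 indicate the selected mixture describes the score distribution
#' well.
#'
#' @param fit a `"gmm1"` mixture fit.
#' @param d score vector or `"diversity_profile"` the fit describes.
#' @return Correlation in `[-1, 1]`, or `NA` (with a warning) when the
#'   scores are constant.
#' @export
qq_diagnostic <- function(fit, d) {
  if (inherits(d, "diversity_profile")) d <- d$d
  d <- as.numeric(d)
  n <- length(d)
  if (n < 3)
    stop_ecodiv("Q-Q diagnostic needs at least 3 regions", "ecodiv_domain_error")
  if (stats::sd(d) == 0) {
    warning("constant diversity scores: Q-Q correlation undefined")
    return(NA_real_)
  }
  theo <- qgmm1((seq_len(n) - 0.5) / n, fit)
  stats::cor(sort(d), theo)
}

# ---- methods -------------------------------------------------------------

#' @export
print.edi <- function(x, ...) {
  cat(sprintf("Ecosystem diversity index for '%s': EDI = %d (%s)\n",
              x$tumor_id, x$edi,
              if (x$edi >= 5) "EDI-high" else "EDI-low"))
  cat(sprintf("  %d regions scored (%d excluded), region size %s um\n",
              x$profile$n, x$profile$excluded_regions,
              format(x$config$region_size)))
  invisible(x)
}

#' @export
summary.edi <- function(object, ...) {
  structure(list(edi = object$edi, tumor_id = object$tumor_id,
                 bic_table = object$bic_table,
                 coef = coef(object),
                 cluster_sizes = table(object$region_labels),
                 qq_correlation = object$qq_correlation,
                 n = object$profile$n,
                 excluded = object$profile$excluded_regions,
                 config = object$config),
            class = "summary.edi")
}

#' @export
print.summary.edi <- function(x, digits = 4, ...) {
  cat(sprintf("EDI = %d for '%s' (%d regions, %d excluded)\n",
              x$edi, x$tumor_id, x$n, x$excluded))
  cat("\nBIC over K:\n")
  print(transform(x$bic_table, bic = round(bic, 2), loglik = round(loglik, 2)),
        row.names = FALSE)
  cat("\nSelected mixture (clusters ordered by mean diversity):\n")
  print(round(x$coef, digits))
  cat("\nRegions per cluster:\n"); print(x$cluster_sizes)
  cat(sprintf("\nQ-Q correlation: %.4f\n", x$qq_correlation))
  invisible(x)
}

#' @export
coef.edi <- function(object, ...) {
  m <- coef(object$best_fit)
  rownames(m) <- paste0("k", seq_len(nrow(m)))
  m
}

#' @export
logLik.edi <- function(object, ...) logLik(object$best_fit)

#' Predict cluster membership for diversity scores
#'
#' Maps scores to the maximum-a-posteriori component of the selected
#' mixture; clusters are labelled `k1..kK` in order of ascending mean
#' diversity.
#'
#' @param object an `"edi"` fit.
#' @param newdata numeric scores; defaults to the fitted regional scores.
#' @param ... ignored.
#' @return Factor of cluster labels.
#' @export
predict.edi <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$profile$d else as.numeric(newdata)
  factor(paste0("k", map_labels(d, object$best_fit)),
         levels = paste0("k", seq_len(object$best_fit$k)))
}

#' @export
simulate.edi <- function(object, nsim = 1, seed = NULL, ...) {
  n <- object$profile$n
  with_seed(seed, as.data.frame(replicate(nsim, rgmm1(n, object$best_fit))))
}

#' Randomized quantile residuals of an EDI mixture fit
#'
#' `qnorm(F(d_j))` under the fitted mixture CDF; approximately standard
#' normal when the mixture describes the scores well.
#'
#' @param object an `"edi"` fit.
#' @param ... ignored.
#' @return Numeric residual vector, one per retained region.
#' @export
residuals.edi <- function(object, ...) {
  u <- pgmm1(object$profile$d, object$best_fit)
  eps <- 1 / (2 * length(u))
  stats::qnorm(pmin(pmax(u, eps), 1 - eps))
}

#' Plot an EDI fit
#'
#' Histogram of the regional Shannon scores with the fitted mixture density
#' and its components overlaid, annotated with the selected K.
#'
#' @param x an `"edi"` fit.
#' @param breaks histogram breaks (see [graphics::hist()]).
#' @param ... further arguments passed to [graphics::hist()].
#' @export
plot.edi <- function(x, breaks = 30, ...) {
  d <- x$profile$d
  h <- graphics::hist(d, breaks = breaks, freq = FALSE,
                      main = sprintf("%s: EDI = %d", x$tumor_id, x$edi),
                      xlab = "Regional Shannon diversity (nats)",
                      col = "grey90", border = "grey70", ...)
  xs <- seq(min(d) - 0.05, max(d) + 0.05, length.out = 400)
  for (j in seq_len(x$best_fit$k))
    graphics::lines(xs, x$best_fit$weight[j] *
                      stats::dnorm(xs, x$best_fit$mean[j],
                                   sqrt(x$best_fit$variance[j])),
                    col = "steelblue", lwd = 1)
  graphics::lines(xs, dgmm1(xs, x$best_fit), lwd = 2)
  invisible(h)
}

#' Dichotomize EDI scores into low/high groups
#'
#' Tumors with the maximal score of 5 form the EDI-high group; scores 1-4
#' are EDI-low.
#'
#' @param scores integer EDI scores in 1-5.
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize_edi <- function(scores) {
  scores <- as.integer(scores)
  if (any(is.na(scores)) || any(scores < 1L | scores > 5L))
    stop_ecodiv("EDI scores must be integers in 1..5", "ecodiv_domain_error")
  factor(ifelse(scores == 5L, "high", "low"), levels = c("low", "high"))
}
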