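# Univariate Gaussian mixture machinery. This is the statistical core of the
# index: regional Shannon scores D = d_1..d_n are fitted with K-component
# mixtures (unequal variances) by EM, and K is chosen by BIC.

mixture_loglik <- function(d, weight, mean, variance) {
  k <- length(weight)
  lp <- vapply(seq_len(k), function(j)
    stats::dnorm(d, mean[j], sqrt(variance[j]), log = TRUE) + log(weight[j]),
    numeric(length(d)))
  lp <- matrix(lp, nrow = length(d))
  mx <- apply(lp, 1L, max)
  list(loglik = sum(mx + log(rowSums(exp(lp - mx)))),
       logpost = lp - mx)    # unnormalized log responsibilities
}

# EM inner loop lives in compiled code (src/em.cpp); NULL means the start
# degenerated (a component lost all responsibility mass) and is discarded.
em_run <- function(d, k, mu, v, w, max_iter, tol, variance_floor) {
  out <- .em_run_cpp(as.numeric(d), as.numeric(mu), as.numeric(v),
                     as.numeric(w), as.integer(max_iter), tol, variance_floor)
  out
}

#' Fit a univariate Gaussian mixture to regional diversity scores
#'
#' Maximum-likelihood fit of a `k`-component normal mixture with unequal
#' component variances, by expectation-maximization with multiple restarts.
#' The first start places component means at evenly spaced sample quantiles
#' with equal weights; the remaining starts draw means uniformly from the
#' data range. The best restart by log-likelihood is returned. `k = 1` is
#' solved in closed form. Component variances are floored at
#' `variance_floor` to keep the likelihood bounded when scores coincide.
#'
#' @param d numeric vector of regional Shannon scores, or a
#'   `"diversity_profile"` from [regional_diversity()].
#' @param k number of mixture components (>= 1; requires `length(d) >= k`).
#' @param n_restarts number of EM starts (default 10).
#' @param max_iter maximum EM iterations per start (default 500).
#' @param tol absolute log-likelihood convergence tolerance (default 1e-8).
#' @param variance_floor lower bound on component variances, in nats^2
#'   (default 1e-4, i.e. a standard deviation of 0.01 nats, the
#'   resolution of Shannon scores computed from a few hundred cells; a
#'   smaller floor lets a component collapse onto tied scores in
#'   bootstrap resamples and spuriously inflate the selected K).
#' @param seed optional seed making the random restarts reproducible.
#' @return An object of class `"gmm1"`: `k`, `weight`, `mean`, `variance`
#'   (components sorted by ascending mean), `loglik`, `n_params` (`3k - 1`),
#'   `converged`, `n_iter`, `n`.
#' @examples
#' set.seed(1)
#' d <- c(rnorm(100, 0.3, 0.05), rnorm(100, 1.0, 0.05))
#' fit_gmm(d, 2, seed = 1)
#' @export
fit_gmm <- function(d, k, n_restarts = 10, max_iter = 500, tol = 1e-8,
                    variance_floor = 1e-4, seed = NULL) {
  if (inherits(d, "diversity_profile")) d <- d$d
  d <- as.numeric(d)
  n <- length(d)
  if (k < 1) stop_ecodiv("k must be >= 1", "ecodiv_parameter_error")
  if (n < k)
    stop_ecodiv(sprintf("cannot fit %d components to %d points", k, n),
                "ecodiv_infeasible_fit_error")
  out <- if (k == 1L) {
    v <- max(mean((d - mean(d))^2), variance_floor)
    list(weight = 1, mean = mean(d), variance = v,
         loglik = sum(stats::dnorm(d, mean(d), sqrt(v), log = TRUE)),
         converged = TRUE, n_iter = 0L)
  } else with_seed(seed, {
    vml <- max(mean((d - mean(d))^2), variance_floor)
    best <- NULL
    for (s in seq_len(max(1L, n_restarts))) {
      mu0 <- if (s == 1L)
        as.numeric(stats::quantile(d, (2 * seq_len(k) - 1) / (2 * k), names = FALSE))
      else stats::runif(k, min(d), max(d))
      fit <- em_run(d, k, mu0, rep(vml, k), rep(1 / k, k),
                    max_iter, tol, variance_floor)
      if (is.null(fit)) next
      if (is.null(best) || fit$loglik > best$loglik ||
          (fit$converged && !best$converged && fit$loglik >= best$loglik - tol))
        best <- fit
    }
    if (is.null(best))  # every start degenerated: fall back to a tied start
      best <- em_run(d, k, rep(mean(d), k), rep(vml, k), rep(1 / k, k),
                     1L, Inf, variance_floor)
    best
  })
  ord <- order(out$mean)
  structure(list(k = as.integer(k), weight = out$weight[ord],
                 mean = out$mean[ord], variance = out$variance[ord],
                 loglik = out$loglik, n_params = 3L * k - 1L,
                 converged = out$converged, n_iter = out$n_iter,
                 n = n, variance_floor = variance_floor, seed = seed),
            class = "gmm1")
}

#' @export
print.gmm1 <- function(x, digits = 4, ...) {
  cat(sprintf("Gaussian mixture, K = %d (n = %d, logLik = %.3f%s)\n",
              x$k, x$n, x$loglik, if (x$converged) "" else ", NOT converged"))
  print(round(rbind(weight = x$weight, mean = x$mean,
                    sd = sqrt(x$variance)), digits))
  invisible(x)
}

#' @export
logLik.gmm1 <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' @export
coef.gmm1 <- function(object, ...) {
  cbind(weight = object$weight, mean = object$mean,
        variance = object$variance)
}

#' Bayesian information criterion of a mixture fit
#'
#' `BIC = -2 logLik + (3K - 1) log(n)`; a `K`-component univariate mixture
#' has `3K - 1` free parameters (`K` means, `K` variances, `K - 1` free
#' weights). Lower is better; the index minimizes this over `K`.
#'
#' @param fit a `"gmm1"` object from [fit_gmm()].
#' @param n number of observations (defaults to the fit's sample size).
#' @return The BIC value.
#' @export
bic_gmm <- function(fit, n = fit$n) {
  if (!is.numeric(n) || n <= 0)
    stop_ecodiv("n must be positive", "ecodiv_domain_error")
  -2 * fit$loglik + fit$n_params * log(n)
}

# mixture density / cdf / quantile / random deviates -----------------------

dgmm1 <- function(x, fit) {
  rowSums(vapply(seq_len(fit$k), function(j)
    fit$weight[j] * stats::dnorm(x, fit$mean[j], sqrt(fit$variance[j])),
    numeric(length(x))))
}

pgmm1 <- function(q, fit) {
  rowSums(matrix(vapply(seq_len(fit$k), function(j)
    fit$weight[j] * stats::pnorm(q, fit$mean[j], sqrt(fit$variance[j])),
    numeric(length(q))), nrow = length(q)))
}

# monotone numerical inversion of the mixture CDF
qgmm1 <- function(p, fit) {
  sd <- sqrt(fit$variance)
  lo <- min(fit$mean - 10 * sd); hi <- max(fit$mean + 10 * sd)
  vapply(p, function(pi) {
    if (pi <= 0) return(lo); if (pi >= 1) return(hi)
    stats::uniroot(function(x) pgmm1(x, fit) - pi, c(lo, hi),
                   extendInt = "upX", tol = 1e-10)$root
  }, numeric(1))
}

rgmm1 <- function(n, fit) {
  comp <- sample.int(fit$k, n, replace = TRUE, prob = fit$weight)
  stats::rnorm(n, fit$mean[comp], sqrt(fit$variance[comp]))
}

# MAP component responsibility labels, components already sorted by mean
map_labels <- function(d, fit) {
  lp <- vapply(seq_len(fit$k), function(j)
    stats::dnorm(d, fit$mean[j], sqrt(fit$variance[j]), log = TRUE) +
      log(fit$weight[j]), numeric(length(d)))
  lp <- matrix(lp, nrow = length(d))
  max.col(lp, ties.method = "first")
}
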