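# Scale-selection and resampling-stability diagnostics. Spatial
# heterogeneity is scale dependent: these routines quantify how the index
# behaves as the region size varies and how stable the EDI subtype is when
# tumor regions are progressively removed.

#' Scan region sizes for one or more tumors
#'
#' Re-tiles, re-scores and re-selects K at each candidate region size and
#' collects descriptive statistics: mean cells per region, regions per
#' tumor, the EDI score, and optionally the bootstrap clustering
#' instability of each profile.
#'
#' @param x a [cell_map()], list of cell maps (one tumor, several
#'   sections), or a named list of such (a cohort of tumors).
#' @param sizes region sizes in micrometres (default
#'   `c(166, 200, 250, 333, 500)`).
#' @param min_cells,control as in [edi()].
#' @param n_boot bootstrap replicates for the instability estimate
#'   (0 = skip, the default).
#' @param seed integer seed.
#' @return A data.frame of class `"scale_scan"`: `tumor`, `region_size`,
#'   `n_regions`, `mean_cells_per_region`, `edi`, `instability` (NA when
#'   not computed or infeasible). Sizes at which a tumor has fewer than
#'   `min_regions` retained regions are reported with NA scores rather
#'   than failing.
#' @export
scale_scan <- function(x, sizes = c(166, 200, 250, 333, 500),
                       min_cells = 10, control = edi_control(),
                       n_boot = 0, seed = NULL) {
  if (any(sizes <= 0))
    stop_ecodiv("region sizes must be positive", "ecodiv_parameter_error")
  cohort <- if (inherits(x, "cell_map")) list(tumor = list(x))
  else if (all(vapply(x, inherits, TRUE, "cell_map"))) list(tumor = x)
  else x
  if (is.null(names(cohort))) names(cohort) <- paste0("tumor", seq_along(cohort))
  rows <- list()
  for (ti in seq_along(cohort)) {
    maps <- cohort[[ti]]
    if (inherits(maps, "cell_map")) maps <- list(maps)
    for (si in seq_along(sizes)) {
      r <- sizes[si]
      res <- tryCatch({
        grids <- lapply(maps, tile_regions, region_size = r)
        prof <- regional_diversity(grids, min_cells = min_cells)
        if (prof$n < control$min_regions)
          stop_ecodiv("too few regions", "ecodiv_insufficient_data_error")
        fit <- edi(prof, control = control,
                   seed = if (is.null(seed)) NULL else seed + 1000L * ti + si)
        inst <- if (n_boot > 0)
          clustering_instability(prof, n_boot = n_boot, control = control,
                                 seed = if (is.null(seed)) NULL
                                        else seed + 1000L * ti + si)
        else NA_real_
        data.frame(tumor = names(cohort)[ti], region_size = r,
                   n_regions = prof$n,
                   mean_cells_per_region = mean(rowSums(prof$counts)),
                   edi = fit$edi, instability = inst,
                   stringsAsFactors = FALSE)
      }, ecodiv_error = function(e)
        data.frame(tumor = names(cohort)[ti], region_size = r,
                   n_regions = NA_integer_, mean_cells_per_region = NA_real_,
                   edi = NA_integer_, instability = NA_real_,
                   stringsAsFactors = FALSE))
      rows[[length(rows) + 1L]] <- res
    }
  }
  structure(do.call(rbind, rows), class = c("scale_scan", "data.frame"))
}

#' Bootstrap clustering instability of a diversity profile
#'
#' Resamples the retained regions with replacement, re-selects K on each
#' replicate, and returns the standard deviation of the selected K -- a
#' small value means the cluster count is insensitive to which regions
#' were observed.
#'
#' @param d a `"diversity_profile"` or numeric score vector.
#' @param n_boot bootstrap replicates (>= 2).
#' @param control an [edi_control()].
#' @param seed integer seed.
#' @return Standard deviation of the selected K across replicates, with
#'   the replicate K values as attribute `"k_values"`.
#' @export
clustering_instability <- function(d, n_boot = 50, control = edi_control(),
                                   seed = NULL) {
  if (inherits(d, "diversity_profile")) d <- d$d
  d <- as.numeric(d)
  if (n_boot < 2) stop_ecodiv("n_boot must be >= 2", "ecodiv_parameter_error")
  if (length(d) < 1)
    stop_ecodiv("profile too small for instability", "ecodiv_empty_profile_error")
  ks <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    db <- sample(d, length(d), replace = TRUE)
    select_k(db, control = control)$edi
  }, integer(1)))
  structure(stats::sd(ks), k_values = ks)
}

#' Cross-scale correlation of EDI scores
#'
#' Pearson correlation of the per-tumor EDI vectors between every pair of
#' region sizes in a [scale_scan()] over a cohort. Entries where a size
#' yields constant EDI across tumors (zero variance) are NA.
#'
#' @param scan a `"scale_scan"` over at least 3 tumors and 2 sizes.
#' @return Symmetric correlation matrix with unit diagonal, dimnames the
#'   region sizes.
#' @export
cross_scale_correlation <- function(scan) {
  stopifnot(inherits(scan, "scale_scan"))
  sizes <- sort(unique(scan$region_size))
  tumors <- unique(scan$tumor)
  if (length(sizes) < 2 || length(tumors) < 3)
    stop_ecodiv("need >= 2 sizes and >= 3 tumors", "ecodiv_parameter_error")
  m <- matrix(NA_real_, length(tumors), length(sizes),
              dimnames = list(tumors, as.character(sizes)))
  for (i in seq_len(nrow(scan)))
    m[scan$tumor[i], as.character(scan$region_size[i])] <- scan$edi[i]
  cc <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  diag(cc) <- 1
  cc
}

#' Region-subsampling stability of the EDI subtype
#'
#' For each fraction `f`, draws `n_repeats` random subsets of
#' `round(f * n)` retained regions without replacement (modelling loss of
#' tumor area), re-selects K on the subset, dichotomizes (EDI = 5 versus
#' < 5), and reports the proportion of repeats agreeing with the full-data
#' subtype. At `f = 1` the full region set is used, so agreement is
#' exactly 1.
#'
#' @param x cell map(s) of one tumor, or a `"diversity_profile"`.
#' @param fractions subsample fractions in `(0, 1]` (default
#'   `c(1, 0.95, 0.90, 0.85, 0.80)`).
#' @param n_repeats repeats per fraction (default 200).
#' @param region_size,min_cells,control as in [edi()].
#' @param seed integer seed.
#' @return A data.frame of class `"stability_result"`: `fraction`,
#'   `n_regions_used`, `agreement`, `n_repeats`. Fractions leaving fewer
#'   than `min_regions` regions are reported with NA agreement.
#' @export
region_subsample_stability <- function(x, fractions = c(1, 0.95, 0.9, 0.85, 0.8),
                                       n_repeats = 200, region_size = 200,
                                       min_cells = 10, control = edi_control(),
                                       seed = NULL) {
  if (any(fractions <= 0 | fractions > 1))
    stop_ecodiv("fractions must lie in (0, 1]", "ecodiv_parameter_error")
  prof <- if (inherits(x, "diversity_profile")) x else {
    maps <- if (inherits(x, "cell_map")) list(x) else x
    regional_diversity(lapply(maps, tile_regions, region_size = region_size),
                       min_cells = min_cells)
  }
  full <- edi(prof, control = control, seed = seed)
  full_high <- full$edi == 5L
  n <- prof$n
  rows <- with_seed(seed, lapply(fractions, function(f) {
    nf <- round(f * n)
    if (nf < control$min_regions)
      return(data.frame(fraction = f, n_regions_used = nf,
                        agreement = NA_real_, n_repeats = n_repeats))
    if (nf >= n)  # full data: identical profile, agreement exact
      return(data.frame(fraction = f, n_regions_used = n,
                        agreement = 1, n_repeats = n_repeats))
    agree <- vapply(seq_len(n_repeats), function(b) {
      idx <- sort(sample.int(n, nf))
      k <- select_k(prof$d[idx], control = control)$edi
      (k == 5L) == full_high
    }, logical(1))
    data.frame(fraction = f, n_regions_used = nf,
               agreement = mean(agree), n_repeats = n_repeats)
  }))
  out <- do.call(rbind, rows)
  attr(out, "full_edi") <- full$edi
  structure(out, class = c("stability_result", "data.frame"))
}
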