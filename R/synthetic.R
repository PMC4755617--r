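# Synthetic tumors, cohorts and genomic matrices with known ground truth.
# These generators define the study conditions under which the estimator is
# validated: rectangular habitat mosaics with habitat-specific cell-type
# compositions, exponential proportional-hazards survival, and binary
# aberration matrices with a planted enrichment block.

#' Specify a synthetic tumor as a habitat mosaic
#'
#' A tumor domain is partitioned into axis-aligned rectangular habitats;
#' each habitat has a cell-type composition (a probability vector over
#' cancer / lymphocyte / stromal) and a cell density. Cells are later
#' placed by a homogeneous Poisson process within each habitat
#' ([simulate_cellmap()]). The number of distinct habitat Shannon values is
#' the ground-truth number of regional diversity clusters.
#'
#' @param habitats list of habitats, each a list with fields `xmin`,
#'   `xmax`, `ymin`, `ymax` (micrometres), `composition` (3-vector summing
#'   to 1) and `density` (cells per square micrometre).
#' @param width,height domain extent in micrometres (defaults to the
#'   habitats' bounding box).
#' @return A list of class `"tumor_spec"` with the habitats, domain size
#'   and `expected_k` ([expected_edi()]).
#' @export
tumor_spec <- function(habitats, width = NULL, height = NULL) {
  stopifnot(length(habitats) >= 1L)
  for (h in habitats) {
    stopifnot(all(c("xmin", "xmax", "ymin", "ymax", "composition", "density")
                  %in% names(h)))
    if (h$xmax <= h$xmin || h$ymax <= h$ymin)
      stop_ecodiv("habitat has zero or negative area", "ecodiv_spec_error")
    if (h$density <= 0)
      stop_ecodiv("habitat density must be positive", "ecodiv_spec_error")
    check_proportions(h$composition)
  }
  if (is.null(width)) width <- max(vapply(habitats, `[[`, 0, "xmax"))
  if (is.null(height)) height <- max(vapply(habitats, `[[`, 0, "ymax"))
  spec <- structure(list(habitats = habitats, width = width, height = height),
                    class = "tumor_spec")
  spec$expected_k <- expected_edi(spec)
  spec
}

#' Convenience mosaic with a target number of diversity levels
#'
#' Builds a vertical-strip mosaic whose habitats realise `k` distinct
#' Shannon diversity levels, well separated in entropy (pairwise gaps of
#' at least 0.19 nats). Compositions are of the form
#' `(1 - 2a, a, a)`, sweeping `a` from 0 (pure cancer, entropy 0) to 1/3
#' (equal thirds, entropy log 3) -- mimicking the progression from
#' cancer-dominated regions to regions rich in lymphocytes and stroma.
#' Strip widths and the cell density are chosen so that, at the default
#' 200 um tiling, each level contributes `regions_per_level` regions with
#' about `cells_per_region` cells each.
#'
#' @param k target number of distinct diversity levels (1-5).
#' @param regions_per_level regions per diversity level at `region_size`
#'   tiling (default 60).
#' @param cells_per_region expected cells per region (default 150, typical
#'   of breast carcinoma H&E sections tiled at 200 um).
#' @param region_size reference tile side in micrometres (default 200).
#' @return A `"tumor_spec"` with `expected_k = k`.
#' @export
synthetic_tumor_spec <- function(k, regions_per_level = 60,
                                 cells_per_region = 150, region_size = 200) {
  stopifnot(k >= 1, k <= 5, regions_per_level >= 1, cells_per_region > 0)
  # minority fractions giving entropies 0, 0.334, 0.639, 0.903, 1.099 nats
  a_levels <- c(0, 0.04, 0.10, 0.18, 1 / 3)[seq_len(k)]
  nrow_grid <- max(1L, floor(sqrt(regions_per_level)))
  ncol_grid <- ceiling(regions_per_level / nrow_grid)
  height <- nrow_grid * region_size
  strip_w <- ncol_grid * region_size
  density <- cells_per_region / region_size^2
  habitats <- lapply(seq_len(k), function(i) {
    a <- a_levels[i]
    list(xmin = (i - 1) * strip_w, xmax = i * strip_w,
         ymin = 0, ymax = height,
         composition = c(1 - 2 * a, a, a), density = density)
  })
  tumor_spec(habitats, width = k * strip_w, height = height)
}

#' Ground-truth EDI of a synthetic tumor specification
#'
#' The number of distinct habitat Shannon values (within 1e-6 nats),
#' capped at 5. Habitats whose compositions are permutations of each other
#' have equal entropy and count once.
#'
#' @param spec a `"tumor_spec"`.
#' @return Integer in 1-5.
#' @export
expected_edi <- function(spec) {
  stopifnot(inherits(spec, "tumor_spec"))
  ent <- vapply(spec$habitats, function(h) shannon_index(h$composition),
                numeric(1))
  ent <- sort(ent)
  distinct <- 1L + sum(diff(ent) > 1e-6)
  min(distinct, 5L)
}

#' Simulate a cell map from a habitat mosaic
#'
#' Places cells by a homogeneous Poisson process within each habitat at its
#' density and draws each cell's class from the habitat composition.
#' Deterministic given the seed. An optional misclassification rate flips
#' each cell's label to a uniformly chosen other class, emulating imperfect
#' upstream image classification.
#'
#' @param spec a `"tumor_spec"`.
#' @param seed integer seed.
#' @param flip_rate per-cell label misclassification probability (default 0).
#' @param tumor_id identifier for the generated map.
#' @return A [cell_map()]; the spec's per-habitat Shannon values are
#'   attached as attribute `"habitat_shannon"`.
#' @export
simulate_cellmap <- function(spec, seed = NULL, flip_rate = 0,
                             tumor_id = "synthetic") {
  stopifnot(inherits(spec, "tumor_spec"), flip_rate >= 0, flip_rate < 1)
  with_seed(seed, {
    parts <- lapply(spec$habitats, function(h) {
      area <- (h$xmax - h$xmin) * (h$ymax - h$ymin)
      nc <- stats::rpois(1, h$density * area)
      if (nc == 0) return(NULL)
      data.frame(x = stats::runif(nc, h$xmin, h$xmax),
                 y = stats::runif(nc, h$ymin, h$ymax),
                 ct = sample(cell_classes(), nc, replace = TRUE,
                             prob = h$composition),
                 stringsAsFactors = FALSE)
    })
    parts <- parts[!vapply(parts, is.null, TRUE)]
    if (length(parts) == 0L)
      stop_ecodiv("simulated tumor contains no cells", "ecodiv_empty_input_error")
    df <- do.call(rbind, parts)
    if (flip_rate > 0) {
      flip <- stats::runif(nrow(df)) < flip_rate
      if (any(flip))
        df$ct[flip] <- vapply(df$ct[flip], function(ct)
          sample(setdiff(cell_classes(), ct), 1L), character(1))
    }
    cm <- cell_map(df$x, df$y, df$ct, tumor_id = tumor_id)
    attr(cm, "habitat_shannon") <-
      vapply(spec$habitats, function(h) shannon_index(h$composition), numeric(1))
    cm
  })
}

#' Simulate a survival cohort with a specified EDI-high hazard ratio
#'
#' Generates disease-specific survival under an exponential
#' proportional-hazards model. A fraction `p_high` of tumors is EDI-high
#' (score 5; the rest draw scores 1-4 uniformly) and carries hazard ratio
#' `hr_edi`; optional TP53-mutant and node-positive effects are
#' multiplicative. Censoring is uniform on `(0, c_max)` with `c_max`
#' calibrated numerically so the expected censored fraction equals
#' `censoring`. Administrative capping at 120 months is applied by
#' [validate_cohort()] downstream, not here.
#'
#' @param n cohort size.
#' @param hr_edi hazard ratio of the EDI-high group (default 2).
#' @param baseline_hazard events per month in the reference group
#'   (default 0.01).
#' @param censoring target random-censoring fraction in `[0, 1)` (default
#'   0.3).
#' @param p_high prevalence of EDI-high (default 0.5, balanced arms).
#' @param hr_tp53,hr_node optional additional hazard ratios (default 1).
#' @param p_tp53,p_node prevalence of TP53 mutation / node positivity.
#' @param seed integer seed.
#' @return A data.frame cohort passing [validate_cohort()] (before the
#'   administrative cap), with attribute `"true_hr"`.
#' @export
simulate_cohort <- function(n, hr_edi = 2, baseline_hazard = 0.01,
                            censoring = 0.3, p_high = 0.5,
                            hr_tp53 = 1, hr_node = 1,
                            p_tp53 = 0.3, p_node = 0.5, seed = NULL) {
  stopifnot(n >= 2, hr_edi > 0, baseline_hazard > 0,
            censoring >= 0, censoring < 1)
  with_seed(seed, {
    edi_score <- ifelse(stats::runif(n) < p_high, 5L,
                        sample(1:4, n, replace = TRUE))
    high <- edi_score == 5L
    tp53 <- ifelse(stats::runif(n) < p_tp53, "MUT", "WT")
    node <- as.integer(stats::runif(n) < p_node)
    rate <- baseline_hazard * hr_edi^high * hr_tp53^(tp53 == "MUT") *
      hr_node^node
    t_event <- stats::rexp(n, rate)
    if (censoring > 0) {
      # P(C < T) for C ~ U(0, cmax), T ~ Exp(rate): (1 - exp(-r c))/(r c)
      cens_frac <- function(cmax)
        mean((1 - exp(-rate * cmax)) / (rate * cmax)) - censoring
      cmax <- stats::uniroot(cens_frac, c(1e-6, 1e6), tol = 1e-8)$root
      t_cens <- stats::runif(n, 0, cmax)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event; event <- rep(1L, n)
    }
    out <- data.frame(tumor_id = sprintf("T%04d", seq_len(n)),
                      survival_months = time, event = event,
                      grade = 3L,
                      size_cat = sample(1:3, n, replace = TRUE,
                                        prob = c(0.35, 0.55, 0.10)),
                      node = node,
                      er = as.integer(stats::runif(n) < 0.75),
                      tp53 = tp53, edi_score = edi_score,
                      stringsAsFactors = FALSE)
    attr(out, "true_hr") <- c(edi = hr_edi, tp53 = hr_tp53, node = hr_node)
    out
  })
}

#' Simulate a copy-number call matrix with a planted enriched block
#'
#' Background aberrations occur independently per gene and sample with
#' probability `background_p` (split evenly between gain +1 and loss -1).
#' Genes in the enriched block have their aberration odds multiplied by
#' `odds` in the EDI-high samples, in the block's direction.
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param groups factor/character of length `n_samples` with levels
#'   `low`/`high` (see [dichotomize_edi()]).
#' @param block_genes indices of the enriched genes (default none).
#' @param direction `"gain"` or `"loss"` for the enriched block.
#' @param odds odds multiplier of the block in the high group (default 1,
#'   i.e. no enrichment).
#' @param background_p per-gene background aberration probability
#'   (default 0.2).
#' @param seed integer seed.
#' @return Integer matrix (genes x samples) with calls in `{-1, 0, 1}`,
#'   rownames `gene0001...`, colnames from `names(groups)` if present.
#' @export
simulate_cna <- function(n_genes, n_samples, groups, block_genes = integer(0),
                         direction = c("loss", "gain"), odds = 1,
                         background_p = 0.2, seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(length(groups) == n_samples, odds > 0,
            background_p > 0, background_p < 1)
  if (length(block_genes) > n_genes)
    stop_ecodiv("enriched block larger than n_genes", "ecodiv_spec_error")
  groups <- as.character(groups)
  with_seed(seed, {
    sign_dir <- if (direction == "loss") -1L else 1L
    # background: aberrant w.p. background_p, sign uniform
    m <- matrix(0L, n_genes, n_samples)
    ab <- matrix(stats::runif(n_genes * n_samples) < background_p,
                 n_genes, n_samples)
    sgn <- matrix(sample(c(-1L, 1L), n_genes * n_samples, replace = TRUE),
                  n_genes, n_samples)
    m[ab] <- sgn[ab]
    if (length(block_genes) && odds != 1) {
      # directional probability in the block: background_p/2 per direction
      p0 <- background_p / 2
      p1 <- (p0 * odds) / (1 - p0 + p0 * odds)
      hi <- which(groups == "high")
      for (g in block_genes) {
        hit <- stats::runif(length(hi)) < p1
        m[g, hi[hit]] <- sign_dir
        m[g, hi[!hit & m[g, hi] == sign_dir]] <- 0L
      }
    }
    rownames(m) <- sprintf("gene%04d", seq_len(n_genes))
    if (!is.null(names(groups))) colnames(m) <- names(groups)
    m
  })
}
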