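# ecodiv

Spatial heterogeneity of the tumor microenvironment, scored from
classified cell positions in histology sections.

Automated H&E image analysis can locate and classify every cell in a
tumor section into cancer, lymphocyte and stromal classes. `ecodiv` turns
such a cell table into a single interpretable number per tumor — the
**ecosystem diversity index (EDI)** — that measures how *spatially*
heterogeneous the microenvironment is, together with the scale-selection,
stability, survival and genomic-enrichment analyses that a cohort study
built on the index needs.

## The method

For each tumor section:

1. tile the section into half-open square regions of side *r*
   (default 200 µm), anchored at the cells' bounding box;
2. score every region with ≥ `min_cells` cells (default 10) with the
   Shannon diversity index over its cell-type proportions,
   *d<sub>j</sub>* = −Σ *p<sub>i</sub>* log *p<sub>i</sub>* (nats; 0 for a
   single-type region, log 3 ≈ 1.10 for an equal three-way mix);
3. pool the regional scores *D* = *d*₁,…,*d*<sub>n</sub> of all sections
   of the tumor and fit univariate Gaussian mixtures
   Σ<sub>k</sub> ω<sub>k</sub> N(µ<sub>k</sub>, σ<sub>k</sub>²) by EM for
   K = 1…5; the BIC-selected K (−2ℓ + (3K−1) log n, minimized, ties to
   the smaller K) **is the EDI score**.

EDI 1 = spatially homogeneous local diversity; EDI 5 = five coexisting
diversity levels (the most heterogeneous class, "EDI-high"). Regions are
labelled k1…kK by ascending cluster mean so the clusters can be mapped
back onto the section.

Around the core estimator the package provides region-size scans and
resampling-stability diagnostics (`scale_scan`, `clustering_instability`,
`region_subsample_stability`), Kaplan–Meier / log-rank / Cox survival
stratification of EDI-high vs EDI-low tumors at a 10-year
disease-specific endpoint (`km_logrank`, `cox_fit`, via the `survival`
package), the combined EDI + TP53 three-group prognostic index
(`combine_edi_tp53`), Fisher-exact copy-number enrichment
(`fisher_enrichment`), an expression screen with Storey-type tail-area
q-values (`expression_correlation`, `qvalues`), and synthetic-data
generators with known ground truth (`synthetic_tumor_spec`,
`simulate_cellmap`, `simulate_cohort`, `simulate_cna`) so the whole
pipeline is testable end to end without any imaging data.

## A worked example

```r
library(ecodiv)

spec <- synthetic_tumor_spec(3)      # 3 habitat types, known ground truth
cm   <- simulate_cellmap(spec, seed = 11)
fit  <- edi(cm, seed = 11)
fit
#> Ecosystem diversity index for 'synthetic': EDI = 3 (EDI-low)
#>   189 regions scored (0 excluded), region size 200 um

summary(fit)
#> EDI = 3 for 'synthetic' (189 regions, 0 excluded)
#>
#> BIC over K:
#>  K     bic loglik converged
#>  1   42.90 -16.21      TRUE
#>  2 -294.58 160.39      TRUE
#>  3 -318.31 180.12      TRUE
#>  4 -304.48 181.07      TRUE
#>  5 -290.60 181.99     FALSE
#>
#> Selected mixture (clusters ordered by mean diversity):
#>    weight   mean variance
#> k1 0.3333 0.0000   0.0001
#> k2 0.3710 0.3512   0.0076
#> k3 0.2957 0.6435   0.0042
#>
#> Regions per cluster:
#>
#> k1 k2 k3
#> 63 69 57
#>
#> Q-Q correlation: 0.9995
```

The three clusters sit at mean diversities 0.00, 0.35 and 0.64 nats —
the pure-cancer, mixed-stroma and near-maximally mixed habitats the
generator planted — and BIC bottoms out at K = 3, so the tumor scores
EDI 3. `plot(fit)` overlays the fitted mixture on the score histogram;
`predict`, `simulate` and `residuals` behave as for any fitted model.

A thin command-line wrapper with `score`, `scan`, `stability`, `survive`,
`enrich` and `simulate` subcommands is installed at
`system.file("scripts", "edi", package = "ecodiv")`.

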