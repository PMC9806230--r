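# spathet — spatial heterogeneity scores for cell-level marker expression

`spathet` quantifies *how* a membrane marker's expression is organized in
space across a tissue sample, not just how much of it there is. It is aimed
at digital-pathology and spatial-biology analysts who have per-cell
readouts from segmented IHC slides — one row per tumor cell with planar
coordinates (µm) and a membrane mean optical density (OD, 0–255) — and want
per-sample heterogeneity scores plus the statistical machinery to test
their prognostic value against overall survival.

## The scores

**Co-occurrence family (16 scores).** Cells form a neighborhood graph with
an edge between every pair closer than a radius r ∈ {10, 25, 50, 75} µm. A
255×255 matrix p(i, j) counts the OD-level pairs of neighboring cells
(symmetrically, normalized to sum 1). Four texture statistics summarize it:

- Homogeneity = Σᵢⱼ p(i,j) / (1 + (i−j)²)
- Contrast = Σᵢⱼ (i−j)² p(i,j)
- Correlation = (Σᵢⱼ i·j·p(i,j) − μₓμᵧ) / (σₓσᵧ)
- Angular second moment = Σᵢⱼ p(i,j)²

**Tessellation family (37 scores).** The tissue (convex hull of the cells)
is covered by a 250 µm square grid; tiles with < 5 cells are dropped. Per OD
threshold θ ∈ {8, 10, 15, 20, 25}: the shift-averaged fraction of
high-expression tiles (grid displaced ±25 µm in x and y, scores averaged),
the mean per-tile Shannon entropy of marker-positive vs -negative cells (in
nats; a tile is *heterogenous* above 0.61, the entropy of a 70/30 split,
otherwise *homogenous-high/low* by tile mean OD), the Ecosystem Diversity
Index (EDI) of the per-tile entropies, the three tile-class fractions, and
the global positive-cell fraction; plus the EDI of per-tile mean and SD of
OD. The EDI of a vector is the BIC-best number of Gaussian mixture
components among 1–5.

**Downstream machinery.** Correlation pruning (|r| > 0.9, keeping the best
univariate Cox association), Cox-lasso stability selection (keep at
selection frequency ≥ 0.20), univariate and stepwise multiple Cox with a
likelihood-ratio test against the clinical base model, quantile-cutoff
(25/50/75%) logrank stratification with Kaplan–Meier curves, bivariate
grouping against average expression, and n×k-fold cross-validated
stratification with permutation-based empirical p-values (defaults n = 20,
k = 10, m = 1000).

A synthetic tissue generator (uniform or Matérn-clustered cells; constant,
gradient or smooth-patchy OD fields; proportional-hazards survival linked
to any driver score) makes the whole pipeline testable without patient
data.

## Worked example

```r
library(spathet)

# a synthetic 30-sample cohort whose survival is driven (HR = 3 per SD)
# by the patchy high-expression area fraction
cohort <- generate_cohort(n_samples = 30, beta = log(3), n_cells = 5000,
                          seed = 11, spec_args = list(patch_scale = 400))
ct <- cohort$cells[["s001"]]
ct
#> <cell_table> sample 's001': 5000 cells, od in [0.00, 36.39]

cooccurrence_scores(ct)[c("homogeneity_r10", "homogeneity_r75",
                          "correlation_r10", "correlation_r75")]
#> homogeneity_r10 homogeneity_r75 correlation_r10 correlation_r75
#>           0.341           0.321           0.966           0.868

tessellation_scores(ct)[c("ratio_high_od15", "mean_entropy_od15",
                          "frac_heterogenous_od15", "edi_mean_od")]
#>  ratio_high_od15 mean_entropy_od15 frac_heterogenous_od15 edi_mean_od
#>            0.393             0.184                  0.172       3.000
```

Homogeneity and Correlation shrink from r = 10 to r = 75 µm — small
neighborhoods stay inside one expression patch, large ones straddle patch
boundaries. 39% of tiles are high-expressing at θ = 15, 17% of tiles are
heterogenous, and the tile-mean distribution splits into 3 mixture
components (EDI 3).

```r
fit <- univariate_cox(cohort$driver, cohort$survival)
#> HR per SD 2.84 (95% CI 1.57-5.14), p = 0.00057

quantile_stratify(cohort$driver, cohort$survival)
#> <strat_result> quantile cutoffs:
#>   quantile cutoff n_high n_low chisq         p median_low median_high
#> 1     0.75 0.4228      8    22 17.84 2.405e-05      67.35       7.791
#> best cutoff: 75% quantile (p = 2.405e-05)
```

The univariate Cox fit recovers the planted hazard ratio (2.84 against a
true 3.0), and the 75% quantile cutoff separates median survival 67 vs 8
months (the 25%/50% cutoffs are skipped here because half the cohort sits
at driver 0, so those cutoffs leave one group empty). `run_scores()`,
`run_survival()` and `run_pipeline()` chain the full battery, selection and
evaluation over a cohort manifest; `inst/scripts/spathet-cli.R` exposes the
same as `simulate` / `score` / `select` / `survival` / `all` subcommands.

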