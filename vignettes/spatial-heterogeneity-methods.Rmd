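---
title: "Spatial heterogeneity scores: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial heterogeneity scores: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spathet)
```

## The problem

Immunohistochemistry quantification in digital pathology typically reduces a
stained tissue section to a single number — the average marker expression
over all tumor cells. Two tissues with identical averages can organize that
expression very differently: one uniformly, the other in sharply demarcated
high- and low-expressing niches. `spathet` computes per-sample scores that
capture this *spatial* organization from nothing more than a table of
segmented cells (planar coordinates in µm and a membrane mean optical
density, OD, on a 0–255 scale), and provides the survival-analysis machinery
to ask whether spatial organization carries prognostic information beyond
the average.

Two score families are implemented.

## Co-occurrence scores

Cells become nodes of a neighborhood graph with an edge wherever two cells
lie within a Euclidean distance threshold *r* (closed ball; the package uses
the radii 10, 25, 50 and 75 µm by default). A 255×255 co-occurrence matrix
$p(i,j)$ is the normalized joint histogram of mapped OD levels over all
neighboring cell pairs; each undirected edge contributes both ordered pairs,
so $p$ is exactly symmetric and its two marginals coincide. Continuous OD is
mapped to the 255 levels $0..254$ by rounding half-up and clamping — the
minimal-assumption binning on a stain scale that is already 0–255.

From $p$ four texture statistics are computed, the object-based analogues of
classical Haralick features:

* Homogeneity $\sum_{ij} p(i,j)/(1+(i-j)^2)$ — large when neighbors share
  similar OD;
* Contrast $\sum_{ij} (i-j)^2\, p(i,j)$ — large when neighbors differ;
* Correlation $(\sum_{ij} ij\, p(i,j) - \mu_x\mu_y)/(\sigma_x\sigma_y)$ —
  the Pearson-type linear dependency of neighboring OD levels;
* Angular second moment $\sum_{ij} p(i,j)^2$ — overall uniformity.

Four features × four radii give 16 co-occurrence scores per sample. A radius
with no edges yields missing values rather than an error, and a zero-variance
matrix (all neighbors at one level) makes Correlation undefined, reported as
`NA`; both conventions keep cohort score tables rectangular. Symmetric
counting is fixed; it matters only for Correlation's sign conventions in
pathological cases, and follows the symmetric-matrix convention of classical
texture analysis.

On tissues with patch-structured expression, Homogeneity and Correlation
decrease as the radius grows — larger neighborhoods reach across patch
boundaries — while Contrast grows. The package's tests assert exactly this
trend on generated tissue.

## Tessellation scores

The tissue region (the convex hull of the cell coordinates; its bounding box
anchors the grid) is covered with square tiles of 250 µm side. Tiles with
fewer than 5 cells are discarded. Cells are assigned to tiles by half-open
intervals anchored at the bounding-box minimum; a cell exactly on the
maximum boundary folds into the last tile. The hull is used only to anchor
the grid — tiles are not clipped to the hull polygon, because the ≥5-cell
filter already removes background tiles.

Per OD threshold $\theta \in \{8, 10, 15, 20, 25\}$:

* each cell is *marker-positive* if its OD ≥ θ (ties positive);
* each tile's Shannon entropy of the positive/negative proportions,
  $H = -p\ln p - (1-p)\ln(1-p)$, is computed in nats. The natural-log scale
  is forced by the heterogeneity threshold of 0.61, which corresponds to
  70/30 class proportions ($H(0.7) = 0.611$); in bits the same boundary
  would be 0.881;
* a decision tree labels each tile: entropy > 0.61 → *heterogenous*,
  otherwise *homogenous-high* or *homogenous-low* by comparing the tile's
  mean OD (unweighted mean over member cells) to θ. Tile mean OD rather
  than the majority cell class is used for the high/low split — the two
  readings are equivalent away from the threshold, and tile mean is the
  quantity the binary expression map is built from;
* the binary expression-map score is the fraction of retained tiles with
  mean OD ≥ θ. To remove the arbitrariness of grid placement it is
  *shift-averaged*: the grid is displaced by a tenth of the tile size
  (25 µm at the default) in each of the four axis directions and the four
  scores averaged. Only the four shifted grids enter the average (the
  unshifted grid can be included via an argument).

The Ecosystem Diversity Index (EDI) of a vector of per-tile values is the
number of components of the best one-dimensional Gaussian mixture with 1–5
components by the Bayesian information criterion, ties resolved toward fewer
components. Mixtures are fitted with `mclust`, whose model-based hierarchical
initialisation is deterministic — identical input always yields identical
EDI, with no need for random restarts. Degenerate inputs short-circuit: a
constant vector has EDI 1 by definition, and with fewer than 10 values the
component range shrinks to $\lfloor n/2 \rfloor$.

The per-sample battery comprises 37 tessellation scores: per θ (×5) the
shift-averaged high-tile ratio, the mean tile entropy, the EDI of tile
entropies, the three tile-class fractions and the global positive-cell
fraction; plus the EDI of tile mean ODs and of tile OD standard deviations.
The seven EDI-type scores are the five entropy-EDIs plus the mean- and
SD-EDI. The global positive-cell fraction is the one member of this
enumeration that is a non-spatial aggregate; it closes the battery at 37 and
doubles as a baseline against which the spatial scores can be compared.
Together with the co-occurrence family the battery has 53 scores.

## Score selection

With 53 scores on cohorts of a few dozen patients, selection must precede
modeling.

1. **Correlation pruning.** Scores are ranked by ascending univariate Cox
   p-value (the score z-scored, Efron ties), ties broken by name so the
   result is independent of column order. Walking down the ranking, a score
   is kept unless its absolute Pearson correlation with an already-kept
   score exceeds 0.9 — so of any correlated set, the member with the best
   survival association survives. Absolute correlation is used: a score and
   its negation carry the same information. Constant columns are excluded;
   columns with more than 20% missing values are dropped, remaining missing
   values are median-imputed, and both actions are logged.

2. **Cox-lasso stability selection.** 100 subsamples of half the cohort are
   drawn without replacement (redrawn if a subsample has fewer than 2
   events); each gets an ℓ1-penalized Cox fit along a fixed 25-step penalty
   path computed once on the full data. Within a subsample the path is
   traversed from the strongest penalty down, and the variables active when
   the cumulative active set first reaches $q = \lceil\sqrt{p}\,\rceil$
   are that subsample's selection — the standard per-fit cap that keeps the
   per-family error controlled without committing to one penalty. A score is
   kept when its selection frequency reaches 0.20. The subsample count,
   fraction, cap and path length are all configurable; the defaults are
   standard stability-selection practice.

## Survival evaluation

* **Univariate Cox** per selected score, z-scored so hazard ratios are per
  SD, Efron tie handling, Wald p-values; non-identifiable or non-converged
  fits are flagged, not raised.
* **Multiple Cox with stepwise reduction.** Clinical covariates (age,
  gender, grade) and the average expression form a base model that is
  forced into the fit. Candidates first pass a multicollinearity screen
  (absolute Spearman correlation with average expression below 0.9), then
  AIC-guided forward-backward search from the base model decides which
  enter. AIC is the criterion because the search is about parsimony of the
  covariate set, not testing; the final-vs-base comparison is a
  likelihood-ratio test with df equal to the number of added terms.
* **Quantile stratification.** The 25/50/75% quantiles of a score are
  candidate cutoffs ("high" = score ≥ cutoff); each is evaluated by the
  logrank test and Kaplan–Meier curves, all three results are retained, and
  the smallest p marks the best cutoff. Cutoffs that empty a group are
  skipped.
* **Repeated cross-validated stratification with permutation p-values.**
  Per repeat (default n = 20), the cohort is split into k = 10 random
  folds. For each fold, the best quantile cutoff is learned on the training
  folds alone — quantiles recomputed on training scores, winner by training
  logrank statistic — and applied to the held-out fold. The pooled held-out
  labels give one cross-validated logrank statistic. Its significance comes
  from applying the *identical* procedure (same fold plan) to m = 1000
  joint permutations of the (time, event) pairs: the empirical p is
  $(1 + \#\{\text{null} \ge \text{obs}\})/(m+1)$, never zero by
  construction. Fold draws are keyed to the sample order after sorting by
  sample id, so row order does not affect results. The quantile-only cutoff
  search on training folds is pinned deliberately: a finer grid would
  overfit small training sets and is not what the rest of the pipeline
  uses.
* **Bivariate grouping** crosses the high/low dichotomies of a spatial
  score and the average expression into four groups with per-group
  Kaplan–Meier median survival, separating "how much" from "how organized".

A hand-written two-group logrank kernel (compiled) backs the permutation
loop — the CV null distribution needs on the order of $n \times k \times m$
logrank evaluations, where a model-fitting interface would dominate the
runtime. The kernel is tested for exact agreement with
`survival::survdiff`.

## Synthetic tissue generator

Every stage is testable without patient data through a generator with three
expression-field models on two position models:

* positions: uniform (fixed cell count) or Matérn-cluster (Poisson parents,
  Poisson offspring in a disc; the expected total matches the requested
  count);
* fields: constant (mean μ plus noise), linear gradient, or *patchy* — a
  smooth stationary Gaussian random field (64 random Fourier features of a
  squared-exponential kernel with a length-scale in µm) thresholded at the
  area quantile that yields a designed high-area fraction; cells in high
  patches draw OD around 30, others around 5, i.i.d. Gaussian noise
  (SD 2) added and the result clamped to [0, 255].

Defaults are a 2×2 mm window with 10⁴ cells — cell densities around
2,500/mm², as in tumor epithelium — and a 500 µm patch length-scale.
Survival is simulated from an exponential proportional-hazards model
(median 36 months at the cohort mean) with log-hazard β per SD of a chosen
driver score and independent exponential censoring tuned to a target
censoring fraction (default 30%). The generator records the realized
high-area fraction and the true β so recovery tests have ground truth.

What the generator does *not* emulate: staining artifacts, segmentation
errors, tissue folds, anisotropic cell packing, or spatial correlation in
the noise. Tests passing on generated tissue therefore demonstrate the
correctness and statistical behavior of the scoring and inference
machinery, not clinical validity on real slides.

## The tile-size robustness experiment

`tile_size_robustness()` checks that tessellation scores measure tissue
organization rather than grid artifacts: the shift-averaged high-tile ratio
is computed at 250 µm and at ±50% (125 and 375 µm) on a cohort of 30 patchy
samples, and the cross-sample Pearson correlation between the reference and
each alternative is reported.

Two design choices matter here. First, the ratio score is a fraction over
retained tiles, so its resolution is 1/#tiles; a region holding only ~30
tiles at the largest grid would cap the attainable correlation near 0.98 by
quantization noise alone, regardless of the method. The experiment therefore
uses 4×4 mm regions (resection-scale; >100 tiles even at 375 µm) with 10⁴
cells. Second, the patch length-scale is set to 750 µm — twice the *largest*
tile size compared — so the marker field is smooth at every grid resolution
tested; high-area fractions are spread evenly over 0.2–0.8 across samples so
there is true between-sample variation to correlate.

## Numerical conventions and degenerate inputs

* Distance ties at exactly the radius are edges (closed ball); coincident
  cells are neighbors at any positive radius; isolated cells keep degree 0.
* Degree medians use midpoint interpolation, so fractional medians are
  representable.
* A convex hull of fewer than 3 non-collinear cells reports area 0 with a
  warning flag.
* $0\ln 0 = 0$ in the entropy; entropies live in $[0, \ln 2]$.
* The co-occurrence matrix is normalized to sum 1 within 1e−12 and is
  exactly symmetric (integer counts before normalization).
* Empirical permutation p-values lie in $[1/(m+1), 1]$.
* All randomness in selection, CV and generation flows from explicit
  integer seeds; reruns with the same seed and configuration are
  bit-identical.

## Problem sizes used in the shipped tests

The packaged test-suite cohorts are sized for a laptop: oracle-equivalence
checks run brute-force comparisons up to 2,000 cells; calibration of the CV
permutation scheme uses 200 null cohorts of 40 samples with the reduced
scheme n = 5 repeats, k = 5 folds, m = 200 permutations; power and
stability-selection recovery use 20 cohorts with a planted hazard ratio of
3; the robustness experiment uses the 30-sample cohort described above.

## Known limitations

* One marker per run; multi-marker joint analysis is left to the caller.
* No edge-effect correction in degree statistics or co-occurrence counts;
  boundary cells simply have fewer neighbors.
* The EDI inherits the known conservatism of BIC for mixture order at small
  tile counts: samples with few retained tiles rarely report EDI > 2.
* The stepwise/LR stage assumes complete clinical covariates; rows with
  missing covariates are the caller's responsibility.
* Scores are computed per sample in memory; cohorts stream sample by
  sample, but a single sample's graph at the largest radius must fit in
  memory (fine up to several 10⁵ cells at usual densities).
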