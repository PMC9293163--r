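---
title: "Ensemble niche modelling for pest-risk mapping: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble niche modelling for pest-risk mapping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it fits,
the parameters that matter, the choices made where the methodology is
genuinely open, and what the synthetic-data tests do and do not demonstrate
about real data.

## The problem

An emerging orchard pest is known from a few hundred georeferenced
occurrence records. The questions a risk analyst asks are: *where is the
climate suitable for this species*, *how does that area overlap with the
area suitable for the crop*, and *do growers in more suitable areas already
report more attacks or damage*? `nichecast` implements that workflow for
presence-only data: true absences are unobtainable for an under-recorded
insect, so absence surrogates must be manufactured from the climate itself,
and the suitability model must be an ensemble rather than a single
algorithm, because algorithm choice is a major, and otherwise invisible,
source of variance in projected ranges.

## Data model

Rasters are plain matrices on a shared `raster_grid` (row 1 = northernmost
row; half-open square cells; WGS84 longitude/latitude labels). A
`climate_stack` carries one named layer per bioclimatic variable and a
single validity mask — a cell is either valid in every layer or masked
everywhere, taking the union of per-layer nodata at construction. Points
are assigned to cells by flooring the fractional index, so a point exactly
on a shared edge belongs to the cell whose half-open interval contains it;
this tie rule is asserted in the tests. Rasters are read and written as
ESRI ASCII grids: a plain-text format with full header georeferencing in
which values are serialised at 17 significant digits, so a write/read cycle
reproduces doubles exactly. Occurrences travel as CSV with
`longitude,latitude,source,year` columns; records on masked cells are
flagged and excluded from fits with a warning rather than dropped silently,
since compiled occurrence sets routinely contain coastal points that miss
the grid.

Duplicate records within a cell are thinned to one before fitting
(configurable off): repeated records reflect collection effort, not extra
climatic information.

## Variable selection

Bioclimatic layers are strongly inter-correlated, and collinear predictors
destabilise every downstream learner. Selection has two stages:

1. **Clustering.** Pearson correlations between layers are computed over
   (a sample of) valid cells and converted to the dissimilarity
   d = 1 − |r|, so the conventional "highly correlated" threshold |r| > 0.7
   becomes a tree cut at height 0.3. Agglomeration uses Ward linkage
   applied to this dissimilarity directly. Ward formally assumes Euclidean
   distances, which 1 − |r| is not; we accept that deviation knowingly —
   it is the established practice in this workflow — and verify the merge
   sequence against an exhaustive greedy Ward oracle in the tests. A layer
   uncorrelated with everything forms a singleton cluster and survives
   unchanged.
2. **Representative choice.** Which cluster member is "most informative" is
   not well defined. The default rule keeps the member whose
   min–max-rescaled values have the largest variance — i.e. the variable
   that spreads the landscape most widely across its own range. (A z-score
   based rule is vacuous here: after standardisation every variance is 1.)
   Because any such rule is a heuristic, `force_keep` can pin the
   representative per cluster, which is also how a published variable set
   can be reproduced exactly on real data.
3. **VIF screen.** VIF_i = 1/(1 − R²_i) from regressing layer i on the
   other survivors, computed on z-scored values at up to 50 000 sampled
   cells (seeded) for tractability. While any VIF exceeds 5 the worst
   offender is dropped; exact collinearity (infinite VIF) is dropped
   immediately with a warning. All intermediate VIF tables are kept in the
   report.

Whether correlations should be computed over all valid cells or presence
cells only is an open question in the source methodology; the default is
all valid cells, with `sample_cells` available to restrict.

## Envelope, background and pseudoabsences

The envelope is the per-variable [min, max] interval spanned by the
presence cells, with closed intervals: a boundary value counts as inside,
which guarantees that every presence cell is classified as background in
its own envelope (asserted property). Each valid cell is then scored by how
many selected variables fall outside their interval:

* 0 failures → **background**: climates the species demonstrably tolerates;
* ≥ 2 failures → **pseudoabsence**: climates clearly outside the envelope;
* exactly 1 failure → **excluded**: the methodology defines the two pools
  above and is silent about single-failure cells, so we place them in
  neither pool rather than force a class. This is deliberately
  conservative: one marginal variable is weak evidence of unsuitability.

Sampling within pools is uniform without replacement and seeded. Defaults
are one pseudoabsence per presence and ten background points per presence,
capped at the pool size; both counts are configurable and an explicit
request larger than the pool is an error reporting the pool size.

## The ensemble

Six algorithms are fitted per iteration. The published workflow ran them
inside biomod2, whose internals are configurable and unreported; the
surrogates here are the standard representatives of each family, each
deterministic under its per-run seed and returning probabilities clipped to
[0, 1]:

| name | implementation | notes |
|------|----------------|-------|
| GLM | `glm`, binomial, linear + quadratic terms | |
| GAM | `mgcv::gam`, per-variable splines, k = 5, fixed df | fixed-df splines: smoothness selection is slow and unstable under the quasi-separation typical of presence/pseudoabsence data |
| ANN | `nnet`, one hidden layer of 5 units, decay 0.01 | inputs z-scored |
| CTA | `rpart` classification tree, depth ≤ 8 | |
| MAXENT | `glmnet` L1 logistic, presences vs background, linear + quadratic + pairwise-product features | the standard MaxEnt–logistic equivalence; lambda chosen by 4-fold stratified CV maximising AUC (deviance-based CV can select the null model on imbalanced data); a short lambda path avoids the slow near-zero-penalty tail |
| RF | `randomForest`, 500 trees | |

Only MAXENT sees background points; the other learners contrast presences
with pseudoabsences. Whether background should enter the other learners is
unstated in the source methodology; presences-vs-pseudoabsences is the
default here.

**Splits and seeds.** A single stratified 25% external holdout of presences
and pseudoabsences is drawn before the iteration loop and never enters any
fit. Each iteration then draws a fresh stratified 75/25 fit/evaluation
split of the training pool; the evaluation part provides the *internal* AUC
of that run. The master seed spawns all per-run seeds, so a whole ensemble
is reproducible from one integer. The pseudoabsence/background sample is
drawn once per pipeline run.

**Keep filter.** A run joins the consensus only if its internal AUC is
strictly greater than 0.7 ("good-to-excellent" discrimination). Fitting
failures are flagged and skipped, never fatal; zero kept runs is an error
carrying the full run table.

**Consensus and bounds.** The consensus map is the cell-wise mean of kept
runs. "Upper and lower bounds models" are not defined in the source
methodology; here they are the cell-wise 2.5th/97.5th percentiles of
kept-run predictions, bracketed with the consensus (lower = min(q2.5,
consensus), upper = max(q97.5, consensus)) so lower ≤ consensus ≤ upper
holds at every cell by construction — without the bracketing, a mean can
in principle escape the percentile band under extreme skew. A `minmax`
alternative is available. AUC is computed by the exact Mann–Whitney
identity (ties worth ½), verified against brute-force pair counting.

**Binarisation and validation.** The consensus is thresholded at 0.55 with
a closed ≥ rule (a map constant at the cut-off is entirely suitable;
documented, asserted). Independent validation records are scored by their
consensus suitability and counted above/below the cut-off.

**Variable contributions.** Permutation importance per algorithm:
contribution = 1 − max(0, cor(predictions, predictions after permuting the
variable's column)), averaged over the algorithm's kept runs, in percent.
The truncation at zero correlation keeps contributions in [0, 100].

## Niche contrast

Presence climates are compared with "no-record" points sampled from valid
cells that hold no record and that both bound maps score below the cut-off.
Each of 100 sets samples exactly as many cells as there are presences,
without replacement. The phrase "average of 100 randomly chosen sets" is
ambiguous; the default averages the value vectors element-wise across sets
(positions are random, so this approximates the pooled mean with reduced
variance), and `mode = "pool"` concatenates the sets instead. The test is
a pooled-variance two-sample Student's t with df = n1 + n2 − 2. Note the
inherent circularity, reproduced as stated: the no-record sample depends on
the fitted model being contrasted, so these t-tests describe the fitted
niche, they do not independently validate it.

## Crop overlap

Pest suitability is paired cell-wise with a categorical crop-suitability
map (nearest-neighbour lookup if the grids differ; pairwise deletion of
nodata), summarised per category as mean ± SE, and compared by one-way
fixed-effects ANOVA with Bonferroni-adjusted pairwise pooled t-tests
(p × number of pairs, capped at 1). Grid cells are treated as independent
observations, as in the source workflow; with 10^5–10^6 cells this yields
enormous F statistics and the p-values should be read as descriptive, since
spatial autocorrelation is not corrected for.

## Survey and field statistics

* `clumping_stats`: Shapiro–Wilk W (Royston approximation) plus the sample
  skewness g1 = m₃/m₂^{3/2} and its small-sample adjusted variant. Strongly
  positive g1 with rejected normality is the signature of clumping — a few
  trees hosting most individuals.
* `count_correlations`: Pearson r with t-transform p-values for the
  standard pairs; the egg-clusters-per-copula ratio is undefined on trees
  with zero copulae, and those trees are dropped for that pair with a note.
* `attack_logistic`: one covariate per fit, as in the source analysis. The
  reported χ² is the likelihood-ratio statistic against the intercept-only
  model (df = 1); D² = (null − residual deviance)/null deviance. Perfect
  separation is detected and reported as non-estimable instead of returning
  runaway coefficients.
* `impact_ordinal`: proportional-odds (cumulative logit) fit of the impact
  rank (0 = no loss, 1 = <10%, 2 = ≥10%). All fields enter, with
  non-attacked fields as rank 0 — consistent with the rank scale, where 0
  is an observable outcome, not a missing value. The statistic is the Wald
  t = coefficient/SE with a normal-approximation p; the model df is printed
  as the number of threshold parameters (2), matching how such tables are
  conventionally reported.

## The synthetic-landscape module

The generators produce inputs with the statistical structure the analysis
assumes, under fixed seeds:

* **Climate layers**: Gaussian-smoothed seeded noise rescaled to ranges
  typical of the six retained bioclimatic variables (BIO3, BIO7, BIO10,
  BIO15, BIO18, BIO19), so synthetic and real configurations are
  interchangeable; a mixing weight injects inter-layer correlation.
* **True niche**: logistic in the z-scored layers, with optional quadratic
  terms. The standard study conditions use an optimum-shaped niche
  (negative quadratics): a species with interior climatic optima is the
  setting in which an envelope method is meaningful, and it yields
  non-trivial background/pseudoabsence pools.
* **Presences**: cells drawn with probability proportional to true
  suitability, mirroring how compiled records over-represent favourable
  areas (enrichment is an asserted property). The standard conditions use
  207 training and 18 validation records, a 165-field survey and 59 trees —
  the sizes of the motivating study's data sets.
* **Crop map**: a smooth field thresholded by rank into three categories
  with exact areal proportions (±1 cell).
* **Survey**: log-normal field areas (meanlog log 6, sdlog 1, giving a
  realistic ~10 ha mean and a long right tail); age compositions as a
  mixture of single-age-class fields (probability 0.64, reflecting how
  often plantations are uniform-aged) and Dirichlet-mixed fields; attack
  drawn from a Bernoulli-logit model and impact from a proportional-odds
  model given attack.
* **Tree counts**: negative binomial, parameterised by mean and dispersion
  k; the source analysis only reports non-normality and skewness, and the
  negative binomial is the standard overdispersed count model with a
  Poisson limit (k → ∞) used to anchor the skewness tests.

What the generators do **not** emulate: real geography (coastlines,
elevation gradients), spatial autocorrelation of survey responses,
observer/effort bias in occurrence records, and temporal structure. Passing
tests therefore demonstrate that the algorithms are implemented correctly
and are well calibrated under their own assumptions — not that those
assumptions hold for any particular real data set.

## Numerical choices and degenerate inputs

* Closed envelope intervals; strict > in the AUC keep filter; closed ≥ in
  binarisation — each matching the natural reading of the corresponding
  rule and asserted in tests.
* Edge points: floor-of-fractional-index cell assignment; points on the
  outer top/right boundary belong to the last cell.
* Constant layers abort variable selection by name; constant covariates
  give exactly χ² = 0, D² = 0; identical t-test groups give t = 0, p = 1;
  zero pooled variance with unequal means reports an infinite t rather
  than NaN.
* Failed ensemble members are contained (flagged, logged, skipped);
  MAXENT without background points is a contained failure too.
* All simulation-based defaults (60×60 grids, 100 iterations, 5-seed
  replication, 500-replicate calibration checks) are the package's standard
  study sizes, chosen to make every property measurable with comfortable
  statistical power.

## Known limitations

* The pseudoabsence definition is model-leading: cells failing ≥ 2 envelope
  variables are by construction climatically extreme, so external AUCs on
  presence-vs-pseudoabsence holdouts are optimistic relative to true
  absences. This mirrors the source workflow and is flagged, not fixed.
* Ward linkage on 1 − |r| is not metrically clean (above).
* ANOVA over raster cells ignores spatial autocorrelation (above).
* The niche-contrast t-tests inherit the model circularity (above).
* No reprojection: all rasters must share a grid, and coordinates are
  assumed WGS84 longitude/latitude.
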