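---
title: "Modeling and optimizing elicited paclitaxel production with GRNN-FOA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and optimizing elicited paclitaxel production with GRNN-FOA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Hazel (*Corylus avellana*) cell suspension cultures synthesize paclitaxel, and
fungal elicitors — a cell extract (CE) and a culture filtrate (CF), dosed in
percent v/v — can strongly stimulate that synthesis. Four culture inputs
govern the outcome: the CE and CF concentrations, the culture day on which
the elicitor is added, and the day the cells are harvested. The responses of
interest are cell growth (dry weight, g/l), intracellular paclitaxel (per
gram dry weight and per liter), extracellular paclitaxel, total yield
(µg/l), and the extracellular (secreted) fraction in percent.

`grnnfoa` models these response surfaces with a general regression neural
network (GRNN) whose single free parameter is tuned by a fruit-fly
optimization algorithm (FOA), ranks the inputs by leave-one-covariate-out
sensitivity, and then maximizes each fitted surface over the culture-input
box with FOA and a real-coded genetic algorithm (GA).

## The model

A GRNN is a Gaussian kernel regressor (the Nadaraya–Watson estimator) viewed
as a four-layer network. For a query $x$ the pattern layer emits, for every
stored training vector $x_i$,

$$p_i = \exp\left(-\frac{\lVert x - x_i \rVert^2}{2\sigma^2}\right),$$

the summation layer forms $S_s = \sum_i p_i$ and $S_w = \sum_i w_i p_i$ with
the interconnection weights $w_i$ equal to the training targets, and the
output layer returns

$$\hat y(x) = \frac{S_w}{S_s} = \frac{\sum_i w_i\, p_i}{\sum_i p_i},$$

a convex combination of the training targets. Fitting is storage only; the
only tunable quantity is the smoothing bandwidth $\sigma$, shared across
input dimensions. Because the kernel distance is scale-sensitive, inputs are
standardized (training statistics only), and $\sigma$ lives on that
standardized scale, searched in $[10^{-3}, 10]$.

Two structural consequences matter for everything downstream:

* predictions can never leave the range of the observed targets, so a
  predicted "optimum" is capped by the best observation;
* as $\sigma \to 0$ the model interpolates (nearest-neighbor), and as
  $\sigma \to \infty$ it collapses to the target mean. If the kernel mass at
  a remote query underflows to zero, prediction falls back to the nearest
  pattern's target (the exact $\sigma \to 0$ limit) with a warning.

## Preprocessing

Each response is Box-Cox transformed before modeling; $\lambda$ is chosen by
profile likelihood on $[-5, 5]$, with an additive shift $1 - \min(y)$ when
values are not strictly positive. $\lambda$ is estimated once on the full
sample, before cross-validation — the workflow order of the original
elicitation studies — which introduces a mild, documented leakage. All fit
metrics are reported on the original units after inverse transformation, so
RMSE values are directly interpretable (µg/l, g/l, percentage points).

A PCA screen flags multivariate outliers: columns are standardized,
components covering 95% of variance retained, and each row's standardized
score distance compared against `mean + z·sd`. The cutoff `z` is
Bonferroni-adjusted to the sample size (`qnorm(1 - 0.01/(2n))`, about 4.2 at
n = 360) because the largest clean-sample distance is already expected
around 3.4 SD at that size; a fixed 3-SD rule would flag ordinary extremes
of clean data. The screen runs on the modeling (Box-Cox) scale and is
advisory — flagged rows are reported, and dropped only on request.

## Cross-validation, bandwidth tuning, and metrics

Prediction skill is estimated by 5-fold cross-validation repeated 10 times
(50 fold fits per response). The bandwidth is tuned once per response by FOA
with the negative mean CV RMSE (on the modeling scale) as fitness, then held
fixed across folds; per-fold retuning is available behind a flag. For speed,
the tuning objective standardizes inputs once on the full sample and reuses
one pairwise-distance matrix across all folds; the reported fold metrics,
in contrast, re-standardize on each training fold so held-out rows only ever
see training statistics.

Performance is summarized by $R^2$, RMSE and MBE (mean of predicted minus
actual). They satisfy $RMSE^2 = MBE^2 + \mathrm{var}(\text{residuals})$,
which the test suite checks to $10^{-10}$. Reported values are means over
the 50 fold evaluations, with standard deviations alongside. Training-subset
metrics are in-fold resubstitution values; with a near-interpolating kernel
they are optimistic by construction and are reported for completeness, not
inference.

## The fruit-fly optimizer

FOA maintains, per search dimension, a pair of location coordinates
$(X, Y)$. Each generation every fly perturbs them by a uniform draw from the
flight distance range ($[-10, 10]$), computes its distance to the origin and
the smell-concentration judgment value $S = 1/\mathrm{Dist}$, the fitness is
evaluated at the candidate derived from $S$, and the swarm relocates to the
best fly's coordinates only when its fitness improves on the incumbent — so
the best-smell trace is non-decreasing and exactly `sizepop * maxgen`
evaluations are spent. Defaults are 10 flies and 100 generations, with
initial coordinates in $[0, 1]$.

$S$ is positive and unbounded, so a mapping must take it into the problem
box. The package maps each generation's raw $S$ values, dimension-wise and
min-max affinely, onto a trust region centered on the incumbent: the full
box during an initial exploration phase (half of the generations by
default), then contracting geometrically to 0.5% of the box range. The
rescaling layer absorbs the large scale mismatch between the location
coordinates and typical problem boxes, the exploration phase protects
against multimodal surfaces, and the contraction gives terminal precision a
fixed-span mapping cannot reach: mapping every generation onto the full box
keeps candidates quasi-uniform forever, which bounds the best-of-1000-sample
precision near 18% of range per dimension on a 4-d problem. The literal
full-box squash (`mapping = "minmax"`) and the raw clipped form
(`mapping = "direct"`) remain available for faithfulness studies.

The same optimizer tunes $\sigma$ (a 1-d search) and maximizes fitted
response surfaces (a 4-d search). For response optimization,
`optimize_response()` runs five independent FOA starts and keeps the best:
a fitted kernel surface over a two-level adding-day design is genuinely
multimodal, and a single 10-fly swarm finds the global basin only part of
the time. The GA comparison arm — tournament selection (size 3), blend
crossover ($\alpha = 0.5$, rate 0.9), Gaussian mutation (rate 0.1, SD 5% of
range), one elite, population 50 — is robust with a single start. All GA
settings are conventional real-coded defaults; none are prescribed by the
study this package models.

Response optimization is confined by default to the training data's support
(observed per-input ranges, observed total-dose range, observed
elicitation-to-harvest gap range): outside it a kernel model has no data and
flattens onto its nearest stored patterns, so apparent optima there are
artifacts. An `extrapolate` flag overrides this. Candidates violating
`harvest_day > adding_day` receive $-\infty$ fitness. Optima are reported
with derived quantities: total dose `ce + cf`, CE:CF ratio as rounded
percentages, and hours post-elicitation, `(harvest - adding) * 24`.

## Sensitivity analysis (VSE/VSR)

The variable sensitivity error (VSE) of an input is the RMSE, over the
entire dataset, of the model retrained without that input ($\sigma$ retuned
by the same seeded procedure; a flag reuses the full model's $\sigma$). The
variable sensitivity ratio is VSR = VSE / RMSE of the full model on the same
rows; higher means more important. Retraining (rather than mean-substitution)
is the natural reading for a lazy learner and makes VSR < 1 possible: losing
a genuinely uninformative input can slightly *improve* the model by removing
a diluting dimension from the kernel distance. VSRs are also min-max
rescaled to $[0, 1]$ within each response; rescaling preserves the ranking.

## The synthetic data generator

The original experimental data are not publicly deposited, so the package
ships a generator that emulates the stated design: five CE:CF blend ratios
(100:0, 75:25, 50:50, 25:75, 0:100), doses 2.5, 5 and 10% v/v, elicitor
added on day 13 or 17, harvests every two days after elicitation through day
23, three replicates — 360 elicitor-arm runs. Control arms (water/broth) map
to zero CE and CF and are optional, since they collapse onto a single input
point.

Ground truth is a separable bump family: each base response (dry weight,
intracellular per gram, extracellular) is a baseline plus a product of
per-input Gaussian terms; intracellular per liter, total, and the secreted
portion are derived identities, exact at zero noise. Noise is multiplicative
Gaussian, independent per response, clipped at zero, with a 10% CV by
default. Calibration choices, made once:

* bump centers sit at the published optimum region (CE ≈ 4.3, CF ≈ 5.4% v/v,
  adding ≈ day 16, harvest ≈ day 20–22);
* the dry-weight and extracellular peaks are 12.57 g/l and 152.15 µg/l, and
  the intracellular bump height is calibrated by a deterministic grid
  root-finder so the maximum total yield over the input box is exactly
  372.89 µg/l;
* baselines and widths are set so each response's signal variance across the
  design dominates the 10% noise (variance ratio ≥ 0.93 for every response),
  placing attainable test-set $R^2$ in the high-0.8s to mid-0.9s — the
  performance band reported for this class of models on the real data;
* the 10% CV itself is a choice, not a published value: replicate scatter of
  this magnitude is typical for HPLC-quantified metabolites in flask
  cultures.

What the generator deliberately does not emulate: longitudinal correlation
between harvests of the same flask (rows are independent, as the original
analysis assumed), heteroscedasticity beyond the multiplicative form,
batch/subculture effects, and any mechanistic elicitation kinetics. Passing
tests therefore demonstrate that the pipeline recovers smooth unimodal
response surfaces from designed, moderately noisy data — not that it would
survive pathologies the generator cannot produce.

## Study sizes used by the tests

The test suite and the acceptance script choose problem sizes appropriate to
each question:

* the reference study is the full 360-run design with 10% noise and
  5-fold × 10 cross-validation;
* optimizer-recovery studies use a noise-free aligned-bump surface (peak at
  CE 4.3, CF 5.4, adding day 15.5, harvest day 19.5; widths 3.5, 3.5, 1.8,
  3.5) sampled at 800 stratified (Latin-hypercube-style) points. The
  factorial design itself cannot support such a test: its (CE, CF) values
  lie on five rays and its adding day takes two values, so no estimator can
  localize an interior optimum to 10% of range from it. Widths are chosen so
  the surface has clear curvature in every input (localizability) while
  kernel smoothing at the CV-tuned bandwidth preserves ≥ 85% of the peak
  height;
* sensitivity-ranking replicates use single-replicate designs (120 runs),
  2 CV repeats, and a 40-generation tuning budget — the ranking, not the
  bandwidth's last decimal, is under test;
* determinism of the command-line workflow is checked at reduced budgets
  (one response, 2 CV repeats, 10 FOA generations).

## Numerical choices and degenerate inputs

* Kernel-mass underflow at remote queries falls back to the
  nearest-pattern target with a warning (exact small-$\sigma$ limit).
* Ties in the FOA generation's best fly go to the lowest fly index;
  the incumbent relocates only on strict improvement, so among equal optima
  the earliest found (for $\sigma$ tuning: the smaller bandwidth candidate
  found first) is kept.
* `NA`/`NaN` fitness values discard the fly (or GA individual) for that
  generation with a warning; `-Inf` marks infeasible candidates and is kept.
* Box-Cox inversion refuses values outside the transform's range; inside the
  pipeline this cannot trigger, because predictions are convex combinations
  of transformed training values.
* Constant responses (no information for $\lambda$ or $R^2$), empty
  designs, harvest days at or before the adding day, missing or non-finite
  cells, and zero-variance inputs are rejected with named errors rather than
  propagated.

## Known limitations

* Table-level reproduction of the original study's metrics is impossible
  without the undeposited raw data; the synthetic study mirrors the design
  and magnitudes, not the measurements.
* The GRNN uses a single shared bandwidth; per-dimension bandwidths (and
  with them automatic relevance weighting) are out of scope.
* The printed form of the GRNN output equation in the source literature
  divides the simple by the weighted summation; this package implements the
  standard weighted-over-simple ratio, without which predictions would be
  dimensionless and unbounded.
* VSR values depend on the retraining convention; with retuned bandwidths
  they are not comparable across packages that use mean-substitution.
* The support constraint approximates the data's convex hull with per-input
  and dose/gap range cuts; for the shipped designs these are the binding
  facets, but for exotic custom designs the approximation is loose.
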