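---
title: "Methods: Rasch evaluation of the Glasgow Coma Scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Rasch evaluation of the Glasgow Coma Scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcsrasch)
```

## The question

The Glasgow Coma Scale (GCS) scores a patient's conscious level on three
sub-scales — Eye opening (1–4), Verbal response (1–5), Motor response (1–6) —
that are routinely summed into a total of 3–15. Summing is only defensible if
the three items jointly behave like a measurement instrument: each response
category should become the most likely response somewhere along the latent
"consciousness" continuum, the items should separate patients reliably, and
the observed response patterns should agree with what an additive latent-trait
model predicts. `gcsrasch` implements that audit with the polytomous Rasch
**partial credit model** (PCM), the category-collapse rescoring procedure that
repairs dysfunctional response categories, and cross-validated mortality
models that ask whether the repaired scale loses predictive information.

National trauma-registry data of the kind this analysis needs cannot be
redistributed, so the package ships a synthetic registry generator calibrated
to the published cohort constants of a large national trauma sample
(n = 364,355 submitted; 321,203 complete adult records). All statistical
machinery is exercised against that fixture and against simulated PCM data
with known parameters.

## The partial credit model and its estimation

For person $v$ with location $\theta_v$ (logits) and item $i$ with Andrich
thresholds $\delta_{i1},\dots,\delta_{im_i}$, the probability of response
$x \in \{0,\dots,m_i\}$ is

$$P(X_{vi}=x) \propto \exp\!\Big(\sum_{k\le x}(\theta_v - \delta_{ik})\Big),$$

with the empty sum equal to zero. The threshold $\delta_{ik}$ is the location
at which categories $k-1$ and $k$ are equiprobable (`pcm_category_probs()`).

Item parameters are estimated by **conditional maximum likelihood** (CML,
`fit_pcm()`): the likelihood conditions on each person's total score, whose
normalising constants are the elementary symmetric functions
$\gamma_r$ of the category weights (`elementary_symmetric()`, computed by the
stable recursive convolution over items). Conditioning removes the person
distribution entirely, which is also why persons with an extreme total (3 or
15 on the raw GCS) contribute nothing to item calibration and are excluded
from fitting — the package's tests verify that adding extreme persons leaves
the estimates bit-identical. Estimation is Newton–Raphson with analytic
gradient and Hessian; sufficient statistics are the item-category counts and
the total-score distribution, so the cost is independent of sample size once
those are tabulated. Convergence requires a maximum absolute gradient below
1e-8 (200-iteration cap); the solution is identified by centring the mean
item location at zero. The commercial RUMM program uses an unpublished
pairwise variant; CML is a consistent, fully documented replacement, so only
qualitative agreement with RUMM output should be expected.

A **null category** (a category observed zero times among non-extreme
persons) makes its threshold inestimable; `fit_pcm()` refuses with a
structured error naming item and category, since collapsing categories is the
analyst's remedy, not something the fitter should silently improvise.

Person locations (`estimate_persons()`) are ML estimates given the fitted
items: $\hat\theta(r)$ solves $\sum_i E[X_i\mid\theta]=r$, with
$SE = 1/\sqrt{\sum_i \mathrm{Var}(X_i\mid\theta)}$. Extreme raw scores have
no finite ML estimate; they are extrapolated at $r=\varepsilon$ and
$r=\max-\varepsilon$ with $\varepsilon = 0.3$ score units (configurable).
RUMM's exact extrapolation rule is unpublished, so reliability statistics
that include extremes are qualitative by construction.

## Diagnostics

**Standardized residuals.** By default
`standardized_residuals()` standardises each response against its
conditional-on-total moments, $E[X_i \mid R=r]$ and
$\mathrm{Var}(X_i \mid R=r)$, computed from the same conditional
distributions that drive the CML fit. This choice matters: because
$\hat\theta$ is a function of the raw total and
$\sum_i E[X_i\mid\hat\theta(r)] = r$ exactly, residuals sum to zero within
each person, and moments conditioned on $\hat\theta$ overstate the residual
variance (for three items, $E[z^2]\approx 2/3$). Conditional-on-total
moments make the residuals exactly mean-zero and unit-variance under the
model, which is what a fit statistic should be standardised against. The
$\hat\theta$-conditioned classical version remains available via
`conditional = FALSE`.

**Fit residuals.** Item and person fit residuals apply the Wilson–Hilferty
cube-root standardisation to the sum of squared residuals
(`fit_residual_transform()`), with $\nu$ equal to the number of contributing
persons (item fit) or items (person fit). Target values are mean 0, SD 1;
the exact value at $Y=\nu$ is $\sqrt{2/(9\nu)}$, so "0" is approached only as
$\nu$ grows. On data simulated from the model at n = 500, pooled item-fit
residuals have mean ≈ 0 and SD ≈ 0.8, and person-fit residuals mean ≈ 0 and
SD ≈ 1.0 — the SDs sit below 1 because the conditional response
distributions of three short items are platykurtic, not because of a
transform error.

**Item-trait interaction chi-square** (`item_trait_chi_square()`): persons
are ranked by $\hat\theta$ (ties broken by person index) and cut into
G equal-count class intervals (default 6); each item-by-interval cell
contributes $(\sum \text{obs} - \sum \text{exp})^2 / \sum \text{var}$, with
$df = n_{items}(G-1)$. G is a parameter rather than an adaptive rule because
published RUMM tables alternate between G values without documenting the
rule. The statistic is *conservative* under the null: the within-person
sum-to-zero constraint removes roughly one effective degree of freedom per
class interval, so at n = 500, G = 6 the empirical type-I rate at the 5%
level is about 1%, and null p-values are stochastically larger than uniform.
The test battery asserts near-nominal-but-small size and the absence of
anti-conservatism; a significant result therefore genuinely indicates
misfit.

**Reliability.** The person separation index
$PSI = (\mathrm{Var}(\hat\theta) - \overline{SE^2})/\mathrm{Var}(\hat\theta)$
accounts for targeting and can be negative when estimation error dominates —
exactly what happens when 85% of a cohort sits at the extreme totals and
enters with wide extrapolated estimates. Cronbach's
$\alpha = \frac{k}{k-1}(1 - \sum s_i^2 / s_T^2)$ moves the opposite way:
a mass of identical all-maximum response vectors inflates inter-item
covariance. On the default fixture the package reproduces this signature
(PSI with extremes < PSI without; $\alpha$ with extremes > $\alpha$
without), which is the substantive reason the analysis interprets PSI, not
$\alpha$, for skewed trauma cohorts.

**Threshold ordering.** `threshold_order_report()` flags each adjacent
threshold pair with $\delta_k \ge \delta_{k+1}$; a disordered pair means
some category is never modal along the trait
(`category_probability_curves()`, `never_modal()`). Detection power on the
designed disorder scenario (a never-modal middle category,
$\delta = (1, -1)$) is essentially 100% at n = 2,000.

**Four-sample design** (`run_sample_design()`): (1) the complete non-extreme
sample; (2) a random n = 500 from it, because very large samples overpower
fit statistics; (3) a random 10% of the full sample (floor rule), dominated
by extremes; (4) a random draw from sample 3 sized as
$\mathrm{round}(500/\text{valid fraction})$ so that roughly 500 *valid*
cases are included alongside their extremes. The draw size for sample 4
follows the "approximately 500 valid cases" reading, since a plain
500-record draw from an 85%-extreme sample would leave only ~75 valid cases
and no interpretable fit statistics.

## Rescoring

`published_rescore_map()` encodes the post-hoc amendment implied by the
threshold analysis: Eye 2–3 merge (eye opening to any stimulus), Verbal 2–3
merge (sounds or inappropriate words), Motor 2–4 merge (any movement other
than localizing), giving rescored maxima (2, 3, 3) and a 0–8 total. Because
the published coding table is typographically ambiguous about which original
columns align with which rescored codes, the map is pinned by the threshold
wording of the mortality-by-threshold table, which names each merged
category unambiguously.

The sensitivity-analysis engine (`enumerate_collapse_candidates()`,
`compare_rescorings()`) enumerates all order-preserving adjacent-category
merges that touch at least one disordered pair (erasing threshold $k$
touches disordered pairs $(k-1,k)$ and $(k,k+1)$), refits each candidate and
ranks by (no residual disorder, chi-square, PSI), breaking ties toward fewer
merges. Only adjacent merges are enumerated: non-adjacent merges would
destroy the ordinal structure of the response scale. The engine deliberately
stops at ranking — the published amendment combined statistics with clinical
judgement about category wording, which no enumeration can replicate.

## The synthetic registry

`generate_registry()` materialises a cohort with the published constants
built in exactly, not in expectation:

* **Counts.** 22,051 paediatric records (age < 18), 21,101 adult records
  with at least one blanked sub-score, and 321,203 complete adult records,
  so the sequential disjoint exclusions (paediatric first, then incomplete)
  reproduce the published accounting identically. The incomplete-GCS count
  is read as post-paediatric because only the disjoint sequential reading
  matches the printed arithmetic.
* **Joint GCS table.** The complete adults realise a 4×5×6 joint table
  (`build_joint_gcs_table()`) whose one-dimensional marginals equal the
  published per-category frequencies exactly, with the all-minimum cell
  pinned at a = 8,000 and the all-maximum cell at b = 264,786 so the
  non-extreme count is exactly 48,417. b is forced within ~4,400 of the
  Verbal-5 marginal; a is only bounded by the Motor-1 marginal (11,072) and
  was fixed mid-range at 8,000 for feasibility, keeping every residual
  marginal strictly positive. The interior is iterative proportional
  fitting from the independence seed with the two extreme cells as
  structural zeros, rounded to integers by largest-remainder on the grand
  total followed by single-unit repair moves along one axis at a time
  (moves along one dimension cannot disturb the other two marginals, so the
  repair is exact and terminates). Cells are then *allocated*, not sampled:
  count targets are exact by construction.
* **Demographics.** Sex ~ Bernoulli(0.559); adult age from a
  piecewise-linear quantile function through (0, 18), (0.25, 44.2),
  (0.5, 62.7), (0.75, 80.8), (1, 100), matching the published median and
  IQR; ISS from a discrete table with quartiles (9, 9, 17); body-region
  probabilities are configurable placeholders (Head 0.25, Limbs 0.30,
  Chest 0.18, Spine 0.08, Abdomen 0.05, Multiple 0.08, Other 0.04,
  Face 0.02) because the source's injury-profile appendix is not available.
* **Mortality.** 30-day death is generated from a logistic model on the
  *rescored* GCS total, $\mathrm{logit}(p) = \beta_0 - 0.45\,(T_{resc}-8) +
  \beta_{region}$ with a +0.5 offset for Head injuries, producing a
  monotone-decreasing mortality gradient across the rescored thresholds.
  $\beta_0$ is calibrated by bisection (`calibrate_mortality_intercept()`)
  so the mean expected mortality over the generated cohort equals 6.6%
  within 1e-6. Outcomes are then blanked at 4.65%, back-derived from the
  published modelling-sample fraction, so mortality among observed outcomes
  stays on target.

What the fixture deliberately does **not** emulate: correlation between
age/ISS and the GCS beyond the mortality link, injury mechanisms,
pre-hospital versus emergency-department score provenance, and any joint
GCS structure beyond the three marginals and the two pinned extreme cells.
Consequently, passing fixture tests demonstrates that the *machinery* is
correct and that the cohort-level constants are reproduced; it does not
validate the psychometric conclusions on real registry data, whose joint
response structure is unavailable. Because mortality is generated from the
rescored total, the fixture also builds in the prediction-equivalence
property by design — the experiments verify the pipeline can detect that
equivalence, not that it holds in nature.

`simulate_pcm()` is the second generator: model-faithful PCM responses at
configurable thresholds and person distribution, used for parameter
recovery (thresholds within 0.1 logit at n = 5,000), residual calibration
and power checks.

## Prediction experiments

`run_pipeline()` mirrors the two experiment families: (1) GCS features only
— sub-scores as categorical indicators plus the numeric total (categorical
coding keeps sub-scores and total jointly identifiable) — and (2) with
age, sex, ISS and region as additive effects, each fitted on original and
rescored scorings under 5-fold cross-validation after case-wise deletion of
missing outcomes. Logistic models use `glm.fit` with a ridge fallback
(penalty 1e-6, penalised IRLS) under separation; the random forest
(`ranger`) tunes its tree count over {100, 250, 500, 1000, 2000} by nested
3-fold CV on the inner Brier score, since tuning on the outer folds would
bias the comparison optimistically. Models are compared by the Brier score
with its empirical standard error, log loss (predictions clipped at 1e-15),
and a two-sided Wilcoxon signed-rank test on per-case squared-error
differences — case-level pairing is chosen for determinism and power; the
in-package exact method (a generating-function DP over doubled mid-ranks)
stays exact under ties, which the reference implementation does not.
`risk_difference_analysis()` reports, per threshold (2.5/5/10%), how many
cases change predicted risk by more than that amount, signed rescored −
original, with ISS/age-bin/region stratification of the exceeding cases.

## Numerical choices and degenerate inputs

* IPF convergence at relative 1e-10; margin repair is exact integer
  arithmetic afterwards.
* CML: gradient tolerance 1e-8, step-halving Newton, 200-iteration cap;
  per-item weight rescaling keeps the symmetric functions in range.
* Person root-finds bracket [-40, 40] logits at tolerance 1e-10.
* Bisection for the mortality intercept brackets [-20, 20] and errors if the
  target is unreachable there.
* Zero-variance residual cells are excluded and counted, not propagated as
  NaN; all-zero Wilcoxon difference vectors return p = 1 with a warning;
  empty class intervals and sub-G samples are refused.
* Seeds: every stochastic entry point takes an explicit seed;
  `run_pipeline()` expands its root seed as `seed + 1000 * stage`.

## Problem sizes used by the test battery

The shipped tests run the full 364,355-record fixture once (a few seconds),
200 null replicates at n = 500 for chi-square size, 100 replicates at
n = 2,000 for disorder detection and repair, parameter recovery at
n = 5,000, and the prediction-equivalence experiment on a one-tenth sample
of the fixture's modelling cohort (~30,600 cases); the full pipeline test
uses a 2% scaled configuration. These sizes keep the whole suite under a
minute while leaving every statistical check adequately powered.

## Known limitations

* CML and RUMM's pairwise estimator agree only asymptotically; published
  RUMM fit values are not numerically reproducible even with the real data,
  and the extreme-score extrapolation constant is a package choice.
* The chi-square remains conservative (documented above); its p-values are
  trustworthy for rejecting fit, not for calibrated type-I spending.
* Unidimensionality testing and differential item functioning by body
  region are out of scope (three items are too few for the former; the
  latter is flagged in the source analysis as future work).
* The fixture's region distribution and missingness mechanism are
  placeholders; conclusions that depend on them (e.g. region-stratified
  mortality tables) are qualitative only.
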