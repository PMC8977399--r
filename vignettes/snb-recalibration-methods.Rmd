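---
title: "Methods: standardized net benefit and targeted risk recalibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standardized net benefit and targeted risk recalibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(snbrecal)
```

This vignette records the statistical definitions, estimators, and numerical
conventions implemented in snbrecal, so that every number the package produces
can be traced to an explicit formula and an explicit tie-breaking rule.

## 1. Standardized net benefit

A risk model produces a score $S \in [0, 1]$ for a binary outcome
$Y \in \{0, 1\}$. A clinical policy treats patients whose score exceeds a
cutpoint $c$, and the intended policy uses the risk threshold $R$ as the
cutpoint. With disease prevalence $\pi = \Pr(Y = 1)$, the standardized net
benefit of the rule $S > c$ at threshold $R$ is

$$
\mathrm{sNB}(c) \;=\; \mathrm{TPR}(c) \;-\;
\frac{R}{1 - R}\,\frac{1 - \pi}{\pi}\,\mathrm{FPR}(c),
$$

where $\mathrm{TPR}(c) = \Pr(S > c \mid Y = 1)$ and
$\mathrm{FPR}(c) = \Pr(S > c \mid Y = 0)$. The factor
$(1 - R)/R$ is the benefit-to-harm ratio implied by the threshold:
`harm_benefit_ratio(0.075)` returns $0.925 / 0.075 \approx 12.33$, meaning
a true positive is worth about 12 false positives at a 7.5% threshold.
sNB is standardized so that a perfect rule (treat all cases, no controls)
scores exactly 1.

Conventions:

* The treatment rule is strict: a score exactly equal to the cutpoint is
  *not* treated. `snb_at_cutpoint()` and `snb_curve()` implement this with
  counting on sorted case/control scores, so the estimate is exact, not
  grid-approximated.
* `snb_curve()` evaluates sNB over the exact set of cutpoints at which the
  empirical step function can change: midpoints between adjacent distinct
  observed scores, together with 0 and 1. The empirical maximizer
  $\hat{r}^\ast$ is the cutpoint with largest sNB; ties are broken toward
  the cutpoint closest to $R$ (the intended policy).
* Scores are clipped into $[\varepsilon, 1-\varepsilon]$ with
  $\varepsilon = 10^{-10}$ on ingestion (`as_cohort()`) so logits are always
  finite.

### Standard error and the 1-SE assessment

The SE of the maximized sNB, $\widehat{\mathrm{sNB}}^{\max} =
\mathrm{sNB}(\hat{r}^\ast)$, is computed by the delta method treating the
prevalence estimate $\hat\pi$ as fixed and the case/control exceedance
proportions at $\hat{r}^\ast$ as independent binomials:

$$
\widehat{\mathrm{SE}}^2 = \frac{\widehat{\mathrm{tpr}}(1 -
\widehat{\mathrm{tpr}})}{n_{\text{case}}} \;+\; k^2\,
\frac{\widehat{\mathrm{fpr}}(1 - \widehat{\mathrm{fpr}})}{n_{\text{control}}},
\qquad
k = \frac{1 - \hat\pi}{\hat\pi}\,\frac{R}{1 - R}.
$$

This conditional-on-$\hat\pi$ form is a deliberate simplification; the test
suite verifies it agrees with a nonparametric bootstrap SE within 25% at
realistic sample sizes, which is adequate for its only use: the graphical
one-standard-error rule. `assess_potential_gain()` flags a model as a
recalibration candidate when its sNB at the intended threshold $R$ falls
strictly below $\widehat{\mathrm{sNB}}^{\max} - \widehat{\mathrm{SE}}$.
That same quantity is the constraint bound used by the constrained fit
(`snb_constraint_bound()`).

## 2. Recalibration maps

All recalibration maps are two-parameter logistic transforms of the score,

$$
S' = \operatorname{expit}\!\big(\alpha_0 + \alpha_1 \operatorname{logit} S\big),
\qquad \alpha_1 > 0,
$$

so recalibration never reorders patients. The slope is bounded below at
$10^{-6}$ (`ALPHA1_MIN`) to keep the map strictly increasing in floating
point.

### Standard fit

`fit_standard()` maximizes the Bernoulli log-likelihood of $Y$ given
$z = \operatorname{logit} S$ — ordinary logistic recalibration. It is
implemented with the same L-BFGS-B machinery as the weighted fit (the
standard fit is the unit-weight special case) and is cross-checked against
`stats::glm` in the test suite.

### Weighted fit

Ordinary recalibration spends fit capacity wherever the data are dense,
which may be far from the decision threshold. The weighted fit targets the
threshold by maximizing

$$
\sum_i w_i \big[ y_i \log p_i + (1 - y_i) \log (1 - p_i) \big],
\qquad p_i = \operatorname{expit}(\alpha_0 + \alpha_1 z_i),
$$

with weights that depend on each patient's *smoothed observed event rate*
$o(S_i)$ — a LOESS (degree 1, span 0.75, `surface = "direct"`, predictions
clipped to $[0,1]$) regression of $Y$ on $S$ — not on the raw score. Using
$o(S)$ concentrates weight on patients whose *actual* risk is near the
threshold, which is the region where a calibration error changes treatment
decisions.

Two weight families (`weight_spec()`):

* **exponential**: $w = \exp\{-(o(S) - R)^2 / \lambda\}$ everywhere; small
  $\lambda$ focuses sharply on the threshold, $\lambda \to \infty$ recovers
  the standard fit (verified in the tests: at $\lambda = 10^6$ the weighted
  coefficients match the standard ones to $10^{-3}$).
* **step**: full exponential weight inside a critical interval
  $[R_l, R_u]$ around the threshold and a constant floor $\delta$ outside.
  To keep the family coherent (no patient outside the interval may outweigh
  one inside), $\delta$ must not exceed the minimum in-interval weight
  $\exp\{-\max((R_l - R)^2, (R_u - R)^2)/\lambda\}$; violations error with
  the bound printed. The step family fixes $\lambda \ge 10$ so the
  in-interval weights are nearly flat.

The *effective sample proportion* $\bar w$ (mean weight) is reported so the
analyst can see how much data the weighting effectively discards. Patients
with a non-finite smoothed event rate receive the floor weight
conservatively. Complete separation of the positively weighted classes is
reported via `converged = FALSE` rather than an error.

### Constrained fit

The constrained fit maximizes the *unweighted* likelihood subject to the
recalibrated rule retaining near-maximal clinical utility:

$$
\max_{\alpha_0, \alpha_1 > 0} \; \ell(\alpha_0, \alpha_1)
\quad \text{s.t.} \quad
\widehat{\mathrm{sNB}}\big(\text{rule } S' > R\big) \;\ge\;
\widehat{\mathrm{sNB}}^{\max} - \widehat{\mathrm{SE}}^{\max}.
$$

Key structural fact: the rule $S' > R$ is equivalent to
$z > c(\alpha) = (\operatorname{logit} R - \alpha_0)/\alpha_1$, so the
constraint depends on $\alpha$ only through the induced cutpoint on the
logit-score axis, and the empirical sNB is a step function of that
cutpoint. The feasible set is therefore a finite union of half-open
cutpoint intervals, each translating to two linear inequalities in
$(\alpha_0, \alpha_1)$. `fit_constrained()`:

1. returns the standard fit unchanged whenever it already satisfies the
   constraint (exact equality of output in that case);
2. otherwise solves a concave maximization with linear constraints on each
   feasible interval via `stats::constrOptim` (BFGS, analytic gradients),
   nudging half-open endpoints inward by a relative $10^{-8}$;
3. returns the best interval's solution; likelihood ties are broken toward
   the solution whose induced cutpoint is closest to $\operatorname{logit} R$.

## 3. Cross-validated tuning and the 1-SE rule

`cv_select()` tunes $\lambda$ (exponential) or $\delta$ (step) by repeated
stratified K-fold cross-validation (defaults: 25 repetitions of 5 folds).
For each training fold the smoothed event rate, the weights, and the fit are
all recomputed from scratch — the held-out fold contributes only its sNB at
$R$ under the trained map. Fold draws are stratified by outcome and redrawn
(up to 100 times) if any training fold lacks both classes. Per-candidate
performance is the mean over folds, then over repetitions; its SE is the SD
across the 25 repetition means divided by $\sqrt{25}$.

Selection uses a one-standard-error rule oriented toward the standard fit:
among candidates within one SE of the best mean sNB, choose the one closest
to unweighted recalibration — the largest $\lambda$, or the $\delta$
nearest 1. Default candidate grids are $\lambda \in 10^{\{-4, \ldots, 1\}}$
(7 log-spaced points) and $\delta \in \{0.01, 0.1, 0.25, 0.5, 0.75,
\delta_{\max}\}$. All randomness is scoped with `withr::with_seed`, so a
seed makes the whole procedure reproducible without touching the caller's
RNG state.

## 4. Bootstrap optimism correction

Apparent sNB of a map fitted and evaluated on the same cohort is
optimistic. `bootstrap_optimism()` implements Harrell's correction: for
each of $B$ (default 500) bootstrap resamples, refit the entire procedure
(including smoothing, weighting, and tuning if the supplied procedure does
so) on the resample, and record

$$
\text{optimism}_b = \mathrm{sNB}_b(\text{fit}_b \text{ on resample}) -
\mathrm{sNB}(\text{fit}_b \text{ on original}).
$$

The corrected estimate is apparent sNB minus mean optimism; a percentile
interval over the bootstrap apparent values is also reported. Resamples
missing a class are redrawn; if more than 10% of $B$ must be redrawn the
procedure aborts. Passing a named list of procedures evaluates all of them
on the *same* resampling stream, making method comparisons paired. Passing
an already-fitted `recal_model` freezes it: a frozen map is never refitted,
so its optimism is the resampling variability of evaluation only.

## 5. Simulation engine

`simulate_cohort()` draws true risks $p$ from a Beta mixture, outcomes
$Y \sim \text{Bernoulli}(p)$, and reported scores $s = g(p)$ through a
monotone miscalibration map $g$, so the true conditional calibration
structure of the cohort is known exactly: $\Pr(Y = 1 \mid S = v) =
g^{-1}(v)$.

The shared default mixture is Beta(2, 10), Beta(6, 9), Beta(9, 4) with
mixing proportions 0.45, 0.35, 0.20 (mean true risk
$\sum_m b_m \alpha_m/(\alpha_m + \beta_m) \approx 0.3535$), representing
low-, medium-, and high-risk subpopulations around a working threshold of
$R = 0.3$.

Miscalibration maps are monotone piecewise cubic Hermite interpolants
(Fritsch–Carlson slope limiting, implemented with explicit per-segment
polynomial coefficients in `piecewise_poly` form) through archetype control
points. Construction validates monotonicity and range $[0, 1]$ on a
10,000-point grid of the *unclipped* polynomial, so an invalid map cannot
be smuggled past validation by clipping. Four shipped archetypes:

* **example1** — underestimates near the threshold, overestimates at the
  extremes (an "S" around the diagonal);
* **example2** — underestimates everywhere;
* **example3** — overestimates near the threshold, underestimates at the
  extremes;
* **example4** — overestimates everywhere.

The control points are a design choice of this package: they are placed so
that each archetype's miscalibration is strong enough *near the threshold*
to move the induced treatment decision materially. This matters because
sNB is locally flat in the cutpoint around its maximum — a map that only
mildly perturbs scores near $R$ produces an invisible utility loss, making
the scenario useless for studying recalibration. Every preset field
(shapes, mixing, map) can be overridden through `make_scenario()`, so
externally specified scenario parameters can be substituted directly.

## 6. Numerical and reproducibility conventions

* Risk clipping $\varepsilon = 10^{-10}$; slope floor $10^{-6}$.
* Strict ">" treatment rule everywhere; half-open feasible intervals
  nudged inward by relative $10^{-8}$ before optimization.
* LOESS: degree 1, span 0.75, `surface = "direct"`, at least 20 distinct
  scores required, predictions clipped to $[0, 1]$.
* Ties: curve argmax toward the cutpoint nearest $R$; constrained-fit
  likelihood ties toward induced cutpoint nearest $\operatorname{logit} R$;
  1-SE rule toward the standard fit.
* All seeded randomness goes through `withr::with_seed`.
* In our own validation experiments we fit on cohorts of 5,000 and evaluate
  on independent draws of $10^6$ with $R = 0.3$ and critical interval
  $[0.25, 0.35]$; these sizes keep Monte-Carlo noise in validated sNB below
  about $10^{-3}$.

## Limitations

The delta-method SE conditions on the estimated prevalence and ignores the
randomness of $\hat{r}^\ast$; it is a screening quantity, not a confidence
procedure. The recalibration family is two-parameter logistic, which cannot
repair non-monotone miscalibration. The shipped simulation archetypes are
qualitative patterns, not estimates of any particular clinical model.
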