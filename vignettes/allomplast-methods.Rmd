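---
title: "Measuring organ-specific nutritional plasticity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring organ-specific nutritional plasticity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allomplast)
```

## The scientific problem

When a holometabolous insect such as *Drosophila* develops under poor
nutrition, the adult is small — but not uniformly so.  Some organs (wings,
maxillary palps) shrink roughly in proportion to the body; others (the male
genitalia) are buffered and barely respond.  The standard way to quantify
this organ-specific plasticity is the **allometric coefficient** *b*: fit a
straight line to log organ size against log body size across individuals
whose size variation is caused by nutrition, and read off the slope.

* *b* ≈ 1: the organ scales proportionally with the body (full plasticity);
* *b* < 1: the organ is under-responsive to nutrition (buffered);
* *b* > 1: the organ is hyper-responsive.

Everything in this package is built around estimating *b*, comparing it
between organs, genotypes and rearing conditions, and testing hypotheses
about how it changes — plus proliferation-rate statistics for the mitotic
clone experiments used to localize growth differences to specific imaginal
discs.

## Standardized major axis estimation

Both axes of a scaling plot are measured with biological and technical
error, so ordinary least squares — which treats x as fixed — systematically
flattens the slope.  We therefore use the **standardized major axis**
(SMA), the classical model-II estimator for allometry:

$$ \hat b = \operatorname{sign}(r)\,\frac{s_y}{s_x}, \qquad
   \hat c = \bar y - \hat b\,\bar x, $$

with $r$ the Pearson correlation and $s_x, s_y$ the sample standard
deviations.  Equivalently, $\hat b$ minimizes the summed triangle areas
between points and line (the loss that penalizes both axes symmetrically);
the test suite checks the closed form against a brute-force minimizer of
that loss.  The slope magnitude is exactly $s_y/s_x$, the estimator is
symmetric under axis exchange ($b_{yx} = 1/b_{xy}$), invariant to
translation and to the base of the logarithm, and equivariant under axis
scaling.

The slope confidence interval uses the standard correlation-based
construction

$$ B = \frac{F_{1-\alpha;\,1,\,n-2}\,(1 - r^2)}{n-2}, \qquad
   \mathrm{CI} = \hat b\left(\sqrt{B + 1} \pm \sqrt B\right), $$

which is exact under bivariate normality and collapses to a point at
perfect collinearity.  A correlation of exactly zero is an error, not a
silent sign choice: the SMA slope sign is undefined there.

### Common-slope tests

To ask whether two or more groups share a scaling slope we use the
likelihood-ratio construction for SMA: for a candidate common slope $b$,
the residual scores $y - bx$ and axis scores $y + bx$ are uncorrelated in
a group exactly when $b$ equals that group's SMA slope, so

$$ \Lambda(b) = \sum_i -(n_i - 2.5)\,\log\!\big(1 - r_i(b)^2\big) $$

is minimized over $b$ (to 1e-10) and the minimum referred to
$\chi^2_{g-1}$.  The $-2.5$ is the Bartlett-type small-sample correction
of the standard SMA common-slope formulation; the null calibration check
(2,000 simulations, two groups of 50) verifies that the empirical size at
$\alpha = 0.05$ lies inside the binomial 99% band.

A permutation variant is provided as an assumption-light cross-check: each
group is centered at its bivariate mean, the centered points are pooled and
reallocated to groups of the original sizes, and the same statistic is
recomputed.  Seeds are mandatory for every resampling method in the
package; a permutation result that cannot be reproduced is not a result.

## Plasticity analyses

`compare_organ_plasticity()` fits per-organ coefficients against a common
reference and runs all pairwise common-slope tests, Holm-adjusted (a
reusable pipeline should control family-wise error even though single
comparisons are often reported unadjusted; both are
emitted).  Effect sizes of a perturbation (`relative_size_effect()`) are
mean ratios on the raw scale — matching how "a ~30% reduction" is
naturally stated — with seeded percentile-bootstrap intervals (2,000
resamples of individuals within group).  The organ-by-treatment
interaction (`differential_effect_test()`) works on log sizes, where equal
proportional change in two organs gives an interaction of exactly zero,
and permutes treatment labels of whole individuals; on toy inputs the
permutation p agrees with exhaustive enumeration of all label
assignments.  This permutation-and-bootstrap pair deliberately replaces
the mixed-ANOVA-plus-Tukey summaries common in the source literature: the
permutation analogue needs no variance-structure assumptions and is
testable against enumeration.

`quadratic_trend()` is a plain least-squares quadratic with a pointwise
confidence band, for hump-shaped relationships between plasticity and an
expression level; it reports the fitted extremum location.

## Normalizing scaling relationships across temperatures

Rearing temperature shifts both mean sizes and scaling slopes, so scaling
relationships measured at different temperatures are not directly
superimposable.  The normalization implemented here makes the *control*
relationships coincide while transporting the experimental animals
rigidly along:

1. **Translate** all rows of a condition by one offset so that the
   bivariate mean of its anchor subset (the un-starved controls) equals
   the reference condition's anchor mean.
2. **Rotate** all rows of the condition about that anchor so the control
   subset's SMA slope equals the reference control slope.

Both steps are rigid motions in log-size coordinates, so all
within-condition pairwise distances — and hence every experimental
animal's position relative to its own controls — are preserved, and the
procedure is idempotent.  Two numerical choices deserve note:

* The rotation acts in **log coordinates**.  Slope-matching by rotation is
  only angle-consistent in a fixed frame, and log-log space is the frame
  in which the scaling relationship is linear.  A shear could also equalize
  slopes but would not preserve distances; "rotation" is taken literally.
* A rigid rotation maps the slope of a *collinear* set exactly, but for a
  noisy cloud the SMA slope after rotating by
  $\theta = \arctan b_\text{target} - \arctan b_\text{current}$ differs
  slightly from the target (the sd ratio is not equivariant under
  rotation).  The implementation therefore re-fits after rotating and
  refines $\theta$ by fixed-point iteration until the control slope
  matches the target to 1e-9 (typically 2–4 iterations).  The composed
  map is still a single rigid rotation; the iteration count is recorded
  in the returned transform for audit.

## The slope-trend permutation test

To test whether plasticity changes monotonically with a covariate
(rearing temperature), each covariate group is centered at its bivariate
mean — which leaves its SMA slope untouched and makes the pooled points
exchangeable under the null — and the observed statistic is the OLS
coefficient $b_\mathrm{obs}$ of per-group SMA slope on covariate value.
Each of the (default 1,000) permutations reallocates the pooled centered
points to groups of the original sizes without replacement, keeping the
covariate values attached to the groups, and recomputes the coefficient.
The default lower-tail p-value is the raw proportion of permuted
coefficients ≤ the observed one, ties counted as extreme; because the raw
proportion can be zero, the add-one estimate $(k+1)/(n_\mathrm{perm}+1)$
is always reported alongside.  Permuted allocations that produce a
degenerate group (zero variance, or exactly zero correlation) have no
defined SMA slope; they are redrawn and the redraw count reported — at
realistic sample sizes redraws essentially never occur.

The test is validated three ways: exact agreement with full enumeration
of all assignments on a 6-point toy problem; approximate uniformity of
null p-values (Kolmogorov–Smirnov); and empirical size at
$\alpha = 0.05$ inside the binomial 99% band.

## Clone proliferation statistics

A clone founded by one labelled cell dividing at rate $r$ for $t$ hours
contains $\approx e^{rt}$ cells, so each clone's rate is $\log(N)/t$
(natural log; `base = 2` re-expresses rates as doublings per hour — the
base is a constant factor and is recorded with every estimate).  Clone
ages are taken per record; no common-age assumption is made.

Clones are nested in larvae, and larvae — not clones — are the
independent units.  `estimate_rates()` therefore uses a two-stage
estimator: clone rates are averaged within each larva (per disc type),
and the group estimate is the unweighted mean of larva means with its
standard error across larvae.  The point estimate is provably invariant
to how many clones each larva contributed, and a larva-level variance
component is reported by method of moments (variance of larva means minus
the expected clone-noise share, truncated at zero).  This transparent
two-stage construction replaces a REML mixed ANOVA with Tukey contrasts;
it is valid under the same nesting, and pairwise comparisons are
permutation tests on larva means with Holm adjustment — checked against
exhaustive enumeration on small designs.  Cells of a contrast must not
share larvae: measurements on the same animals are not exchangeable
units, and the function refuses such contrasts rather than permuting
invalidly.

## The synthetic-data generators

No raw measurements are distributed with the package, so seeded
generators supply data with exactly the structure the analyses assume.

**Allometry** (`simulate_allometry()`): a latent log body size per
individual (treatment mean ± biological spread) drives each organ's
latent log size through its true slope and intercept; genotype and
temperature act as additive offsets on the slope.  Observation noise is
added to *both* axes with the variance ratio
$\sigma_y^2/\sigma_x^2 = b^2$ — the identification condition under which
the SMA estimand equals the generating slope, so coverage and recovery
tests are well posed.  Defaults: genital $b = 0.55$ versus wing
$b = 1.0$ (the canonical control-fly contrast for these organs, with the
mutant genital slope 0.93 available through the `foxo_mutant` scenario); latent log-body
sd 0.3 with treatment means 5.0 (fed) and 4.7 (starved), which makes
starvation shrink the wing by ~26% and the genitalia by ~15%, the
magnitudes reported for these organs; axis noise sd 0.15, giving
$r^2 \approx 0.8$, chosen to reproduce the relative width of slope
confidence intervals reported for such data (0.45–0.68 around 0.55) at
desk-scale n.  The temperature scenario uses four rearing temperatures
(17, 20, 23, 25 °C) and a default wing-slope trend of −0.0105 per degree,
the magnitude reported for wild-type flies.

**Clones** (`simulate_clones()`): per genotype, 8–10 larvae; per larva a
normal random effect on rate (sd 0.005 h⁻¹, ~6% of the control rate);
per disc 5–30 clones with independent clone-level rate noise (sd
0.01 h⁻¹) and ages uniform on 44–52 h; cell counts
$\max(1, \mathrm{round}(e^{rt}))$ — a clone always contains its founder.
The control rate defaults to $\ln(64)/48 \approx 0.0866\,h^{-1}$
(64-cell clones at 48 h, an 8-hour effective doubling time); the
IIS-mutant genotype is slowed in the wing and eye-antennal discs (0.068)
much more than in the genital disc (0.082), and its cell areas are
reduced ~10%.  Design constants (larvae per genotype, clones per disc,
clone ages) follow the reference experimental design; rate noise
magnitudes are package defaults chosen to keep desk-scale tests
informative.

### What the generators do and do not emulate

They reproduce the *statistical* structure — lognormal sizes, error on
both axes in the SMA-consistent ratio, slope heterogeneity, larva-level
clustering, integer cell counts.  They do not emulate measurement-protocol
artefacts (digitization error, allometry curvature at size extremes,
non-normal larva effects, clone competition or apoptosis).  Passing tests
therefore demonstrate that the estimators recover what the model says they
should and that the tests hold their error rates under the stated
exchangeability — not that any particular biological dataset satisfies
those assumptions.

## Problem sizes and determinism

The validation suite uses desk-scale simulation sizes chosen to make the
Monte-Carlo error small relative to the property being checked: 100
random datasets for the loss-minimizer oracle, 1,000 simulations for CI
coverage at n = 50, 2,000 null simulations for test size, 200 replicates
for the genotype-contrast reconstruction, 500 runs for trend-test
uniformity, and 500 replicates for clone-rate recovery.  Every stochastic
routine requires an explicit integer seed and touches only R's global RNG
through `set.seed()` at entry, so identical calls are bit-reproducible.

One validation bound is worth flagging: a ±2·SE recovery check on a group
estimated from k larvae has Student-t, not normal, coverage —
$P(|t_7| \le 2) \approx 0.914$ through $P(|t_9| \le 2) \approx 0.923$ —
so with 8–10 larvae per genotype the attainable coverage of that check is
~92%, whatever the noise magnitudes.  The estimator is unbiased and its
standard error is honest; the shortfall is a property of the 2·SE rule at
small k, and the package reports it rather than widening the interval.

## Known limitations

* SMA is appropriate when both axes carry comparable relative error; with
  very asymmetric error structures the allometric coefficient estimand
  differs from the functional slope.
* The common-slope chi-square reference is asymptotic; below ~15 points
  per group prefer the permutation method.
* The anchor normalization assumes the condition effect is a rigid
  displacement-plus-tilt of the whole scaling relationship; curvature or
  variance changes across conditions are not corrected.
* The two-stage clone estimator gives each larva equal weight; with very
  unequal clone counts a weighted estimator would be more efficient
  (but not design-consistent under larva-level confounding).
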