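---
title: "Methods: directional asymmetry inference for vestigial hindlimbs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directional asymmetry inference for vestigial hindlimbs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dasym)
```

## The scientific problem

In bilateral structures, *directional asymmetry* (DA) is a population-level
bias toward one side; *fluctuating asymmetry* (FA) is random individual
left–right deviation around symmetry. In hindlimb development, Pitx1 drives
outgrowth symmetrically while its paralog Pitx2 is expressed more strongly
on the left; when Pitx1 function is reduced — as in pelvic-reduced
stickleback — the left bias of Pitx2 is unmasked and left-larger vestiges
result. `dasym` implements the statistical side of testing for that
signature in limb-reduced squamates: given left and right lengths of a
vestigial pelvis or femur across many museum specimens, is there a
consistent side bias in *how often* one side is larger (frequency) and in
*how much* (magnitude)?

The package assumes per-specimen bilateral lengths as its central data
structure; upstream of that it handles only landmark files (MeshLab
picked-points XML), because that is the interchange point between
interactive digitization and reproducible analysis. CT acquisition,
surface reconstruction, and the digitization itself are out of scope.

## The measurement model

An element's length is the Euclidean distance between its two landmarks,
**rounded half-to-even to 2 decimal places in mm, once, at measurement
time**. All downstream statistics consume the rounded values. This is a
deliberate modelling choice with a visible consequence: percent asymmetry

$$PA = 100\,\frac{R - L}{R + L}$$

(also reported at 2 dp) can be exactly 0.00, and those specimens form a
third, *symmetric*, class — counted in N, excluded from the frequency
test, included in the paired t. PA is antisymmetric in its arguments and
scale-free, so pooling specimens of different body size is valid exactly
when asymmetry is isometric with size; the package does no allometric
correction, making that assumption explicit rather than adjusting for a
covariate (sex is likewise unmodelled — it is rarely scorable on dried or
fluid museum specimens without dissection).

Negative PA means left-larger. That sign convention propagates everywhere:
the paired t is computed on $d_i = R_i - L_i$, so $\mathrm{sign}(t) =
\mathrm{sign}(\overline{PA})$, and a left-biased taxon prints a negative
mean PA and negative t.

## The frequency statistic

The headline test asks whether left-larger and right-larger counts
$(n_L, n_R)$ deviate from 50:50. The implemented statistic is **not** the
textbook one-sample goodness-of-fit. It is the chi-square computed on the
2×2 table

$$\begin{pmatrix} n_L & n_R \\ E & E \end{pmatrix},
\qquad E = \frac{n_L + n_R}{2},$$

with cell expectations $\hat E_{ij}$ from the table margins and the Yates
continuity correction,

$$\chi^2_1 = \sum_{ij} \frac{(\,|O_{ij} - \hat E_{ij}| - 1/2\,)^2}{\hat E_{ij}},$$

clamping $|O - \hat E| - 1/2$ at zero. The second row may hold
half-integral "observations"; the margins absorb them. Algebraically every
cell has the same deviation $|n_L - n_R|/4$, which yields two useful exact
facts, both tested:

* the statistic depends only on the unordered pair $(n_L, n_R)$;
* it is exactly 0 whenever $|n_L - n_R| \le 2$.

This construction was chosen because it is the one that reproduces, to the
printed 2 dp, all nine published chi-square statistics in the squamate
vestige count table shipped with the package (`vestige_counts()`) —
including the half-integral-expectation rows — whereas the plain
goodness-of-fit does not (48 vs 70 gives 4.10 uncorrected versus the
printed 1.71). The uncorrected statistic is roughly twice the corrected
one here, so the choice matters materially; both it and an exact binomial
test remain available via `method =` so users can see the sensitivity.
The correction makes the test conservative: at $n = 100$ informative
specimens it rejects at $\alpha = 0.05$ only when the counts split at
least 65:35, an exact type-I rate of about 0.004. The package's
Monte-Carlo calibration (`recovery_experiment()`) measures ~0.005 under
the null, and the paired t about 0.05 — worth knowing when interpreting a
non-significant frequency test next to a significant t.

## Outlier screens

Two 3-SD screens are provided, both **single-pass**: the group mean and
sample SD (n − 1 denominator) are computed once from all non-excluded
values, then values with $|x - \bar x| > 3s$ (strict inequality) are
flagged. No re-estimation after flagging — iterating would make the rule
order-dependent and progressively greedy, and nothing in the screening
rationale requires it.

* `flag_length_outliers()` screens raw lengths per taxon × element ×
  **side**. Sides are separated because genuine directional asymmetry
  inflates a pooled SD and would mask errors.
* `flag_asymmetry_outliers()` screens PA per taxon × element. It is off
  by default (`dasym(..., filter_asymmetry = TRUE)` enables it): the
  primary analysis convention screens lengths only, with the PA screen as
  a post hoc robustness check.

A flagged record is excluded whole — both sides — because asymmetry needs
both; the same specimen's other element is retained. Whether the analyst
removes the value or re-digitizes is a human decision: the package only
flags and reports (`exclusions.csv`, the pipeline log), and clearing the
`excluded` flag un-excludes a record. Groups with fewer than 3 usable
values are not screened (an SD from 2 points flags nothing sensibly).

## Magnitude test and multiple testing

The paired t runs on raw length differences by default. On genuinely
bilateral data the alternative — testing the PA values against zero
(`t_on = "pa"`) — gives the same sign and usually similar inference, but
weights each specimen equally instead of proportionally to its size; raw
lengths were chosen as the default because the magnitude question is
phrased in mm, not in percent. Zero-variance differences leave t
undefined and are reported as `NA`, never coerced to 0.

Each statistical approach (frequency, magnitude) forms its own Bonferroni
family: with m taxon × element comparisons the corrected threshold is
$\alpha/m$ (0.05/9 ≈ 0.006 for the nine shipped comparisons). The family
size defaults to the number of comparisons in the fitted object and can
be fixed with `n_tests` when an analysis is part of a larger family.

## Power analysis

`chisq_power()` evaluates $P[\chi^2_{df}(\lambda) > \chi^2_{df,1-\alpha}]$
with noncentrality $\lambda = N w^2$, using R's noncentral chi-square
distribution functions; at $w = 0$ it returns $\alpha$ exactly (the null
*is* the alternative, and floating-point round-trip through the quantile
function should not obscure that identity). N is the count of informative
(asymmetric) individuals, the same N that enters the frequency test. At a
moderate effect $w = 0.25$ power at $N = 60$ is 0.491; the smallest N
exceeding power 0.50 is 62 — hence the planning rule of thumb that
samples beyond 60, in practice ≥ 80 specimens per taxon, are needed for
even coin-flip power at moderate effects. `chisq_power_n()` inverts the
curve by exponential bracketing + bisection (power is strictly monotone
in N), and a Monte-Carlo oracle in the test suite — $10^6$ draws of
$(Z + \sqrt\lambda)^2$ against the 3.841 critical value — pins the
implementation to within 3 Monte-Carlo standard errors.

## What the synthetic generator emulates — and what it does not

`simulate_measurements()` makes PA, not the raw side difference, the
generative primitive: per specimen, size $S_i = \mu_S e^{\epsilon_i}$
with $\epsilon_i \sim N(0, cv^2)$ (lognormal: positive lengths,
CV-parameterized), true asymmetry $P_i \sim N(\mu_{PA}, \sigma_{PA}^2)$,
and

$$R_i = S_i(1 + P_i/100), \qquad L_i = S_i(1 - P_i/100),$$

so `percent_asymmetry(L, R)` returns $P_i$ exactly before rounding, and
the true parameters live on the same percent scale as the reported
"mean PA (SD)" summaries. Gross errors are injected by multiplying one
random side by `outlier_scale` with probability `outlier_rate`.
`simulate_landmark_files()` renders measurements as picked-points files —
two landmarks per side at exactly the stated separation, under a random
rigid transform per specimen, plus optional isotropic Gaussian
digitization noise — so the parse → map → measure path is exercised end
to end; at zero noise the round trip is exact at 2 dp.

Defaults (`mean_size = 10` mm, `size_cv = 0.15`, `sigma_pa = 1`) are of
the order observed in real vestige samples, where reported PA standard
deviations run from 0.6 to 7 percent; validation scenarios in the tests
and acceptance script instead take their parameters directly from the
shipped count table (e.g. the strongest reported magnitude regime, mean
PA −0.64, SD 1.62, n = 72, where the paired t's analytic power is ≈ 0.9).

The generator emulates the *statistical* structure the tests assume:
independent specimens, Gaussian FA on the percent scale, size-independent
asymmetry, landmark noise isotropic and independent per point. Real
museum samples violate several of these in ways the generator
deliberately does not model: ossification and age structure, litter or
locality clustering, asymmetric breakage, digitizer drift between
sessions, and any size-dependence of asymmetry. Passing the recovery
experiments therefore demonstrates correctness of the *pipeline and
tests under their own assumptions*, not robustness of the biology to
those violations.

## Numerical and design choices

* **Rounding**: half-to-even (base `round`) at 2 dp, applied once.
  Downstream exactness tests use `expect_identical` on the rounded
  values.
* **Ties/degenerate inputs**: zero-variance groups flag no outliers; a
  fully symmetric sample has no frequency test (error on
  $n_L + n_R = 0$, `NA` in the assembled summary) and an undefined t;
  `percent_asymmetry` refuses $L + R = 0$.
* **.pp dialect**: points are read by attribute (`x`, `y`, `z`, `name`,
  `active`) anywhere under the root; unknown elements and attributes are
  ignored (exporter versions vary); inactive points are parsed but never
  mapped. Writing uses 17 significant digits so parse ∘ write is the
  identity on doubles.
* **Name mapping** is config-driven regex rules, not positional order —
  no export order is assumed; unmatched names are reported, duplicate
  anatomical assignments are an error.
* **Seeding**: every generator takes a single integer seed and seeds the
  RNG locally (the caller's `.Random.seed` is restored), so runs are
  reproducible and composable.
* **Problem sizes** in the shipped validation: 500 replicates for the
  signal-regime power check, 1000 replicates of n = 100 for null
  calibration, 1000 random count pairs against the brute-force
  chi-square oracle, $10^6$ Monte-Carlo draws for the power oracle —
  large enough that the 3-SE agreement bands are a fraction of a percent.

## Known limitations

* The per-specimen raw data behind the shipped count table are not
  included, so the published t statistics, means and SDs cannot be
  recomputed here; only the count-based frequency statistics can (all
  nine reproduce exactly). Magnitude-side correctness is established on
  synthetic data instead.
* The frequency test's conservatism at small-to-moderate N is inherent
  in the continuity-corrected construction; users wanting nominal size
  should use `method = "binomial"`.
* One element per simulated taxon per call; multi-element taxa are built
  by repeated calls sharing specimen ids, as in the examples.
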