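---
title: "Dose estimation from gamma-H2AX focus counts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose estimation from gamma-H2AX focus counts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h2axdose)
library(dplyr)
```

## The problem

Within minutes of exposure to ionizing radiation, phosphorylation of the
H2AX histone produces microscopically countable foci at DNA double-strand
breaks. The number of foci per blood lymphocyte rises approximately
linearly with absorbed dose, which makes the assay attractive for rapid
triage after a radiological incident: score a few tens to hundreds of
cells from a finger-prick sample and read the dose off a calibration
curve. Two statistical steps are involved — estimating the calibration
curve from laboratory data, and inverting it at an observed yield — and
the difficulty lies almost entirely in the uncertainty quantification.
`h2axdose` implements both steps for homogeneous (whole-body) exposures,
together with the reference-sample validation logic that decides whether a
laboratory's calibration curve can be trusted for a new scorer, scope, or
shipment condition.

## The calibration model

Let $Y_{ij}$ be the total focus count of sample $j$ at design dose $x_i$,
scored over $n$ cells, and $y_{ij} = Y_{ij}/n$ the yield in foci per cell.
The dose response is modelled as

$$\mu_i \equiv E(y_{ij} \mid x_i) = A + B x_i,$$

an identity-link model on counts: $Y_{ij} \sim \text{Pois}(n(A + B x_i))$
up to dispersion. Focus counts are strongly *overdispersed* relative to
the Poisson law — empirical variance/mean ratios of 50–60 are typical for
manually scored foci, driven by intra- and inter-individual variability —
so the package fits the model as a quasi-Poisson: the score equations

$$\sum_{i,j} \binom{1}{x_i} \frac{Y_{ij} - n(A + Bx_i)}{A + B x_i} = 0$$

do not involve the dispersion $\varphi$, so point estimates coincide with
the plain Poisson fit, while the standard errors are inflated by
$\sqrt{\hat\varphi}$ with

$$\hat\varphi = \frac{1}{N - p} \sum_{i,j}
  \frac{(Y_{ij} - n\hat\mu_i)^2}{n\hat\mu_i},$$

the Pearson estimate with $p$ mean parameters (2 for a linear fit, 3 for a
quadratic or joint fit). Unequal cells per sample are supported by
carrying $n$ per row through the weights.

`fit_calibration()` solves the score equations by Fisher scoring on the
counts (iteratively reweighted least squares with working weights
$n/\mu$). Numerical choices:

* **Starting values** are ordinary least squares of yields on dose; the
  weights are near-constant at moderate yields, so OLS starts close to
  the solution. If the OLS line dips non-positive anywhere in the design,
  the intercept is shifted up just enough before iterating.
* **Step control**: each update is halved until all fitted means stay
  positive *and* the Poisson deviance does not increase. The deviance
  guard matters: identity-link Poisson scoring can oscillate when a
  fitted mean approaches zero and its working weight blows up.
* **Convergence** is declared at a relative parameter change or relative
  deviance change below `tol` (default `1e-8`), capped at `max_iter`
  (default 100) iterations, after which a `h2ax_fit_failure` condition is
  raised — a fit is never silently truncated.

The same machinery fits the two-stratum joint model
$E(y) = a + b_1\,\text{dose} + b_2\,\text{dose}\cdot 1\{\text{late
stratum}\}$ (`fit_joint_model()`). The shared intercept encodes that the
background yield cannot depend on "time after exposure" when there was no
exposure; the late stratum's slope is $b_1 + b_2$, with its standard
error taken from the full covariance of $(b_1, b_2)$.

`donor_effect_test()` addresses whether donors must be modelled: it adds
a donor factor after dose and the dose-by-time interaction and refers the
donor-explained Poisson deviance, scaled by the full model's Pearson
$\hat\varphi$, to $\chi^2$ with (donors − 1) degrees of freedom. A
non-significant result supports folding all individual variability into
the single dispersion parameter, which is the package's working
assumption.

## The dispersion index

$\varphi$ plays a different role from $A$ and $B$. The curve parameters
are experiment-specific constants to be pinned down as precisely as
possible; $\varphi$ is a property of focus scoring at large, and for a
new customer sample it is usually neither known nor estimable. The
package therefore resolves $\varphi$ in a fixed order: an explicit
argument, else the curve's own fitted value, else the conservative
consensus default **60** (for manually scored foci) with a `DEFAULT_PHI`
warning code. Since $\varphi$ enters all uncertainty formulas under a
square root, moderate misspecification is dampened.

## Dose estimation and the variance decomposition

Given a curve $\{\hat A, \hat B, SE(\hat A), SE(\hat B)\}$ and a customer
sample with yield $y_*$ over $n_*$ cells, the dose estimate is the
inverse-regression value $x_* = (y_* - \hat A)/\hat B$. Its uncertainty
is propagated by the covariance-free delta method:

$$SE^2(x_*) = \frac{SE^2(\hat A)}{\hat B^2}
  + \frac{(y_* - \hat A)^2}{\hat B^4} SE^2(\hat B)
  + \frac{\hat\varphi\, y_*}{n_* \hat B^2}.$$

The three additive components — intercept, slope, and sampling — are
reported per estimate (`estimate_dose()`, `variance_decomposition()`),
so the dominant uncertainty source is always visible. Covariance terms
are deliberately omitted (they are small relative to the variance terms
in this setting) and there is no option to include them. Negative dose
estimates are reported as-is with a `BELOW_ZERO` flag: a slightly
negative value is evidence of an unexposed sample, and clipping would
bias averages of repeated estimates.

Quadratic curves ($E(y) = A + Bx + Cx^2$, saturating with $C<0$) are
supported for fitting and for the variance decomposition only, not for
routine estimation. The inversion takes the smaller positive root of
$Cx^2 + Bx + (A - y_*) = 0$ and obtains the partial derivatives by
implicit differentiation ($\partial x_*/\partial C = -x_*^2/(B + 2Cx_*)$,
etc.), verified in the tests against numerical differentiation. Two
findings from this decomposition motivate the package's linear-only
estimation policy: the quadratic term's variance grows explosively as the
yield approaches the saturation level $A - B^2/(4C)$, where the total
variance dwarfs the linear model's; away from saturation our arithmetic
puts the sampling term first at typical yields, so the quadratic term
buys nothing and can cost everything.

## Reference samples, validation, and the reference curve

Calibration curves are specific to laboratory, scorer, technology, and
shipment conditions. Before using a curve for a customer, two *reference
samples* scored under the customer's own conditions are checked against
it: a negative control at 0 Gy and a positive control at a known dose
$x_r$ (typically 1.5 Gy). Each is compared with an approximate
quasi-Poisson prediction interval at its dose,

$$\hat A + \hat B x \pm q_{\text{crit}}
  \sqrt{\frac{\hat\varphi (\hat A + \hat B x)}{n'}},$$

with $q_{\text{crit}} = 3$ for the negative control (more leeway for the
small background, which rarely justifies discarding an established curve)
and $q_{\text{crit}} = 2 \approx$ 95% for the positive control, whose
slope information is what matters. There are two yields to check but one
decision: the curve is discarded as a whole if either falls outside. A
yield exactly on an endpoint counts as inside (conservative toward
retaining the curve). Replicate reference samples at a common dose are
pooled as total foci over total cells; at 0 Gy the pooling may span time
labels, since the time label is meaningless without exposure. $\varphi$
is never estimated from the reference samples themselves — two yields
cannot support a dispersion estimate — and only the two-dose (0, $x_r$)
layout is accepted; more reference doses are rejected with a clear
message rather than silently regressed.

When validation fails, the two reference points determine a replacement
line in their own right: $\tilde A = y_0$, $\tilde B = (y_r - y_0)/x_r$,
with quasi-Poisson standard errors
$SE(\tilde A) = \sqrt{\varphi y_0 / n_0}$ and
$SE(\tilde B) = \sqrt{\varphi (y_0/n_0 + y_r/n_r)}\,/\,x_r$. These are
unbiased for the customer's conditions but much noisier than a fitted
curve — often still precise enough for triage. Bayesian or weighted
hybrid updating of the calibration curve with reference information is
out of scope. The *reference sample ratio*
$(\hat A + \hat B x_r)/y_r$ is reported as a diagnostic only; the
workflow never applies it as a multiplicative correction, leaving that
judgement to the laboratory.

`resolve_curve()` wires these pieces into the decision logic used by the
estimation front end: calibration data, when supplied, are fitted and win
over an explicitly supplied curve (`DATA_OVERRIDES_CURVE` — a fitted
curve carries its own SEs and dispersion); missing SEs are substituted by
0 (`MISSING_SE`) and missing dispersion by 60 (`DEFAULT_PHI`), both
applied together when a bare curve is supplied; with reference samples
the curve is validated and, on rejection, replaced by the reference
curve; without them it is used uncontested with `NO_REFERENCE`. Every
substitution emits exactly one machine-readable code, and each estimate
records the provenance of the curve that produced it
(`validated_calibration`, `reference_curve`, or
`unvalidated_calibration`). Per-sample time labels select among supplied
per-time curves; a label without a matching curve is an error, never a
silent fallback.

## The synthetic-data generator

All distributional tests run on data from `simulate_calibration()` and
`simulate_customer()`, which emulate the structure the framework assumes:
total counts with mean $n(A + Bx)$ and variance $\varphi$ times the mean
around a linear per-stratum dose response with a shared intercept. The
generating family is negative binomial with size $= \text{mean}/(\varphi
- 1)$, which matches that first-two-moment law exactly ($\varphi = 1$
degenerates to Poisson); this is a modelling choice — the quasi-Poisson
framework itself specifies only the two moments. Defaults are the
published study conditions: intercept 0.150 foci/cell, slopes 12.518
(1h) and 1.956 (24h) foci/cell/Gy, $\varphi = 60$, 500 cells per sample,
and the experiment's design (doses 0–4 Gy with its replicate counts per
time stratum, 339 samples in total, `phe_design()`). Each design row
draws from its own seed-derived substream, so extending a design never
perturbs earlier rows. An optional lognormal donor-specific multiplier
(default off, reflecting the finding that donor variation is absorbed by
the overdispersion) exists for power studies of the donor test.

What the generator does *not* emulate: partial-body exposure mixtures,
donor random effects by default, scorer drift within an experiment, or
any cell-by-cell frequency information (only per-sample totals). Passing
tests therefore demonstrate correctness of the statistical machinery
under the assumed mean-variance law, not robustness to those real-data
features.

## Problem sizes and observed operating characteristics

The test suite sizes its simulations to make Monte-Carlo error small
relative to each tolerance: 500 replicate fits of the full 339-sample
design for parameter recovery (empirical SDs of $\hat A$, $\hat B$ match
the reported SEs within 15%), 200 seeds for dispersion recovery
($\hat\varphi \in [50, 70]$ in ≥90%), 2000 draws for prediction-interval
coverage, about 2000 pooled draws for dose-interval coverage, and $10^5$
draws for the Monte-Carlo cross-check of the delta-method SE (agreement
within 2% in the small-noise regime).

Two honest limitations surfaced by these checks. First, the nominal
95% coverage of $x_* \pm 1.96\,SE(x_*)$ holds (93–97%, pooled over doses
0.5–2 Gy and $n_* \in \{50, 200\}$) when mean counts are large, as under
the steep 1h curve; under the shallow 24h curve at low doses the counts
are small and skewed and coverage drops to ~91% at 0.5 Gy with
$n_* = 200$ (and lower for $n_* = 50$) — a known property of Wald-type
intervals for overdispersed counts, worth remembering when triaging
low-dose, late-scored samples. Second, the delta-method SE is accurate
to a couple of percent only while parameter SEs are small relative to
the parameters; reference-derived curves with few cells stretch that
premise, and their intervals should be read as approximate.

## Worked example

The published two-curve example runs end-to-end in a few lines:

```{r example}
curve_1h <- calibration_curve(0.150, 12.518, 0.013, 0.158,
                              phi = 60, time_label = "1h")
curve_24h <- calibration_curve(0.150, 1.956, 0.013, 0.037,
                               phi = 60, time_label = "24h")
y0 <- pool_reference_samples(
  tibble::tibble(yield = c(68, 117) / 200, n_cells = c(200, 200))
)
refs <- list(
  `1h` = reference_set(y0$yield, y0$n_cells, 5.02, 200, 1.5),
  `24h` = reference_set(y0$yield, y0$n_cells, 2.92, 200, 1.5)
)
samples <- tibble::tibble(
  time = c("1h", "1h", "24h", "24h"),
  yield = c(0.72, 5.53, 0.32, 0.77),
  n_cells = c(200, 53, 200, 200)
)
report <- run_dose_estimation(samples,
                              curve = list(`1h` = curve_1h, `24h` = curve_24h),
                              ref = refs)
report |>
  dplyr::select(time, yield, x_star, se_x_star, provenance) |>
  dplyr::mutate(dplyr::across(dplyr::where(is.numeric), \(x) round(x, 3)))
```

The 1h curve fails its positive control (yield 5.02 against a prediction
interval of roughly [14.2, 23.7]) and is replaced by the reference curve
through (0, 0.4625) and (1.5, 5.02); the 24h curve passes (2.92 inside
[1.160, 5.007]) and is used directly — visible in the `provenance`
column above.
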