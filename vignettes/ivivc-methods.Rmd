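---
title: "Methods: one- and two-step level-A IVIVC modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one- and two-step level-A IVIVC modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivivc)
```

## Scope and model overview

`ivivc` implements the complete analysis chain used to establish a level-A
in vitro-in vivo correlation (IVIVC) for oral immediate/modified-release
products whose absorption is dissolution-limited: non-compartmental analysis
and cross-study normalization of plasma data, Weibull modelling of
dissolution, Loo-Riegelman deconvolution against a two-compartment
disposition model, Levy-plot time scaling, the classical two-step linear
correlation with FDA percent-prediction-error (%PE) validation, and a
one-step differential-equation IVIVC in which the in vitro release rate
drives the disposition model directly through empirical link functions.

The package works on the scale the clinic reports: concentrations in ng/mL,
volumes in mL, times in hours, doses entered in mg and converted to ng.

### Disposition

Disposition is the two-compartment open model in micro-constant form
(`k10`, `k12`, `k21`, `Vc`). The hybrid constants are the roots of

$$s^2 - (k_{10}+k_{12}+k_{21})\,s + k_{21}k_{10} = 0,$$

computed with the numerically stable quadratic formula, and
$V_{ss} = V_c(1 + k_{12}/k_{21})$. `fit_two_compartment()` estimates the
four micro-constants from IV bolus data on the log scale
(Levenberg-Marquardt, uniform weights by default, optional $1/\hat y^2$),
initialized by deterministic curve stripping so runs are reproducible
without random restarts.

### Dissolution

Release curves are modelled with the three-parameter Weibull form

$$F(t) = F_{max}\left(1 - e^{-t^{\beta}/\alpha}\right),$$

with $\alpha$ the scale (h$^\beta$), $\beta$ the shape and $F_{max}$ the
asymptote, allowed up to 1.25 because fractions are expressed against label
claim and complete release can slightly exceed it. Two derived forms are
used throughout and are implemented as exact algebra on this equation: the
inverse (time to reach a fraction) and the release rate (its time
derivative, which integrates back to $F_{max}$ — a mass-consistency
property the tests enforce). Published renderings of both derived equations
are typographically inconsistent with the base model; the algebraic forms
are the only ones compatible with it, and they are what the package uses.

Profile similarity uses the standard $f_2$ factor on the percent scale; the
conventional "at most one point above 85% dissolved" truncation is
available behind `guard_85` but off by default, matching the plain-formula
usage the analysis chain expects.

### Deconvolution and convolution

`loo_riegelman()` implements the classical stepwise recursion with the
trapezoidal AUC and the $k_{12}\,\Delta C\,\Delta t/2$ peripheral
correction. Because published variants of the recursion differ in that
correction term, the package takes the self-consistency route: the
convolution step `inverse_loo_riegelman()` is derived symbolically from the
same recursion (the target absorbed amount is linear in the unknown
concentration at each step), so deconvolution followed by convolution is an
identity at machine precision on a shared grid *whatever* variant had been
chosen. That round-trip is the module's central contract and is tested to
1e-10.

Fractions absorbed are normalized by the largest AUC$_{0\to\infty}$ across
the formulations under study, so each product's plateau reads as relative
bioavailability. A practical consequence: the plateau of the best product
is $1/(1-\varepsilon)$ with $\varepsilon$ the AUC-extrapolation error, so
minute overshoots above 1 are clamped silently and only overshoots beyond
0.5% warn.

The recursion is a discrete-time scheme: with sampling intervals of several
hours its tail is appreciably more damped than the continuous model
(deconvolution error is first-order in the step). The tests quantify this
against an analytic first-order-absorption oracle: on a 5-minute grid the
maximum error in fractions absorbed is below 1%.

### Two-step correlation

The Levy plot pairs the times at which the same fraction is absorbed in
vivo and dissolved in vitro, both obtained from the fitted Weibull inverses,
and fits `t_vivo = intercept + slope * t_vitro` over the pairs with
`t_vivo <= t_limit` (default 3.5 h; beyond it the in vitro/in vivo relation
stops being a single function for this drug class). The fit includes an
intercept by default with a `through_origin` flag, so either convention can
be audited. In vitro times are then rescaled through the mapping, the
Weibull model is refitted on the scaled clock, and the level-A line
`fabs = a + b * fdiss` is estimated by OLS pooled across products (with
per-product fits reported as diagnostics). Prediction chains the pieces
forward and reconvolutes; predicted fractions are clipped to [0, 1] and
forced non-decreasing by a running maximum before convolution, since an
out-of-range linear extrapolation is not a valid cumulative input.

Validation applies the FDA criterion: signed
$\%PE = (obs - pred)/obs \times 100$ for Cmax and AUC, accepted when
$|\%PE|$ is below the 10% threshold (configurable), with held-out products
scored separately as external validation.

### One-step correlation

The one-step model drives the disposition system directly:

$$\frac{dQ_c}{dt} = \mathrm{dose}\cdot\varphi(t)\cdot SC\cdot
  r_{diss}(s_0 t^{s_1}) - (k_{10}+k_{12})Q_c + k_{21}Q_p,\qquad
\frac{dQ_p}{dt} = k_{12}Q_c - k_{21}Q_p,$$

with the logistic cut-off $\varphi(t)=1/(1+e^{\eta(t-t_{cut})})$
(absorption lost past the distal gut, midpoints around 10-13 h), the extent
scale $SC = SC_1F_{max}^{B}$ (an empirical stand-in for
bioavailability/first-pass losses) and the nonlinear time map
$t_{vitro} = s_0t^{s_1}$. Two conventions are kept exactly as the source
model states them, because the model is semi-empirical and $SC_1$ absorbs
any constant factor: plasma concentration is reported as $Q_c/V_{ss}$ (not
$Q_c/V_c$), and no chain-rule factor $dt_{vitro}/dt$ multiplies the input
term. The peripheral balance equation is written as $dQ_p/dt$ (the source
prints the left-hand side of both equations identically, which cannot
conserve mass). The in vivo Weibull parameters entering $r_{diss}$ come
from per-parameter linear maps fitted between in vitro and
deconvolution-based in vivo Weibull fits across products.

Integration uses `deSolve::lsoda` at rtol 1e-8 / atol 1e-10 with dense
output at the sampling times; shapes below 1 would make the rate singular
at the origin, and the in vitro clock is floored at 1e-8 h in that case
(the singularity is integrable). `fit_onestep()` estimates all six link
parameters simultaneously from the pooled residuals of every product,
log-scale Levenberg-Marquardt from fixed documented starting values
(`s0 = s1 = B = 1`, `eta = 2`/h, `tcut = 12` h, `SC1` from a deterministic
scale match). The optimization is box-bounded (`tcut` in [0.1, 100] h,
`eta` in [0.01, 1000]/h): the cut-off is weakly identified whenever
absorption finishes well before `tcut` — reported CV% above 100 for these
parameters is the norm, not a defect — and a bound hit simply reads "no
cut-off visible in these data". Standard errors come from the local
curvature at the optimum, transported to the natural scale by the delta
method, with the full covariance returned for joint Wald checks.

## The synthetic-data generators

No public individual-level data exist for this kind of study, so the
package generates its own, with the structure the analysis assumes:

* **Four products** (one reference, three tests) with Weibull release
  parameters spanning the published range (scales ~3-7 h$^\beta$, shapes
  ~1.5-2.2, asymptotes ~0.75-1.02), at a 10 mg dose.
* **Two trials with a shared reference**: study 2 uses the full dense
  schedule (pre-dose and 0.5-24 h with 15-min resolution around Tmax);
  study 1 omits the 3.25/3.75/4.25 h draws, so combining the studies
  genuinely requires the interpolation-to-combined-grid machinery. A
  multiplicative between-study exposure bias (default 1.15) is applied to
  study-1 concentrations; cross-study normalization by the reference ratio
  must remove it.
* **Between-subject variability** as a log-normal exposure multiplier with
  25% CV — a typical magnitude for a moderately variable oral drug — drawn
  per subject (36 and 24 subjects, matching the two trial sizes).
* **Dissolution replication**: 6 units per product with additive Gaussian
  noise (sd 0.02 fraction units, truncated at zero). The real assay's error
  structure is unknown beyond reported sd bars; this additive model is a
  documented stand-in.

All generators are pure functions of the design object (seed included), a
determinism contract the tests assert byte-for-byte.

What the generators deliberately do **not** emulate: assay LLOQ censoring,
heteroscedastic bioanalytical noise, subject-level differences in lag time
or Tmax (the analysis averages profiles, so only exposure-scale variability
matters to it), and carry-over. Passing tests on this synthetic material
therefore shows the chain is mathematically self-consistent and robust to
the nuisances modelled — not that it is robust to every feature of real
clinical data.

## Numerical choices and edge cases

* **Terminal phase selection**: best adjusted R² over all suffix windows of
  at least 3 positive post-peak samples, ties to the longer window —
  deterministic, no analyst judgement in the loop.
* **Combined-grid normalization**: factor 1 where both references are zero
  (pre-dose); a zero reference against a positive one at t > 0 is an error,
  not a guess. Interpolation is inward-only; extrapolation is refused.
* **Weibull fitting**: bounded Levenberg-Marquardt; asymptote capped at
  1.25; deterministic initialization (largest observed fraction, unit
  shape, scale through the half-maximal observation).
* **Levy/level-A degeneracies**: fractions at or above either asymptote are
  excluded from the Levy grid (and counted); a level-A regression without
  variance in fractions dissolved errors out.
* **Closed-loop testing**: the two-step chain is validated on data built by
  the package's own discrete convolution on a grid with hourly tail
  sampling, where the discrete recursion is well conditioned; on such data
  the full pipeline closes with |%PE| well below 1%. On the sparse clinical
  tail (4 h gaps) the discrete scheme is visibly dissipative — a property
  of the classical method itself, which the test suite documents rather
  than hides.

## Problem sizes

The shipped tests and the acceptance script run the whole chain at the
study's own scale: 3-4 products, 17-20 plasma samples per mean profile,
32-point dissolution curves, 6 dissolution units, and one-step fits over
three products simultaneously (~60 pooled residuals, 6 parameters). These
sizes reproduce every published anchor value to its printed precision and
keep any single fit under half a minute on one core.

## Known limitations

* Mean-profile analysis only; no population (mixed-effects) modelling.
* Level-A linear correlation only; no level-B/C or nonlinear maps.
* The Loo-Riegelman variant is fixed to the classical correction-term form;
  regularized (spline/Tikhonov) deconvolution is out of scope.
* Bioequivalence confidence-interval machinery is not reproduced: it needs
  individual cross-over data the package's mean-profile pipeline does not
  consume.
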