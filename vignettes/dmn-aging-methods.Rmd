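---
title: "Methods: static and dynamic DMN connectivity across age"
author: "dmnAging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: static and dynamic DMN connectivity across age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmnAging)
```

## The scientific question

Resting-state fMRI studies of the default-mode network (DMN) consistently
report that within-network functional connectivity (FC) weakens with age
while its moment-to-moment fluctuation increases. If a psychiatric
condition accelerates brain aging, that acceleration should appear as a
*diagnosis-by-age interaction*: the age slope of a connectivity outcome
differs between patients and controls. This package implements the full
analysis chain for testing that hypothesis on ROI-level time series —
no image processing is involved; the pipeline starts where a standard
preprocessing pipeline ends, at one `volumes x ROIs` matrix per subject
for a fixed 58-region DMN parcellation.

## The two outcome measures

**Within-network FC strength.** For each subject the `58 x 58` matrix of
pairwise Pearson correlations between ROI time courses is computed, and FC
strength is the mean over all `58 * 57 / 2 = 1653` unordered ROI pairs
(strict upper triangle; the unit diagonal never enters any average).

**Temporal variability of dynamic FC.** The series is segmented into
sliding windows (default width 100 s, step 6 s; with TR = 2 s that is 50
and 3 volumes) and the same correlation matrix is computed per window.
Only full windows are used; trailing volumes that do not fill a window are
dropped, and window ranges are handled as 0-based half-open intervals so
the window count is exactly `floor((n - width) / step) + 1`. For region
*k*, its *connectivity profile* in window *i* is row *k* of the *i*-th
windowed matrix with the self-entry removed. Node-wise variability is

&nbsp;&nbsp;&nbsp;&nbsp;V_k = 1 − mean over window pairs (i, j), i ≠ j, of
cor(F(i, k), F(j, k)),

implemented over the `T (T − 1) / 2` unordered pairs, which equals the
i ≠ j average by symmetry at half the cost. Network variability V is the
mean of V_k over the 58 regions. Both are bounded in [0, 2]: 0 means the
profile shape never changes, 2 perfect anti-correlation between windows.
Because Pearson correlation is location- and scale-invariant, V_k responds
only to changes in profile *shape*, never to a uniform rise or fall of all
connections — a property worth keeping in mind when interpreting V and one
that drove the simulator design below.

The variability code is cross-checked in the test suite against an
explicit double-loop oracle (all window pairs, sum-formula Pearson) at
tolerance 1e-12.

## Group-level models

**Interaction regression.** Each outcome is modelled by ordinary least
squares:

&nbsp;&nbsp;&nbsp;&nbsp;outcome ~ intercept + diagnosis + age +
diagnosis × age + sex + education + site + head motion

with diagnosis coded patient = 0 / control = 1, sex male = 0 / female = 1,
acquisition site as treatment dummies against the lexicographically first
site, and mean framewise displacement (mm) as the motion covariate. The
interaction regressor is diagnosis times *mean-centered* age; with both
main effects present this leaves the interaction t and p identical to the
uncentered parameterization (asserted on random data in the tests) while
keeping the main-effect coefficients interpretable at the sample's mean
age. Standardized coefficients are reported per term as
`b * SD(x) / SD(y)`, dummies included — the convention of mainstream
statistics GUIs, so values are comparable to published tables.
Rank-deficient designs raise an error naming the aliased columns rather
than silently dropping terms.

**Comparing group correlations.** Within-group Pearson correlations
between age and an outcome are compared across independent groups with the
classical Fisher r-to-z statistic
`z = (atanh r1 − atanh r2) / sqrt(1/(n1−3) + 1/(n2−3))`, two-tailed.

**Clinical associations.** Partial Pearson correlations between outcomes
and clinical scores (severity scales, illness duration) residualize both
variables on age, sex, education, site and motion, with
`df = n − 2 − k`; first-episode versus recurrent status is tested by
ANCOVA with the same covariates, where F is exactly the squared t of the
factor term.

**Heteroscedasticity.** Each regression is checked by the Spearman rank
correlation between age and the absolute residuals. When significant at
α = 0.05, the model is refit on the natural logarithm of the outcome; the
transform is refused (with an informative error, never a silent shift) if
any outcome value is non-positive.

**Validation grid.** The dynamic-FC regression is repeated over all
window-width × step combinations {80, 100, 120} s × {6, 8, 10} s; the cell
at the primary parameters reproduces the primary fit exactly, which the
tests assert.

**Summary-statistic tests.** Pooled-variance two-sample t from published
means/SDs/sizes and the 2 × 2 Pearson chi-square without continuity
correction allow demographic group comparisons to be recomputed directly
from printed tables.

## Quality control

Subjects are excluded in a fixed order, each attributed to the *first*
failing criterion so the bookkeeping identity
`retained + excluded = input` holds exactly: (1) age under 18; (2)
incomplete demographics; (3) TR ≠ 2 s (uniform temporal resolution for
windowing); (4) manual image-quality review — this has no computable
definition from ROI series and is explicitly logged as *not applied*;
(5) mean framewise displacement above 0.2 mm; (6) signal loss,
approximated by a zero-variance ROI series.

## The synthetic cohort generator

Because consortium subject-level data cannot be redistributed, every stage
is exercised on simulated cohorts whose statistical structure mirrors the
study conditions: two groups scanned at 20 sites with per-site scan
lengths of 150–250 volumes at TR = 2 s and site sampling weights
proportional to realistic per-site sample sizes; age uniform over 18–65;
education truncated normal(12, 4); mean FD truncated normal(0.07, 0.03) in
[0, 0.2] mm; patient-only clinical scores with realistic missingness.

Per subject, the signal model is a one-factor design: at volume *t*,
region *k* receives `sqrt(rho_k(t)) * c_t + sqrt(1 − rho_k(t)) * e_tk`
with a shared standard-normal factor `c_t`, so the instantaneous
correlation between regions j and k is `sqrt(rho_j(t) rho_k(t))` — exactly
`rho` when the coupling is constant, which gives a sharp analytic link
between the coupling target and expected FC strength (verified on a
2000-volume subject in the tests). The coupling drifts sinusoidally with
amplitude `alpha`, one subject-level phase, and *independent per-region
phase offsets*, and each series finally passes an AR(1) filter
(coefficient 0.3, hemodynamic-like smoothness) and is re-standardized,
which leaves zero-lag correlations unchanged.

Two design choices here are deliberate and non-obvious:

* **Per-region phases.** A *common* coupling fluctuation shifts every
  connectivity profile by a constant per window, and V is invariant to
  exactly that (Pearson location invariance). A generator with a single
  shared rho(t) therefore produces a variability statistic blind to its
  own fluctuation amplitude. Independent phase offsets make the profile
  *shape* rotate over time, which is what V measures.
* **Drift period 200 s, longer than the 100 s window.** Fluctuation faster
  than the window averages out inside each window (attenuated by a
  sinc-like factor) and is nearly invisible to windowed estimates; a
  period of twice the window width survives windowing while still cycling
  several times within a 300–500 s scan. With this design the median V of
  paired-seed subjects increases strictly with the injected amplitude,
  which the test suite asserts at amplitudes 0 / 0.2 / 0.4.

Age structure enters through the targets: coupling
`rho = clip(0.40 + slope_group * (age − midpoint) + N(0, 0.05))` with
slopes −0.0015/yr (controls) and −0.0030/yr (patients) — the steeper
patient slope *is* the interaction to be recovered, with the implied
positive sign for the fitted coefficient under control-coded-1 — and
amplitude `alpha = clip(0.15 + 0.002/yr * (age − midpoint) + N(0, 0.05))`,
clipped so that `rho ± alpha` stays inside (0, 1). The baseline coupling
of 0.40 keeps that clip from binding for older patients (a lower baseline
would truncate the amplitudes of exactly the low-coupling subjects and
distort the age–variability relation in one group). Slopes are free
parameters in generator-native units; no published effect size maps onto
them directly, so they were fixed once at values that make the interaction
detectable at the desk-scale default of 150 subjects per group, and are
not tuned thereafter.

What the generator does *not* emulate: realistic spatial covariance of an
atlas parcellation (all regions are exchangeable up to their phase),
motion artefacts and their correlation with age or diagnosis, site
differences beyond scan length, non-sinusoidal connectivity dynamics, and
any genuine group difference in variability. Passing tests therefore show
that the estimators and tests behave correctly under a known
data-generating process — not that real cohorts satisfy that process.

## Numerical choices and degenerate inputs

* Zero-variance series (flat signal) are an error naming the region — they
  indicate signal loss, which is an exclusion criterion, and must not
  propagate as NaN.
* Under the Fisher variant, off-diagonal |r| within 1e-7 of 1 is clipped
  to 1 − 1e-7 with a warning before `atanh`, keeping outputs finite.
* Window widths/steps that are not whole multiples of TR are an error (no
  rounding); a plan with fewer than two windows is an error for
  variability use.
* V_k is snapped into [0, 2] only against floating-point overshoot at the
  boundaries (order 1e-16), far below the 1e-12 oracle tolerance.
* Metrics tables are written with 17 significant digits so write/read
  round-trips are bit-exact, and analysis outputs contain no timestamps so
  reruns are byte-identical.

## Problem sizes used by the tests

Unit tests run on toy inputs (≤ 10 regions, ≤ 60 volumes) against
brute-force oracles. End-to-end checks use 150 subjects per group for the
20-replicate interaction-sign recovery (the size at which the generator
defaults were fixed) and 200 per group for the 500-replicate null
calibration of the interaction test, the latter on phenotype-level
simulation (coupling target plus measurement noise) so that 500 ordinary
least squares fits, not 200 000 time-series simulations, carry the
computation.

## Known limitations

The pipeline treats site as fixed dummies (no random-effects pooling),
performs no multiple-testing correction across outcomes, and implements
only the independent-groups Fisher z comparison (no confidence-interval
variants). The manual image-quality exclusion cannot be automated and is
reported as not applied. Sliding-window variability itself conflates true
dynamics with sampling noise of the windowed estimates; V should be
compared across groups or parameters, not interpreted as an absolute
quantity.
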