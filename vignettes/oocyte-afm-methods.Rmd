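---
title: "Methods: oocyte mechanics from AFM force spectroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oocyte mechanics from AFM force spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovomech)
```

## The assay

An unfertilized MII oocyte kept in culture ages and, after a few hours,
degrades visibly. The working hypothesis behind this package is that the
degradation is announced mechanically: spontaneous cortical-granule (CG)
exocytosis cross-links the zona pellucida (ZP) — the same "zona
hardening" that normally blocks polyspermy after fertilization — so the
inner ZP stiffens and the indentation cycle dissipates less viscous
energy about an hour before any morphological change, with the CG
fluorescence signal rising about an hour earlier still. The package
implements each measurement in that chain and a synthetic-data layer
that generates all of its inputs with known ground truth.

## Units and conventions

All curve-level quantities are carried in the units the instrument
reports: heights and deflections in µm, time in s, force in nN, moduli
in Pa, energies in fJ (1 nN·µm = 1 fJ, so force–indentation areas need
no conversion). Deflection is positive when the cantilever is pushed up,
force is positive in compression, indentation positive into the sample.
Curves travel as UTF-8 TSV files with `#`-prefixed `key: value` headers;
everything needed to interpret the data (spring constant, bead radius,
speed, setpoint) rides in the header.

## Contact mechanics

### Single layer

A rigid sphere of radius $R$ on an elastic half-space follows
$F = \tfrac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2}$.
The Poisson ratio is not measurable in this geometry; we fix $\nu = 0.5$
(incompressible soft matter), configurable. The bead radius defaults to
2.25&nbsp;µm (a 4.5&nbsp;µm silica microbead); where sources quote a
5&nbsp;µm bead we treat that as rounding of the diameter and follow the
measured 4.5&nbsp;µm, also configurable.

### Two layers and the meaning of E2

Oocyte approach curves show two regimes. We model the force as the *sum*
of two Hertz contributions, the second engaging at an indentation offset
$\delta_{c2}$:

$$F(\delta) = H(\delta - \delta_0;\,E_1) +
  [\delta - \delta_0 > \delta_{c2}]\; H(\delta - \delta_0 - \delta_{c2};\,E_2')$$

Two conventions for the "inner modulus" coexist in this model: the
additive component $E_2'$, and the modulus a single-layer fit re-zeroed
at the second contact point would report for the combined post-$\delta_{c2}$
response. We report the latter as **E2** — it is what a two-contact-point
analysis of the raw curve measures — and keep $E_2'$ alongside. The
reported value has a closed form: the projection of the model's force
increment beyond $\delta_{c2}$ onto the shifted Hertz shape
$(\delta-\delta_0-\delta_{c2})^{3/2}$. The synthetic generator inverts the
same projection, so its `E2_true` is in the reported convention and
estimator checks close exactly. The additive form is isolated in one
internal function so a piecewise alternative could be swapped in.

### Fitting strategy

At fixed contact points the model is linear in $(E_1, E_2')$, so
`fit_two_layer()` grid-searches $(\delta_0, \delta_{c2})$ — coarse pass
over the whole plausible range, fine pass around the coarse optimum at
half the sample spacing — solving a small linear system at each
candidate, then polishes all five parameters with Levenberg–Marquardt
from the grid optimum. Two details matter in practice:

* **A free force offset.** Contact detection on the soft outer layer is
  late by construction (the force must clear the noise floor), which
  leaves the force zero slightly wrong after re-zeroing at the detected
  contact. A free intercept in the linear solve absorbs this; without
  it the offset aliases into $\delta_0$ and biases $E_1$ upward
  severely at realistic noise.
* **Nested-model support.** The second contribution is only accepted if
  it improves the residual sum of squares by more than 5% and
  $\delta_{c2}$ is interior to the fitted range; otherwise the curve is
  reported as single-layer ($E_2 = E_1$, flag cleared). This keeps the
  estimator honest on ZP-removed (ooplasm-only) curves.

Contact detection itself returns the first height at which the force
exceeds 3 baseline-noise SDs for 5 consecutive samples; the threshold
and run length are configurable, and detection is deliberately
conservative because the fits refine the contact anyway.

## Dissipated viscous energy

The energy dissipated over one indentation cycle is the area enclosed
between approach and retraction, restricted to the positive-force
region. We interpolate the retract branch linearly onto the approach
indentation grid, clamp negative forces to zero, and integrate the
difference by the trapezoidal rule. On piecewise-linear cycles this
equals the shoelace polygon area exactly, which the tests use as an
independent oracle. Slightly negative results (noise on a closed cycle)
are reported as-is; values more negative than 3 noise SDs times the span
raise a flag.

## Stress relaxation

Whole-cell holds (20 µm compression at 2 µm/s, 30 s hold) are fitted by
$F(t) = a_0 + a_1 e^{-(t-t_0)/\tau_1} + a_2 e^{-(t-t_0)/\tau_2}$ with
$\tau_1 < \tau_2$ enforced by output ordering. The initializer peels the
exponentials in stages: a log-linear fit on the last 40% of the hold
estimates the slow component, which is subtracted before fitting the
head for the fast one. Two elements are declared resolvable only when
$\tau_2/\tau_1 \ge 1.5$ and both amplitudes exceed twice the
high-frequency noise estimate; otherwise a single-element fit is
returned with a flag, and compartment assignment refuses it. The strain
history during the loading ramp is ignored ($t_0$ = end of ramp): the
hold alone identifies the model. The Maxwell element relates time
constant, viscosity and stiffness as $\tau = \eta/E$ — note that this is
the standard spring–dashpot-in-series relation; we use it in the form
$\eta = \tau E$ to convert fitted times into viscosities. The faster
time maps to the ZP (stiff, weakly viscous), the slower to the ooplasm.

## Calibration

The thermal-noise route is pure equipartition on the time-domain
variance of the detrended deflection, $k = \beta\,k_B T / \langle d^2
\rangle$, with the first-mode optical-lever correction $\beta = 0.817$
as default; no power-spectrum fitting is attempted, because the variance
form is the part that is testable against a generator and the correction
is instrument-specific and exposed as configuration. The spring-on-spring
route inverts the force balance $k\,d = k_\mathrm{ref}(z - d)$ exactly,
$k = k_\mathrm{ref}(1-s)/s$ for slope $s = d/z$, assuming an ideal
massless reference spring.

## Fluorescence quantification

Five line profiles at equally spaced angles through the intensity
centroid sample each frame (the number and the angular placement are
defaults, not measurements; parallel lines would work as well and can be
built from `extract_profile()` directly). Per profile, the PVS peak
window is the widest interior run exceeding the flank median plus twice
the flank SD (flanks = outer 15% of the profile, which stays outside the
cell for edge-to-edge profiles); the background is the median of the 25%
flanking samples around the window, and the signal is the
background-subtracted positive area. Areas are averaged over the five
profiles with their standard error, and series are normalized to the
first value. Background subtraction makes the area invariant to additive
offsets and linear in gain, which the tests assert as properties.

## The synthetic-data layer

The generators encode the study conditions as defaults: 0.32 N/m
cantilever, 2.25 µm bead, 1 nN setpoint at 5 µm/s, outer/inner moduli
50/160 Pa with a second contact at 1 µm, force noise 1% of the setpoint,
3×3 grid × 3 replicates with per-position lognormal jitter of CV 40%
(E1) and 7% (E2) reproducing the outer-mesh heterogeneity contrast,
relaxation truths (a₀, a₁, a₂) = (0.5, 1.0, 0.5) nN with (τ₁, τ₂) =
(1, 10) s, cohorts of 15 healthy + 20 degrading oocytes with degradation
hours uniform on 4–6 h, E2 doubling one hour before degradation (then
×0.7 post-peak), dissipation halving, CG fluorescence rising two hours
before, and 20% photobleaching over 90 min in the continuous-illumination
control. Where a study condition fixes no value (grid sample counts,
frame cadence of 5 min, image geometry, cohort baselines of 160 Pa and
50 fJ, hour-to-hour measurement CV of 5%) we chose plausible
instrument-scale values once and documented them here.

Hysteresis is phenomenological — the retract force is the approach force
scaled down in proportion to a viscosity index and the loading rate —
because the assay *measures* dissipation rather than modelling its
microscopic origin; the generator only needs ordinal fidelity (more
viscous ⇒ more enclosed area), which the tests check as a rank
correlation. Likewise the aging trajectories are step multipliers on
per-oocyte baselines, not a biophysical model of zona cross-linking.
Passing recovery tests on these inputs therefore demonstrates that the
estimators are unbiased and well-conditioned under the assumed noise
structure — Gaussian force noise, lognormal biological variability — not
that real oocyte curves obey the two-layer Hertz form; model adequacy on
real data is outside what synthetic tests can show. Every generator is a
deterministic function of (config, seed) and attaches its ground truth
to the output.

## Cohort statistics and the change-point flag

Timelines are aligned on the first visually degraded timepoint (time
zero; earlier points negative). Degradation observed exactly at the
6 h horizon counts as degraded — a closed-interval rule, configurable.
Group comparisons (one-way ANOVA F, Kruskal–Wallis H with tie
correction, Mann–Whitney U with normal approximation and continuity
correction) are implemented from the standard definitions and validated
in the tests against both `stats` and exhaustive enumeration at small n.

`headline_summary()` tests each aligned hour against the earliest shared
hour and flags the first significant departure. Because one flag is
chosen among several hourly comparisons, we Holm-adjust the hourly
p-values by default: with per-comparison testing alone, the chance of
flagging *some* hour on a null cohort grows with the number of hours and
the flag would not be calibrated at its nominal level. The raw p-values
are always reported, and `p_adjust = "none"` restores plain
per-comparison testing for users who want the uncorrected view. This is
the one place the package imposes multiplicity control; no correction is
applied across endpoints (E2 vs dissipation), which are reported
separately. Missing hours stay missing — the cadence is 1 h and no
interpolation is ever performed.

Yield percentages are computed from raw counts and rounded half-up to
integers; when a published percentage disagrees with its own counts the
table annotates the discrepancy rather than reproducing it.

## Numerical choices and limitations

* Grid-search resolution is tied to the sample spacing (fine pass at
  half-spacing), so fitted contact points are accurate to roughly a
  sample; the LM polish removes the residual discretization.
* Single-layer fits use a 5-start deterministic multistart over the
  contact offset; two-layer support requires ≥ 40 in-contact samples,
  single-layer ≥ 20.
* Degenerate inputs fail loudly and early: non-monotone approach
  segments, windows too short for baseline estimation, zero-variance
  thermal records, slopes outside (0, 1), non-overlapping
  approach/retract ranges.
* Problem sizes in the tests and acceptance script (30–50 curves per
  recovery check, 100 relaxation holds, 500 null cohorts, 96 px frames
  at 5 min cadence) were chosen as the smallest sizes at which the
  cohort-level standard errors are a few times tighter than the
  tolerances being checked.
* Out of scope by design: bottom-effect (finite-thickness) corrections,
  adhesive contact (JKR/DMT), more than two layers, Ting-style
  viscoelastic contact solutions, photobleaching *correction* (the 20%
  control bounds the effect instead), oocyte segmentation beyond the
  intensity centroid, and proprietary instrument file formats.
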