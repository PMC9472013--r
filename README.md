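# ovomech

Mechanical profiling of mammalian oocytes by AFM force spectroscopy,
built around a single biological question: can the stiffening of the zona
pellucida (ZP) be used as a label-free clock for postovulatory aging?
Unfertilized MII oocytes age and eventually degrade; roughly one hour
before any visible morphological change, the inner ZP stiffens sharply
and the viscous energy dissipated during indentation drops — the same
mechanical signature that cortical-granule (CG) exocytosis produces after
fertilization ("zona hardening"). `ovomech` implements the full analysis
chain for this assay, for biophysicists working with force-distance
curves on soft cells, plus synthetic-data generators that stand in for
raw recordings.

## What it computes

**Two-layer Hertz elasticity.** A spherical bead (radius R) indenting an
elastic half-space obeys the Hertz relation

    F(δ) = (4/3) · E/(1 − ν²) · √R · δ^{3/2}

Oocyte approach curves show two slope regimes: a soft outer ZP response
engaging at the first contact point and a stiffer inner response
engaging at a second contact point deeper in. `fit_two_layer()` models
the force as a sum of two Hertz contributions,

    F(δ) = H(δ − δ₀; E1) + [δ − δ₀ > δ_c2] · H(δ − δ₀ − δ_c2; E2′)

with the contact points found by a coarse-to-fine grid search (the
moduli enter linearly and are solved in closed form at each candidate
pair, followed by a continuous polish). The reported **E2** is the
modulus of the combined second-regime response — what a single-layer fit
re-zeroed at the second contact would report. A nested-model criterion
(relative rss improvement > 5%) guards against inventing a second layer
on single-layer data.

**Viscous dissipation.** `dissipated_energy()` integrates the area
enclosed between approach and retraction in the positive-force region
(trapezoidal rule after interpolating the retract branch onto the
approach indentation grid); with force in nN and indentation in µm the
area is directly in fJ.

**Stress relaxation.** Whole-cell holds are fitted by a two-element
generalized Maxwell model

    F(t) = a₀ + a₁·exp(−(t − t₀)/τ₁) + a₂·exp(−(t − t₀)/τ₂),  τ₁ < τ₂

with a two-stage exponential-peel initializer and a single-element
fallback when the two time constants are unresolvable.
`assign_compartments()` maps the fast time to the ZP and the slow one to
the ooplasm; `viscosity_from()` applies the Maxwell relation η = τ·E.

**Calibration.** `thermal_noise_k()` (equipartition,
k = β·k_B·T/⟨d²⟩) for bead-mounted microcantilevers and
`spring_on_spring_k()` (force balance k = k_ref·(1 − s)/s on the
deflection-sharing slope s) for whole-cell macroprobes.

**Fluorescence.** CG exocytosis releases α-mannose residues into the
perivitelline space (PVS); lectin-bound fluorophore intensity forms a
ring between ooplasm and ZP. `extract_profile()`, `pvs_peak_area()`
(background-subtracted peak area), `aggregate_signal()` (five profiles
per cell) and `normalize_series()` quantify it over time.

**Aging pipeline.** Per-oocyte timelines are aligned on the *time before
degradation* (`align_to_degradation()`), split into healthy/degraded
groups (`classify_groups()`), compared hour-by-hour against baseline
with ANOVA / Kruskal–Wallis / Mann–Whitney implemented from the textbook
definitions (`compare_groups()`), and summarised with a change-point
flag (`headline_summary()`). `yield_table()` reproduces the embryo-yield
percentage arithmetic from raw counts.

## Worked example

```r
library(ovomech)

cfg   <- synth_config(seed = 1)            # study conditions as defaults
curve <- baseline_correct(gen_force_curve(cfg, seed = 1))
ind   <- to_indentation(curve, detect_contact(curve))

fit_two_layer(ind)
#> <two_layer_fit> E1 = 48 Pa, E2 = 157 Pa
#>   second contact at delta = 0.989 um; rss = 0.0374 nN^2

dissipated_energy(ind)
#> <dissipation_result> 0.177 fJ over 2.44 um (399 points)

fit_maxwell2(gen_relaxation(cfg, seed = 1))
#> <maxwell_fit> a0 = 0.496, a1 = 1.02, a2 = 0.483 nN; tau1 = 1.04 s, tau2 = 10.6 s
```

The generator's defaults are the study conditions (outer/inner moduli
50/160 Pa, 1 nN setpoint, 0.32 N/m cantilever, 2.25 µm bead, 1% force
noise); the fits recover them within the per-curve noise — 48 and 157 Pa
here — and the relaxation fit recovers the (1 s, 10 s) time-constant
pair from a 30 s hold.

## Analysis workflow

The `analysis/` scripts run the whole study on synthetic data and write
their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | cohort timelines, a 27-curve grid (TSV), hourly relaxation holds |
| `02_fit_elasticity.R` | two-layer fits, grid summary, E1-vs-E2 heterogeneity |
| `03_relaxation.R` | Maxwell fits per hour, ZP/ooplasm assignment |
| `04_fluorescence.R` | bleaching control and CG-release series |
| `05_aging_summary.R` | degradation-aligned summary, change-point flags, yield table |

Run them in order: `for f in analysis/0*.R; do Rscript $f; done`

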