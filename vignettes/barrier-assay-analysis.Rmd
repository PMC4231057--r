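---
title: "Methods: transwell permeability, TEER and grouped barrier assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transwell permeability, TEER and grouped barrier assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbbflux)
```

## The measurement model

A transwell barrier experiment places an endothelial monolayer on a
permeable membrane insert between a small luminal (donor) compartment and a
larger abluminal (receiver) compartment. With volumes $V_d$ and $V_r$ and a
barrier of permeability–surface product $PS$ (µl/min), concentrations obey
the conservative two-compartment exchange

$$\frac{dC_r}{dt} = \frac{PS}{V_r}(C_d - C_r), \qquad
  \frac{dC_d}{dt} = -\frac{PS}{V_d}(C_d - C_r),$$

whose closed form (`two_compartment_solution()`) is an exponential decay of
the concentration difference at rate $PS(1/V_d + 1/V_r)$ around the mass
equilibrium $(C_dV_d + C_rV_r)/(V_d+V_r)$. Total tracer mass is conserved
exactly, which the test suite checks to $10^{-9}$ relative; the closed form
is checked against an independent fixed-step Runge–Kutta integration to
$10^{-6}$ relative.

The estimation chain inverts this model under the near-sink conditions of
the real assay:

1. **Clearance.** Each interval sample gives a cleared volume
   $C_{abl} V_{abl} / C_{lum}$ (µl), a flux summary that is invariant to
   the tracer's absolute scale.
2. **PS regression.** Cumulative cleared volume is regressed on time by
   ordinary least squares; the slope is $PS_{total}$.
3. **Series correction.** The bare coated filter conducts in series with
   the monolayer: $1/PS_e = 1/PS_t - 1/PS_f$, with $PS_f$ the mean over
   the plate's cell-free inserts for that tracer.
4. **Pe.** $P_e = PS_e / A$ after converting µl/min to cm³/s, reported on
   the conventional $10^{-6}$ cm/s scale.

TEER readings are normalized as $R_{raw} \cdot A - \text{blank}$ with the
blank (empty coated insert) given in Ω·cm²; subtracting after area scaling
is algebraically identical to subtracting the blank's raw ohms first when
all inserts share an area.

## Assumptions and their consequences

- **Which luminal concentration enters the clearance formula.** Both
  compartments are sampled in the wet protocol, but the formula needs a
  single $C_{lum}$; we use the *nominal initial* donor concentration. For
  monolayers the donor depletes by well under 1 % over an hour, so the
  bias is negligible. For cell-free inserts (conductances two orders of
  magnitude higher) the same convention underestimates $PS_f$ by roughly
  15 % for the fluorescein defaults — but because $1/PS_f$ is a small
  correction to $1/PS_t$, the induced error in $P_e$ stays well below 1 %,
  which the noise-free inversion test verifies directly. The estimator and
  the simulator share the protocol, not the inversion: the simulator
  integrates the exact ODE with donor carry-over, the estimator assumes a
  near-sink linear accumulation.
- **Cumulation across intervals.** The insert moves to a fresh well at
  each sampling time, so the receiver resets while the donor carries over;
  cleared volumes are therefore summed across intervals before the
  regression, making "cleared volume vs time" a single line through the
  whole hour.
- **Origin anchoring.** The regression prepends the origin (0, 0) — no
  tracer has crossed at $t = 0$ — but still estimates an intercept, so a
  systematic lag (mixing, temperature equilibration) perturbs the
  intercept rather than the slope. A caller who supplies an explicit
  $t = 0$ sample overrides the prepending.
- **Series bound as a data check.** A fitted monolayer insert whose
  $PS_t$ reaches $PS_f$ is physically impossible and signals a failed
  monolayer or gross noise; such inserts are flagged, excluded and
  reported, never silently corrected.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| luminal / abluminal volume | 70 / 530 | µl | 24-well insert format |
| insert area | 0.33 | cm² | 24-well insert membrane |
| sample times | 20, 40, 60 | min | interval-transfer protocol |
| donor concentration | 10 / 165 | µg/ml | fluorescein / EB–albumin load |
| blank TEER | 70 | Ω·cm² | empty coated insert |
| filter Pe (cell-free) | 20 / 5 | 10⁻⁶ cm/s | typical coated-membrane values for a small dye vs a 67 kDa protein conjugate; free parameters of `true_kinetics()` |
| measurement noise CV | 0.10 | – | plate-reader noise scales with signal |
| in vivo biological CV | 0.20 | – | between-animal spread of tissue dye content |
| extract volume | 0.5 | ml | formamide extraction |
| bootstrap resamples | 2000 | – | percentile CIs for fold-changes |

All constants are named defaults of `assay_design()`, `default_kinetics()`,
`default_effects()` and `load_config()`; nothing is hard-coded inside the
computations.

## What the simulator emulates — and what it does not

`simulate_permeability_dataset()` reproduces the assay's geometry,
interval-transfer protocol, series conductances, and multiplicative
lognormal measurement noise (mean-one, so group means are unbiased);
TEER readings get additive Gaussian noise on the raw ohms. The default
ground truth encodes the studied effect structure: basal Pe of 0.21 and
0.043 ×10⁻⁶ cm/s, permeability elevation from day 2 at 2 and 10 Gy
(largest at day 2) and from day 3 at 0.1 Gy for the paracellular marker
only, a 30 % TEER drop confined to 10 Gy at day 2, a doubling of in vivo
albumin leakage at 1 week in adults (shifted to 4 weeks in infants, fully
recovered by 26 weeks), progenitor-colony depression at day 1 after 0.1
and 2 Gy, cell-density loss at 2/10 Gy from day 3, and senescent fractions
raised 30 %/40 % at 2/10 Gy on day 5. The sham in vivo tissue content
(15 ng/mg) is a free parameter, since only relative changes are
interpretable.

The simulator deliberately omits several features of real data: spatial
plate effects and edge wells, drift between experiment repeats, correlated
errors between the two tracers measured on the same insert, non-linearity
of the fluorescence calibration at high dye loads, monolayer heterogeneity
within a group beyond a single CV, and any mechanistic radiobiology
(DNA-damage kinetics, senescence signalling). Passing recovery tests
therefore demonstrates that the estimation chain is a correct inverse of
the stated measurement model at realistic noise — not that the model
captures every failure mode of a wet experiment.

## Grouped statistics

The study design is dose × timepoint with modest, sometimes unequal group
sizes. `two_way_anova()` fits a fixed-effects model with interaction and
reports Type III sums of squares under sum-to-zero contrasts — the
decomposition a GUI statistics package produces — which reduces to the
textbook decomposition on balanced tables (verified to $10^{-10}$).
Post-tests (`bonferroni_vs_sham()`) compare each dose to sham within each
timepoint using a $t$ statistic on the ANOVA's pooled error variance, the
classical Bonferroni post-test. The declared family defaults to *all*
dose-vs-sham comparisons across timepoints (m = doses × timepoints
comparisons), matching figure conventions that star every such comparison;
a per-timepoint family is available. Adjusted p-values are
$\min(1, m\,p)$ and star codes follow the usual 0.05/0.01/0.001 cuts.
A 2000-replicate null simulation in the test suite confirms the
family-wise error stays at or below the nominal 0.05.

Fold-changes vs sham are ratios of group means — the natural reading of
"about two-fold" — with seeded bootstrap percentile intervals; ANOVA stars
and fold-change intervals are complementary summaries of the same table.

## Image quantification

Stained-area intensity follows a thresholding procedure: a global
threshold separates expressing from non-expressing pixels, the mean of the
non-expressing (sub-threshold) pixels is taken as background and
subtracted from every pixel (floored at zero), and the mean of the
above-threshold pixels after subtraction is returned. The threshold
algorithm is unspecified in common practice ("the threshold feature" of an
image tool), so the deterministic default here is Otsu's
between-class-variance criterion, computed exactly over the observed gray
levels with ties broken toward the lowest level; a manual threshold
override is provided. The procedure is invariant to additive offsets and
equivariant to multiplicative gain on two-level images, both tested.
Background is a pixel mean, not a rolling-ball filter, consistent with
"subtraction of gray values of non-expressing pixels".

## Numerical and degenerate-input choices

- Readings below the calibration intercept clip to 0 ng/mg with a flag —
  plate noise routinely produces small negatives near blank.
- TEER below the blank clips to 0 Ω·cm² with a warning flag.
- A constant image is a degenerate-threshold error, not a zero.
- `fit_ps()` with fewer than two distinct times, or a standard series with
  one distinct concentration, is a fit error; a standard curve with
  $r^2 < 0.98$ warns.
- Every simulator requires an explicit integer seed and is bit-reproducible
  from it; pipeline stages write the seed and parameter snapshot as
  provenance beside their outputs.
- Senescence intervals are exact Clopper–Pearson beta quantiles, not
  normal approximations — group counts of 400–500 cells make the
  difference visible near small fractions.

## Problem sizes

The validation suite uses the study's own scales: 48 inserts for basal-Pe
recovery at 10 % CV, 16 inserts per TEER group, 12 animals per in vivo
group at 20 % CV (two regions each), 19 coverslips of 400–500 cells for
senescence, and 2000 replications for the null family-wise-error
simulation. These sizes keep the full suite under a minute on one core
while leaving Monte-Carlo error well inside each check's tolerance.

## Known limitations

- The Pe estimator assumes the linear (near-sink) accumulation regime;
  for barriers approaching the filter's conductance the cleared-volume
  line curves and the slope underestimates PS. The series correction
  absorbs most of this for the filter itself, but a genuinely leaky
  "monolayer" close to $PS_f$ will be excluded rather than corrected.
- PS pooling uses the plate's cell-free inserts; between-plate filter
  variation is not modelled (a global `ps_insert` override exists).
- The two-way ANOVA is fixed-effects; experiment-repeat random effects
  are not modelled, mirroring the original analysis rather than extending
  it.
- Image quantification operates on plain numeric matrices; file decoding
  is out of scope.
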