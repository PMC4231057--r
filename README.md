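# bbbflux

Quantitative analysis of blood-brain barrier (BBB) integrity assays:
transwell tracer permeability, transendothelial electrical resistance
(TEER), Evans blue tissue extravasation, and count-based cellular
endpoints, with dose-by-time group statistics. The package targets
radiobiology and barrier-biology labs that measure how an insult
(here, X-ray doses of 0–10 Gy) changes the permeability of brain
endothelial monolayers in vitro and of cerebral vessels in vivo — but the
estimators apply to any transwell barrier model.

A forward simulator of every assay, with configurable true parameters,
effect structure and noise, is a first-class part of the package: it is how
the estimation chain is validated end to end.

## The estimators

**Endothelial permeability coefficient (Pe).** Tracer flux across a
monolayer grown on a permeable insert is summarized per sampling interval
as a *cleared volume*,

    cleared volume (µl) = C_abluminal · V_abluminal / C_luminal ,

the donor-volume equivalent completely cleared of tracer. Cumulative
cleared volume is regressed on time (OLS, free intercept, origin
prepended); the slope is the permeability–surface area product PS (µl/min).
The monolayer conductance is obtained by removing the bare coated filter
in series,

    1/PS_endothelial = 1/PS_total − 1/PS_insert ,

with PS_insert measured on cell-free inserts, and the permeability
coefficient is Pe = PS_endothelial / A on the 10⁻⁶ cm/s scale
(A = 0.33 cm²).

**TEER.** Raw meter readings are normalized as
`TEER = R_raw · A − blank`, with the empty coated insert (70 Ω·cm²)
subtracted; negative values are clipped to zero and flagged.

**Evans blue extravasation.** Plate fluorescence is mapped to dye
concentration through a 7-point linear standard curve (classical
calibration) and expressed as ng dye per mg tissue; group effects are
reported as fold-change vs sham with seeded bootstrap intervals.

**Cellular endpoints.** Endothelial-progenitor colonies per 10⁵ PBMC,
SA-β-gal-positive percentages with exact (Clopper–Pearson) intervals,
cells/mm², and background-subtracted stain intensity of thresholded
(Otsu) image fields.

**Statistics.** One-way and two-way fixed-effects ANOVA (Type III sums of
squares under sum-to-zero contrasts) followed by Bonferroni post-tests of
each dose against sham at matched timepoints, with the conventional
star codes.

## Worked example

Simulate a two-dose, two-day plate at the default ground truth (sham Pe
0.21 / 0.043 ×10⁻⁶ cm/s for fluorescein / Evans blue–albumin; TEER
382.6 Ω·cm² with a 30 % drop at 10 Gy on day 2) and run the full
estimation chain:

```r
library(bbbflux)
kin <- default_kinetics(doses = c(0, 10), days = c(1, 2))
sim <- simulate_permeability_dataset(kin, n_inserts = 6, noise_cv = 0.1,
                                     seed = 42)
fit <- fit_permeability(sim$permeability)
summary(fit)
#>        tracer dose_gy day    mean_pe       sd_pe n
#> 1  eb_albumin       0   1 0.04274723 0.002238326 6
#> 5  eb_albumin       0   2 0.04204945 0.003625820 6
#> 3  eb_albumin      10   1 0.04297298 0.002654649 6
#> 7  eb_albumin      10   2 0.12684851 0.002904533 6
#> 2 fluorescein       0   1 0.21581003 0.016980109 6
#> 6 fluorescein       0   2 0.20739407 0.013823744 6
#> 4 fluorescein      10   1 0.20850738 0.010380903 6
#> 8 fluorescein      10   2 0.63563787 0.040592507 6
```

The sham groups recover the true basal coefficients (0.21 and 0.043) to
within a few percent at n = 6, and the day-2 high-dose groups show the
simulated ~3-fold permeability elevation. The matching TEER readings:

```r
teer <- cbind(sim$teer, compute_teer(sim$teer$raw_ohm))
aggregate(teer ~ dose_gy + day, teer,
          function(v) round(c(mean = mean(v), sd = sd(v)), 1))
#>   dose_gy day teer.mean teer.sd
#> 1       0   1     390.8    31.9
#> 2      10   1     392.4    45.5
#> 3       0   2     385.1    32.0
#> 4      10   2     261.6    17.5
```

i.e. a 32 % TEER decrease at 10 Gy on day 2 and none elsewhere. The same
workflow is available as a staged pipeline over CSV tables:

```r
cfg <- list(seed = 1, output_dir = "bbbflux_out")
run_pipeline(cfg, "simulate")     # writes permeability/teer/invivo/counts CSVs
run_pipeline(cfg, "permeability") # Pe + TEER results
run_pipeline(cfg, "evansblue")    # standard curve, ng/mg, fold vs sham
run_pipeline(cfg, "assays")       # count-endpoint summaries
run_pipeline(cfg, "stats")        # ANOVA + Bonferroni post-tests
run_pipeline(cfg, "report")       # group means ± SD with star codes
```

Every stage writes a provenance block (seed, parameters, package version)
next to its tables; identical configs yield byte-identical outputs.

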