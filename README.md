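# fermkin

Batch fermentation kinetics in R: simulation, kinetic descriptors, Monod
fitting, and condition comparison for bioethanol optimization studies.

## What this is for

A common design in bioprocess microbiology — here, ethanol production by a
halotolerant marine yeast on seawater-based medium — screens conditions one
factor at a time (carbon source, initial glucose 50–250 g/L, salinity from
distilled water to 4 M NaCl, pH 3–7), samples biomass *X(t)*, ethanol *P(t)*
and residual sugar *S(t)* over a 72 h batch, and summarizes each condition
with a standard set of kinetic descriptors:

| symbol | definition | units |
|---|---|---|
| *E*<sub>p</sub>, *X*<sub>m</sub> | peak ethanol / peak dry biomass | g/L |
| *Y*<sub>P/S</sub>, *Y*<sub>X/S</sub> | *E*<sub>p</sub>/*S*<sub>G0</sub>, *X*<sub>m</sub>/*S*<sub>G0</sub> (initial-substrate yields) | g/g |
| *Q*<sub>p</sub> | *E*<sub>p</sub>/*t*<sub>peak</sub> (volumetric productivity) | g/(L·h) |
| *Q*<sub>s</sub> | (S(0) − S(*t*<sub>peak</sub>))/*t*<sub>peak</sub> (substrate uptake) | g/(L·h) |
| *v* | (d*P*/d*t*)/*X* (specific production rate); table summary *v*<sub>g</sub> = *Q*<sub>p</sub>/*X*<sub>m</sub> | g/(g·h) |
| *μ* | slope of ln *X* vs *t* over the best log-linear window | 1/h |

The specific rates are then related to the initial substrate concentration
through the Monod saturation model,

&nbsp;&nbsp;&nbsp;&nbsp;rate(*S*<sub>G0</sub>) = rate<sub>max</sub> · *S*<sub>G0</sub> / (*K*<sub>s</sub> + *S*<sub>G0</sub>),

fitted by nonlinear least squares, and condition means are compared with
one-way ANOVA plus Tukey HSD at the 5% level, reported as compact letter
displays (conditions sharing a letter are statistically indistinguishable).

No raw time courses are deposited for such studies, so the package ships a
mechanistic generator (`simulate_batch()`, `generate_study()`) producing
batch trajectories with the structure the analysis assumes: Monod growth,
Andrews substrate inhibition, product toxicity, Luedeking–Piret product
formation, a yield/maintenance substrate balance, cardinal-pH and salinity
stress responses, and multiplicative log-normal replicate noise. Every
downstream stage is therefore testable end to end with known ground truth.

## Worked example

```r
library(fermkin)

# one noise-free reference fermentation: 150 g/L glucose, seawater, pH 5.5
tc <- simulate_batch(sim_params())
kinetic_descriptors(tc)[c("e_p", "x_m", "y_ps", "q_p", "q_s", "mu")]
#> $e_p  89.43      # peak ethanol, g/L
#> $x_m  9.779      # peak biomass, g/L
#> $y_ps 0.5962     # ethanol yield on initial glucose, g/g
#> $q_p  1.242      # volumetric productivity, g/(L h)
#> $q_s  2.024      # substrate uptake, g/(L h)
#> $mu   0.07782    # specific growth rate, 1/h

# Monod fit to a noise-free rate-vs-substrate point set
s <- c(50, 100, 150, 200, 250)
fit_monod(data.frame(s = s, rate = monod(s, 0.141, 24.4)))
#> <monod_fit> rate_max = 0.141 (se 2.94e-17), Ks = 24.4 (se 2.93e-14) g/L
#>   n = 5, SSE = 1.733e-33, R2 = 1.0000, converged = TRUE (1 iterations)
```

The peak ethanol (~89 g/L), yield (~0.60 g/g) and productivity
(~1.25 g/(L·h)) are the magnitudes a strong marine isolate reaches at 15%
glucose; the fitter returns the generating Monod parameters exactly on
noise-free data.

## Analysis workflow

The `analysis/` directory holds the numbered study drivers, each a thin
script over the package functions, writing its tables under `results/`:

1. `01_simulate.R` — generate the three one-factor designs (glucose
   gradient, pH gradient, salinity gradient; 3 replicates, 2% noise).
2. `02_descriptors.R` — descriptor tables per condition with replicate
   means ± SD.
3. `03_monod.R` — Monod fits of specific growth/production rates vs initial
   glucose, plus a Monte-Carlo parameter-recovery experiment; also shows
   why *K*<sub>s</sub> ≈ 24 g/L is unidentifiable from a 50–250 g/L
   gradient alone.
4. `04_compare.R` — Tukey letter tables and optimum identification per axis
   (the run identifies pH 4.5 and 100% seawater as the optima).
5. `05_run_study.R` — the same pipeline as a single `run_study()` call with
   a JSON-configurable `study_config()` and a reproducibility manifest.

## Methods

See `vignettes/fermentation-kinetics.Rmd` for the model equations,
parameter choices, numerical details and known limitations.
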