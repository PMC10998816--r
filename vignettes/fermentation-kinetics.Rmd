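---
title: "Batch fermentation kinetics: model, descriptors and comparison methods"
author: "fermkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Batch fermentation kinetics: model, descriptors and comparison methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermkin)
```

## The problem

Bioethanol optimization studies with non-conventional yeasts — here the
motivating system is a halotolerant marine yeast fermenting glucose in
seawater-based medium — characterize each culture condition by a handful of
kinetic descriptors computed from batch time courses of biomass $X(t)$,
ethanol $P(t)$ and residual substrate $S(t)$, then locate the optimal carbon
source, initial substrate concentration, salinity and pH. The raw
trajectories behind such studies are rarely deposited; what survives are
descriptor tables and fitted saturation curves. This package implements the
full analysis chain as tested, reusable code, and couples it to a
mechanistic simulator so that every stage can be exercised against known
ground truth.

## The generative model

`simulate_batch()` integrates the minimal standard structure consistent with
the behaviours such studies report. Specific growth rate is Monod in
substrate, optionally damped by Andrews substrate inhibition and by product
toxicity, and scaled by an environmental stress factor $f \in [0,1]$:

$$\mu(S, P) \;=\; f \cdot \mu_{max}\,\frac{S}{K_s + S}
  \cdot \frac{1}{1 + S/K_i}
  \cdot \max\!\left(0,\, 1 - P/P_{crit}\right)^{n}$$

Product formation is Luedeking–Piret (a growth-associated term $\alpha\mu X$
plus a non-growth-associated term $\beta f X$), and substrate closes the
balance through the two yields and a maintenance term:

$$\frac{dX}{dt} = \mu X, \qquad
  \frac{dP}{dt} = (\alpha\mu + \beta f)\,X, \qquad
  \frac{dS}{dt} = -\frac{1}{Y_{X/S}}\frac{dX}{dt}
                  -\frac{1}{Y_{P/S}}\frac{dP}{dt} - m_s X .$$

Substrate exhaustion is a terminal event: once $S = 0$ all rates freeze,
which avoids negative-substrate artifacts. Integration uses a stiff-safe
adaptive solver (`deSolve::lsoda`, rtol $10^{-8}$, atol $10^{-10}$), and the
output grid ($0, \Delta t, 2\Delta t, \dots$) is independent of the
integrator's internal stepping — halving the sampling interval changes
nothing at shared times beyond solver tolerance.

The exactness of the balance is testable: on any noise-free run,
$(S_0 - S) - \left[\Delta X / Y_{X/S} + \Delta P / Y_{P/S} + m_s\int X\,dt\right]$
re-integrated trapezoidally from the emitted trajectory stays below
$10^{-6} S_0$ (the quadrature, not the solver, is the limiting error, so the
check uses a 0.5 h output grid).

### Environmental stress

The factor $f$ is a product of two terms evaluated once per condition:

* a **cardinal pH** term
  $\dfrac{(pH - pH_{min})(pH - pH_{max})}{(pH - pH_{min})(pH - pH_{max}) - (pH - pH_{opt})^2}$,
  zero at and outside the cardinal extremes (defaults 2.5 and 8.0) and 1 at
  the optimum (default 4.5) — the standard three-parameter cardinal model
  for microbial pH response;
* a **salinity** term $\exp(-d_{hi}\max(0, m - m_{opt}) - d_{lo}\max(0, m_{opt} - m))$
  on a single molar NaCl axis, where the labels `distilled`,
  `half_seawater`, `seawater` map to 0, 0.3 and 0.6 M (seawater carries
  roughly 35 g/L salt). A marine isolate grows best at full seawater
  strength: capacity decays at $d_{hi} = 0.5$/M above the optimum (growth
  persists, markedly reduced, at 4 M) and at a gentler $d_{lo} = 0.25$/M
  below it. The sub-optimal decay is deliberate: with no below-optimum
  penalty, distilled water would tie seawater, contradicting the osmotic
  preference the simulator is meant to emulate (fresh-to-seawater yield
  ratio comes out near 0.86, matching the observed behaviour of marine
  isolates).

### Reference preset and noise

The defaults of `sim_params()` form the package's reference preset for a
strong glucose-fermenting marine isolate: $\mu_{max} = 0.141$/h and
$K_s = 24.40$ g/L (the magnitudes reported for such isolates), with
$K_i = 450$ g/L, $\alpha = 3$ g/g, $\beta = 0.18$ g/(g·h),
$Y_{X/S} = 0.22$, $Y_{P/S} = 0.88$, $m_s = 0.005$ g/(g·h),
$P_{crit} = 110$ g/L, $n = 2.2$, $x_0 = 0.5$ g/L, $s_0 = 150$ g/L over 72 h
sampled every 4 h. These constants were chosen once so that the base
condition (150 g/L glucose, seawater, pH 5.5) lands at the magnitudes a
top-performing isolate reports — peak ethanol ≈ 90 g/L still rising at 72 h
(so $Q_p \approx 1.25$ g/(L·h)), peak biomass ≈ 9–10 g/L, ethanol yield
≈ 0.60 g/g, near-exhaustion of substrate — and so that the ethanol response
over 50–250 g/L initial glucose peaks interiorly near 175 g/L with a decline
above it (the Andrews term supplies the decline; the product-toxicity term
lets fermentations terminate below full exhaustion).

Measurement noise is multiplicative log-normal, parameterized to mean 1 and
a chosen coefficient of variation (concentrations are positive and their
dispersion scales with level). Replicate streams use per-cell,
per-replicate seeds derived by a counter-based mixing scheme
(`derive_seed()`), so a study is reproducible element-wise and any replicate
can be regenerated in isolation.

The default study (`study_config()`) runs the substrate axis at pH 5.5 in
seawater, and the pH and salinity axes at 175 g/L glucose — the level at
which the modeled ethanol response peaks — with 3 replicates at 2% noise.
At 150 g/L the near-exhaustion ceiling flattens the pH response near its
optimum; at 175 g/L the optimum is expressed cleanly (~105 g/L ethanol at
pH 4.5 versus ~90 g/L at pH 5.5, and a sharp drop toward pH 3).

## Kinetic descriptors

For each time course, `kinetic_descriptors()` computes peak-based summaries:
$E_p = \max P$, $X_m = \max X$ (peaks, not final values, since productivity
is referred to "the time giving the highest ethanol concentration");
$Y_{P/S} = E_p/S_{G0}$ and $Y_{X/S} = X_m/S_{G0}$ on the *initial* substrate;
$Q_p = E_p/t_{peak}$ with $t_{peak}$ the *earliest* time attaining the
maximum (deterministic tie-break); $Q_s = (S(0) - S(t_{peak}))/t_{peak}$
over the same window as $Q_p$ for consistency, reported as absent when no
substrate series exists.

Two readings of the specific production rate are exposed: the pointwise
$v(t) = (dP/dt)/X$ by central differences (one-sided at the ends, floored
at 0), summarized by its maximum `v_peak`; and the ratio form
$v_g = Q_p / X_m$, which is the summary that published descriptor tables
actually print (it reproduces their specific-rate rows exactly from the
printed $Q_p$ and $X_m$ columns). Both are reported; the identities
$Y_{P/S} S_{G0} = E_p$ and $v_g X_m = Q_p$ hold exactly by construction and
are asserted in the tests.

The specific growth rate $\mu$ is the slope of $\ln X$ versus $t$. Because
"the logarithmic plot" implies a manually chosen exponential phase, the
window is formalized as: the contiguous window of at least 4
positive-biomass points maximizing the regression $R^2$ subject to a
positive slope, ties broken toward longer and then earlier windows; if no
positive-slope window exists, $\mu = 0$ with an empty window. On exact
exponential data this returns the full range; on
exponential-then-plateau data it stays inside the exponential phase and
recovers the generating rate within 2%.

No smoothing is applied before differencing; noise handling belongs to
replication, and the comparison layer consumes replicate dispersion
directly.

## Monod fitting

`fit_monod()` minimizes the least-squares criterion for
$\mathrm{rate}(S) = \mathrm{rate}_{max} S/(K_s + S)$ with
Levenberg–Marquardt on *log-parameters* (positivity by construction;
`minpack.lm::nls.lm` with ftol = ptol = $10^{-10}$, at most 500 iterations).
Starting values come from the Hanes–Woolf linearization ($S/\mathrm{rate}$
regressed on $S$), which is exact on noise-free Monod data, with a stated
fallback for degenerate (rate-flat) inputs. Non-convergence is a returned
state with diagnostics, never an exception, so batch studies proceed.
$R^2 = 1 - SSE/SST$ about the mean rate (the convention nonlinear-regression
software reports); it can be negative for bad fits and is flagged undefined
when the rates are constant. Asymptotic standard errors come from the
Gauss–Newton Hessian via the delta method.

Tests pin the fitter to independent oracles: exact recovery on noise-free
curves, the closed-form reciprocal-linear solution for two-point systems,
and a 400×400 logarithmic grid search whose best SSE the fit must match or
beat.

Two practical identifiability points, surfaced by the workflow in
`analysis/03_monod.R`:

* Over a 50–250 g/L gradient with $K_s \approx 24$ g/L, the growth rate is
  already ≥ 67% saturated at the lowest level, and substrate inhibition
  flattens the top, so $K_s$ is essentially unidentifiable from that design
  ($R^2$ near 0 is the honest outcome, not a fitting failure). A gradient
  reaching below $K_s$ recovers both parameters to within ~2%.
* A fitted $K_s$ far above the tested range (as happens for the specific
  production rate) means the curve is operating in its near-linear regime:
  the ratio $\mathrm{rate}_{max}/K_s$ is well determined but the two
  parameters separately are not.

`fit_monod(..., exclude_inhibited = TRUE)` optionally drops points above the
rate-maximizing substrate level, for data whose decline the saturation model
cannot represent; the default fits all points, matching the common practice
of fitting the full tested range.

`recovery_experiment()` quantifies fit reliability by Monte Carlo: rates
generated from a known curve with mean-1 multiplicative noise, refitted, and
summarized as per-parameter median bias and RMSE. At 5% noise on five
substrate levels and 200 replicates, the maximum-rate parameter is recovered
with sub-percent median bias and median $R^2 \approx 0.9$.

## Condition comparison

Replicate descriptor values per condition are compared with one-way ANOVA
(via `stats::lm`/`anova`) and Tukey's HSD: for each pair,
$q = |\bar y_i - \bar y_j| / \sqrt{MSW\,(1/n_i + 1/n_j)/2}$ (the
Tukey–Kramer harmonic form, reducing to the classical statistic for the
balanced $n = 3$ designs these studies use), compared against the
studentized-range quantile at $(k, df_{within}, \alpha = 0.05)$ computed
numerically (`qtukey`/`ptukey`; the quadrature is accurate to ~$10^{-8}$,
which bounds the agreement with the pooled $t$ test at $k = 2$).

Letters are assigned by insert-and-absorb: starting from one class holding
all groups, each significant pair splits every class containing both
members, and subset classes are absorbed. The resulting display satisfies
the defining invariant — two conditions share a letter **iff** their
comparison is non-significant — which the tests verify by round-trip against
1,000 random significance patterns (including non-transitive ones). Classes
are lettered in descending order of their top member's mean, so `a` always
marks the best group. Degenerate inputs (groups with fewer than 2 values,
all-identical data, zero within-group variance everywhere) raise classed
errors rather than returning misleading statistics; `find_optimum()` and
`run_study()` degrade gracefully (noise-free replicates fall back to
equal-mean ties; single-replicate designs skip the comparison stage with a
warning).

A note on published letter patterns: letter displays in printed tables are
not always consistent with the printed dispersions. With group means
separated by more than 1.5 g/L and standard deviations of 0.1–0.2 at
$n = 3$, *every* Tukey pair is significant ($q \approx 20$ against a
critical value near 4.7); a shared letter between the two lowest-yield
isolates in the motivating study's screening table cannot be reproduced
from its own printed values, and this package's comparison layer does not
attempt to force it.

## Study driver and reproducibility

`run_study()` ties generation → descriptors → Monod fits → comparison →
optima into one call from a validated `study_config()` (JSON-serializable; a
reference configuration ships in `inst/extdata/ze75_study.json`). Every
artifact is written in the package's own delimited formats and is
re-readable by its own readers; a manifest records the package version, the
seed, an MD5 hash of the configuration and the artifact list, and is written
even when a stage fails (with the failing stage named). A single master
seed drives stage-scoped derived seeds, so identical configurations give
byte-identical numeric outputs while stages remain independently
re-runnable.

Problem sizes were chosen to keep the full workflow light: the default
study integrates 75 fermentations of 72 h at 4 h sampling, and the
recovery experiment uses 200 Monte-Carlo replicates of a 5-point fit —
a few seconds in total.

## What the simulator does and does not establish

Passing tests on synthetic data show that the analysis chain is correct
*given* data of the assumed structure: Monod growth with multiplicative
stress factors, Luedeking–Piret production, log-normal replicate noise
independent across sampling times. Real fermentations violate parts of
this: measurement error is partly systematic (assay calibration),
autocorrelated within a run, and heavier-tailed; diauxic or lag-phase
behaviour is not modeled (the 5 h aerobic lead-in such protocols use is not
represented as a separate phase); temperature and gas-phase effects are
absent; and the cardinal-pH/salinity response is a smooth caricature of
physiology. Descriptor definitions and the comparison layer do not depend
on these assumptions, but end-to-end optimum-recovery results should be
read as validating the pipeline, not as evidence about any particular
organism.

Known limitations: no alternative rate laws (Moser, Tessier, Contois)
beyond the optional inhibited-branch exclusion; no weighted or robust
regression; no multi-factor ANOVA or interaction analysis (the emulated
designs vary one factor at a time); letter displays support up to 26
classes.
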