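---
title: "Models and methods: fluorescence-based mitochondrial thermometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: fluorescence-based mitochondrial thermometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotherm)
```

## The inference problem

A temperature-sensitive fluorescent probe inside mitochondria reports the
organelle's temperature only relative to an unknown, per-experiment gain.
Two design elements make the readout quantitative:

1. **Internal step calibration.** At the end of each recording the Peltier
   jacket imposes known temperature steps on the cuvette. The fluorescence
   (or fluorescence-ratio) change per imposed °C is a per-trace conversion
   factor, so dye loading, expression level, lamp intensity and detector
   gain all cancel.
2. **The full-inhibition assumption.** When an inhibitor abolishes
   mitochondrial heat production, the probe relaxes to the cuvette
   temperature. The measured fluorescence shift therefore equals the
   pre-inhibition *elevation* of mitochondrial temperature above ambient,
   and ambient + decrease is a lower bound on the pre-inhibition
   mitochondrial temperature (`reconstruct_mito_temperature()`).

Everything in this package is organised around testing that chain by
parameter recovery: a forward simulator renders traces from a known
ground-truth elevation trajectory `E(t)`, the pipelines invert them, and
the tests assert the truth is recovered.

## Forward models

**Cuvette thermal dynamics.** The cuvette follows setpoint changes with a
first-order lag, `dT/dt = (setpoint − T)/τ`, evaluated with the exact
exponential solution per sample (`build_peltier_trace()`). The default
`τ = 40 s` makes equilibration (~3τ) take about two minutes, matching
stirred-cuvette behaviour; `τ = 0` gives an idealised instantaneous
jacket, which the algebra-isolating tests use.

**MTY.** `render_mty_trace()` renders
`F = q·g·[1 − s·(T − T_ref) − c₂·(T − T_ref)²]·e^(−λt) + A + ε`,
with i.i.d. Gaussian noise of SD `noise_sd · g`. Defaults: gain
`g = 1000 AU`, fractional response `s = 0.025 /°C`, autofluorescence
`A = 50 AU`, no bleaching, quadratic term `c₂ = 0`. The mild quadratic
term exists because the dye's response may deviate slightly from
linearity at high temperature; it is off by default since its magnitude
is not established. Two artifact switches mimic known failure modes: a
`leakage` flag adds an unbounded slow rise after the drug event (the
behaviour that prevents any stable reading in some cell types), and
`quench_factor` models drugs that quench the dye directly.

**mito-gTEMP.** `render_gtemp_trace()` renders mT-Sapphire as
temperature-independent (`e·k + A_sap + ε`) and Sirius as strictly
decreasing in temperature. The Sirius channel uses the reciprocal-affine
form `e / (1 + s_sir·(T − T_ref)) + A_sir + ε`, a deliberate design
choice: it is locally indistinguishable from a linear decrease for small
slopes, yet makes the Sapphire/Sirius ratio *exactly* affine in
temperature with zero backgrounds. The linear ratio calibration is then
the exact algebraic inverse of the generator, so zero-noise round trips
close to machine precision and any residual error in tests is
attributable to the analysis, not to model mismatch. Default
`s_sir = 0.025 /°C`, `k = 1`, expression 1000 AU, noise SD
`noise_sd · expression` per channel.

**Scenarios.** `build_scenario()` encodes the study conditions as
elevation trajectories. The kinetic laws are modelling choices — the
experiments report phenomenology (plateau "over ~10 min", rewarming "over
40–70 min"), not rate laws — and single exponentials are the simplest
forms consistent with them:

* `inhibitor`: constant elevation (default 18 °C), exponential decay to a
  residual (default 0, the calibration assumption) with τ = 180 s after
  the drug at 600 s, terminal +3/−3 °C staircase at 2100 s with 360 s
  holds (satisfying the ≥4 min spacing policy).
* `starvation`: rise with τ = 150 s to a peak elevation of 16.5 °C near
  10 min, then linear decline of 4 °C over the following 25 min — the
  reported behaviour of substrate-starved cells.
* `substrate_rescue`, `bka`: variants with substrate arrest of the
  decline, and a small transient bump plus ~1 °C net decline respectively.
* `aox_inhibitor`: fast cooling (τ = 120 s for the rotenone preset, drop
  10 °C) to a fluorescence peak ~10 min after the drug, then exponential
  rewarming toward the pre-drug elevation with τ = 1800 s (full recovery
  for rotenone; the antimycin/KCN presets use smaller drops, faster onset
  and partial recovery, reflecting the qualitative per-inhibitor
  differences). The calibration staircase sits late in the record
  (5400 s).
* `anisomycin`: a Gaussian-shaped +4 °C transient centred at 1 h with
  σ = 25 min, reverting over ~2–3 h.

Noise is i.i.d. Gaussian per sample with no autocorrelated drift other
than the bleaching exponential and the explicit leakage artifact — the
simplest model under which the plateau criterion is meaningful. Sampling
is 1 Hz, matching continuous fluorimeter acquisition.

**Fractionation.** `simulate_fractionation()` splits a labelled pool
twice (mitoplast vs OM/IMS; SMP vs matrix). Each labelled reading is
`retention · pool + autofluorescence + noise`; the paired blank reading is
`autofluorescence + noise`. Default autofluorescence is 4–8 % of the pool
per fraction and noise is relative to each reading's mean.

## Analysis defaults and why

* **Plateau criterion** (`detect_plateau()`): first sliding window
  (default 300 s) whose least-squares slope magnitude is below tolerance;
  the default tolerance is 0.1 % of the pre-drug baseline per minute.
  "Reached a stable value" is otherwise unquantified; this makes it
  operational and is validated against a brute-force per-window
  regression oracle.
* **Analysis windows**: baseline = the 60 s before the drug event;
  response = the 60 s before the first calibration step. Fixed windows
  are reproducible and, at the default kinetics, the elevation residual
  at the response window is negligible relative to measurement noise.
* **Calibration step reduction**: discard the first 120 s of each step
  (thermal re-equilibration, ~3τ), average the final 60 s. For the
  ratiometric staircase with 3-min steps this *is* "the third minute";
  the same rule is applied to MTY, where no averaging span is prescribed.
  The default staircase holds the first (large, −8 °C) shift for 300 s
  before the 3 °C/180 s steps, because a bigger shift needs longer to
  equilibrate; the whole staircase spans 17 min, well inside the 35-min
  photodamage limit that `fit_ratio_calibration()` enforces as an error.
* **Suspicious-fit policy**: an MTY calibration slope ≥ 0 or r² < 0.9 is
  flagged, never silently dropped; an unstable trace yields an estimate
  with `stable = FALSE` rather than no estimate.
* **Extrapolation**: inferred temperatures outside the calibrated
  30–42 °C range are reported unchanged with `extrapolated = TRUE` — the
  dotted-line convention. Physiological readings (~50–55 °C) are always
  extrapolated; the inference is only as good as the linearity assumption.
* **Replicate pooling** for calibrations: fit per staircase, average
  coefficients (`pool_ratio_calibrations()`); a pooled-points fit is
  available by flag. With equal-design replicates the two coincide.
* **Drug-background QC** (`check_drug_background()`): a cell-free blank
  may shift its individual channels (oligomycin-style) as long as the
  mean ratio moves by at most 2 % (`ratio_tol`); a Sirius-specific shift
  (antimycin-style) fails. The 2 % default corresponds to <1 °C at the
  default ratio sensitivity.
* **Fractionation accounting**: corrected signal = labelled − blank;
  negative corrected signals are an error (surfacing assay/simulation
  faults) rather than being clipped to zero; SD is reported only with
  ≥3 trials, since two-trial experiments quote only a mean.
* **Statistics**: Student's (equal-variance) t by default since that is
  the named test, Welch by flag; Tukey HSD via the studentized range
  distribution (`stats::TukeyHSD`); stars at 0.05/0.01/0.001.

## Numerical choices

* The Peltier ODE is advanced with its exact per-segment exponential
  solution — no integration error at any `dt`.
* Rolling window slopes are computed by convolution with the centred
  abscissa weights, algebraically identical to per-window `lm()` (and
  tested against it up to 10⁴ samples).
* r² is computed from residual and total sums of squares directly, with
  a zero-variance response defined as a perfect fit (r² = 1), so exact
  two-point and collinear calibrations behave sensibly.
* Seeded rendering saves and restores the caller's RNG state; identical
  seeds give bitwise-identical traces.
* Ratio denominators below 1 % of the Sirius channel median are masked,
  not zero-filled; >10 % masked samples abort the analysis.
* Degenerate designs (all calibration temperatures equal, zero slope,
  empty intervals, insufficient post-drug record) raise typed errors
  (`mitotherm_validation_error`, `mitotherm_qc_error`) that the CLI maps
  to exit codes 2 and 3.

## Problem sizes used in validation

The test suite and the acceptance script run entirely on simulated data
at the study's own scale: records of 2 000–10 000 one-second samples, 20
replicate traces for the oligomycin recovery, 10 for the rotenone/AOX
response, two-trial fractionations (50 trials in the noise-property
test), and 20 noisy replicates for the ratiometric recovery property.
These sizes were chosen to match the experimental designs they emulate
while keeping every check comfortably deterministic in outcome.

## What passing tests do and do not show

The generator emulates the features the pipelines rely on: first-order
cuvette dynamics, linear (or reciprocal-affine) probe responses,
plateau-forming kinetics, calibration staircases, autofluorescent
backgrounds, and the known artifact modes (leakage, quenching,
drug-specific background shifts). It does not emulate photon statistics,
spectral bleed-through, membrane-potential or pH cross-sensitivity,
cell-to-cell heterogeneity (averaged out in a stirred cuvette), or slow
autocorrelated drifts other than bleaching. Parameter recovery on these
simulations therefore validates the *inference algebra and its
robustness to the modelled noise* — it cannot by itself certify the
probes' in-vivo linearity, which is an assumption inherited from their
characterisation, flagged wherever extrapolation is involved.

## Known limitations

* The elevation kinetics (exponential cooling/rewarming, linear
  starvation decline) are modelling choices; only their phenomenological
  envelopes are constrained by observation.
* No correction is applied for the possible MTY nonlinearity above
  ~50 °C (the optional quadratic term defaults to 0), consistent with
  quoting reconstructed temperatures ±2 °C.
* A calibration staircase recorded while the elevation is still changing
  (e.g. during active rewarming) biases the fitted slope by a few per
  cent; placing the staircase after the kinetics have settled avoids
  this, and the rewarming tests do so.
* Bleaching correction (linear detrend of the pre-drug plateau,
  extrapolated through the record) is available via
  `estimate_temperature_shift(detrend = TRUE)` but off by default.
  Because bleaching is multiplicative and the detrend is linear, the
  correction reduces but does not eliminate the bias; at realistic rates
  the residual is small against measurement noise.
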