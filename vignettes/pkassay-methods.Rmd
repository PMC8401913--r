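---
title: "Models, conventions and design decisions in pkassay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, conventions and design decisions in pkassay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkassay)
```

`pkassay` covers the computational side of a plasma LC-MS/MS assay and
its pharmacokinetic application: internal-standard calibration and
quantification, the bioanalytical validation battery, chromatographic
signal handling, and noncompartmental analysis (NCA), together with a
synthetic-data generator that provides known ground truth for all of
it. This vignette records the models, the conventions behind every
reported number, and the decisions taken where the design was genuinely
open.

## 1. The simulated world

### Pharmacokinetic model

The generator uses one-compartment kinetics as its generative truth —
the simplest model consistent with a mono-exponential terminal phase,
which is the assumption NCA's λz regression itself makes:

* IV bolus: $C(t) = \dfrac{D}{V} e^{-kt}$
* Oral (Bateman): $C(t) = \dfrac{F_{abs}\,D\,k_a}{V\,(k_a-k)}
  \left(e^{-kt} - e^{-k_a t}\right)$, with analytic
  $T_{max} = \ln(k_a/k)/(k_a - k)$. The flip-flop degenerate case
  $k_a = k$ is rejected rather than handled with its special-case
  limit.

The absolute dose is `dose_per_kg * body_weight` expressed in ng, so
with $V$ in mL concentrations come out in ng/mL.

### Default parameters and why

| parameter | default | unit | rationale |
|---|---|---|---|
| IV dose | 2 | mg/kg | the study design being emulated |
| oral dose | 20 | mg/kg | idem |
| body weight | 0.02 | kg | adult female BALB/c mouse; per-animal weights are never published, so one nominal weight is fixed |
| V | 14.4 | mL | with k below, puts the first IV sample near the observed Cmax scale (≈ 2.6 µg/mL at 5 min) |
| k | 0.014 | 1/min | IV terminal half-life ≈ 49.5 min, the observed scale |
| ka | 0.07 | 1/min | oral Tmax ≈ 29 min, inside the observed 15–40 min window |
| f_abs | 0.004 | — | F ≈ 0.4 %, the poor-phytosterol-absorption regime reported for this compound class |
| error_cv | 0.05 | fraction | 5 % assay-level CV, the upper end of the validated precision |
| schedules | 5–120 (IV), 15–240 (oral) | min | the emulated sparse mouse design, configurable |
| LLOQ | 4 | ng/mL | the validated quantification range 4–300 ng/mL |

One deliberate inconsistency with the emulated study: its IV and oral
arms report different terminal rate constants (0.016 vs 0.005 /min).
A single-compound, single-compartment simulator cannot produce both, so
both routes share k = 0.014 /min; the oral λz of the simulated world is
therefore k, not the smaller printed oral value. These defaults were
fixed once, before any acceptance measurement, and are not tuned.

### Noise model

Measurement error is multiplicative lognormal,
$C_{obs} = C_{true}\,e^{\sigma Z}$ with
$\sigma^2 = \log(1 + cv^2)$ — median-preserving: the noise-free value
is the *median* of the noisy draws, and the mean is inflated by
$e^{\sigma^2/2}$ (0.125 % at cv = 0.05). The tests check the mean
against that documented value rather than pretending the bias away.
Concentrations stay positive by construction, matching how assay CVs
are specified. Simulated values below the configured LLOQ keep their
raw value and carry a BLQ flag, so downstream BLQ policy is testable.

### What the generator does not emulate

No extraction-recovery chemistry, hydrolysis kinetics, ion-source
physics, retention-time drift, peak tailing, or between-run calibration
drift. A green recovery test therefore establishes that the *estimators*
behave on sparse noisy data from the stated kinetic model — not that
the wet-lab method would validate.

## 2. Signal processing

A chromatogram is a uniformly sampled time–intensity trace on one MRM
channel. Peak integration subtracts a baseline estimated as the mean
intensity over flanking regions (one window-width each side by default,
explicit windows allowed) — flanking means rather than a local minimum
because the former is deterministic and unbiased on noisy synthetic
traces. Area is the trapezoidal integral of the baseline-subtracted
intensity clipped at zero; height is the baseline-subtracted apex,
earliest sample on ties.

S/N is defined as peak height over baseline-noise SD (peak-to-RMS), and
the LLOQ rule takes the lowest standard with S/N at or above a
threshold, default 10. The emulated study names the S/N criterion but
defines neither the ratio nor the threshold; both are configuration
here, not an inference about the original software. Noise is the
empirical SD with divisor *n*: on the mandated ≥ 10 samples this is
within 5 % of the n−1 convention, and it makes the alternating ±d
fixture exact. A noise estimate below `eps = 1e-8` raises a zero-noise
error instead of returning an infinite S/N.

## 3. Calibration and quantification

The calibration line is least squares of the response ratio
(analyte/IS) on nominal concentration. Default weighting is `none`,
because a single reported line with a plain R² is what simple linear
regression produces; `1/x` and `1/x²` are offered since bioanalytical
labs routinely use them. R² under weights is computed about the
weighted mean so that `weighting = "none"` is exactly the unweighted
fit.

Back-calculation is the algebraic inverse; negative values are
*reported* with a BLQ flag, never clamped, because clamping would bias
the validation statistics computed from them. The deviation of a
back-calculated standard is `(calculated − nominal)/nominal × 100`
(within 15 %, 20 % at the LLOQ level). The prose definition in the
emulated study inverts numerator and denominator relative to its own
tables; the tables' arithmetic is what is implemented.

`quantify()` flags, rather than fails: measured value below LLOQ → BLQ;
above ULOQ → needs dilution; the dilution factor multiplies the
measured value and the result is linear in it.

## 4. Validation statistics

Every statistic and its judgment are separate. The statistic layer:

* `mean_sd_cv()` — SD divisor *n* (population) by default, because that
  convention reproduces the emulated study's printed triplicate
  summaries exactly (e.g. 108/115/130 → SD 9, CV 8; the n−1 SD of 11.2
  does not); the sample convention is a config switch.
* accuracy = mean determined / nominal × 100 — again the direction the
  printed tables actually use, not the inverted prose sentence.
* between-run pools replicates across ≥ 2 runs; within-run requires a
  single run.
* IS-normalized matrix factor = (analyte matrix/solvent) / (IS
  matrix/solvent), so common-mode suppression cancels.
* carryover: blank-after-ULOQ analyte response strictly below 20 % of
  the LLOQ response and blank IS strictly below 5 % of working IS —
  strict, so "exactly at the limit" fails, the conservative reading.
* stability and dilution integrity reuse the same mean/CV/accuracy
  machinery; dilution levels are judged on the non-LLOQ bounds since
  they sit far above the LLOQ.

The judgment layer ships as two presets: `"paper"` (CV ≤ 5 %, accuracy
85–115 %, LLOQ 80–120 %) and `"ema"` (CV ≤ 15 %, 20 % at LLOQ, same
accuracy bounds). The emulated study claims EMA compliance yet states
the 5 % CV limit, so neither preset is asserted as the authors' intent;
accuracy and CV bounds are inclusive (85.0 passes), carryover is
strict. Reported numbers are rounded half-up (not banker's rounding) to
the configured decimals; all pass/fail flags are reproducible from the
printed statistics plus thresholds alone.

## 5. Noncompartmental analysis

* **λz**: OLS of log concentration on time. Candidate points are the
  positive, non-BLQ concentrations strictly after Tmax (oral) or after
  the first sample (IV bolus, where the first sample is the peak). The
  default policy searches every contiguous subset of ≥ 3 candidates
  ending at the last point and keeps the best adjusted R², ties
  (within 1e-10) to more points — the common automatic rule when the
  original point selection is unknown. `"last3"` exists for
  reproducibility comparisons. A non-negative best slope is a
  no-elimination-phase error, not a silent NA.
* **T1/2** = ln 2/λz; at one-decimal reporting this is identical to the
  0.693/λz convention (0.693/0.005 = 138.6 either way).
* **AUC/AUMC**: linear trapezoid only, because that is the stated
  method of the emulated analysis; a log-linear down-slope variant was
  considered and deliberately not defaulted. Time-zero convention:
  oral curves prepend (0, 0); IV curves back-extrapolate
  $C(0) = e^{b}$ from the log-linear line through the first two points
  when the profile starts declining, else fall back to the first
  observed concentration (also selectable as `"first_obs"`). `t_end`
  between samples is handled by linear interpolation on the chord, which
  keeps AUC additive over adjacent intervals.
* **BLQ policy**: zero before Tmax, excluded after — standard NCA
  practice; the emulated study is silent.
* **Vd, Cl**: `Vd = Dose/(λz·AUC)` with either AUC0–t (`"standard"`) or
  AUC0–t + Clast/λz (`"auc_inf"`); `Cl = λz·Vd` holds identically in
  both. Units are mL and mL/min from the nominal mouse dose; the
  emulated study's printed Vd (0.281 mL) and Cl ("0.004 ng/min") cannot
  be reconciled with any standard definition without the unpublished
  per-animal dose amounts, and are not reproduced.
* **F** = dose-corrected AUC ratio × 100. Per-subject parameters are
  computed first and then averaged (the emulated study's IV T1/2 mean
  49.35 ≠ 0.693/0.016 shows its authors did the same). In the
  truncation-matched recovery test F is computed on extrapolated AUCs:
  with route-specific truncation (120 vs 240 min) the AUC0–t ratio
  carries an ≈ 18 % upward truncation bias at the default parameters —
  an artifact of unequal sampling windows, not of the estimator.

## 6. Numerical choices and degenerate inputs

* Regressions use `stats::lm`; adjusted R² is computed from residual
  sums directly so perfect (noise-free) fits do not warn.
* `round_half_up()` implements the half-away-from-zero reporting rule.
* All user-facing failures are classed conditions
  (`pkassay_*_error`), so callers and the CLI can translate failure
  kinds into exit codes (1 config, 2 I/O) without parsing messages.
* Determinism: every stochastic function takes a mandatory integer
  seed and restores the RNG state (`withr::with_seed`); identical seeds
  give byte-identical CSV output.

## 7. Known limitations

* One-compartment truth only; multi-exponential disposition (which the
  emulated IV profile's MRT hints at) is out of scope, as is any
  compartmental fitting.
* No incurred-sample reanalysis, recovery-by-spiking, or regulatory
  report formatting.
* The λz subset search is over contiguous terminal windows only; it
  will not drop interior outliers.
* Simulated chromatograms are single Gaussian peaks; the peak
  integrator is not a deconvolution tool and applies no smoothing.
* Absolute Vd/Cl recovery is limited by the nominal body-weight
  assumption; only ratios (F, T1/2, MRT) are weight-free.
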