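---
title: "Extracting SF6 washout signals from ultrasonic molar-mass recordings"
author: "sf6mbw"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting SF6 washout signals from ultrasonic molar-mass recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sf6mbw)
```

## The measurement and its confounders

Infant multiple-breath washout (MBW) with SF6 uses a single ultrasonic
flowmeter that senses the transit time of sound across its measurement
path. The acoustic relation

$$c = \sqrt{\gamma R T / MM}$$

lets the instrument report a molar-mass (MM) signal, assuming a calibration
temperature and adiabatic index $\gamma$. A 4% SF6 admixture raises the
molar mass of air by about 4.7 g/mol, but three other things move the
signal on the same scale:

1. **Tidal temperature and humidity swings.** Expired gas is warmer and
   saturated; inspired gas is near ambient. Because the device inverts the
   acoustic relation at a fixed temperature, a 3 K tidal swing alone
   perturbs the displayed molar mass by ~1% (≈ 0.3 g/mol), a fifth of the
   full SF6 signal.
2. **CO2/O2 exchange**, which changes the composition of expired gas.
3. **Side chambers**: recesses of the measurement path that exchange gas
   with the main stream only gradually, so the displayed signal blends the
   current gas with a lagged copy of it.

The classical approach models these disturbances explicitly (temperature
and diffusion models with many center- and subject-specific input
parameters). This package instead uses only reference information contained
in the recording itself: phases of the measurement where the SF6
concentration is known exactly.

## Pipeline

`analyze_recording()` chains five stages. All tunables live in
`analysis_config()`; defaults are given in parentheses.

### 1. Breath and phase detection

Breaths are cut at zero crossings of lightly smoothed flow (moving average,
50 ms) — the smoothing provides hysteresis against sensor noise — and
candidate half-breaths smaller than 2 mL or shorter than 0.3 s are merged
into their neighbours. Each breath's end-tidal molar mass is the median
over the last 5% of its expired volume, which is robust to noise and to the
choice of window.

Phases are assigned on the end-tidal series, not on raw samples, so tidal
confounders cannot trigger false transitions. The pre-phase grows while
end-tidal values stay within 5 robust spreads (MAD, floored at 0.02 g/mol)
of the running pre-phase median; the first breath exceeding that threshold
starts the washin. The washout starts at the first breath falling below the
running washin maximum by 8% of the washin rise. Washin is flagged complete
when the last 5 washin end-tidals have relative spread < 0.5%; an
incomplete washin invalidates the maximum boundary condition and, in strict
mode, aborts the analysis.

### 2. Tidal change correction

For the two phases where the SF6 concentration is known — the pre-phase
(0%) and the end of washin (the supply concentration $C_{max}$, typically
4%) — the molar-mass samples of each contributing breath are re-indexed by
cumulative volume within the breath and binned on a 1 mL grid; per-bin
medians across breaths yield four boundary **respirograms** (min/max SF6 ×
inspiration/expiration). The pre-phase breaths feed the minimum curves and
the last 5 washin breaths the maximum curves. One-mL bins average a few
hundred samples per contributing breath at 200 Hz while staying well below
the volume scale of the within-breath temperature/humidity transition
(~8 mL), so curvature is preserved.

Every sample is then normalised between the matching-phase boundary
interpolants:

$$x(t) = \frac{MM(t) - MM_0(v, p)}{MM_{max}(v, p) - MM_0(v, p)}$$

with $v$ the volume within the phase $p$. Any disturbance that is a
reproducible function of $(v, p)$ — tidal temperature, humidity, steady gas
exchange — appears identically in the boundary traces and cancels. This is
the key assumption: it requires the regular breathing of sleeping infants
and steady CO2/O2 exchange. A single molar-mass sensor cannot distinguish
rising SF6 from rising CO2, so departures from steady exchange propagate
into the outcomes.

Samples beyond the boundary volume range use the clamped end-bin value and
are flagged; breaths with more than 10% flagged samples are QC-flagged.
Boundary curves closer than 0.05 g/mol anywhere on the needed range abort
the analysis as ill-posed.

### 3. Side-chamber correction

With a chamber occupying fraction $w$ of the measurement path and holding
the normalised tracer state $s(t)$, the normalised signal during the
washout is

$$x(t) = (1 - w)\,u(t) + w\,s(t),$$

where $u$ is the main-path concentration (in units of $C_{max}$). Three
known states identify the correction:

* During **washout inspirations** the main path carries tracer-free supply
  gas ($u = 0$), so $x = w s$ directly. Each inspiration is fitted with
  $a\,e^{-v/\lambda}$ in inspired volume $v$ — the form a lumped
  first-order chamber obeys under through-flow washout; $\lambda$ is its
  volume constant in mL. Fits use bounded Levenberg–Marquardt
  (`minpack.lm`); non-convergence or $\lambda$ at its bound falls back to a
  monotone-decreasing isotonic fit and flags the breath. Because the
  $a \ge 0$ bound would rectify pure noise into a spurious carry-over, a
  decay is only fitted when the head of the inspiration exceeds its tail by
  more than twice the standard error of the difference; otherwise the flat
  fit $a = 0$ is used. The first millilitre of each inspiration is excluded
  from all fits: it carries the previous phase's gas front and
  boundary-assignment jitter.
* During **expirations** the chamber estimate is interpolated linearly in
  time between the end value of the preceding inspiration's fit and the
  start value of the following one, which is continuous by construction
  and tracks the chamber's first-order recharge closely.
* The **first washin inspiration** (main path at $C_{max}$, chamber still
  empty: $x(v) = 1 - w e^{-v/\lambda}$) and the **first washout
  inspiration** (main path tracer-free, chamber still full) have fully
  known states. The maximum curve is the affine transform
  $\alpha + \beta m(t)$ of the minimum curve $m$; the washin anchor pins
  $\alpha$ (the $v \to 0$ extrapolation of the first washin inspiration,
  $\alpha = 1 - w$ in the ideal model) and the washout anchor pins $\beta$
  through $\alpha + \beta m_0 = 1$. A proportional single-factor variant is
  available (`scale_mode = "proportional"`) for sensitivity analysis; it is
  degenerate as $w \to 0$ and not the default.

The final signal is $SF6(t) = C_{max} (x - m) / (\alpha + \beta m - m)$,
clamped to $[0, 1.25\,C_{max}]$. The reported clamped fraction counts only
samples moved by more than 1% of $C_{max}$ — rectifying zero-mean noise
around 0% is not signal loss — so the 5% QC threshold flags genuine
problems such as incomplete washin.

### 4–5. BTPS correction and outcomes

Flow is scaled phase-wise by BTPS factors (inspired gas at ambient
temperature/humidity, expired gas saturated at the sensor temperature). For
water-bath bench models without a body compartment, `btps_mode = "none"`
reports volumes at sensor conditions; this is the default and the setting
used for all simulated validations here.

The **initial** end-tidal concentration is extracted from the last washin
breath under the full-chamber state; by the anchor construction it equals
$C_{max}$ up to measurement error, and because the washout concentrations
are normalised by the same boundary, any residual scale error cancels in
FRC. The end of test is the first washout breath whose end-tidal SF6 falls
below 2.5% of the initial value (a three-consecutive-breath confirmation
mode is available, as used by consensus guidelines; the single-breath rule
is the default). Then

$$FRC = \frac{\sum SF6 \cdot \dot V_{exp}\,dt - \sum SF6 \cdot \dot V_{insp}\,dt}
{C_{initial} - C_{final}} - V_D,$$

summed over washout samples through the end-of-test breath. In a single
compartment with dead-space re-breathing this identity is exact: the
end-tidal ratio per breath is $(FRC + V_D)/(FRC + V_T)$ and the raw
estimate equals $FRC + V_D$ for any test length, which is why the apparatus
dead space $V_D$ (4.6 mL infant / 9.6 mL toddler settings) is subtracted.
CEV subtracts one dead space per breath by default so that LCI = CEV/FRC
reflects alveolar gas turnover; the alternative (include dead space) is a
config toggle, since either convention is found in practice.

## The simulator

`simulate_recording()` forward-models the whole chain so the analysis can
be validated against exact ground truth:

* **Gas side**: parallel perfectly-mixed compartments (volumes `frc_ml`,
  ventilation split `vent_frac`) with a shared apparatus dead space,
  sinusoidal half-wave flow at the configured VT and RR, and per-breath
  dilution updates that include dead-space re-breathing. Tracer bookkeeping
  is exact and shipped with the recording for conservation checks.
* **Measurement side**: the local gas composition (including humidity via
  an explicit water-vapour species) determines the speed of sound; a
  "device" inverts it at a fixed calibration temperature and
  $\gamma = 1.400$, which is what creates the multiplicative tidal
  confounders of the real instrument. Within-breath temperature and
  humidity transitions follow first-order volume profiles (volume constant
  8 mL); the expired dead-space gas front at the sensor is smoothed over
  0.7 mL. A lumped first-order side chamber (fraction 0.10 of the path,
  volume constant 15 mL — plausible values for a small ultrasonic
  sensor head) filters the displayed signal, and Gaussian noise
  (SD 0.02 g/mol at 200 Hz) is added last. All randomness hangs off a
  single integer seed.

`condition_grid()` reproduces a bench validation design for infant MBW:
small (FRC 80 mL, VT 30 mL, RR 30/min) and large (FRC 210 mL, VT 50 mL,
RR 20/min) lung models in a 32.5 °C water bath, with variants at room
temperature, +66%/+50% respiratory rate, +66%/+60% tidal volume, and a
two-compartment 0.7/0.3 ventilation split, six seeded replicates per cell
(60 runs). The tidal temperature amplitude is derived from the bath-sensor
difference assuming partial thermal equilibration in the tubing (factor
0.3). Phase lengths are 10 pre-phase, 30 washin and 45 washout breaths —
enough for washin completeness (< 0.5% plateau spread) and for the slowest
grid cell to reach the end-of-test threshold.

```{r grid, eval = FALSE}
errs <- run_condition_grid(replicates = 6, seed = 1)
frc_accuracy_report(errs)
```

### What the simulator does and does not emulate

It reproduces the confounder structure the corrections target: tidal
temperature/humidity swings that are stationary functions of volume and
phase, composition-dependent acoustics, side-chamber lag, dead-space
fronts, sensor noise, and ventilation inhomogeneity. It does **not**
emulate irregular breathing (sighs, apnoeas, volume drift), unsteady
CO2/O2 exchange, supply-concentration drift, or sensor calibration drift —
the main failure modes visual quality control screens for in practice.
Passing the simulated validations therefore demonstrates correctness of the
signal processing under the method's stated assumptions, not robustness to
every clinical artefact.

## Numerical choices and known limitations

* **Composition-dependent $\gamma$.** The simulator computes the true
  adiabatic index of the local mixture, while the analysis — like the
  method it implements — interpolates linearly between the boundary
  conditions. Because $\gamma$ varies slightly with SF6 fraction, the
  displayed molar mass is mildly nonlinear in concentration; this leaves a
  small inherent FRC underestimate (~0.7% at the bench geometries) that is
  visible even in the noiseless, chamber-free, confounder-free limit. It is
  a property of molar-mass-based SF6 sensing, not of the implementation.
* **Multi-compartment underestimation.** With unequal specific ventilation
  the end-tidal concentration weights fast compartments more than the
  volume-weighted mean, so FRC is underestimated (≈ 1–3% at a 0.7/0.3
  split). This is inherent to end-tidal-based washout analysis and shows up
  in the ventilation-inhomogeneity cells of any validation grid.
* **LCI granularity.** The end of test is a whole-breath index, so LCI
  moves in quanta of roughly one expired volume per FRC. The
  ventilation-asymmetry sweep shipped in `asymmetry_sweep()` spaces its
  five points (0, 0.2, 0.3, 0.35, 0.4 offsets) so that consecutive points
  differ by at least one end-of-test breath under the closed-form dilution
  model; finer sweeps would alias onto identical breath counts.
* **Degenerate inputs.** Zero flow, missing phases, indistinct boundary
  respirograms, non-positive concentration drops and over-range breaths all
  raise classed conditions (`mbw_*`) rather than producing numbers; the CLI
  maps them to machine-readable categories.
* **Problem sizes.** Validation simulations use 200 Hz sampling and 85
  breaths per recording (about 34 000 samples); these match typical
  ultrasonic flowmeter rates and keep a 60-run grid comfortably
  reproducible on a laptop.

## Session info

```{r session, eval = FALSE}
sessionInfo()
```
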