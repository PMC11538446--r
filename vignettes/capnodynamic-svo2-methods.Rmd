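---
title: "Capnodynamic SvO2: model, estimator and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capnodynamic SvO2: model, estimator and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capnosv)
```

## The problem

Mixed venous oxygen saturation (SvO2) summarizes the balance between
whole-body oxygen delivery and consumption, which makes it a core
monitoring variable in sepsis and other shock states. Measuring it
directly requires a pulmonary artery catheter — either intermittent
CO-oximetry on pulmonary-artery blood samples (the reference standard)
or a continuous fiberoptic reflectance catheter. `capnosv` implements a
non-invasive alternative: SvO2 derived breath by breath from volumetric
capnography in a mechanically ventilated subject, plus the statistical
machinery used to validate any such monitor against the invasive
standards, plus a synthetic endotoxemia experiment that exercises the
whole chain with known ground truth.

## The capnodynamic chain

The method rests on the differential Fick principle applied to the
lung. Three quantities are maintained continuously:

1. **CO2 elimination (VCO2)** from volumetric capnography, as a moving
   mean over a trailing 20-minute window (`windowed_vco2()`), long
   enough to reflect metabolism rather than ventilatory transients.

2. **Oxygen consumption** via the respiratory quotient,
   `VO2 = VCO2 / RQ` (`vo2_from_vco2()`), with RQ fixed at 0.97 — a
   cohort-level porcine value. A different RQ shifts the computed SvO2
   but not its ability to track change.

3. **Effective pulmonary blood flow (EPBF)** — the non-shunted fraction
   of cardiac output that participates in gas exchange — fitted from
   the fluctuations in alveolar CO2 that a cyclic ventilation pattern
   induces: six breaths at the normal rate followed by three breaths
   with a 2.5 s expiratory pause. Over the nine breaths of one cycle
   the single-compartment alveolar CO2 balance

   ELV·(F_n − F_{n−1}) = Δt_n·EPBF·(CvCO2′ − b·F_n) − VTCO2_n

   (F: end-tidal CO2 fraction; ELV: effective lung volume; b:
   linearized blood CO2 dissociation slope; CvCO2′: venous CO2 content
   offset) is linear in the unknowns (ELV, EPBF, EPBF·CvCO2′), so each
   new breath yields a least-squares refit over the trailing window
   (`fit_epbf_window()`). The commercial capnodynamic equation is not
   public; this formulation is the standard mass-balance reconstruction
   and is validated against the package's own simulator rather than
   against any proprietary implementation. Both a full refit per breath
   and a carry-forward mode (venous CO2 treated as known between fits)
   are provided; refit is the default.

SvO2 then follows from the Fick identity. Pulmonary end-capillary blood
is assumed fully saturated and in equilibrium with alveolar oxygen
tension from the alveolar gas equation
(`alveolar_po2()`), with end-tidal CO2 standing in for alveolar CO2:

* CcO2 = Hb·1.34 + 0.03·PAO2 (`oxygen_content()`),
* CvO2 = CcO2 − VO2 / EPBF (ml·min⁻¹ over L·min⁻¹ gives ml·L⁻¹),
* SvO2 = the saturation whose total content equals CvO2
  (`saturation_from_content()`).

The content inversion uses the Severinghaus dissociation curve with an
exact closed-form (Cardano) inverse, rescaled to a configurable P50
(default: the curve's native ≈26.9 mmHg; `porcine_constants()` provides
a right-shifted 35 mmHg preset). A Hill curve is available as a
fallback. Hüfner's constant (1.34 ml·g⁻¹) and the plasma solubility
(0.03 ml·L⁻¹·mmHg⁻¹) are common clinical values and are configurable;
temperature/pH shifts of the curve and dyshemoglobins are out of scope.

**Clamping.** EPBF ≤ 0 or CvO2 < 0 produce SvO2 = 0 with a quality
flag rather than an error: the method genuinely displays transient
zeros during circulatory collapse because it reports the equilibrium
implied by the *current* EPBF and VCO2 instantly, ahead of the slower
in-vivo mixing. A trailing 50 s moving mean (`moving_mean_filter()`)
provides the less reactive display value.

## Numerical choices

* The saturation inversion runs a vectorized fixed-point iteration
  (the dissolved term is a small bounded perturbation) with a bracketed
  `uniroot` fallback; round-trip error is below 1e−9 across
  saturations 0.05–0.95 and hemoglobin 50–180 g·L⁻¹.
* The EPBF fit uses `.lm.fit` on the 9×3 design; rank deficiency (for
  example a CO2-free stream) flags the estimate as degenerate and
  carries the last valid EPBF forward.
* Trailing time windows are half-open `(t − w, t]`; before the VCO2
  window fills, the partial-window mean is used and flagged as warm-up
  rather than returned as `NA`.

## The synthetic experiment

`run_scenario()` integrates a piecewise-smooth hemodynamic trajectory
at 1 s resolution for a 31.5 kg virtual pig: endotoxin infusion ramps
cardiac output down and pulmonary shunt up over the first hour, partial
recovery under rescue care follows, and the seven stabilization-phase
challenges (crystalloid bolus, FiO2 0.3→0.5→0.8→1.0→0.3, PEEP
5→10→15→5, dobutamine, norepinephrine, 15 ml·kg⁻¹ hemorrhage,
whole-blood retransfusion) each move a target that the state approaches
with a 120 s first-order time constant (30 s for inspired-gas effects).
That deliberate response lag is what creates the transient
disagreement between the instantaneous capno value and
catheter-side readings during fast maneuvers.

True SvO2 is solved at every second from the whole-body Fick relation
with venous admixture (arterial content as the shunt-weighted mixture
of end-capillary and venous blood), which reduces to
CvO2 = CcO2 − VO2/EPBF with EPBF = CO·(1 − shunt); a test re-checks
this content balance independently of the solver to 1e−8.

Baseline defaults (CO 4.0 L·min⁻¹, VO2 180 ml·min⁻¹, Hb 90 g·L⁻¹,
shunt 0.10) were chosen once as plausible anesthetized-pig values that
place baseline true SvO2 near 60% with a sepsis nadir near 40%, the
directional anchors of the emulated protocol; no quantitative
trajectory data exist to calibrate against, so the magnitudes are
directional, not quantitative.

`synthesize_breaths()` runs the same single-compartment CO2 store
forward under the 6+3 pattern (normal rate 15 min⁻¹, pause 2.5 s,
tidal volume 10 ml·kg⁻¹ with 30% dead space, effective lung volume
35 ml·kg⁻¹), with the venous CO2 offset calibrated per breath so the
periodic solution eliminates exactly VO2·RQ. Because generator and
estimator share the mass-balance model family, noise-free parameter
recovery is exact to machine precision — that verifies the estimator's
algebra, not the model's fidelity to a real lung, which is the
generator's intrinsic limitation (no serial dead space, no
ventilation–perfusion heterogeneity, no CO2 store outside one
compartment).

`sample_measurements()` emits the three recording streams:
CO-oximetry spot samples with multiplicative noise; a fiberoptic trace
with a 40 s lag and −2%/h drift reset at each calibration; and the
capno stream, i.e. the actual estimator run on the synthesized breaths.
The CVs (0.0585, 0.0372, 0.0319 extra for capno, 0.002 per breath) are
calibrated so five baseline repeats reproduce, in expectation, inherent
precisions of about 11%, 7% and 6% — the study conditions the
comparison statistics are meant to operate under; the factor-of-two
plus c4(5) ≈ 0.94 correction converts a target precision into a CV.
Per-animal biological variability is log-normal on cardiac output and
VO2 (σ = 0.08), normal on hemoglobin (σ = 5 g·L⁻¹), uniform 0.7–1.3 on
LPS severity.

The estimator receives hemoglobin from the simulated blood-gas values
(per breath) rather than a frozen baseline: in practice Hb is entered
into the capnodynamic calculation from each blood-gas analysis, and a
stale value after crystalloid hemodilution would otherwise dominate
the error budget.

## The comparison statistics

* **Inherent precision** = 2 × CV of the five stable baseline repeats,
  per animal, averaged over animals (`inherent_precision()`).
* **Least significant change** = precision × √2
  (`least_significant_change()`), reported rounded: 11% → 16%. The
  concordance **exclusion zone** is the LSC (relative) times the mean
  baseline reference SvO2, rounded to integer percentage points
  (≈10 points under the defaults) and directly overridable.
* **Bland–Altman corrected for repeated measurements**
  (`bland_altman_repeated()`): the variant for multiple observations
  per individual when the true value varies — total SD of differences
  from one-way variance components (between-animal from the
  unequal-n ANOVA identity, within-animal from the residual mean
  square). Bias CI on k−1 df via the between-animal mean square; LoA
  CIs by the standard large-sample approximation. A unit test pins the
  decomposition to an independent `aov()` oracle at 1e−10.
* **Four-quadrant concordance** (`concordance()`): change pairs at the
  designated intervention extremes
  (`select_intervention_extremes()`), reference-only exclusion zone,
  Wilson score CI. The Wilson choice is a documented judgment call —
  no standard binomial interval reproduces the CI printed alongside
  the published worked counts, so only the rate itself is treated as
  reproducible.

## What passing tests do and do not show

The acceptance-grade checks run the full pipeline: a noiseless
three-animal study must give |bias| < 2 percentage points and 100%
concordance, and the default noisy ten-animal study (290 paired
recordings, ~55 retained change pairs) must keep capno concordance
above 90%. Problem sizes (10 animals, 5.1 simulated hours, ≈3 800
breaths per animal) were chosen to mirror the emulated protocol while
keeping a full run around five seconds. These results demonstrate
internal consistency of estimator, simulator and statistics under the
stated noise model — they cannot demonstrate performance on real
animals, where the lung model mismatch, RQ drift, and
mitochondrial-dysfunction (high-SvO2) sepsis phenotypes (all outside
the simulator) would widen the limits of agreement.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_experiment(n_animals = 10, seed = 1)
cmp <- compare_methods(sim$recordings)
print(cmp)
```

See the README for the printed output and its interpretation, and
`scripts/acceptance.R` for the end-to-end reproduction run.
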