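---
title: "Methods: behavioral PET analysis of prepulse inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral PET analysis of prepulse inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppipet)
```

## The problem ppipet addresses

Prepulse inhibition (PPI) of the acoustic startle reflex is the standard
operational measure of sensorimotor gating: a weak acoustic prepulse
presented ~100 ms before a startling pulse reduces the startle amplitude,
and the size of that reduction indexes how well a weak stimulus can gate
the motor response to a strong one. Combining a passive PPI session with
behavioral FDG-PET — injecting the tracer before the session so uptake
accumulates during behavior and is imaged afterwards — links the
behavioral readout to metabolic activity across the whole brain.

Raw recordings from such experiments are rarely distributed, so `ppipet`
implements the complete analysis chain **together with a synthetic-data
layer that carries known ground truth**: startle sessions with per-trial
amplitudes, brainstem auditory evoked potential (BAEP) sweep series, and
phantom PET cohorts on a labelled volume-of-interest (VOI) atlas. Every
analysis stage can therefore be validated end to end — calibration on pure
noise, recovery of injected effects, reproduction of in-paper arithmetic —
without any external data.

## Behavioral model and quantification

### Session structure

A PPI session (45 min at a 65 dB SPL background) consists of a
habituation block of 25 startle-alone trials (110 dB SPL), a paradigm
block of 300 trials in pseudorandomized order — 30 background, 30
startle-alone, 120 prepulse-alone and 120 prepulse+startle trials, 30 per
prepulse level in {68, 72, 78, 84} dB SPL, prepulse leading the pulse by
100 ms — and a closing block of 20 startle trials. Inter-trial intervals
are uniform on 1–13 s. Pseudorandomization is implemented as a seeded
uniform shuffle of the fixed trial multiset; no ordering constraints
(e.g. repeat avoidance) are imposed because none are part of the standard
design description. A startle-control session replaces every paired trial
with a startle-alone or background trial so that the startle-alone count
matches the animal's startle-reaction count from its PPI session; a
background session presents the background noise only.

### Amplitude quantification

`integrate_startle_amplitude()` baseline-corrects a piezo trace and
integrates it over the 5–105 ms window after pulse onset. The default
`"mean"` mode divides the integral by the window length, keeping the
result in mV so it is directly comparable to the 30-mV startle-event
threshold; the raw integral (mV·ms) is available as `mode = "integral"`.

PPI is the percent reduction of the average startle amplitude,

$$\mathrm{PPI}[\%] = (A_{\text{startle alone}} - A_{\text{prepulse+startle}})
 \times 100 / A_{\text{startle alone}},$$

negative values indicating facilitation. Event classification works per
trial: startle events are startle-alone trials above 30 mV plus paired
trials whose per-trial PPI is below 15%; PPI events are paired trials
above 15%; ties at a threshold count as neither. Because the PPI formula
is defined on averages, per-trial PPI uses the session-mean startle-alone
amplitude as denominator — the only reading that yields a per-trial
value. The relative event difference,
$(n_{\mathrm{PPI}} - n_{\mathrm{startle}}) \times 100 /
(n_{\mathrm{PPI}} + n_{\mathrm{startle}})$, bounded in [−100, 100] and
antisymmetric under swapping counts, is the behavioral covariate for the
correlation maps. Habituation and closing blocks are excluded from all
paradigm statistics.

### Group statistics

All percentages are arcsine-square-root transformed,
$\arcsin\sqrt{p/100}$, with the sign preserved for negative PPI
(facilitation) and values clipped to ±100 so the transform stays in its
domain. The transformed per-level PPI enters a two-way mixed-design ANOVA
(within factor: prepulse intensity; between factor: strain). Per-level
strain contrasts are **model-based simple effects**: the error term pools
the two ANOVA strata, $(\mathrm{MS}_{\text{subj within}} +
(k-1)\mathrm{MS}_{\text{resid}})/k$, with Satterthwaite degrees of
freedom, and p-values are Sidak-adjusted over the $k = 4$ levels. This is
the standard post-hoc contrast after a mixed design; separate per-level
two-sample tests were rejected because a pooled t is anticonservative
when the smaller group carries the larger variance (the hearing-impaired
strain here) while Welch's t loses too much power at the softest
prepulse. Strain contrasts of the relative event difference and of
startle amplitudes use Mann-Whitney U (exact null for small samples
without ties; tie-corrected normal approximation otherwise), and hearing
threshold vs. relative event difference uses Pearson correlation.
Session-half comparisons split the paradigm block at its midpoint trial
and compare early vs. late means by paired t-test; for PPI both the
percentage-point difference and the relative change are reported because
either reading of a "percent change in a percentage" is meaningful.

## Audiometry

Hearing thresholds come from BAEP series descending from 100 dB pSPL in
10-dB steps. Per level, 1000 sweeps are averaged; a response is declared
when the peak absolute amplitude in the 2–5 ms response window exceeds
`k` times the SD of the 7–10 ms noise window. The criterion is a
package convention (descending-threshold protocols typically state only
"until no further response"); the default `k = 4` keeps the familywise
false-alarm probability across the ~60 samples of the response window
below ~1%, whereas `k = 3` would false-alarm on roughly one noise-only
level in six and derail the descending scan. The threshold is the
midpoint of the lowest responding level and the first silent level below
it (so the zero-noise estimation error is at most half a step), converted
from peak to continuous level by the multiplicative calibration factor
0.8509 — multiplication of the dB value being the only reading consistent
with a single printed factor.

## Imaging statistics

Volumes are intensity-normalized by the **ratio technique**: each image is
divided by the mean of its own olfactory-bulb reference VOI, which removes
per-subject global scaling (dose, metabolic rate), makes the operation
idempotent, and fixes the reference mean at exactly 1. Olfactory input is
assumed condition-independent, which is why the phantom generator refuses
condition effects in the reference VOI.

Voxelwise tests are computed independently per voxel with no smoothing or
spatial normalization, matching the minimal-preprocessing philosophy of
small-animal behavioral PET:

* **paired t** (df $n-1$) between two conditions over the same subjects;
* **one-way repeated-measures ANOVA** with subject as blocking factor
  (error df $(k-1)(n-1)$) followed by **Tukey studentized-range q** per
  condition pair, $q = (\bar{y}_a - \bar{y}_b)/\sqrt{\mathrm{MSE}/n}$,
  signed (positive = first condition higher) with two-sided p from the
  studentized range distribution on $|q|$;
* **Pearson r** between per-subject difference volumes and a behavioral
  covariate, with $t = r\sqrt{(n-2)/(1-r^2)}$.

Zero-variance voxels make these statistics 0/0; they are set to `NA`
(masked) rather than 0, and excluded from all summaries. In the
repeated-measures decomposition the degeneracy test uses a relative
tolerance (`ss_err <= 1e-12 * ss_total`) because exact cancellation is
not representable in floating point.

### Empirical noise floors

p-values are deliberately uncorrected; instead the maps are read jointly
with an **empirical noise floor** estimated from null comparisons of the
background-control images:

* **split-half**: a seeded random split into two equal groups, voxelwise
  two-sample t (df $n-2$), summarized by mean and SD over the brain mask;
* **hemisphere flip**: each volume is mirrored across the midline sagittal
  plane (exact on a synthetic grid — no coregistration), mirrored is
  subtracted from original in alternating direction across subjects, and
  the differences are tested against zero by paired t; mean/SD are taken
  over the left hemisphere only, the field being antisymmetric.

The alternation makes the flip test a pure noise estimate — an asymmetry
shared by all subjects cancels out of the mean difference. For detecting
consistent lateralized effects the uniform direction is available as
`alternate = FALSE`.

A voxel is *above noise* when its statistic exceeds
$\text{mean}_t + 2\,\text{SD}_t$ (mirrored below
$\text{mean}_t - 2\,\text{SD}_t$ for negative effects);
`threshold_and_mask()` intersects this cut with `p < 0.05`. The
criterion t against which floor separations are reported is configurable
between df = 12 (the split-half null's $n-2$, which reproduces the
canonical printed value 2.18 at $n = 14$) and df = 13 (the paired test's
$n-1$); the package default is 12 and the choice is a config parameter
because the two conventions genuinely differ. The VOI symmetry check then
verifies that areas contralateral to significant clusters change in the
same direction, with a contralateral mean of exactly zero counted as
disagreement.

## The synthetic-data layer

### What the generators emulate

`subject_profile()` collects the ground truth for one animal: hearing
threshold, startle gain (startle-alone amplitude at session start, mV),
prepulse sensitivity, maximal inhibition fraction, sensitization rate,
trial noise and a daily calibration value. Startle-alone amplitudes
follow $\text{gain}\times(1 + \text{rate}\times\text{trial index})$ plus
Gaussian noise; paired trials are additionally scaled by
$1 - \text{inhibition}$; prepulse-alone and background trials are noise
only. Traces reproduce these amplitudes as rectangular responses over the
integration window on a configurable baseline, so trace integration
inverts the generator exactly at zero noise.

Inhibition is driven by prepulse **salience against the background**:
$\text{inh} = \text{ppi}_{\max}\cdot\min(1,\, u \cdot (L - 65))$ with
$L$ the prepulse level (dB SPL) and $u$ the subject's sensitivity per dB
above background. Salience-re-background, rather than absolute level, is
what makes the loudest prepulse equally effective in well-hearing and
hearing-impaired animals — the behavioral signature the two-strain design
rests on. Hearing loss lowers $u$ through a shallow logistic in the
hearing threshold (`ppi_sensitivity()`: floor 0.055, range 0.065,
midpoint 45 dB SPL, scale 6 dB). These four numbers were calibrated once,
analytically, to the qualitative two-strain pattern the design must
reproduce: a well-hearing subject (threshold ≈ 24 dB SPL) saturates
inhibition by the 78-dB prepulse, while a hearing-impaired subject
(threshold ≈ 61 dB SPL) sits clearly below saturation at 78 dB
(inhibition ≈ 0.77 of the cap) yet saturates at 84 dB with a >4-SD margin
over its within-strain threshold scatter. The shallow logistic is
essential: with only 6 dB between the last two prepulse levels and ±2.4 dB
threshold scatter, any mapping that shifts the saturation point
one-for-one with threshold cannot separate "unsaturated at 78" from
"saturated at 84" across subjects.

Strain profiles draw thresholds from 23.6 ± 5.7 (well-hearing) and
60.8 ± 2.4 dB SPL (hearing-impaired) and startle gains from 226 ± 99.3
and 120.8 ± 59.1 mV, truncated at 30 mV. The gain anchors the session
start; measured session means sit ~35% higher under the default
sensitization rate (0.002 per trial, chosen so the startle-control
session shows a ~30% early-to-late amplitude increase), with the strain
ratio preserved. Trial noise defaults to 20 mV.

BAEP sweeps contain a Gaussian deflection at 3.5 ms whose amplitude grows
with the level excess over threshold, plus white noise; levels below the
true threshold are noise only. Phantom PET cohorts place a baseline of
100 a.u. on the atlas grid, multiply by a per-subject global scale
(SD 10%), apply VOI-wise condition and covariate effects from a
ground-truth `effect_table`, and add i.i.d. multiplicative Gaussian voxel
noise (SD 5%) — deliberately **no** spatial autocorrelation, point-spread
blur, kinetics or attenuation, mirroring the unsmoothed analysis.

### What passing tests do and do not show

Because phantom noise is i.i.d. and the anatomy is spherical VOIs on a
regular grid, the validation demonstrates that the *statistics* are
correctly calibrated (5% false-positive rate at α = 0.05; split-half
noise floor centred on zero) and that the *pipeline* recovers known
effects (+12% uptake in 3 of 12 VOIs detected through the p < 0.05 ∧
above-noise mask with no whole-VOI false alarms). It does not demonstrate
robustness to spatially correlated noise, partial-volume effects,
misregistration or atlas error, which real data would add.

## Problem sizes and determinism

All generators accept a seed and restore the caller's RNG state; equal
seeds reproduce sessions, cohorts and whole pipeline runs bitwise
(verified by file checksums in the run report). The validation suite uses
the cohort sizes of the emulated design — 14 + 5 subjects, with 9 in the
three-condition repeated-measures subset — on a 32 × 32 × 16 phantom grid,
and 100 Monte-Carlo seeds for each property check (null calibration,
effect recovery, strain-pattern recovery); the full suite and the
acceptance script each complete in about a minute on one CPU. The
strain-pattern check reads per-level significance at the Sidak-adjusted
p ≤ 0.001 mark conventionally used to annotate such per-level strain
differences; at α = 0.05 the "no difference at the loudest prepulse" leg
would by construction fail ~5% of seeds even for a perfectly calibrated
test, so the stricter mark is the only self-consistent readout for a
≥95%-of-seeds reproduction target.

## Known limitations

* The event-classification denominator (session-mean startle-alone
  amplitude) is one of several defensible readings of a per-trial rule
  defined via an average-based formula.
* The BAEP response-detection rule is a convention; real ABR scoring uses
  waveform morphology and replication across runs.
* The hemisphere-flip floor assumes an exactly mirrorable grid; real data
  require flip + coregistration, whose residual error the phantom does
  not model.
* Normalization to the daily calibration value is implemented as
  division; an affine calibration would need two reference points.
* Counterbalancing of session order is recorded as metadata only; the
  generators do not model order effects beyond within-session
  sensitization.
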