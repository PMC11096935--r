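---
title: "Methods: ICP/CaBV pulse-shape similarity during plateau waves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ICP/CaBV pulse-shape similarity during plateau waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pulsedi)
```

This vignette documents the models, the numerical choices and the
limitations of the `pulsedi` pipeline: what each stage assumes, which
knobs matter, and what passing the package's tests does and does not
demonstrate about real neuromonitoring data.

## The analysis chain

A recording holds three channels sampled concurrently at 50 Hz:
intracranial pressure (ICP, mmHg), invasive arterial blood pressure
(ABP, mmHg) and transcranial Doppler cerebral blood flow velocity
(CBFV, cm/s). The chain is:

1. **Trends and plateau-wave detection** on 10-s moving means of the
   raw channels.
2. **Preprocessing** of the pulsatile channels: linear upsampling to
   200 Hz, zero-phase low-pass filtering at 12 Hz.
3. **Pulse onset detection** (multiscale minima) on ICP and CBFV,
   beat segmentation, rule-based quality control, per-cycle pairing.
4. **CaBV** per CBFV pulse via the constant flow forward (CFF) model.
5. **Difference index (DI)** per ICP/CaBV pair, inside the selected
   baseline and plateau periods.
6. **Paired nonparametric comparison** of per-wave median DI.

## The CFF model and its assumptions

The cerebral arterial blood volume change over a cardiac cycle is the
running integral of inflow minus outflow. The CFF model makes two
assumptions, both stated as contracts rather than checks: venous
outflow pulsates little within a cycle, so it can be replaced by the
6-s moving mean of arterial inflow; and the insonated artery's
cross-section is constant, so CBFV can replace flow. The result,

$$\Delta \mathrm{CaBV}(n) = \sum_{i=1}^{n}
  \left[\mathrm{CBFV}(i) - \overline{\mathrm{CBFV}}\right]\,\Delta t,$$

has units of cm (volume divided by the unknown cross-sectional area),
so absolute values are not comparable between subjects; only
within-recording shape is used here. A heuristic monitor warns when
the 6-s mean moves more than 5% within one pulse — there the
constant-outflow idealization is strained, typically at trend
transitions. The windowed mean is evaluated per sample along the pulse
(default) because that is what "a 6-s average" means at every instant;
a frozen-at-onset variant (`freeze_at_onset = TRUE`) exists for
sensitivity analysis, since either reading of the definition is
defensible. A CaBV pulse typically dips to its minimum a few samples
*after* the cycle onset (inflow still runs below its slow mean during
late diastole), which is why the synchronization audit tolerates an
early-phase minimum.

## The difference index

Both pulses of a pair are min–max normalized to $[0,1]$ — the DI
compares shapes, not amplitudes — and aligned at their onsets with no
resampling or time warping. Then

$$\mathrm{DI} = \sum_{i=0}^{M-1}
  \left| \widehat{\mathrm{ICP}}(i) - \widehat{\mathrm{CaBV}}(i) \right|,$$

where $M$ is the CaBV pulse length. When the ICP pulse is shorter, its
last sample is held (`tail = "hold"`): this follows "to the end of the
CaBV pulse" literally without discarding late-cycle area; a
truncate-to-shorter variant is available. DI is reported as the raw sum,
not divided by $M$, so it scales with beat length (heart-rate
dependence is a known caveat of the raw index); `n_compared` is stored
with every record so users can derive a length-normalized variant.
Time-axis normalization of pulses to a common length is deliberately
out of scope.

## Plateau-wave detection and period selection

Waves are detected on 10-s centered moving means. The criteria are the
standard clinical definition: relative mean-ICP rise $\ge$ 15 mmHg over
a pre-wave reference, peak $>$ 40 mmHg, CPP drop $\ge$ 10 mmHg below
its pre-wave reference, sustained $\ge$ 3 min. Two operational choices
had to be made where the criteria leave room:

- **Pre-wave reference.** The median of mean ICP over the 240 s before
  the rise onset; the rise onset is the last upward crossing of
  (reference + 5 mmHg) before the peak, iterated once so the reference
  settles on the pre-rise segment. The median resists transient dips
  and artifact spikes.
- **Gap tolerance.** Sub-threshold dips of up to 10 s inside a
  candidate are tolerated when forming the wave and plateau intervals.
  A single 1–2-s dropout artifact otherwise splits an interval in two
  and can halve the selected plateau; a 10-s tolerance is far below
  any plausible between-wave separation.

The baseline period is the 240 s before the wave start (shortened with
a warning when the recording starts late; below 60 s the wave is
excluded). The plateau period is the maximal contiguous interval where
mean ICP $\ge$ 0.9 × the wave's maximum. The duration criterion is
applied to the above-reference condition, reading "for at least 3 min"
as qualifying the sustained rise.

## Onset detection

Onsets (the minima at the start of each pulse's ascending slope) are
found with a deterministic multiscale minima detector: within 10-s
windows (50% overlap), sample $i$ is marked at scale $k$ when
$x_i < x_{i\pm k}$; the scale $\gamma$ with the most marks tracks the
dominant beat half-period; onsets are the samples marked at every scale
$1..\gamma$. There is no randomness anywhere in detection. Two
post-steps make the detector robust on realistic signals: candidates
within one sample (window overlap duplicates) merge, and candidates
closer than a 0.4-s refractory separation collapse onto the deeper
sample. The refractory default tolerates heart rates to 150 bpm —
appropriate for sedated adult neurocritical-care patients — and
suppresses inter-peak notch dips that survive in windows where
$\gamma$ underestimates the half-period.

## Quality control in place of visual review

The source methodology reviewed every pulse visually. Automation
replaces that with explicit rules and machine-readable reason codes:
beat duration in [0.3, 2] s; all samples finite and inside per-channel
plausibility ranges (ICP $[-10, 120]$ mmHg, CBFV $[1, 250]$ cm/s — a
velocity at zero is signal loss, not physiology); peak-to-trough
amplitude above a floor (1 mmHg / 5 cm/s); and at most 8 prominent
local extrema. Extrema are counted with a prominence threshold (swings
$<$ 5% of the pulse amplitude are ignored): a strict count is
meaningless on any noisy signal, while artifact-induced oscillations
comfortably exceed 5%. Thresholds live in `qc_config()` so stricter or
looser review styles can be emulated; tightening any bound can only
shrink the accepted set.

ICP and CBFV pulses pair greedily by nearest onset within 0.25 s —
within a 0.6–1.2-s cardiac cycle the two systolic onsets are
near-simultaneous — each pulse used at most once, and the signed onset
lag is kept on every pair so either synchronization convention can be
audited. No transit-time correction is applied.

## The synthetic generator: what it emulates, and what it does not

The generator exists because the clinical recordings are unavailable;
it emulates the statistical structure the analysis relies on, not
cerebrovascular physiology. A recording is built from a shared cardiac
beat schedule (Gaussian beat lengths around 60/HR, CV 5%, truncated to
[0.45, 1.8] s), slow trapezoidal mean trends, per-beat rendered pulse
waveforms, white Gaussian noise per channel, and injected artifacts
(spike, flatline, dropout-to-zero — one per QC rule family) whose
locations are recorded in the ground truth.

**Pulse model.** One cycle is a sum of raised-cosine components on a
diastolic baseline shelf. For ICP: P1/P2/P3 at latencies 0.12/0.45/0.70
of the cycle with amplitudes 1.0/0.8/0.6 and width 0.20. A scalar
*roundness* morphs the shape: the three peaks fade with
$(1-r)^2$ while a broad hump (width 0.9) centered on the tidal latency
grows with $r$. This blend was chosen over moving or widening the peak
components because it is structurally monotone: a submerged peak cannot
re-emerge, so the rendered maxima count falls 3 → 2 → 1 along the
roundness grid, and the DI against a fixed CaBV-shaped reference
decreases monotonically — both properties the test suite checks. The
baseline term $b(\varphi) = 0.4\,(1 - \cos^{320}(\pi\varphi))$ is a
flat shelf with steep symmetric walls into a narrow onset trough. Its
shape encodes three contracts at once: the flat mid-cycle cannot create
inter-peak maxima; the symmetric walls keep the low-pass-filtered
trough centered on the true onset (an asymmetric trough shifts the
filtered minimum by several samples); and the last sample of the cycle
stays high enough that the onset remains the strict beat minimum even
while the mean trend falls during wave resolution. CBFV and ABP use
fixed two-phase morphologies (sharp systolic peak, smaller dicrotic
component); the analysis manipulates ICP shape only, so no CBFV shape
parameters are data-derived — they are a modeling choice.

**Levels.** Defaults place mean ICP at 19.4 mmHg rising to 42.7 mmHg
over a 30-s rise, a 240-s plateau and a 90-s resolution (plateau waves
resolve over roughly a minute; the gentler fall also keeps the
per-beat trend drop below the pulse's end-diastolic offset, preserving
the onset-minimum contract). Mean CBFV falls 44.2 → 32.9 cm/s, ABP is
constant at 94 mmHg, so CPP falls by the full ICP rise. The ICP pulse
amplitude grows with mean ICP (4 mmHg baseline + 0.15 per mmHg of
rise), reflecting amplitude–pressure coupling; roundness ramps 0.15 →
0.85 in step with the trend. Recordings are 660 s so a 240-s baseline
precedes the wave. The ground truth annotates the wave interval as the
span where the noise-free trend exceeds baseline + 15 mmHg — the same
margin a detector keys on, so boundary-error measurements gauge
detection error rather than a definitional offset.

**Cohorts** jitter level parameters per recording with ±10%
multiplicative log-normal noise (sdlog 0.1; heart rate sdlog 0.05). To
keep every simulated wave a detectable plateau wave under jitter, the
plateau ICP is floored at baseline + 16 mmHg and at 41 mmHg; without
the floor roughly one cohort in three would contain a sub-threshold
wave, which is a different experiment.

**Not emulated:** autoregulatory dynamics and the vasodilatory cascade
(trends are phenomenological ramps), pink/physiological noise spectra
(noise is white), respiratory and slow B-wave modulation, probe drift,
or between-channel transit delays (onsets are exactly simultaneous by
construction). Passing tests therefore demonstrates that the pipeline
measures what it claims on signals with known truth — not that real
TBI recordings would yield the same sensitivity figures.

## Statistics

Per-period values are summarized as median (Q1–Q3) with quartiles by
linear interpolation of order statistics. The paired Wilcoxon
signed-rank test drops zero differences (Wilcoxon's rule, the default
of the era's clinical software, rather than Pratt's), ranks |d| with
average ranks on ties, and takes $W$ as the smaller rank sum. The
two-sided p is exact — from the signed-rank null distribution by
convolution — whenever there are no ties and $n \le 25$; beyond that a
normal approximation with tie and continuity correction is used. The
test suite verifies the exact branch against full $2^n$ sign-assignment
enumeration for every $n \le 12$ and the approximate branch against the
reference implementation in `stats`.

The inference unit is the **wave**: each wave contributes its median
baseline DI and median plateau DI, and the test pairs those 15 values.
Pooling all pulse pairs instead would treat hundreds of highly
autocorrelated beats per wave as independent (pseudo-replication); the
pooled mode exists (`pairing = "pooled"`) but is flagged for
exploration only. No multiple-testing correction is applied across the
ICP/CBFV/ABP/DI comparisons, matching standard practice for a
three-signal descriptive table. Type-I calibration of the engine is
checked on null cohorts simulated at the wave-summary level
(exchangeable baseline/plateau aggregates sharing a wave-level random
effect); simulating 200 full recording cohorts would test the same
code path at three orders of magnitude more cost.

## Numerical choices

- **Upsampling** is linear interpolation (exact on affine signals;
  error $\le h^2 \max|f''|/8$), reproducing original samples exactly
  for integer rate ratios.
- **Low-pass** is a 4th-order Butterworth applied forward–backward
  (zero-phase, so onset timing is unbiased). The single-pass design
  cutoff is widened to 13.4 Hz so the −3 dB point of the combined
  response lands at 12 Hz. Edge transients are suppressed by odd
  reflection padding spanning nine time constants of the filter.
- **Moving means** are centered with truncated windows at the edges
  (no invented samples), rounded to an odd sample count so centering
  is exact; a centered 6-s window avoids the systematic lag a trailing
  window would imprint on CaBV. Implemented via cumulative sums
  (long-double accumulation; matches an $O(NW)$ brute force to
  1e-12).
- **Determinism.** A single master seed fans out to per-recording
  seeds through fixed integer mixing kept below $2^{53}$ so the
  arithmetic is exact in doubles; detection contains no randomness;
  reruns are bit-identical.
- **Degenerate inputs.** Flat pulses cannot be normalized and are
  rejected upstream by the QC amplitude floor; constant series yield
  no onsets; recordings shorter than one analysis window are errors,
  not empty results.

## Problem sizes

The bundled analysis and the acceptance script use 15 recordings of
660 s at 50 Hz (about 800 beats each; roughly 8,600 scored pulse pairs
per cohort), 20 no-wave recordings for detector specificity, and 500
summary-level null cohorts for test calibration. These sizes mirror the
15-wave clinical cohort the methodology targets while keeping a full
run in the minutes range on one core.

## Known limitations

DI scales with beat length, so heart-rate differences between periods
leak into the index; the stored `n_compared` permits a normalized
re-analysis. The CFF model is uncalibrated between subjects and rests
on idealizations that are monitored, not enforced. The automated QC
approximates, but cannot reproduce, expert visual review. And all
quantitative performance figures in the tests are statements about the
synthetic generator's signal class, not about clinical recordings.
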