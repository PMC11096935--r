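# pulsedi

Quantifying the similarity between intracranial pressure (ICP) pulse
waveforms and cerebral arterial blood volume (CaBV) pulse waveforms
during ICP plateau waves.

## The scientific problem

The ICP waveform pulsates with the cardiac cycle. A normal ICP pulse is
a saw-tooth with three peaks — percussion (P1), tidal (P2) and dicrotic
(P3) — and P1 dominant. As mean ICP rises or cerebrospinal compliance
falls, P2 overtakes P1 and the pulse becomes a rounded single hump. One
candidate driver of this transformation is the pulsatile cerebral
arterial blood volume: when compliance is exhausted, arterial volume
pulsations transmit more directly into pressure. During ICP plateau
waves (Lundberg A waves) — sustained vasodilatory ICP elevations above
40 mmHg — this transmission should be strongest, and the ICP pulse
shape should approach the CaBV pulse shape.

`pulsedi` implements a complete, tested pipeline to quantify this from
multimodal neuromonitoring recordings (ICP, arterial blood pressure
ABP, and transcranial Doppler cerebral blood flow velocity CBFV, all at
50 Hz), intended for researchers in neurocritical-care signal analysis.
Because the clinical recordings the methodology was developed on are
not publicly available, the package includes a ground-truth-annotated
synthetic signal generator that emulates their statistical structure,
so every stage is testable end to end.

## The model and the statistic

**CaBV (constant flow forward model).** Venous outflow is approximated
by the 6-s moving mean of arterial inflow, and CBFV stands in for flow
under a constant insonated-artery cross-section, giving the per-cycle
volume change (units cm, cross-sectional area divided out):

    dCaBV(n) = sum_{i=1..n} [ CBFV(i) - mean(CBFV) ] * dt

**Difference index (DI).** Each reliable ICP pulse is paired with the
CaBV pulse from the same cardiac cycle; both are min–max normalized to
[0, 1] and synchronized at their onsets (the minima at the start of
the ascending slopes). The DI is the sum of absolute sample-wise
differences from the onset to the end of the CaBV pulse — the area
between the two unit contours. Lower DI = more similar shapes.

**Plateau waves** are detected on 10-s trend signals by the standard
criteria: mean ICP rise >= 15 mmHg above the pre-wave reference, peak
above 40 mmHg, and a cerebral perfusion pressure (CPP = ABP − ICP)
drop >= 10 mmHg, sustained for at least 3 min. The baseline period is
the ~4 min before the wave; the plateau period is where mean ICP stays
at or above 90% of the wave maximum. Per-wave median DI enters a paired
Wilcoxon signed-rank test (exact null distribution for n <= 25 without
ties), summarized as median (Q1–Q3).

## Worked example

Simulate one plateau-wave episode and run the full chain:

```r
library(pulsedi)

rg  <- generate_recording(episode_plan(seed = 1))
res <- analyze_recording(rg$recording)

res$wave
#> <plateau_wave> 289-572 s, peak ICP 42.8 mmHg (baseline 19.4)
#>   baseline 49-289 s, plateau 295-556 s

median(res$di_records$di[res$di_records$period_label == "baseline"])
#> [1] 46.5
median(res$di_records$di[res$di_records$period_label == "plateau"])
#> [1] 20.7
```

The wave was found within a fraction of a second of where the generator
planted it, and the per-pulse DI roughly halves from baseline to
plateau: the ICP pulse, rounding as mean ICP climbs, has moved toward
the CaBV contour.

The cohort-scale analysis lives in `analysis/01...04` (simulate 15
recordings, detect waves, score pulses, compare periods). Its last step
prints:

```
DI [baseline]: median 46.5 (Q1-Q3 42.9-49.6), n = 3949
DI [plateau]:  median 20.9 (Q1-Q3 18.6-23.5), n = 4663
Wilcoxon signed-rank: W = 0, n = 15, p = 6.104e-05 (exact)
DI decreased at the plateau in 15/15 waves
```

i.e. across 8,612 scored pulse pairs the area between the ICP and CaBV
contours is significantly smaller during the plateau phase in every
simulated wave — the direction and decisiveness of the effect the
pipeline is designed to measure, under the programmed morphology shift.

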