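---
title: "Quantifying embryonic zebrafish cardiac function from fluorescence time-lapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying embryonic zebrafish cardiac function from fluorescence time-lapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfcardio)
```

## The measurement model

A lateral-view fluorescence time-lapse of a myl7:GFP-labelled embryonic
heart shows the ventricle as a bright, roughly elliptical blob whose
projected area oscillates with the heartbeat. The pipeline reduces each
movie to per-fish cardiac parameters in five stages:

1. **Segmentation.** Each frame is thresholded (Otsu by default),
   interior holes are filled, small components are discarded, and one
   connected component — the ventricle — is selected.
2. **Geometry.** From each mask we take the projected area `A`
   (pixel count × pixel area), the length `L` (extent of the mask along
   its first principal axis, the automated analogue of the apex-to-
   outflow-tract distance) and the diameter `D` (the chord perpendicular
   to the long axis through the axis midpoint, i.e. at the middle of the
   length measurement).
3. **Cycle detection.** End-diastole (ED) frames are local maxima of the
   area trace and end-systole (ES) frames local minima; each ED is
   paired with the following ES.
4. **Chamber equations.** Volumes come from the prolate-spheroid
   approximation `V = (pi/6) L D²`, evaluated at ED and ES of every
   cycle; per cycle we compute `SV = EDV − ESV`, `EF = SV/EDV × 100`,
   `FS = (Dd − Ds)/Dd` and `FAC = (Ad − As)/Ad × 100`. Heart rate is the
   number of complete ED-to-ED intervals divided by the acquisition
   time, and `CO = mean(SV) × HR`.
5. **Per-fish averaging.** Every parameter is evaluated per cycle first
   and then averaged across cycles; fish with fewer than three usable
   cycles are rejected rather than averaged, so each reported data point
   represents at least three contractions.

The prolate-spheroid model assumes the chamber is a body of revolution
about its long axis, so a single 2-D projection determines the volume.
This is the standard single-view approximation for the tubular embryonic
ventricle; it is exact for the synthetic data (which renders exactly such
a spheroid) and an approximation for real hearts.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `pixel_size` | user-supplied (1.0 for synthetic) | um/px | Mandatory calibration; TIFF metadata dialects are unreliable, so it is never guessed. |
| `frame_rate` | user-supplied (50 for synthetic) | fps | Denominator of heart rate; 50–75 fps resolves a ~2 Hz beat with 20+ frames per cycle. |
| `min_area` (segmentation) | 50 | px | Rejects hot pixels and debris; well below any plausible chamber cross-section. |
| `outlier_factor` (stack) | 3 | — | A frame whose mask area departs from the running median threefold is a segmentation failure, flagged and interpolated, never silently kept. |
| `min_separation` (cycles) | 0.6 | periods | Two same-type extrema closer than 0.6 of the FFT-estimated period cannot both be genuine; the weaker is dropped. |
| `min_prominence` (cycles) | 0.1 | trace range | Extrema shallower than 10% of the area range are noise ripples. |
| `min_cycles` | 3 | cycles | A per-fish average must represent at least three contractions. |
| `quantile` (NV/SV call) | 0.05 | — | A fish is called "small ventricle" when its EDV falls below the 5th percentile of the control EDV distribution; the threshold is always reported with the label. |
| `fdr_max`, `lfc_min` (DEG) | 0.05, 0.4 | — | Inclusive on FDR, strict on |log2FC|, exactly as the thresholds are stated. |

## What the synthetic generator emulates

`generate_beating_movie()` renders the ventricle as the 2-D projection
of a contracting prolate spheroid: a filled ellipse with semi-axes
`L(t)/2` and `D(t)/2`, where both dimensions interpolate linearly
between their diastolic and systolic values along a raised-cosine
contraction waveform (one maximum and one minimum per period;
`systolic_fraction` controls the asymmetry between contraction and
relaxation). The image model is the standard fluorescence camera chain:
Gaussian PSF blur, Poisson shot noise on signal plus background,
additive Gaussian read noise. Defaults (100 frames at 50 fps, 120/100 um
diastolic/systolic length, 60/45 um diameters, 0.45 s period ≈ 2.2 Hz —
a plausible embryonic heart rate at these stages, chosen once as a
default rather than taken from any particular recording) give a
ground-truth ejection fraction of 53.125%.

The generator deliberately omits: z-sectioning and out-of-plane motion,
within-frame motion blur, scattering, wall thickness (the chamber is
rendered filled, matching what filled-mask area measurements represent),
and any atrio-ventricular interaction — an optional static "atrium"
ellipse exists purely to exercise chamber selection. Passing the
recovery tests therefore demonstrates that the measurement chain is
correct for an ideal prolate chamber under realistic camera noise; it
does not certify accuracy on hearts that violate the spheroid
assumption, and real recordings additionally contain yolk
autofluorescence and neighbouring structures the generator does not
model.

## Numerical choices

- **Otsu thresholding** is parameter-free and invariant to intensity
  scaling, which matters because absolute GFP brightness varies between
  embryos. Fixed thresholds remain available.
- **Hole filling** is applied because membrane-localised GFP labels the
  chamber wall as an annulus; the filled area is what "ventricle area"
  means in the chamber equations.
- **Component ties** (equal pixel counts) are broken by the smaller
  centroid row, then column; projection ties for axis endpoints are
  broken by pixel scan order. Both rules make the pipeline fully
  deterministic.
- **The perpendicular chord** is sampled at 0.25-px steps to reduce
  aliasing. Length and diameter are distances between extreme
  *pixel centres*, so both carry a discretisation error of up to about
  one pixel; at the default chamber sizes this propagates to roughly a
  one-percentage-point systematic offset in EF in the noiseless limit
  (measured by the benchmark below), which is the accuracy floor of the
  pixel-extent definitions.
- **Period estimation** uses the dominant FFT bin of the mean-subtracted
  area trace; a trace whose dominant component does not complete at
  least two periods, or whose spectral peak does not rise above the
  noise floor, is rejected as aperiodic rather than mined for cycles.
- **Record boundaries count as extrema.** The acquisition window is not
  phase-locked to the heartbeat, so a first or last frame that dominates
  its one-sided neighbourhood is a genuine ED/ES; excluding boundary
  extrema would systematically undercount ED-to-ED intervals in short
  records and bias heart rate low. At least one *interior* extremum of
  each type is still required, so monotone traces are rejected.
- **Heart-rate quantisation.** Counting whole ED-to-ED intervals in a
  2 s record quantises HR in steps of 0.5 Hz; at the default 0.45 s
  period the recovered 2.0 Hz sits exactly 10% below the true 2.22 Hz.
  This discretisation, not segmentation error, dominates the cardiac-
  output error budget at short record lengths. Longer records shrink it
  proportionally.
- **Degenerate inputs** fail loudly with classed conditions: constant
  frames (Otsu undefined), empty masks, sub-3-pixel masks (no axis),
  all-flagged stacks, zero margins in the 2×2 test, zero variance in
  the t-test/ANOVA, ES larger than ED (a mis-paired cycle).
- **Fisher two-sidedness** follows the point-probability rule (sum of
  all tables with the observed margins whose probability does not
  exceed the observed table's, with 1e-7 relative tie tolerance),
  computed by full enumeration; this matches the convention of the
  common statistics suites. The classic (non-Welch) ANOVA and pooled
  t-test are the defaults for the same reason; Welch variants sit
  behind a flag. No multiplicity adjustment is applied to cohort tests —
  p-values are reported per comparison.
- **Averaging order.** EF, FS and FAC are computed per cycle and then
  averaged, not computed from averaged volumes; with several cycles per
  fish the two orders differ, and the per-cycle-first order is what "an
  average of all cycles" denotes.

## Validation problem sizes

The test suite validates parameter recovery on 20 seeded synthetic
movies at the default noise (100 frames, 50 fps, 160×160 px), requiring
EF within ±5 percentage points, CO within ±15%, at least 3 detected
cycle pairs per movie, and every detected ED/ES index within one frame
of truth. The exact 2×2 test is checked against an independent
log-factorial enumeration oracle on every table with total up to 40
(over 10⁵ tables, max |Δp| < 1e-12), and the t-test/ANOVA null
calibration uses 10 000 simulations each. The recovery benchmark spans
noise levels from the noiseless limit to an eightfold signal reduction,
where segmentation error finally dominates the discretisation floor.

## Known limitations

- Volumes come from one 2-D view; chambers that are not bodies of
  revolution about their long axis are systematically mis-estimated.
- The outflow tract is not separated from the chamber mask; if the
  segmentation includes it, the length measurement runs to the end of
  the combined component, matching what the mask represents but not
  necessarily a manual annotation.
- The length endpoints do not distinguish apex from outflow tract; the
  measurement is symmetric.
- HR is quantised by whole-cycle counting (see above); records much
  shorter than ~5 periods carry a correspondingly coarse HR.
- The NV/SV classifier is an operational EDV-quantile rule, not a
  replication of visual scoring.
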