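---
title: "Scoring immobility in FST and TST videos: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring immobility in FST and TST videos: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immobilitr)
```

## The measurement problem

The forced swim test (FST) and tail suspension test (TST) index behavioral
despair in rodents by the time the animal spends immobile: floating
passively in a water cylinder, or hanging passively by the tail. Manual
scoring with a stopwatch is slow and shows substantial observer-to-observer
variability. This package scores immobility automatically from video, on
the premise that a well-lit recording of a dark animal against a bright
uniform background makes the animal trivially segmentable in every frame,
and that the frame-to-frame change of the segmented silhouette is a direct
proxy for gross body movement.

## The model

Let $A(t)$ be the area in pixels of the binarized animal mask in frame
$t$. The per-frame motion signal is the unsigned relative area change

$$\delta(t) = 100 \cdot \frac{|A(t) - A(t-1)|}{A(t-1)},$$

averaged over the frames of each second $s$ (half-open bins: frame indices
$[s f, (s+1) f)$ at $f$ fps, relative to the start of the analysis window)
to give the per-second statistic $\Delta_s$, the *delta-area %*. Second
$s$ is scored immobile when $\Delta_s < c$, strictly; a value exactly at
the cut-point scores mobile. The unsigned difference matters: signed
changes would largely cancel within a second, and the statistic is meant
as a motion magnitude.

Two alternative per-frame features are implemented behind the same
surface: the major-axis length of the mask's best-fit ellipse
(`mode = "length"`, same relative-change formula), and the XOR pixel count
between consecutive masks relative to the previous area
(`mode = "variation"`). Area is the default: in validation on both tests
it is the most versatile of the three. One wording ambiguity deserves a
note: the denominator could be read as the previous *frame's* area or the
previous *second's* mean area. We use the per-frame ratio and then average
within the second; for lab-scale recordings the two readings differ only
through rasterization noise, and the per-frame reading keeps $\delta(t)$
a self-contained frame statistic.

Frames whose previous-frame area is zero (a lost mask) are flagged
invalid, never silently zeroed; a second with no valid frames inherits the
previous second's label and is marked `imputed` (a leading invalid second
scores mobile).

## Segmentation

Each grayscale frame (Rec. 709 luminance weights for RGB input, recorded
in the run log) passes through:

1. optional absolute difference against a background model,
2. Gaussian blur, `blur_sigma` (default 2 px — enough to suppress
   single-pixel sensor noise without eroding limb detail at the
   ~100-px-body scale the defaults assume),
3. a global threshold: Otsu's method per frame by default, or a fixed
   user level, with `polarity` choosing the foreground side,
4. removal of connected components smaller than `min_component_px`
   (default 50 px, rejecting glare and ripple speckle),
5. retention of the largest remaining component.

A frame that yields nothing (e.g. blank) produces an *empty, flagged*
mask rather than an error, so a transient segmentation failure cannot
abort a run.

The background model is built by marking the animal's outline in a
reference frame and replacing the interior with the median intensity of a
3-px ring just outside the polygon (ring-median inpainting — simple,
deterministic, and adequate for the uniform backdrops these tests use).
When a background model is active, segmentation thresholds
$|I - I_{bg}|$ with bright-side polarity; the difference image is bright
wherever the animal is, which is what makes the method work for black and
white animals alike. Largest-component selection and the minimum
component size are pragmatic robustness additions; localized/learned
segmentation and multi-animal tracking are out of scope.

## Analysis window, ROI, containers

The analysis window is given in seconds; frame indices
$[\mathrm{round}(t_0 f), \mathrm{round}(t_1 f))$ are used (sub-second
boundaries round to the nearest frame) and the analyzed duration is
$\lfloor t_1 - t_0 \rfloor$ whole seconds. The region of interest is a
multi-point polygon reduced to its minimal axis-aligned bounding
rectangle — the crop is rectangular; the polygon is never used as a mask.
Videos are processed at native frame rate with no resampling; 15 fps is
the validated reference. Supported containers are multi-frame TIFF stacks
and directories of numbered PNG/TIFF frames, with the frame rate supplied
as an argument or a JSON sidecar; these lossless, codec-free containers
keep every analysis bit-reproducible, and the synthetic renderer emits
them directly.

## Bout analytics

From the per-second 0/1 track: percent time immobile, latency to the
first immobile second, longest immobility and mobility bouts, block-wise
immobile seconds (non-overlapping blocks from second 0, last block
possibly partial) and raster intervals. A bout is any maximal run of
$\ge 1$ s — no minimum-bout smoothing, since none is part of the method's
definition; latency likewise requires no minimum bout length. A track
with no immobile second reports latency as missing (`NA`, an empty CSV
cell), never 0 or the track length.

## Threshold calibration

Given manual per-second labels (1 = immobile) and the corresponding
trace, seconds within $k$ of every manual transition are excluded:
human scorers lag a state change by roughly 1–3 s, so labels adjacent to
a boundary are unreliable. "k seconds around a boundary" is interpreted
per side: the boundary between seconds $t-1$ and $t$ removes seconds
$t-k \ldots t+k-1$. The default $k = 3$ matches the shipped calibration.
Exclusion windows are nested in $k$, so raising $k$ can only remove more
seconds.

On the kept seconds, with immobile as the positive class and "value
$< c$" as the positive prediction, the threshold grid is every distinct
observed value plus one sentinel below the minimum and one above the
maximum. This makes the trapezoidal AUC exactly the Mann–Whitney
pair-ordering probability (ties ½) and makes the selected cut-point
independent of any sweep resolution. The optimum cut-point maximizes
$\mathrm{Sens}(c) \times \mathrm{Spec}(c)$; ties break toward the smaller
$c$ (the more conservative choice: fewer seconds called immobile).
When several videos are calibrated together their kept seconds are pooled
into a single ROC — per-video ROC averaging is a defensible alternative,
but pooling weights every labeled second equally and needs no extra
convention for videos of unequal length. A 60/40
calibration/validation split (seeded, deterministic) is provided for
larger studies.

The shipped defaults — $c = 2.5861$ (FST), $c = 0.7808$ (TST), $k = 3$,
split fraction 0.60 — come from the reference calibration on mouse
videos and are applied automatically whenever no threshold is supplied;
the resolved value is always written to the run log.

Method agreement between automated and manual scoring is assessed with
Bland–Altman bias and 95% limits of agreement (bias ± 1.96 × sample SD,
$n-1$ denominator — the standard construction) and Pearson correlation
with a two-sided $t$-based p-value.

## The synthetic fixture generator

`render_video()` draws a dark ellipse (default intensity 40/255,
semi-axes 12 × 7 px) on a bright background (220/255) with Gaussian pixel
noise (SD 5 on the 8-bit scale), at 15 fps in a 96 × 128 frame, following
a per-second mobile/immobile schedule; the default schedule alternates
20-s bouts across a 300-s test, mirroring a 5-minute recording with
roughly balanced states. During mobile seconds the blob takes an
integer-pixel random-walk step (amplitude 2 px/frame) and its area
oscillates sinusoidally with peak fractional amplitude `deform_frac`
(default 0.15, period 10 frames). Integer translation preserves the
rasterized area exactly, so the deformation is what drives the delta-area
statistic — the analogue of limb and posture movement; at the defaults the
mobile-state delta-area sits near 6% per frame, comfortably above both
shipped thresholds, while immobile seconds (no deformation, optional
micro-jitter, noise only) stay near 0.3%. At those separations the
end-to-end recovery checks run in FST mode, whose default threshold sits
mid-gap.

`simulate_human_labels()` delays every ground-truth transition by an
independent uniform integer lag (default 1–3 s), resolving overlapping
delayed transitions in chronological order — a model of scorer reaction
time sufficient to reproduce the characteristic pattern that calibration
AUC improves as the exclusion window $k$ grows. For studies of the
calibration procedure across many replicates, `simulate_motion_trace()`
skips rendering and draws per-second delta-area values directly from
per-state lognormal distributions (mobile median 6%, immobile median
0.35%, $\sigma_{\log} = 0.45$), calibrated to match what the renderer's
defaults produce through the full segmentation path.

What the generator does **not** emulate: water ripples and reflections,
glare, shadows, tail-climbing artifacts, camera motion, non-elliptical
posture change, or occlusion. Passing the package's validation therefore
demonstrates the correctness of the measurement chain and the calibration
machinery on ideal-contrast scenes — not robustness to difficult optics,
which must still be controlled at acquisition time (matte background,
top lighting, fixed camera).

## Validation scale and numerical choices

The test suite validates the pipeline end to end on a full-scale fixture
(300 s at 15 fps, 4500 frames, alternating 20-s bouts, noise SD 5),
requiring ≥ 95% per-second agreement with the schedule away from ±1 s
around transitions and percent-immobile recovery within 3 points; a
noise-free static-blob video must give an identically zero trace and
exactly 100% immobility. Calibration behavior is validated on 50
surrogate replicates (300-s schedules, lagged labels), where AUC must be
non-decreasing in $k = 0..3$ in at least 95% of replicates. AUC is
checked against a brute-force pairwise oracle to $10^{-9}$, the cut-point
against exhaustive grid search, bout summaries against a scan oracle on
every binary track up to length 12, and the agreement statistics against
direct arithmetic to $10^{-12}$.

Numerical conventions, collected: strict `<` at the threshold (ties
mobile); unsigned area differences; half-open second bins; frame 0 of a
window skipped (no predecessor); round-to-nearest-frame window
boundaries; ROC tie-break toward the smaller threshold; latency undefined
(not 0) without immobility; empty masks flagged, not erroring; 8-bit
quantization of rendered fixtures so in-memory and decoded frames are
bit-identical; all stochastic components (renderer, lag model, surrogate
traces, splits) consume an explicit seed and restore the caller's RNG
state.

## Limitations

Single animal per crop; global thresholding assumes bimodal intensity
within the ROI; the delta-area statistic cannot distinguish
head-only micro-movements from stillness at coarse resolution; calibrated
thresholds transfer only across recording setups with comparable
geometry, contrast and frame rate — recalibrate when any of these change.
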