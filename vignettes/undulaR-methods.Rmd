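---
title: "Methods: posture, calcium and correlation analysis of crawling C. elegans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: posture, calcium and correlation analysis of crawling C. elegans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(undulaR)
```

# Scope

`undulaR` quantifies the undulatory locomotion of single crawling
*Caenorhabditis elegans* and relates it to neural and muscular calcium
signals. The pipeline has six analysis stages — segmentation and
midline extraction, posture metrics, track quality control, fluorescence
trace extraction and normalization, moving-neuron tracking with the
vulva bending angle, and event-wise cross-correlation — plus a
synthetic-data generator that produces videos with exact ground truth so
every stage can be validated end to end. A small synapse-count module
summarizes the wiring motif that motivates the biology: the AS motor
neurons innervate dorsal body-wall muscle (BWM) and the inhibitory
ventral VD neurons almost exclusively, an asymmetry that makes their
activity interesting for dorso-ventral coordination.

This vignette records the models, the parameter choices that matter,
and the design decisions taken where the underlying procedures are
conventionally under-specified.

# The synthetic worm

## Posture model

The generator represents posture by the tangent angle along normalized
arc length $s \in [0, 1]$:

$$\theta(s, t) = A(t)\,\sin\!\big(2\pi s/\lambda - 2\pi f t - \phi(t)\big)
  + B(t) + C\,(s - \tfrac12)$$

* $A$ — tangent-angle amplitude (default 0.45 rad). Typical adult
  crawling postures have peak tangent angles of roughly 0.4–0.7 rad.
* $\lambda$ — wavelength as a fraction of body length (default 0.8).
* $f$ — undulation frequency (default 0.5 Hz, the rate of freely
  crawling adults on agar; animals recorded under a coverslip are
  slower, and the neuron-imaging scenario uses 0.25 Hz).
* $B$ — a constant angular offset. Note that adding a constant to all
  tangent angles is a rigid rotation of the animal: it changes heading,
  not shape. Signed bending metrics are therefore invariant to $B$; the
  unit tests assert this explicitly.
* $C$ — static body curvature, a linear tangent ramp. This is the term
  that produces a genuine dorsal bend: all signed 3-point angles share
  one sign and the animal circles, the behaviour seen when dorsally
  innervating motor neurons are depolarized.
* $\phi(t)$ — optional cycle-to-cycle phase jitter, a seeded Gaussian
  random walk (SD in rad per $\sqrt{s}$, default 0). Real undulation is
  not clockwork; beyond realism, a strictly periodic wave makes any
  lead/lag relation identifiable only modulo the period, so parameter-
  recovery scenarios use a small nonzero value (0.3).

The midline is reconstructed by integrating unit tangents from the head
over 99 equal segments, so the arc length equals the commanded body
length exactly, and the centroid is advanced head-first at the commanded
speed. Perturbation epochs rescale $A$, $B$, speed and body length
multiplicatively, which reproduces the qualitative optogenetic effects
(deeper bends, slowing, contraction) without modelling their mechanism.
No muscle forces, proprioception or photophysics are simulated — the
generator is a kinematic oracle, not a biomechanical model. Passing the
round-trip tests therefore demonstrates correctness of the *analysis*,
not robustness to every artefact of real microscopy (uneven
illumination, omega turns, coiling, debris other than the simple border
blob the renderer can add).

## Rendering

Silhouette videos draw filled disks along the midline with a
$\sin^p(\pi s)$ half-width profile ($p = 0.5$, peak width 0.08 mm),
which guarantees one connected blob tapering to sub-pixel width at head
and tail — the taper is what lets skeleton ordering identify the body
axis ends. Default scale is 0.01 mm/px, so the 1-mm adult spans 100 px.
The worm is bright on dark by default (`invert` covers the opposite
convention), Gaussian pixel noise is seeded, and all frames are clipped
to $[0, 1]$.

Fluorescence movies are simpler: muscle movies place disk ROIs in a
dorsal and a ventral band whose intensities follow antiphase waveforms
(sinusoidal by default; a rectified mode exists for burst-like traces —
note that with half-wave rectified antiphase signals the Pearson
correlation between the sides is only about $-0.68$, which is why the
sinusoid is the default for reciprocity checks), and neuron movies place
Gaussian spots riding the midline at fixed arc-length fractions.
Neuron movies are rendered in a stage-compensated frame (centroid pinned
to the image centre), as produced by a tracking stage that keeps the
fluorescent landmark in view.

# Segmentation and the 100-point midline

Per frame: global Otsu threshold, discard connected components touching
the image border, keep the largest remaining blob, then clean up by
thickening (one 3×3 diamond dilation), spur removal (5 iterations),
a majority filter and hole filling. The threshold is computed by
`otsuThreshold()`, an exhaustive maximization of between-class variance
over a 256-level histogram; the test suite checks it against an
independently written brute-force search on every seeded random image.

The mask is thinned to a 1-px skeleton (Zhang–Suen), skeleton pixels
become a graph with 8-neighbour edges weighted by Euclidean step length,
and the spine is the longest geodesic between skeleton endpoints. Side
branches up to 10 px (geodesic) are ignored; anything longer flags the
frame `branching_unresolved`, and skeletons under 20 px flag
`skeleton_too_small`. Two numerical details matter for accuracy:

* the pixel staircase of the skeleton inflates arc length by ~3%, so the
  path coordinates are smoothed with a 7-point moving average before
  resampling;
* thinning retracts from the tapered tips, so both spine ends are
  extended along their local tangent until they leave the mask.

With both corrections, noise-free synthetic frames are recovered with
RMS point error below 1 px and arc-length error below 2%. The spine is
resampled to 100 points at equal arc length; coordinates are 1-based
(row, col) pixels throughout the package.

Head/tail assignment chains frame-to-frame (the orientation minimizing
summed point distances to the previous frame) and fixes the global
choice either from a user hint or automatically from motion: the end
whose offset from the centroid projects positively on the centroid
velocity over the first second is the head. Tangent angles are then
unwrapped and smoothed along the body with a centered 15-point moving
average, truncated at the ends. The 15-sample window is read as *body
points*, not frames; the temporal smoothing used by the differential-
bending metric is a separate, equally configurable 15-frame window.
Frames that fail any stage stay missing (`NA`), never zero.

# Posture metrics

* **2-point-angle kymograph** — per frame, the 99 segment angles minus
  their frame mean. Mean subtraction removes global heading, so rows sum
  to zero and a straight worm gives zeros at any orientation; stripes
  advance head-to-tail at $\lambda f$ body lengths per second.
* **3-point angles** — 13 points at equal arc-length fractions define
  eleven angles, $180°$ minus the interior angle at the middle point,
  signed dorsal-positive. The dorsal side is declared per video
  (`vulva_side`), replacing the manual vulva annotation of interactive
  trackers; with `"unknown"` the result is flagged as having an
  arbitrary sign convention. Angles are stored in degrees.
* **Dorso-ventral ratio** — mean of dorsal samples over |mean| of
  ventral samples of one angle trace, conventionally the 2nd angle; a
  one-sided trace is an explicit error, not an infinity.
* **Differential bending** — 15-frame temporal smoothing, per-frame
  |difference|, epoch means, and light-minus-dark differences averaged
  over anterior (1–5) and posterior (6–11) angles.
* **Eigenworms** — principal components of mean-centered normalized
  tangent angles via `prcomp`; the basis object enforces orthonormality
  to 1e-8. The published N2 basis is not bundled; the default is to fit
  a basis from a supplied posture library and project onto it.

# Track quality control

Speed is centroid displacement times frame rate, smoothed over 15
frames (the cap below is applied to the smoothed trace; raw-speed
gating is available by disabling smoothing). Frames are discarded when
speed exceeds 1.25 mm/s — crawling worms do not move that fast, so
faster apparent motion is a tracking failure — or when body length
deviates more than 25% from the mean over the first five seconds.
A video is excluded when *strictly more than* 15% of frames were
discarded; exactly 15% keeps the video, and the tests pin this boundary.
Window summaries (mean ± SEM, $n-1$ denominator) drop masked samples
from $n$ and report empty windows as missing.

# Fluorescence traces

ROI traces are per-frame means over a signal ROI minus a same-size
background ROI; background subtraction must precede normalization
because $\Delta F/F$ is scale-invariant but not offset-invariant (both
properties are tested). Normalization follows
$\Delta F/F = (F_i - \bar F)/\bar F$ with $\bar F$ the mean of the
entire corrected trace, so every normalized trace has exactly zero mean.
Ratiometric recordings use $R_i = \mathrm{YFP}_i/\mathrm{CFP}_i$ and
$\Delta R/R = (R_i - \bar R)/\bar R$; $\bar R$ defaults to the full
trace with a stimulation-window option, since both conventions are in
use, and the ratio cancels any per-frame factor common to both channels
(uniform bleaching leaves $\Delta R/R$ unchanged). Trace sets can be
aligned to the first peak of a reference trace; "peak" means a local
maximum with prominence at least twice the reference SD by default, and
recordings without a qualifying peak are excluded with a reason rather
than dropped silently.

# Neuron tracking and the vulva angle

Spots are detected per frame by Otsu binarization of the marker channel
and connected-component centroids (components under 4 px are ignored).
Identities are kept by greedy nearest-neighbour linkage against each
track's last known position with a 20-px gate; the linkage rule is a
package choice, as centroid-linking conventions are rarely printed.
Intensity is the mean over an 18-px-radius circular ROI centred on the
(translation-corrected) centroid minus the mean over the surrounding
5-px-wide annulus, which cancels additive background by construction.
Channel alignment is translational only. The vulva angle is the
interior angle at the vulva landmark between the two flanking neurons
(180° = locally straight); coincident or missing spots give missing
frames.

One geometric fact shapes the synthetic scenario: the interior angle is
invariant to rigid rotation, so the constant offset $B$ cancels between
the two arms and a straight-mean posture rectifies the angle to twice
the wave frequency. The default scenario therefore uses a curved
posture ($C = 2$ rad), under which the angle oscillates at the
undulation fundamental — as it does in real, dorsally biased animals.

# Event-wise cross-correlation

Traces are linearly resampled to 10 samples/s — the lag grid of 100
lags spanning 10 s fixes that analysis rate — and smoothed with a
centered 10-sample moving average. A bending event is the segment of
the angle trace between consecutive local minima (prominence 10% of the
trace range by default; events under 1 s are dropped and counted).
For each event the cross-correlogram is computed at integer lags
$-100..+100$; positive lag means the first signal leads.

Two normalizations are provided. `"pearson"` (default) is the Pearson
correlation of the overlapping lag-shifted samples; it has no
attenuation, so the peak of a lag-shifted copy is exact, and overlaps
under 3 samples are missing. `"coeff"` centres each event once,
zero-pads, and normalizes by total event energy — the convention of
whole-trace cross-correlation routines; its attenuation with |lag| is
what gives strictly periodic signals a unique peak. Per-lag means and
SEMs are taken across events.

The reported `peak` of a correlogram set is the lag of *maximum
positive* mean correlation — where the signals align — rather than the
largest magnitude: with events of about one period, a lead of half a
period always has an antiphase alias near lag zero whose magnitude
rivals the true peak, and the positive maximum is the quantity with a
physiological reading. The signed "largest magnitude, positive or
negative" rule is implemented where condition comparisons use it:
`peakCorrelation()` searches a 5-s window centred on the peak lag of a
control correlogram and preserves the sign. Reversal episodes are
selected as maximal reverse runs of at least 10 s.

In the standard synthetic scenario (60 s, 0.25 Hz jittered wave, curved
posture, activity leading the vulva angle by 2 s, AS7 trailing AS6 by
1 s) the full pipeline — rendering, tracking, angle geometry,
resampling, event segmentation, correlation — recovers the 2.0-s and
1.0-s lags exactly at the 0.1-s lag resolution.

# Synapse-count summaries

`synapseFractions()` turns a transcribed (source, target, count) table
into outgoing fractions and whole-number percentages. Rounding is half
away from zero, matching the printed convention (68/144 → 47%,
66/144 → 46%); fractions sum to 1 and rounded percentages to 100 ± 1.
The bundled table transcribes only published counts for the VNC motor
neuron classes; of the 144 documented AS synapses, 68 + 66 go to dorsal
BWM and VD respectively, and the 10-count remainder is pooled as
"other".

# Problem sizes and determinism

The validation suite runs on deliberately small inputs: 20 rendered
frames for midline recovery, 50 random images for the threshold oracle,
a 300-sample muscle movie, and one 1200-frame neuron scenario that is
built once and shared across tests. Every stochastic step — rendering
noise, phase jitter, test-case sampling — is seeded, and identical
parameters plus seed give bit-identical stacks and ground truth.
`scripts/acceptance.R` recomputes the headline quantities from scratch
for any seed.

# Known limitations

* Self-intersecting postures (omega turns, coiling) are flagged invalid
  rather than resolved.
* Multi-animal tracking, stage-control loops and whole-field neuron
  segmentation are out of scope.
* The generator's single-harmonic wave and disk-based rendering do not
  emulate photon statistics, illumination gradients or body-texture
  detail; conclusions about robustness to such artefacts require real
  recordings.
* Inferential statistics on group data are intentionally absent; the
  package exports per-track and per-window summaries for analysis in
  the user's statistics environment.
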