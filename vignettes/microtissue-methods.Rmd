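---
title: "Methods: fiber orientation mapping and growth-front profiling of cleft-grown microtissues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fiber orientation mapping and growth-front profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(microtissue)
library(ggplot2)
```

## The system and the measurement problem

Fibroblast microtissues grown de novo in 45° angular scaffold clefts organize
along a sharp spatial program: a myofibroblast-rich growth front facing the
culture medium deposits fibronectin (Fn), tenascin-C (TNC) and
alpha-smooth-muscle actin (aSMA) in a band 10–20 µm wide, while the maturing
core behind the front accumulates SHG-visible (second-harmonic-generation)
fibrillar collagen. Three quantitative readouts characterize this program on
multi-channel micrographs:

1. **Pixel-level collagen fiber orientation** of the SHG channel, summarized
   as orientation histograms and a midline-symmetry score;
2. **Cleft-aligned intensity profiles** of the marker channels versus
   distance to the growth front, with the front located by a
   cumulative-intensity threshold;
3. **Growth kinetics**: tip-to-front distances over days, fitted to a rate.

This vignette documents the models, conventions, parameter choices and known
limitations of each stage, and what the synthetic-data generator does and
does not emulate.

## Fiber orientation model

Local orientation is estimated from second-order intensity structure. The
basic 5×5 derivative operator (a Gaussian-derivative operator optimized by
Kroon) is applied twice — sequentially, or equivalently once with the
composed 9×9 kernel — to obtain the second derivatives $I_{xx}$, $I_{yy}$,
$I_{xy}$. These are smoothed with a Gaussian of $\sigma = 4$ px, and the
local orientation follows from the half-angle arctangent

$$\varphi = \tfrac{1}{2}\,\mathrm{atan2}\!\left(-2 I^{*}_{xy},\; I^{*}_{xx} - I^{*}_{yy}\right)
\in [-90^\circ, 90^\circ).$$

We use the two-argument arctangent: a single-argument arctan of the ratio
cannot distinguish orientations 90° apart, and the two-argument form is
standard structure-tensor practice. At bright ridge pixels (fiber cores) the
angle is the fiber direction; at dark valley pixels the same formula returns
the normal. The default validity mask therefore combines three criteria:

* response magnitude $\sqrt{(2I^{*}_{xy})^2 + (I^{*}_{xx}-I^{*}_{yy})^2}$
  above $10^{-3}$ of its global maximum (orientation undefined on flat
  regions — a uniform image yields an all-invalid field);
* brightness above an Otsu threshold of the input channel (restricts the
  field to fiber pixels; the published analysis does not state how
  background was excluded, so this is our declared choice, exposed as
  `brightness_mask`);
* a border strip equal to the effective support of the filter chain
  (derivative support 4 px plus the Gaussian truncation radius), because
  pixels closer to the border are contaminated by boundary padding.
  Convolutions use mirror-reflect padding.

**Coordinate and angle conventions.** Rasters are indexed `[row = y,
col = x]`; angles are measured counter-clockwise from the +x axis in display
orientation (y up), so 0° is the cleft bisector after alignment. The printed
operator grid carries its differentiation axis along its own rows, which in
this storage convention means the x-derivative applies the transposed grid;
the half-angle formula above then produces display-convention fiber angles
directly. These conventions are pinned down empirically by the test suite:
grating-angle recovery at nine signed angles, rotational equivariance, and
mirror antisymmetry under vertical flips.

**Histograms and the modal angle.** Orientation histograms default to
unweighted pixel counts in 2° bins (the published figures specify neither
the weighting nor the bin width; brightness weighting is available). The
modal angle is estimated by locating the peak on a circularly smoothed
histogram (moving average, ±2 bins) and refining it as the circular center
of mass of the raw histogram within ±10°, in the doubled-angle space. A raw
single-bin argmax is available (`smooth_bins = 0, refine_halfwidth = 0`) but
jitters by several bins on noisy data; the smoothed estimator recovers
grating angles within ±1° noise-free and within ±5° at SNR 3.

**Symmetry score.** Mirror symmetry of a histogram $h$ about the 0° midline
is scored as $1 - \lVert h - \bar h\rVert_1 / (2\sum h)$ where $\bar h$ is
the reflection about 0°: exactly 1 for mirror-symmetric and 0 for fully
one-sided histograms. This quantifies the qualitative observation that
intact microtissues have midline-symmetric fiber populations.

**HSV rendering.** Hue encodes $2\varphi$ (so the 180°-periodic orientation
spans the full hue circle), saturation is 1, and value is the
contrast-adjusted brightness (see below); invalid pixels render black. The
published description adjusts contrast for display, so contrast-adjusted
value is the default, with the raw brightness available.

## Cleft-aligned profiles and front detection

Images are rotated so the cleft bisector is parallel to +x with the tip on
the left (rotations by multiples of 90° are exact array reindexing; others
use bilinear interpolation, whose error is second-order after band
averaging). A symmetry axis parallel to the bisector is then chosen. The
published procedure assessed this axis visually; our automated surrogate
takes the row, within ±20 px of the bisector, maximizing total in-band
intensity summed over channels — and a user-supplied row overrides it. The
criterion behind the visual choice cannot be recovered from the paper; ours
is declared, not inferred.

Profiles average each channel over a 100-pixel band: rows $y-50$ through
$y+49$ around the axis row (the verbal rule "50 above and 50 underneath"
does not resolve the axis row's own membership; this assignment is fixed and
documented). Each channel is then normalized by its own maximum, so each
peaks at exactly 1; all-zero channels stay zero and are flagged.
Normalization is idempotent. Integrated intensities (sums of the raw
profiles) complement the normalized curves as the absolute readout.

The growth front is detected on the cumulated signal — the sum of the
per-channel *normalized* profiles. The published text does not state whether
cumulation preceded normalization or included the SHG channel; we cumulate
normalized profiles of all channels so that no channel dominates through
acquisition gain. Scanning from the open (tissue–medium) side toward the
tip, the boundary is the first x where the cumulative signal exceeds 25% of
its maximum, anchoring the distance axis (0 at the front, positive into the
core). On a monotonic profile the detected fraction equals the threshold to
one pixel of quantization, and raising the threshold never moves the front
toward the open side.

## Growth kinetics

The growth distance is measured from the cleft tip to the outermost
above-threshold (or masked-in) pixel along the bisector ray, in µm. The rate
is the ordinary-least-squares slope of distance versus day within a fit
window — robust to single-day noise and identical to the endpoint formula
for two points, and invariant to a constant offset in the distances. On
synthetic series (9 daily observations, 5 µm distance noise) the fitted rate
recovers the simulated 60 µm/day within 5%.

## Visualization conventions

`percentile_contrast()` linearly rescales a raster so that 0.05% of pixels
saturate, using order statistics so the realized fraction matches the
request to one-pixel quantization. Whether the published convention
saturates 0.05% per image in total or per tail is not stated; we default to
splitting the fraction between both tails with a one-sided (`tails =
"high"`) option. The mapping is monotone and idempotent up to quantization;
constant rasters pass through unchanged with a warning.
`split_lut_overlay()` renders rows above/below the symmetry axis with two
different channel-to-color assignments (additive blending, clipped at 1) —
the convention for showing two marker sets in one mirror-symmetric tissue.

## The synthetic-data generator

No images are deposited with the original study, so validation rests on
synthetic data with known ground truth.

**Fiber phantoms** render either oriented sinusoidal gratings (the default
for orientation tests, because their per-pixel orientation is exact) or
anti-aliased line segments. Multi-mode gratings tile the image into blocks
whose orientations follow the requested distribution; for exact mode weights
the allocation is deterministic (largest-remainder) with a seeded shuffle.
A fixed seed reproduces any phantom bit-exactly.

**Synthetic microtissues** place a 45° wedge at a configurable tip, fill it
up to a growth distance, and assign each channel an axial profile in
distance-to-front coordinates: front markers as a Gaussian peak of
configurable FWHM (default 15 µm, the middle of the observed 10–20 µm front
width) centered half a width behind the front plus a plateau approached
with a decay length; SHG as a logistic rise behind the front, optionally
textured (tangentially aligned ripples near the front, wavy in the core).
Noise is additive Gaussian (a deliberately simple model — adequate for
property tests, not a shot-noise model). The generator returns, alongside
the image, the exact front position and the *noiseless band-averaged*
per-channel profiles. Near the tip the 100-row band partially exits the
wedge, so the band average differs there from the axial profile function by
construction; the band average is the correct oracle for profile
extraction, and the analytic profile functions are returned as well.

**What passing tests do and do not show.** The generator emulates the
statistical structure the analysis assumes — oriented fibrous texture,
steep front-localized gradients, a wedge mask advancing over days, additive
noise. It does not emulate SHG image formation, optical blur, cell bodies,
tissue curvature, uneven illumination, or rupture artifacts; recovery on
synthetic data therefore validates the implementation and its numerical
behavior, not performance on real micrographs.

**Pixel size** is a free parameter with no canonical default in the source
material; the generator uses 1 µm/px, chosen once for convenience of
px↔µm reasoning and stated wherever distances are reported.

## Numerical choices and degenerate inputs

* Convolution: FFT-based with mirror-reflect padding; the Gaussian kernel is
  truncated at 5σ (tail mass < 1e-6), so smoothing twice with σ = 4 matches
  a single pass at σ = √32 to RMS ~1e-8 away from borders.
* The sequential (two 5×5 passes) and composed (one 9×9 pass) derivative
  paths agree to < 1e-15 away from the border and are cross-checked against
  a loop-based reference implementation in the tests.
* Orientation undefined (flat image): all-invalid field; zero-mass
  histograms are rejected by the symmetry score.
* Front detection on an all-zero profile raises a "no tissue detected"
  error rather than returning a position.
* Growth distance on an empty mask is 0 µm; rate fitting requires at least
  two in-window observations.
* TIFF I/O: integer-valued channels round-trip bit-exactly via 16-bit
  samples; continuous data use 32-bit samples (relative quantization
  2^-32). Orientation maps are written scaled as (degrees + 90)/180, with
  the scaling recorded in the report, because the TIFF writer stores
  samples in [0, 1].

## Problem sizes used in the validation suite

The test and acceptance runs use phantom sizes of 96–192 px (the larger for
noisy modal-angle estimation, which needs more valid pixels), microtissues
of 320×256 px with 150 µm growth (so the 100-px band fits inside the 45°
wedge over the front-peak region), 20-seed front-recovery replicates, and
9-day growth series at 60 µm/day — sizes chosen so every recovery statistic
is well determined while the full suite runs in minutes.

## Known limitations

* The orientation estimator is 2D; out-of-plane fibers bias angles toward
  the projection.
* No coherence/anisotropy index is computed beyond the symmetry score, and
  no individual fibers are traced; waviness is not quantified.
* The symmetry-axis surrogate assumes the tissue straddles its bisector;
  markedly asymmetric (e.g. ruptured) tissues may need the manual override.
* Cleft geometry is supplied, not detected from phase contrast.
* The growth-distance threshold (Otsu by default) assumes a bimodal
  intensity histogram along the ray; masks are preferred when available.
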