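---
title: "Pipette tip localization and closed-loop correction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pipette tip localization and closed-loop correction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipettefix)
```

## The problem

Automated patch-clamp rigs position a glass pipette (1-2 µm tip) against a
~10 µm neuron using motorized micromanipulators whose random and systematic
errors, accumulated over long moves, reach the order of 10 µm — larger than
the target cell. The remedy studied here is visual: estimate the tip
position from the microscope image and correct it in closed loop before each
attempt. `pipettefix` implements the full method at desk scale: a synthetic
image generator with exact ground truth, the preprocessing and augmentation
chain, a convolutional regression network predicting the `(x, y, z)` tip
position, the normalized cross-correlation (NCC) template-matching baseline
it is compared against, an iterative proportional feedback loop against a
simulated manipulator, and the statistical evaluation layer.

## Coordinate frames and the three errors

The stage origin is the centre of the field of view with the tip in focus;
x runs along camera columns, y along rows (+y is up, i.e. decreasing row),
z along the optical axis. The default camera is a 1024 x 1280, 8-bit frame
spanning 116 x 92 µm (0.0906 / 0.0898 µm/px); `desk_camera()` is a 256 x 320
crop at the same pixel pitch used for CPU-scale experiments. Pixel
coordinates are 0-based `(col, row)` pairs with sub-pixel values; the frame
centre `((cols-1)/2, (rows-1)/2)` maps to the origin. The y-axis sign is a
convention (all reported quantities are differences, so any consistent
choice works); it is fixed once, here.

For an attempt with desired position `d`, true position `p`, and estimate
`p̂`, three error vectors are defined: the true error `t = p - d`
(unobservable on a rig), the estimator error `c = p - p̂`, and the measured
error `m = d - p̂`. Only `m` is observable; it drives the correction. The
identity `t = c - m` holds by construction and is asserted in the tests.
Convergence of the loop requires the estimator errors to be smaller than the
positioning errors being corrected.

## The synthetic scene model

No public image-formation model exists for DIC pipette scenes, so the
generator uses the cheapest model that makes xy estimable from edges and z
from defocus:

* **Pipette**: two converging walls meeting at the tip, shaft oriented 24°
  in-plane (the manipulator approach angle), taper half-angle 4°, tip width
  1.5 µm. Each wall carries a bipolar bright/dark relief profile (width
  0.8 µm) emulating DIC shading. A bipolar intensity dipole along the shaft
  axis at the apex models the tip aperture; its amplitude is chosen so that
  the point of maximal image gradient coincides with the annotated tip (a
  tested invariant) while staying below the clipping range.
* **Defocus**: the pipette layer is blurred with
  `sigma = 1 px + 1.0 px/µm * |z|`. This growth rate is conservative for a
  high-NA water-immersion objective; it is the dial that trades z
  identifiability against xy difficulty at defocus. Symmetric blur makes
  +z and -z indistinguishable, so a structural asymmetry (default 0.3)
  rescales the bright vs dark lobes with the sign of z, emulating the halo
  reversal through focus. Because the cue is a ratio, it survives the
  per-image affine contrast stretch (a global brightness offset would not).
* **Background**: plain (uniform) or slice. The slice texture is a sum of
  two correlated Gaussian fields — coarse mottle at the stated correlation
  length (default 5 µm) and subcellular granularity at a quarter of that
  length — plus DIC-shaded cell somata (Poisson-placed relief blobs of
  roughly neuronal size, default 6 per 1000 µm²) whose dipole shading
  locally resembles a pipette tip. The granularity and the somata are what
  defeat template matching over real tissue; a single smooth field leaves
  NCC essentially unimpaired. Both kinds carry a random linear illumination
  tilt (up to 10%).
* **Pipette variation**: datasets draw one appearance per xy position from
  `pipette_variation()` — tip width uniform on 1–2 µm (the range of 3–5 MΩ
  patch pipettes), relief contrast 0.25–0.55, and a small Gaussian jitter
  on the mounted angle. A fixed template cannot absorb this variation; a
  trained network learns it, which is a large part of why learning beats
  template matching on real rigs.

All randomness flows from explicit integer seeds; rendering is bit-exact
reproducible.

### Acquisition emulation

`generate_dataset()` reproduces the two annotation protocols: *test* style
draws independent uniform positions in a `±xy_range x ±z_range` box
(defaults ±27 µm and ±6 µm at full frame); *train* style images one xy
position at z = 0, then descends in constant steps (5-20 µm, constant per
position) to a random limit of up to 100 µm and re-ascends above focus to a
random limit (default up to 30 µm — the protocol's upper limit is not
printed, so it is a package choice). `generate_mixed_dataset()` renders half
the positions over each background kind, mirroring the original data
collection over both plain backgrounds and brain slices.

## Preprocessing

Each image is contrast-stretched: the window `mean ± 2 SD` (population SD,
the usual image-statistics convention; at 10^5-10^6 pixels the difference
from the sample SD is negligible) is mapped linearly onto [0, 1] and clipped
after mapping. The frame is centre-cropped to a square (removing
`(cols - rows)/2` columns per side) and resized to the network input
(224 px at full scale; 64 px in the desk experiments) by bilinear
interpolation with a Gaussian prefilter when downsampling. Annotations are
transformed with the exact ratio `out_side / rows` — no rounding — and tips
cropped out are flagged, never silently dropped. Training sets are augmented
with the horizontal, vertical, and combined flips (4n images from n);
annotation coordinates follow `S - 1 - coord`. Validation and test sets are
preprocessed but not augmented: the augmentation exists to diversify
training, and an augmented validation set would only re-weight the same
information.

## The regression CNN

Both backbones end in one fully connected layer emitting the continuous
3-vector `(col, row, z)` in the preprocessed frame, trained under a
mean-squared-error loss (the regression-layer convention; only RMSE
*monitoring* is specified upstream). The `"small"` backbone is four 3 x 3
convolutions (12, 24, 48, 48 channels) with three 2 x 2 max-pool stages —
the final 8 x 8 grid (for 64 px input) keeps enough spatial resolution for
sub-pixel regression; a fourth pool measurably hurts localization. The
`"resnet_class"` backbone is a deeper residual network (three stages with
identity-skip blocks) with its classification head replaced by the same
regression layer, randomly initialized; nothing in the package requires a
pretrained-weight download.

Targets mix units (pixels for col/row, µm for z), so each target column is
standardized (zero mean, unit SD over the training set) before the loss and
de-standardized on output; otherwise one axis dominates the objective.
Optimization is RMSprop (squared-gradient decay 0.9, epsilon 1e-8) with
mini-batches of 16 drawn after per-epoch reshuffling and a piecewise
learning-rate schedule `lr0 * factor^floor((epoch-1)/period)`. The reference
recipe (lr0 1e-4, factor 0.09, period 10, 60 epochs, validation every 50
iterations, infinite patience) is the package default; it was tuned for
~90,000 fine-tuning iterations on a pretrained 101-layer backbone. The
desk-scale experiments train a ~43k-parameter network from random
initialization for 1250 iterations, where that schedule barely moves the
weights; they therefore override to lr0 3e-3 with factor 0.3 every 4
epochs, chosen once in a pilot sweep on validation loss. Training aborts
with a batch diagnostic on a non-finite loss, and identical seeds reproduce
identical runs.

## The NCC baseline

The comparator detects the tip by zero-normalized cross-correlation between
the image and an idealized in-focus template (rendered over a plain
background), with the peak refined by a three-point parabola per axis and a
detection threshold (default 0.5) on the peak score. Zero-normalization
(mean-subtracted in both window and template) is used because it is
invariant to illumination offsets — the standard choice in microscopy;
constant windows are defined as score 0. The baseline estimates xy only:
template matching carries no depth cue, so z comparisons are CNN-only. Its
characteristic failure, reproduced on the synthetic benchmark, is at
defocus over textured backgrounds: the sharp template no longer matches the
blurred tip, and granular texture offers false peaks that still score high.

## The correction loop

`correct_iteratively()` runs the closed loop: render the scene at the true
position, estimate, command `gain * m` (gain 1.0 = full correction of the
measured error; the gain is exposed but the reference controller is plain
proportional), and repeat — by default twice, after which the error
distribution plateaus. The simulated manipulator quantizes commands to the
encoder step (0.1 µm, round half to even), then adds a systematic offset
and per-move Gaussian noise. Two regimes matter: long moves (e.g. returning
from a cleaning bath) with offset ~2 µm and noise ~3 µm per axis — the
error source the method exists to correct, used as the *initial* placement
error — and short corrective moves, which on a well-calibrated stage are
encoder-limited (`encoder_limited_manipulator()`: no offset, 0.1 µm noise).
The published two-iteration floor of ~0.6 µm, with visible encoder
discretization, is only attainable in the second regime; modelling
corrective moves with multi-µm noise would contradict the observed floor.

With estimator noise SD `σ_c` and move noise SD `σ_m` per axis, the
steady-state per-axis true-error SD across trials is `sqrt(σ_c² + σ_m²)`
(tested at 10^4 trials). For the convergence-shape experiments the oracle
estimator supports a state-dependent noise term (SD grows by a fraction of
the distance from the origin, default experiments use 0.4 µm + 0.05/µm):
an image-based estimator is least accurate far off-centre and defocused,
which is exactly why the first iteration lands short of the floor and the
second reaches it — the two-iteration plateau. `convergence_summary()`
reports per-iteration quartiles, the fractions within 2.5 µm (xy; half a
typical cell) and 3 µm (z), and the fractions within one and two SD radii,
where the radius is the pooled per-axis SD (for isotropic Gaussian xy
errors these approach the Rayleigh values 1 - e^{-1/2} ≈ 0.39 and
1 - e^{-2} ≈ 0.86).

## Statistics

`fisher_exact_2x2()` computes the two-sided exact p by summing
hypergeometric point probabilities no larger than the observed one (relative
tolerance 1 + 1e-7, the mainstream convention); it is tested against
exhaustive enumeration for every table with N ≤ 40. `one_way_anova()` and
`tukey_hsd()` wrap the standard `aov()`/`TukeyHSD()` decompositions, with
the degenerate all-identical case reported as F = 0. `dagostino_k2()`
implements the skew + kurtosis χ² normality test (D'Agostino's skewness
transformation, Anscombe-Glynn kurtosis, K² = Z₁² + Z₂² on 2 df), refuses
n < 20, and holds its nominal type-I error within [0.03, 0.07] at α = 0.05
in simulation. `success_rate_report()` reports integer percentages
(half-away-from-zero by default; truncation exposed because one published
rate, 37 from 12/32 = 37.5%, is only reproduced by truncation) and relative
improvements computed from exact count fractions — the count route, not the
rounded-percentage route, reproduces the published 52/54/70 improvement
triplet.

## Desk-scale study conditions

The CPU experiments use, chosen once: the 256 x 320 desk camera; xy
placement ±9 µm (the full ±27 µm box does not fit the cropped 29 x 23 µm
desk field of view) and z ±6 µm as specified; mixed plain/slice sets (500
training positions -> 2000 images after flips, 100 validation, 200 test);
slice texture SD 0.15 with 5 µm correlation; pipette contrast 0.4; defocus
1.0 px/µm with asymmetry 0.3; 64 px network input; 10 epochs. The
held-out localization criterion is the mean xy error in the network's
native (preprocessed-frame) pixels, the frame its output contract is
defined in.

## What the synthetic benchmark does and does not show

Passing tests on this generator demonstrate that the implementation is
internally correct (geometry, preprocessing, optimization, the loop) and
that the *relative* claim — a trained CNN is robust where template matching
fails, and closed-loop correction converges in two iterations when
estimator errors are small — holds under a plausible image model. They do
not certify accuracy on real DIC images: real tissue texture is not
Gaussian, real defocus is not a Gaussian kernel, annotation error is absent
here, and the desk network is orders of magnitude smaller than a production
backbone. The published real-rig error magnitudes (sub-µm localization) are
therefore not targets of the desk experiments.

## Numerical choices and degenerate inputs

Contrast stretch of a constant image returns uniform 0.5. NCC windows with
zero variance score 0; the sub-pixel parabola is skipped at surface borders
and clamped to ±0.5 px, with ties broken toward the smallest (col, row).
Fisher tables with a zero margin return p = 1. The encoder quantization
uses round-half-to-even. Flip augmentation requires square inputs. Off-crop
and off-frame annotations are flagged rather than dropped or clamped, so
downstream counts remain honest. Manifest z is carried in µm everywhere; a
pixel-equivalent z column can be derived at the manifest layer
(`z_px = z_um / um_per_px_x`) but the package never stores z in pixels
internally, avoiding silent unit bugs.

## Configuration and orchestration

The `cmd_*` pipeline functions are thin, seeded compositions of the module
operations; every run writes a reproducibility block (config echo, seed,
versions). Configuration files are YAML (`read_run_config()`), with file
values merged over `default_run_config()`. A command-line wrapper,
`exec/pipettefix`, exposes `simulate`, `train`, `evaluate`, `correct`,
`compare`, and `reference-numbers` subcommands over the same functions.
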