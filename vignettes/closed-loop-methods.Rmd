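---
title: "Closed-loop shaping of retinal activation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop shaping of retinal activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Epiretinal prostheses evoke visual percepts by passing current through
disk electrodes placed on the retinal ganglion cell (RGC) side of the
retina. A focal, round patch of RGC activity over the stimulating
electrode maps to a compact phosphene; elongated activity — usually from
inadvertent capture of axon bundles passing over the electrode — and
oversized activity that spills onto neighboring electrode territories
both degrade the percept. Which pulse settings produce focal activity
varies strongly from retinal region to retinal region, so the settings
must be searched per electrode, and each trial is expensive (it occupies
preparation time in vitro, or patient attention in a fitting session).

`focalstim` implements a closed-loop search over two pulse parameters —
cathodic amplitude `a` and pulse "type" `t`, the ordinal index of the
anodic/cathodic duration ratio in {1, 2, 5, 10, 20} — that minimizes

    f(a, t) = |A(a, t) - C| + E(a, t)

where `A` is the activation area and `E` the eccentricity of the
best-fit ellipse to the supra-threshold calcium activity, both estimated
by per-region feedforward nets, and `C` is the electrode area. Area and
`C` are normalized by the region's maximum observed activation area, so
`f = 0` is a perfectly round response exactly the size of the electrode.

## Stimuli

All stimuli are charge-balanced biphasic anodic-first pulse trains
(120 Hz, 5 s), cathodic phase fixed at 100 us, interphase gap 5 us
(carried as metadata; it affects no computation here). Charge balance
forces `anodic amplitude = a / ratio` and `anodic width = ratio x
100 us`; the stimulator resolves 1 uA, so `a` must be divisible by the
ratio. The default experimental grid spans 20-110 uA in 10 uA steps for
ratios 1, 2, 5 and 10 (10 amplitudes each) and the six multiples of
20 uA up to 120 uA for ratio 20 — 46 combinations. The exact ratio-20
amplitude set is a reconstruction: the divisibility rule pins "multiples
of 20", and taking them from the window extended one step above the main
grid reproduces the canonical count of six.

## Imaging model

A recording is 5 s of pre-stimulus and 5 s of during-stimulus frames at
10 frames/s. The baseline (stimulation) image is the mean over frames
2-3 s after recording (stimulus) onset — frame indices `[20, 30)` of
each epoch, a half-open window. `dff = (stim - baseline) / baseline`
pixelwise; pixels with non-positive baseline are masked with a warning
count. The activity mask is `dff > 0.15`, strictly: 15% sits well above
the fluorescence noise floor (see noise calibration below).

The response shape is the second-central-moment (equivalent) ellipse of
the active pixel set, treated as one point set — no connected-component
selection, since one ellipse is fitted per image. Semi-axes are
`2 * sqrt(eigenvalue)` of the pixel covariance with the 1/12
single-pixel spread added, which keeps one-pixel and collinear masks
finite; a moment fit was chosen over contour least squares because it is
deterministic, closed-form, and natural for filled regions. Area is
`pi * semi_major * semi_minor * pixel_size^2`; eccentricity
`sqrt(1 - (minor/major)^2)`, identical to focal distance over major-axis
length. An empty mask reports area 0 and eccentricity 0 as sentinels;
classification keys off the active-pixel count, not these values.

## Response classes

Five classes: 0 no meaningful activity, 1 round & small, 2 elongated &
small, 3 round & large, 4 elongated & large. "Large" means the fitted
area reaches twice the electrode area — the scale at which activity
overlaps the neighboring electrode at a 500 um pitch; "elongated" means
eccentricity reaches 0.5, the midpoint of its range. Equality goes to
the large/elongated side (the verbal rules use strict inequalities both
ways and never cover equality; a convention had to be fixed, and it is
tested at the exact boundary). Masks with fewer than 5 active pixels are
class 0: sparse one-or-two-cell images support an ellipse fit yet carry
no meaningful spatial response, so they are floored away rather than
classified by their (unstable) descriptors.

## The synthetic retina

The simulator replaces the in vitro preparation so the whole loop is
runnable and testable without recordings. Each region carries latent
surfaces over the amplitude x type box:

* **Area**: zero below a per-type activation threshold; at threshold it
  jumps to the region's threshold-response size `A_min` (10,000-15,000
  um^2 — a cluster of somata over the electrode, since a threshold
  response recruits cells, not arbitrarily small patches) and then
  saturates as `A_min + (A_max - A_min)(1 - exp(-(a - th)/tau))` with
  `A_max` 100,000-130,000 um^2 and `tau` 24-32 uA. These proportions
  put the desirable small-response band (area below twice the electrode
  area) at roughly 20 uA of amplitude, slightly above threshold — a
  narrow dynamic range in which the optimum hugs the threshold, with
  large responses dominating the upper half of the window.
* **Thresholds**: a region base threshold (25-55 uA) plus a systematic
  per-type slope (0-2 uA per type index) and a small residual jitter
  (+-2 uA). The slope is systematic rather than random because the
  duration ratio changes pulse efficacy in a consistent direction; this
  also means a handful of trials carries threshold information across
  types.
* **Eccentricity**: a near-threshold value of 0.50-0.90 at type 1,
  falling 0.02-0.12 per type index toward a region-specific roundest
  type (3, 4, or 5), rising again beyond it, and increasing
  0.0005-0.003 per uA above threshold (axonal recruitment at high
  amplitude). Which type is most focal varies by region — responses do
  not follow one clean type trend — and roundness, not smallness, is
  the scarce resource: many regions are elongated everywhere and top
  out at class 2, while the rest reach class 1 at only a few grid
  points.

Rendering draws a solid ellipse with the latent area and eccentricity,
centered near the electrode (jitter SD 20 um) and oriented along the
region's axon direction, as a fractional fluorescence gain of 0.6 over a
static baseline (level 100 counts, 3% multiplicative pattern), with
additive per-frame noise of SD 8 counts and a 0.3 s calcium onset time
constant. For small eccentricity this footprint is a round soma blob;
as eccentricity grows it elongates into an axonal streak. The default
field is 192 x 192 pixels at 4 um/pixel (768 um — the 500 um-pitch
neighborhood of the electrode); none of these imaging constants is
claimed from data, and all are configurable.

Noise calibration: averaging 10 frames per window gives a per-pixel
delta-F/F noise SD of about `sqrt(2) * 8 / (sqrt(10) * 100) = 0.036`,
so the 0.15 threshold sits at 4.2 SDs and rejects a baseline pixel with
probability about 1 - 1.3e-5 — comfortably above 99% of pixels, which
is the threshold's stated purpose. A stray supra-threshold pixel per
image remains possible; the 5-pixel class-0 floor absorbs it.

What the simulator does **not** emulate: biophysical membrane dynamics,
heterogeneous degeneration, multi-electrode interactions, indicator
bleaching, motion, or non-elliptical activity footprints. Tests passing
on this generator show the pipeline recovers what the generative family
produces; they do not certify performance on real tissue.

`render_activity_images()` draws the two averaged-window images directly
(noise scaled by `1/sqrt(10)`, matching the distribution of a 10-frame
mean); the closed loop and the ensemble evaluation use this path, while
the frame-stack renderer backs the TIFF round-trip and timing tests.

## Surrogates and the objective

Both nets take min-max-scaled `(a, t)` and have one hidden layer of 10
hyperbolic-tangent units with a linear output (41 weights). They are
fitted with Levenberg-Marquardt least squares. Trials with fewer than 5
active pixels are excluded before fitting; at least 3 responsive trials
are required. Rows split into training / validation / test at 60-80% /
10-20% / 10-20% depending on the table size (a 5-point table keeps 3
rows for training and one each for validation and test). Two seeded
initializations are fitted and the validation split picks the winner —
with 41 parameters on as few as 3-32 rows, the fit is kept well-posed by
an L2 penalty of 3e-3 on non-bias weights. That value matters: much
weaker decay leaves high-frequency tanh ripples between the five
discrete type values and between amplitude samples, which litter the
objective surface with spurious local minima that trap the single-start
search; 3e-3 suppresses the ripples while leaving the held-out MSE of a
noiseless 46-point fit near 1e-3, far below the 0.05 recovery contract.
Eccentricity predictions are clamped to [0, 1] (its physical range),
which also keeps the objective surface nonnegative; the area net is not
clamped because `|A - C|` is nonnegative regardless.

`C` defaults to the electrode area divided by the region's maximum
observed activation area and is recomputed each iteration as the
observed maximum grows. Nets are retrained from scratch each iteration;
warm-starting across iterations is a plausible variant but the loop is
specified over fresh fits.

## Interior-point search

The minimizer works in box-scaled coordinates on [0, 1]^2 with a
logarithmic barrier, `phi_mu(x) = f(x) - mu * sum(log(x - lo) +
log(hi - x))`, solving a quasi-Newton line-search subproblem per barrier
weight `mu` in 1e-2, 1e-3, ..., 1e-9 from the previous solution.
Candidates that do not improve the true objective are rejected, so the
accepted-iterate record is non-increasing. Termination: the last step
falls below the 1e-4 step tolerance (Euclidean, scaled coordinates) —
but only once `mu <= 1e-5`, so the barrier bias cannot freeze the search
early (larger starting values of `mu` were also examined and degrade the
corner-start search). Gradients of the tanh nets are analytic; the
absolute value contributes `sign(A - C) * dA` and the eccentricity clamp
zeroes its gradient where active. The start is the minimum corner of the
box (lowest amplitude, type 1), nudged 1e-3 inside so the barrier is
finite; the iteration cap is 500. A single start is deliberate — it is
how such a search runs against live tissue, where extra starts cost
trials — and it accepts local minima; the ensemble evaluation
measures how often the single-start solution is near the dense-grid
global minimum rather than assuming it.

The continuous optimum is then rounded to a deliverable setting: type to
the nearest index, amplitude to the nearest integer-uA multiple of the
chosen duration ratio within the window. Rounding can cost objective
value — most visibly for ratio 20, whose 20 uA amplitude granularity can
jump across the narrow near-threshold optimum — and both the continuous
and the deliverable objective values are logged.

## Classifier

The rule labeler is the class definition itself and is the loop's
default classifier. The CNN reproduces the image-based protocol:
conv-ReLU-maxpool blocks, a dense block, softmax output, categorical
cross-entropy, Adam at learning rate 0.001, 20% dropout, L2 7e-4, batch
32, 25 epochs, 90-10 train-test then 90-10 train-validation splits.
`cnn_config()` defaults encode the full-scale architecture (three conv
layers of 128 3x3 kernels; four fully connected layers, three of 128
units plus the 5-class output). That width costs on the order of 1e13
FLOPs to train at desk scale, so the package's own tests and acceptance
run use `cnn_config_desk()`: 48 x 48 inputs (the central 576 um of the
delta-F/F map at 12 um cells — cropping preserves resolution where the
class-boundary-sized footprints live), conv widths 16/32/32 and dense
64/64. The network is implemented directly on BLAS matrix products
(im2col gathers, max-pool routing by argmax, inverted dropout, Adam) and
its gradients are verified against finite differences in the test suite.

The training corpus is generated by the simulator and labeled by the
rules at full resolution. Images whose descriptors fall within a margin
of a class boundary (eccentricity within 0.10 of 0.5, or area within 20%
of twice the electrode area) are excluded: a response a hair either side
of a boundary belongs to different rule classes while being visually
indistinguishable, so such images carry no learnable signal — this
operationalizes restricting the corpus to visually distinguishable
categories, the same reason the original labeling was curated by hand.
Set both margins to 0 for a raw rule-labeled corpus. Augmentation
(orthogonal rotations, flips, Gaussian and salt-and-pepper noise,
applied to classes 1-3 by default) is available for unbalanced corpora;
the default corpus is balanced by construction.

## The closed loop and its evaluation

Each iteration samples amplitudes without replacement per pulse type
(1, 2, 3, 4 per type — 5, 10, 15, 20 trials — then the full 46-point
grid), renders and quantifies the responses, fits the surrogate pair,
minimizes the objective, delivers the rounded optimum, and classifies
its response. The loop stops when the delivered response reaches the
target class (default 1); otherwise it reports the best-classed
delivered stimulus at schedule end. Samples are drawn fresh each
iteration — information from earlier iterations is deliberately not
reused by the sampler, only by the stopping rule; a cumulative mode is
a natural extension but is not the default. Samples come
from the grid window so every sample is deliverable.

`evaluate_ensemble()` runs the loop across synthetic regions and
repeats, against a random-sampling control that draws k of the 46 grid
stimuli uniformly without replacement (nested draws: the k-trial control
is a prefix of the 20-trial one, so its per-run success indicator is
cumulative). Every response in the loop is classified — the randomly
sampled training trials and the delivered optimum alike — so the loop
has found the best class at trial count k when any response observed by
that iteration is at least as desirable as the grid best (order
1 > 2 > 3 > 4 > 0; delivery runs on the finer integer-uA set, so it can
even beat the coarse grid). The loop's edge over the control is its
guided deliveries; `method_delivered_curve` isolates them by counting
delivered optima only. Achievement is scored on the noiseless latent
class of the chosen stimuli for both arms: the loop still trains on
noisy rendered responses, but latent scoring separates search
performance from imaging-noise misclassification and lets the control
be compared exactly with its hypergeometric closed form,
`1 - choose(46 - m, k) / choose(46, k)` for `m` best-class grid points.

The default evaluation sizes — 24 regions, 20 repeats, the 5/10/15/20
trial counts — are the package's standard experiment; the same code
scales to larger ensembles.

## Numerical and degenerate-input choices

* Sub-seeds for sampling/training/rendering streams derive from one
  master seed by integer mixing mod 2^31 - 1; every randomized function
  takes an explicit seed and runs on a private RNG stream, so run logs
  are byte-reproducible from their seed triple.
* All-class-0 iterations raise a typed insufficient-data condition; the
  loop records the iteration and enlarges the sample rather than
  aborting. A region whose threshold exceeds the window completes with
  achieved class 0 and no surrogate ever trained.
* Levenberg-Marquardt runs are capped at 100 iterations; reaching the
  cap with a tiny residual is routine and not surfaced as a warning.
* TIFF export stores 16-bit pages with a scale factor in the JSON
  sidecar; intensities survive the round trip to about 1 part in 6e4.

## Known limitations

* The generative family is an engineering surrogate for retinal
  activity, not a biophysical claim; its parameter ranges were chosen to
  reproduce the qualitative regime reported for in vitro preparations
  (narrow dynamic range slightly above threshold; small responses below,
  large responses above; region-dependent focality with class 1 or 2
  attainable everywhere) and all of them are exposed in `region_hyper()`.
* Ratio-20 delivery granularity (20 uA) can round the optimizer's
  solution below threshold when a region's optimum hugs the threshold;
  this is a faithful property of the stimulator constraint, visible in
  the run logs as a delivered class 0 following a good continuous
  optimum.
* The CNN's recall ceiling is set by corpus resolution: descriptor
  differences smaller than one downsampled cell are invisible at 48 px
  input, which is why boundary-margin images are excluded from training.
* A single global model across regions is deliberately out of scope —
  per-region fits are the point of the loop; so are uncertainty-aware
  surrogates (e.g., Gaussian processes), frequency/pulse-width sweeps,
  and hardware control.
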