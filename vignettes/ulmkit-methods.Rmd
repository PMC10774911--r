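---
title: "Models and methods in ulmkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ulmkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ulmkit implements an ultrasound localization microscopy (ULM) analysis
chain for contrast-enhanced ultrasound (CEUS) image sequences: synthetic
scene generation, microbubble localization by blind deconvolution and by
two residual-learning networks, Kalman tracking with overlapping-trace
correction, and micro/macro-vessel metrology. This vignette documents the
underlying models, the tunable parameters and their defaults, the numerical
choices, and what the synthetic benchmark does and does not establish about
real data.

## The image formation model

A CEUS frame is modeled as point scatterers blurred by a spatially varying
point spread function with additive background noise,

$$y = k \otimes x + n,$$

where $x$ lives on a fine "synthesis" grid (6 µm, one tenth of the 60 µm
native pixel, comparable to the physical microbubble diameter), $k$ is the
local PSF with unit peak, and intensities are clipped to $[0, 1]$. The
default geometry mirrors a 5.5 MHz pediatric transducer: wavelength
$\lambda = 280$ µm, native pixel 60 µm ($\lambda/4.6$), 48 frames/s,
80 × 80-pixel interrogation windows (4.8 × 4.8 mm²) inside which the PSF is
treated as constant. Localizers report centers on a 3× super-resolution
grid (20 µm = $\lambda/14$).

Coordinates are continuous, in µm from the top-left corner; axis 1 is depth,
axis 2 lateral. Pixel $i$ covers the half-open interval
$[(i-1)\Delta, i\Delta)$ with center $(i-\tfrac12)\Delta$. A center lying
exactly on a pixel boundary therefore belongs to the pixel on its
high-coordinate side, deterministically.

### PSF family

Clinical scanners do not expose their beamforming, so the shipped PSFs are
parametric stand-ins: rotated anisotropic Gaussians specified by their
full widths at half maximum (FWHM), optionally with a one-sided
depth-direction tail (`family = "gaussian_with_tails"`). Derived measures
are the FWHM area $S$, aspect ratio $AR \ge 1$, and $L_p(\theta)$, the
half-maximum chord length along direction $\theta$, which is the quantity
controlling the separability of structures across a vessel. The evaluation
ladder fixes five increasingly elongated shapes — FWHM major
{263, 320, 400, 500, 561} µm with $AR$ {1.20, 1.35, 1.50, 1.65, 1.81} —
bracketing the $L_p$ range over which trace elongation degrades
localization; the training pool (`training_psf_pool()`) uses different base
shapes so that evaluation PSFs are never trained on. Because these
parametric kernels are much smoother than experimentally estimated ones,
their bicubic up/down-resampling error `psf_resampling_error()` is far
below 1%; with empirical kernels this round trip is the dominant
discretization error and should be checked per dataset.

### Background noise

Speckle-like background is modeled as i.i.d. exponential draws per native
pixel, blurred by a Gaussian of $\sigma = 1$ pixel and rescaled so the field
maximum equals the prescribed peak level exactly (common peaks: 0.10, 0.15,
0.20, 0.25 for training; 0, 0.08, 0.16, 0.24 for evaluation, with 0.16 the
typical clinical level). The exponential-then-blur construction reproduces
the monotonically decaying intensity histogram of sampled CEUS backgrounds;
it does not attempt to reproduce any scanner's exact noise spectrum.

### Motion scenarios

Two scenario generators create the ground truth used by the vessel-level
metrology:

* **Parallel lines** (`simulate_lines()`): bubbles arrive on two lines
  separated by $D_l \in \{18, ..., 360\}$ µm by independent Poisson
  processes (default rate 1/40 per line per frame — a stand-in for measured
  arrival histories, chosen to give a realistic per-frame bubble count) and
  advect at 5 mm/s, a typical microvascular speed (104.2 µm per frame at
  48 fps).
* **Tubular vessel** (`simulate_vessel()`): bubbles keep a radial
  coordinate drawn uniformly over the lumen and move along the axis at the
  parabolic speed $U(r) = U_{max}(1 - (r/R)^2)$ with $U_{max} = 5$ cm/s;
  the population is replenished at the inlet to keep the mean along-axis
  spacing near 330 µm. Bubble peak intensity is drawn once per bubble
  (uniform 0.6–1) and kept constant along its path.

## Blind deconvolution

The conventional baseline minimizes, per interrogation window,

$$\|x \otimes k - y\|_2^2 + \gamma\|k\|_2^2 + \alpha_1\|x\|_0
  + \alpha_2\|\nabla x\|_0,$$

with $\gamma = 2$ and $\alpha_1 = \alpha_2 = 4\times10^{-3}$, alternating a
scatter-map step and a kernel step.

* **Scatter step.** The $L_0$ terms are handled by half-quadratic splitting
  with hard thresholding: auxiliary variables for $x$ and $\nabla x$ are
  hard-thresholded (and clamped nonnegative), then $x$ is updated by a
  Fourier-domain ridge solve on a replicate-padded domain. The splitting
  weight is held fixed at $\beta = \alpha_1/f^2$ with the support floor
  $f = 0.01$: because the ridge step conserves the trace integral, a
  bubble of intensity 0.6–1 becomes a compact blob with per-pixel
  amplitudes of order 0.05–0.1, and an annealed threshold schedule would
  cull dim bubbles before the data term can anchor them. The solver output
  is consequently a sparse field of compact, fairly uniform blobs — the
  documented visual character of blind-deconvolution ULM output — rather
  than isolated unit spikes.
* **Kernel step.** Given scatter maps, the kernel solve is closed-form in
  the Fourier domain with the $\gamma$ ridge, followed by projection onto a
  centered nonnegative unit-peak patch (default 31 × 31 native pixels).
  The kernel is initialized from the data — the average of
  background-subtracted patches around the brightest trace of each frame —
  falling back to a centered Gaussian disk of FWHM 4 pixels for degenerate
  stacks; a blob-width shrinkage bias is inherent to the alternation (the
  scatter maps are compact blobs, not ideal deltas, so the fitted kernel
  is the true kernel "deconvolved" by the blob width) and is why
  evaluation studies deconvolve with their known generating kernels. An
  accept-if-improved guard keeps the joint objective non-increasing across
  outer iterations even though the projection is not exactly the proximal
  step.
* **Center extraction.** Scatter maps are bicubically interpolated to the
  $\lambda/14$ grid, thresholded, segmented by intensity watershed (with
  merge tolerance equal to the threshold, so that maxima whose prominence
  is below the background level do not split a trace), and reduced to
  intensity-weighted centroids. Deconvolution enhances some noise into
  blob-like clusters, and two defenses remove them. The amplitude
  threshold is derived from the stack itself as the mode plus three median
  absolute deviations of the pooled component peak histogram (noise
  components dominate that histogram by count), capped at 0.4 × the
  median per-map maximum so a clean stack cannot threshold away its own
  signal. Independently, components with integrated mass below 0.1 native
  intensity units are dropped: deconvolution conserves the trace integral,
  so a real bubble (intensity ≥ 0.6) leaves a component of mass near its
  intensity even when partially cropped, while measured enhanced-noise
  masses stay below ~0.05 at the 0.16 noise peak.

Bicubic interpolation throughout the package is Keys cubic convolution
($a = -0.5$) with pixel-center alignment and replicated edges, implemented
as precomputed interpolation matrices.

## The supervised localizer

`build_supbd()` maps an 80 × 80 native window to a 240 × 240
center-likelihood map: two convolution blocks (convolution + instance
normalization + leaky rectifier, slope 0.2), four residual blocks, a global
residual addition, a stride-3 transposed convolution (implemented as
zero-stuffing onto cell centers followed by a 3 × 3 convolution — with
stride 3 every output pixel is within one pixel of a stuffed sample, so
3 × 3 taps cover the plane exactly), and a final convolution squashed by a
sigmoid. Kernels are 9 × 9 for the first and last convolutions and 3 × 3
elsewhere; instance (rather than batch) normalization removes
frame-specific intensity and noise statistics. The full-scale
configuration uses 64 feature channels.

The training references are blurred center maps: super-resolution pixels
containing true centers set to 1, blurred by a fixed 5 × 5 Gaussian
($\sigma = 1$ super-resolution pixel), rescaled so an isolated blob peaks
at 1. Training pairs span concentrations 0.1–1.0 mm⁻² (Poisson counts,
uniform placement), intensities 0.6–1, PSF rotations ±20°, resize factors
0.8–2, and the four training noise peaks with 0.15 most frequent.

Training follows Adam with minibatch 16, initial rate $10^{-3}$ reduced
×0.1 every 5 epochs, a 70/30 train/validation split reshuffled every epoch,
early stopping after 5 epochs without validation improvement, and
best-of-last-five checkpoint selection.

**Scaled-down configuration.** The engine is a compact
single-threaded im2col/BLAS implementation, so full-scale training
(250,000 pairs) is supported in configuration but not what the test suite
runs. The in-suite study trains 10 channels on ~1,600 pairs of 16-pixel
windows for ≤10 epochs. At that sample count the plain pixelwise MSE
barely escapes the all-zero prediction (reference maps are ~99% zeros), so
scaled-down trainings weight the squared error by $1 + w\,\mathrm{ref}$
with $w = 20$ (`peak_weight`), which reweights the foreground/background
imbalance without changing the optimum of the full-scale loss; the
full-scale default remains the plain MSE. Centers are extracted from the
likelihood maps as intensity-weighted centroids of 8-connected clusters
above 0.5.

## The self-supervised pair

For data whose PSF differs from anything trained on, a second network
(k-net: same backbone with 3 residual blocks, 7 × 7 kernels, no upscaling,
no squashing) estimates the kernel directly from raw frames. Its input is a
fixed Gaussian disk ($\sigma = 5$ native pixels, unit peak) on an odd
kernel grid (window + 1 pixels); the net's output is added to the disk,
clamped nonnegative and renormalized to unit peak, so an untrained k-net
starts exactly at the disk and "deforms" it.

The losses use only raw frames. With $\tilde x$ the (super-resolution)
center map and $\tilde k$ the kernel estimate,

$$\mathcal L_y = \alpha_1\|r\|_2^2 + \alpha_2\|\nabla r\|_2^2
  + \alpha_3\|H r\|_2^2, \qquad
  r = D(\tilde x \otimes U \tilde k) - y,$$

with $U$/$D$ the bicubic up/down-sampling operators, central differences
for $\nabla$ and all four terms of the finite-difference Hessian (the mixed
term appears twice), and weights $\alpha_{1,2,3} = 1, 5, 25$ chosen so the
three channels have comparable magnitude; the gradient and Hessian channels
carry a higher signal-to-noise ratio than raw intensity
(`snr_channels()` measures this). The sparsity prior on $\tilde x$ uses the
$\tanh$ surrogate
$\alpha_4\|\tanh 5\tilde x\|_1 + \alpha_5\|\tanh 5\nabla\tilde x\|_1$
($\alpha_4 = \alpha_5 = 4\times10^{-3}$, forward differences), which counts
bright pixels to within 0.1%; the kernel penalty is $\gamma\|\tilde k\|_2^2$
with $\gamma = 2$. All operators are linear with exact adjoints, so both
nets receive exact gradients.

Adaptation runs in two steps per window. Step 1 freezes the x-net: its maps
on 8 randomly chosen frames (fixed for the whole adaptation) are sparsified
to the brightest super-0.5 peak per cluster, where a cluster is an
8-connected component and components whose peaks fall within 100 µm of a
brighter peak are merged into it. Without the merge, an unfamiliar
elongated PSF is interpreted as several disconnected blobs near the true
center, each surviving per-component selection, and the kernel estimate
shrinks to the blob spacing. The k-net is then trained (Adam,
$10^{-4}$, ×0.1 after 5 stalled iterations) until the kernel RMS change
drops below $10^{-6}$. Step 2 freezes the kernel and refines only the x-net
layers after the global residual addition, with 8 held-out validation
frames, validation every 5 iterations, three ×0.1 rate reductions, and
best-validated parameters returned.

## Tracking and overlap correction

Detections are linked by a constant-velocity Kalman filter with globally
optimal gated assignment per frame (a hand-written $O(n^3)$ Hungarian
solver; no assignment package is used). The assignment includes explicit
unassignment penalties (dummy nodes), so an association is made only when
it beats leaving both ends unmatched. Defaults: gate 150 µm, measurement
noise 15 µm, coast limit 2 frames, minimum reported length 3 samples.

Fast macrovessel flow is a genuinely harder regime: at 5 cm/s and 48 fps a
centerline bubble moves 1042 µm per frame, three times the mean bubble
spacing, so purely positional nearest-neighbor association aliases onto
neighboring bubbles. The tracker is therefore multi-parameter: when
detections carry a `weight` (intensity mass, or the raw-frame amplitude
via `annotate_intensity()` for the intensity-blind network maps), the
association cost adds `weight_gain` × the weight mismatch — bubble
intensity persists along a track — and at track birth, where any candidate
inside the wide gate is kinematically possible, the weight term dominates
with distance only tie-breaking. Once a track has two samples its velocity
is locked and a tight `gate_locked` applies; a single-sample track that
fails to re-acquire immediately is discarded as spurious. Downstream,
speed samples are only taken from consecutive-frame differences,
per-sample velocity kinks beyond `accel_max` are rejected
(straight-vessel flow is steady), and tracks failing a constant-velocity
straightness residual bound can be filtered
(`filter_straight_tracks()`). On synthetic parabolic vessels with exact
detections, these rules keep track impurity below ~3% and the measured
velocity profile within a few percent of the prescribed parabola
everywhere except the outermost near-wall bins, where the relative error
is dominated by the vanishing reference velocity.

When two traces merge for one frame, the merged detection is typically won
by the faster track and the slower track dies — biasing near-wall
velocities high. `correct_overlaps()` detects the signature (a detection
that is one track's sample while lying within the gate of another track
that has no sample of its own that frame), removes the merged sample from
both, and re-acquires each track one frame later; re-acquired tracks get
the skipped position filled by per-coordinate piecewise-cubic interpolation
in time (exact for linear motion), while tracks with no candidate are
terminated before the event. "Bicubic" interpolation of a trajectory is
interpreted as 1-D-in-time cubic interpolation per coordinate; a 2-D image
interpolant does not apply to a time series.

## Vessel metrology

Track heatmaps count distinct track traversals per super-resolution pixel.
Cross-sectional profiles (averaged along the line axis) are fitted by sums
of Gaussians, one component per local maximum of the profile smoothed with
$\sigma = 1$ super-resolution pixel; the line location error $E_l$ is the
distance from each fitted peak to the nearest true line and the line width
$\epsilon_l$ is twice the fitted standard deviation. Where two vessels'
traces overlap, a spurious "ghost" line can appear between them; each
fitted component gets an area fraction $AF$ (percent of total fitted area)
and an index of detection $ID$ (profile peak over the linewise standard
deviation at that position, normalized to 0–100), and the shipped decision
rule

$$0.10\,AF + 0.038\,ID - 4.64 < 0$$

declares a ghost negligible (a score of exactly zero is nonnegligible).
Both features enter on 0–100 scales — the only reading under which the
printed coefficients are dimensionally sensible — and
`fit_ghost_boundary()` refits the maximum-margin boundary for data on any
other scale. Separation outcomes are graded five ways: unseparated (single
peak, or a trough above 95% of the primary peak, "primary" being the lower
of the two main peaks), overlapped, non-negligible ghost, negligible ghost
(interior components judged by the rule above), and fully separated
(trough below 5% of the primary — the drawn-but-undefined floor, fixed
here at 5%).

Velocity profiles bin per-sample track speeds (central differences × frame
rate) by signed radial coordinate (bin width 20 µm) and compare with
$U_{ref}$; the relative error is $E_u(r) = |(U_m - U_{ref})/U_{ref}|$, with
the first-order proxy $|dU_{ref}/dr \cdot E_c / U_{ref}|$ available for
attribution. The per-bin estimator is the median (the mean is available
via `stat = "mean"`): with desk-scale tracking a small fraction of
mis-associated samples survives every filter, and the median is robust to
them while agreeing with the mean when tracking is clean. Vessel inlet
seeding is flux-weighted ($p(r) \propto U_{ref}(r)$), the steady state of
a spatially uniform bubble concentration; uniform-in-$r$ seeding would
pile bubbles into the slow near-wall lanes and is also what would break
the parabolic track-count profile that the radius estimators rely on. The vessel radius is the zero crossing of a least-squares
parabola fitted to the velocity profile or to the track-count profile
(linear model in $r^2$, refusing concave-up fits); Gaussian fits to track
counts are provided for comparison only, since the prescribed radius
corresponds to an inconsistent multiple of the fitted width across vessel
sizes. Scaling of the normalized line errors with $L_p/D_l$ is summarized
by `power_law_fit()` in log–log space.

## Numerical and policy choices

* Convolutions are FFT-based on replicate- or zero-padded domains sized to
  preclude wraparound; kernel grids are odd so the center pixel is exact.
* The Hungarian solver breaks cost ties deterministically by scan order;
  sparsification ties take the row-major first peak.
* Tracking gates use predicted positions; the first frame of a track uses
  its detection position with zero velocity prior.
* `localization_error()` matches detections to truth by nearest-truth
  ownership for $E_c$ (so falsely split pairs contribute every detection)
  and by optimal one-to-one assignment within a gate (default: half the
  PSF minor FWHM) for the false-detection percentage $\eta$, with
  detections as the denominator.
* Seeds: every generator and trainer takes an explicit seed; fixed seeds
  reproduce outputs bit-exactly on one platform.

## Problem sizes used by the shipped studies

The test suite and the acceptance script run desk-scale versions of the
benchmark: 500 two-bubble trials for the separation study and 200
80 × 80 frames for the localization study (both with the blind
deconvolution path), a ~1,600-pair/10-epoch supervised training on
16-pixel windows with 10 feature channels, k-net adaptations on 40-pixel
windows, and vessel runs of a few hundred time steps. These sizes were
chosen so each study stays in the minutes range on one CPU core while
keeping the statistical resolution needed by the assertions (binomial
confidence at the 5% level for separation fractions; ±2 µm standard error
on $E_c$).

## Known limitations of the scaled-down networks

The shipped checkpoint (8 channels, ~4,000 pairs, ~1 h of training)
reproduces the supervised localizer's qualitative behavior — sub-pixel
accuracy on typical cells, clear superiority over blind deconvolution —
but not every full-scale number. Specifically: noise-free frames are
outside the training noise range (0.10–0.25), so instance normalization
meets unfamiliar statistics there and dim bubbles can be missed on the
largest PSFs; separating pairs below ~0.8 FWHM reliably is exactly the
regime that demands full-scale capacity and data; and the self-supervised
refinement converges to intensity-valued (rather than unit-peak) maps, so
its outputs are not compatible with the fixed 0.5 peak-detection rule —
kernel recovery reaches correlations of about 0.98 against the true
rotated PSFs, limited by the anchor quality of the scaled-down x-net.
`scripts/train_supbd.R` reproduces the checkpoint; scaling `channels`,
`n_pairs`, and the window size upward moves all of these toward the
full-scale behavior at proportional cost.

## What the synthetic benchmark does and does not show

The generator reproduces the features that drive ULM difficulty — elongated
spatially varying traces, overlapping bubbles, speckle-like background,
realistic concentrations and speeds — with exact ground truth, which is
precisely what real data cannot provide. It does not emulate scanner
post-processing nonlinearities, tissue motion, attenuation with depth,
curved or branching vessels, radial bubble migration, or non-parabolic
profiles; conclusions about those require real acquisitions. Passing tests
therefore certify the algorithms against the stated forward model, not
against any particular scanner.
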