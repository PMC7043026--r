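---
title: "Smart line scanning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smart line scanning: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Raster-scan two-photon imaging of genetically encoded calcium indicators
(GCaMP6s) spends most of its dwell time on pixels that carry no neuronal
signal: background, neuropil, and dim nuclei. When the field of view grows
to hundreds of neurons, the per-cell photon budget collapses and single
action potentials become undetectable. Smart line scanning (SLS) inverts
the trade-off: a reference raster series is segmented pixel-wise by
signal-to-noise ratio (SNR), only the most informative pixels of each cell
are kept, and the galvanometric mirrors are driven along a closed
trajectory that visits exactly those pixels (plus an adjustable surround
and optional reference patch). The scan rate becomes `1 / (L * dwell)` for
a trajectory of `L` pixels, typically 20--120 Hz for tens to hundreds of
cells at a 4.4 microsecond dwell.

This package implements the full analysis chain — segmentation, trajectory
generation, acquisition simulation, motion-artifact handling, neuropil
decontamination, event detection, and ensemble/NMF analysis — together
with a synthetic-scene simulator that provides ground truth for every
stage.

# The pixel-SNR statistic

For pixel $(i,j)$ over a reference interval, $\mathrm{SNR}_{i,j} =
\max_t F_{i,j}(t) / \mathrm{noise}_{i,j}$, where the noise is the standard
deviation of the pixel's values strictly below its 25th percentile
(linear-interpolation percentile). Where the strict subset is degenerate a
$\le$ fallback is used, and a still-degenerate pixel gets SNR 0 with a
warning. The ROI-level statistic ranks box pixels by descending SNR and
scores the mean trace of the top-$n$ pixels with the same max-over-noise
rule; the curve $A(n)$ rises while informative pixels accrue and falls
once nuclear and neuropil pixels join, and the selection is the top-$n^*$
at its maximum.

Two readings of the printed ROI-SNR rule exist: selecting the top-$n^*$
pixels at the curve's argmax (the default here, consistent with the
reported 48 +/- 32 pixels per cell), or selecting every pixel whose
individual SNR is at least the curve's maximum (`rule = "threshold"`,
which is the literal phrasing but typically selects far fewer pixels).
Both are implemented. The SNR interval defaults to the whole reference
series.

# The synthetic world

`scene_params()` / `make_scene()` define a continuous-time intensity model
$I(x, y, t)$ that any scanner can sample. The defaults are the stated
world of the package's tests; they were calibrated once against the
published regime and are not tuned per test:

* **Geometry.** Donut-shaped somata of nominal extent 11.8 +/- 0.7 um at
  0.77 um/pixel; the fluorescent soma fills 0.7 of that extent
  (`fill_fraction`), consistent with whole-cell areas of ~75 pixels inside
  15-pixel boxes. The nucleus occupies 0.45 of the soma radius, at 0.25 of
  the cytoplasmic brightness, with its calcium response attenuated to 0.2
  (nuclear GCaMP is largely excluded). Log-normal across-cell brightness
  (sdlog 0.35) and within-cell texture (sdlog 0.2) emulate heterogeneous
  staining. Cell masks are disjoint by construction; the ground-truth
  "cytoplasm" mask includes the one-pixel bilinear sampling support of the
  bright ring, because those boundary pixels genuinely record cytoplasmic
  fluorescence.
* **Activity.** Bursty discharge: firing events are Poisson with mean
  `firing_rate / burst_mean` per second, each carrying `1 + Pois(burst_mean
  - 1)` action potentials 10--50 ms apart, preserving the 0.29 Hz mean AP
  rate. Each AP adds a kernel $(1 - e^{-t/\tau_r})e^{-t/\tau_d}$
  peak-normalized to a dF/F of `single_ap_dff` (default 0.2, a free
  simulator parameter — the source preparation's single-AP amplitude is
  not published). Kinetics default to $\tau_r = 0.18$ s, $\tau_d = 1.8$ s,
  standard GCaMP6s values.
* **Neuropil.** A smooth log-normal spatial field (about 25% of typical
  cell brightness) multiplied by a shared temporal signal: low-passed
  population-mean calcium plus an independent slow component with
  fluctuation s.d. ~0.15. This shared flicker is deliberately the dominant
  common-mode noise: it is what makes the ROI-SNR curve peak in the
  interior and what the neuropil-correction stage removes.
* **Noise.** Gaussian with variance `gain * mean + read_var` per sample
  (gain 100 counts/photon, read s.d. 50): a photon-limited but
  approximately Gaussian regime, chosen so the sub-percentile noise rule
  is well behaved (a deeply photon-starved discrete regime makes that
  estimator degenerate).
* **Motion.** Ornstein--Uhlenbeck jitter (0.15 um s.d. by default —
  reference rasters are motion-corrected upstream in the source workflow,
  which is out of scope here) plus Poisson-timed locomotion epochs
  (default 12 s) carrying a >= 3 um step, fast lateral tremor, and
  synchronous aperiodic defocus dimming with a weak 9-Hz stride component.
  The dimming is the load-bearing part: a clean instantaneous step leaves
  an AR(2) one-step prediction almost perfect, and a purely periodic
  distortion is learnable by the globally fitted AR(2), so neither is
  detectable by the windowed-correlation screen; erratic synchronous
  dimming is, and it is also what locomotion artifacts look like in the
  source data (fast synchronous distortions of all trajectory pixels).
* **Stimulus.** Air-puff trials: 4 trains at 0.5 Hz, each of 4 puffs of
  200 ms at duty cycle 0.5 (16 onsets per trial); responsive cells fire
  extra spikes shortly after puff onsets with probability 0.6.

What a green test does *not* establish: the simulator has no optics PSF,
no bleaching or photodamage, no galvanometer inertia, no non-rigid tissue
deformation, and its neuropil is a single shared component rather than a
mixture of many axonal sources. Directional comparisons (SLS vs raster)
transfer to real data only insofar as those omissions are neutral between
the two modalities, which is the design intent.

# Acquisition timing

`acquire_raster()` samples pixel $k$ (row-major) of frame $f$ at
$t = f N_y N_x \delta + k\delta$ for dwell $\delta$; `acquire_sls()`
samples trajectory pixel $k$ of scan $s$ at $t = s L \delta + k\delta$
with no flyback gap (the path is closed; transit pixels are recorded like
any others and later pooled into the global neuropil when they are far
from every cell). Sub-pixel motion is applied by bilinear interpolation.
The noise model does not scale with dwell: a per-sample draw has the same
statistics at every rate, so rate comparisons isolate sampling-density
effects, which is the comparison of interest.

# Trajectory construction

Cells are ordered by a traveling-salesman genetic algorithm over ROI
centroids (population 200, up to 2000 generations with 200-generation
stagnation stop, order crossover plus swap and 2-opt mutations, seeded and
never worse than the input order). The cycle is then rotated so the
longest inter-cell edge becomes the closing junction. Within a cell, ROI
pixels and then surround pixels are chained greedily by nearest neighbor
from the entry point; consecutive cells are joined by 8-connected Bresenham
transit pixels. The surround is a chessboard dilation of width 0--3 with
nearest-cell tie-breaking. Trajectories serialize losslessly to an XML
dialect (one element per pixel: x, y, label, roi) or JSON.

# Compartment assignment and extraction

Recorded trajectory pixels are re-assigned against the reference
segmentation by Euclidean distance d to the nearest ROI: d < 1 is ROI,
2 < d < 4 is that cell's local neuropil, d > 4 from every cell is global
neuropil, and everything else — the boundary gaps at d = 1..2 and d = 4
exactly, and multi-cell conflicts — is skipped, honoring the strict
inequalities literally. Group means per scan give the ROI, local-np and
global-np traces; reference-patch samples are reshaped into a mini-movie
for phase-correlation motion readout (sub-pixel by parabolic peak fit
against the temporal median frame).

# Motion artifacts

Large artifacts: the first right-singular time vector (PC1) of the
per-pixel mean-centered recording is fitted by AR(2) least squares on the
whole series (a per-window refit is available), and the Pearson
correlation between PC1 and its one-step prediction is computed in ~10-s
windows stepped one scan at a time (odd window length, truncated edges).
Correlation below 0.3 flags an artifact and data from the first detection
are marked for discard. Small artifacts: within each sliding window, each
ROI keeps its N highest-SNR pixels among ROI + local surround
(deterministic tie-break by trajectory order); the per-window mean pixel
position, averaged over ROIs and centered, reads out displacement. Note
the readout tracks the *apparent* cell displacement in the image, which is
minus the scene's motion path.

# Neuropil correction

Three strategies, all built on the first SVD component (sign-fixed against
the row-mean): `global` and `local` subtract `alpha` (default 0.7) times
the component of the global-np pixel raster or the per-cell local-np
raster, amplitude-matched to each ROI by least squares so that alpha means
the same thing for every cell (the source procedure subtracts an
unnormalized component; `rescale = "none"` reproduces that);
`weighted_pc1` subtracts each ROI's own projection onto the first
component of the ROI-by-scan raster, with no alpha. The local strategy
requires surround width > 1. Corrected traces are not clipped; clipping
happens at the dF/F0 stage.

# Events, spikes, accuracy

dF/F0 uses baseline samples strictly below the trace's 25th percentile,
F0 = mean of those samples (a median alternative is a one-line change),
and clips negatives. Events are local maxima outside the baseline mask
that exceed the 50th percentile of the trace **and** a robust noise floor
of 3.5 MAD of the unclipped series, whose onset-to-peak time (time since
the trace last sat at or below 10% of the peak) lies in 0.05--1.0 s;
events within 1 s are merged keeping the largest. The floor and the merge
are numerical guards: the three bare criteria admit arbitrarily small
noise peaks on a clipped trace and re-trigger on decay bumps, which
contradicts the intended "one transient, one event" behavior. Event sizes
split at the median amplitude (ties small). The series SNR is
max |dF/F0| over the baseline standard deviation.

Electrophysiology: a brick-wall 100-Hz high-pass, threshold crossings at
2 s.d. of the quietest 10-s segment, a 2-ms refractory period, and a
peak-amplitude floor of 6 quiet-segment s.d. — the bare 2-s.d. crossing
rule fires on ~2% of the samples of any stationary noise, so automated use
needs the floor. Isolated APs have no neighbor within 0.4 s before and 1 s
after; accuracy is the fraction of isolated APs with an event peak within
0--1.5 s (the kernel argmax plus a few sample periods), each event
matching at most one spike.

# Ensembles, NMF, decoding

Traces are denoised by sparsity-regularized non-negative deconvolution
against the indicator kernel (FISTA, FFT convolutions, penalty scaled to
the trace's MAD), binarized at 3 s.d. of the denoised trace, and screened
for coactivity: 1000 surrogates permute each ROI's frames independently,
the per-frame coactive counts are pooled, and k* is the smallest count
with pooled exceedance probability below 0.05 (per-surrogate maxima are
available as the stricter alternative). Ensemble frames have coactive
count >= max(k*, 2). NMF uses seeded multiplicative updates, best of five
restarts, with VAF = 100 (1 - ||E||^2/||F||^2). The sparseness index is
s = sum(w^2) / (sum(w))^2 — the printed source formula (sum(w^2)/sum(w))
cannot reach its stated maximum of 1 for a single-participant module, so
the normalized form that does is used. Decoding uses a linear
maximum-margin classifier (L2-regularized squared hinge) on per-frame
population vectors, a random 50/50 split, 10-fold cross-validation over
the regularization grid on the training half, and reports accuracy above
the majority-class chance level.

# Numerical choices and degenerate inputs

* Percentiles are linear-interpolation (type 7); "below" is strict with a
  documented `<=` fallback.
* Ties in pixel SNR break by row-major order; ties in reassignment by
  trajectory order; event-amplitude ties class as small.
* All randomness flows through explicit seeds; fixed seeds give
  bit-identical scenes, acquisitions, and pipeline outputs. Helper RNG use
  never perturbs the caller's stream.
* Degenerate inputs (constant traces, all-zero rasters, empty trajectories,
  flat patches) produce warnings with defined fallbacks or early errors
  naming the offending object.

# Known limitations

The AR(2)/PC1 screen detects sustained erratic displacement epochs, not
isolated clean steps (see above); frame-by-frame motion correction of SLS
data is out of scope, as in the source workflow. HDF5 export is not
provided (CSV/JSON/TIFF/XML cover all artifacts at this scale). The
simulator's noise does not scale with dwell time, so absolute photon-budget
comparisons across dwell settings are outside its remit.
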