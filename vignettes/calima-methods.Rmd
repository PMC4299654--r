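---
title: "Methods and design of the calima two-photon analysis toolchain"
author: "calima authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the calima two-photon analysis toolchain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

calima is a toolchain for episodic two-photon calcium imaging experiments:
large multi-file stacks are exposed as one lazily-read tensor, every frame
is tagged with the stimulus shown while it was acquired, frames are
re-registered at sub-pixel resolution, fluorescence is converted to
\(\Delta F/F_0\) against an assigned baseline distribution, ROIs are
detected or imported, and randomised stimulus presentations are regrouped
into per-stimulus, per-trial responses and PSTHs. This vignette documents
the models, conventions, parameters and numerical choices behind each
stage, and what the bundled synthetic-experiment generator does and does
not emulate.

# The lazy stack layer

A recording session commonly spans several gigabyte-scale files; loading
them eagerly multiplies memory use by the element-size ratio between the
detector's integers and doubles. `open_binary_stack()` and
`open_tiff_stack()` instead map an ordered list of files to a single
4-D tensor (rows, columns, frames, channels) from which arbitrary regions
are read on demand with `read_region()`. Three properties are contractual
and are verified by the test suite:

* **Laziness.** Opening a stack reads only metadata. An instrumented
  counter (`io_read_count()`) increments once per file block touched by a
  read; structural operations never change it.
* **O(1) structure.** `permute_axes()` reorders the view's axes and
  `scale_offset()` composes an affine value transform
  \(v \mapsto a\,v + b\) (negation is \(a=-1\)); both return immediately
  and share the underlying files. Transforms compose exactly:
  applying \((a_2, b_2)\) after \((a_1, b_1)\) reads as
  \((a_2 a_1,\; a_2 b_1 + b_2)\).
* **Bounded memory.** `slice_apply()` iterates a function over one axis,
  holding one slice plus a bounded frame buffer (at most 16 frames) in
  memory; mapping-mode output goes to a temporary disk-backed stack
  created with `create_binary_stack()`.

## The raw-binary dialect

Raw blocks use a single documented layout so that any acquisition system
can emit it: little-endian elements of type `u8`, `u16`, `i16`, `f32` or
`f64`, ordered **channel-fastest, then columns, then rows, then frames**.
One frame is therefore a contiguous span of
`n_rows * n_cols * n_channels` elements, which makes single-frame access
one sequential read. Files concatenate along the frame axis in the order
given. An optional per-file byte offset skips foreign headers. Writes
(`write_region()`, raw backend only) store raw dtype values — the
read-side transform is deliberately not inverted, so the on-disk
representation is independent of any transform composed on a handle — and
out-of-range values for integer dtypes are clipped to the representable
range with a warning, mirroring detector saturation rather than silently
wrapping.

TIFF stacks are read-only, restricted to 8/16-bit grayscale with at most
2 samples per pixel; page geometry is read once at open time and pages are
decoded on demand through libtiff.

# The sidecar header and the stimulus timeline

All stack-global metadata lives in one JSON document shared by every block
of a stack (`stack_header()`, `write_stack_header()`):

| field | meaning |
|---|---|
| `n_rows`, `n_cols`, `n_channels`, `dtype` | frame geometry and element type |
| `frames_per_file` | frames in each block file, in order |
| `byte_offset` | offset of pixel data within each raw file |
| `f_pixels_per_um` | spatial calibration, px/µm |
| `t_frame_duration` | acquisition time per frame, s |
| `f_z_step` | axial step between frames, µm |
| `t_blank_time` | blank time between presentations, s |
| `sequence_ids_per_block` | per block: stimulus sequence IDs in presentation order |
| `stimulus_durations` | entry *i*: duration (s) of stimulus ID *i* |
| `use_times` | per stimulus: `[t_start, t_stop)` analysis window offsets from onset, s |
| `stimulus_ids_per_block` | optional block-level stimulus ID per file |

`build_timeline()` derives presentation intervals: within each block,
presentations of that block's sequence are laid back-to-back starting at
the block's first-frame time, each followed by `t_blank_time` of untagged
gap; blocks abut exactly (dead time, if any, is modelled as trailing blank
inside a block). A presentation overrunning its block is an error rather
than silently spilling into the next file.

`frame_stimulus_info()` tags frames by **onset time** membership in the
half-open interval `[t_start, t_end)`. Half-open intervals make the
tagging a partition: no frame ever belongs to two presentations, and a
frame landing exactly on a boundary belongs to the later presentation.
`use_frame` is true when the frame's time since stimulus onset falls in
that stimulus's `use_times` window — the mechanism for excluding onset
transients or late adaptation from analysis. Frame tagging is a pure
function of the header (`header_frame_info()`), so identical inputs always
give identical tables.

Indexing conventions: the R API is 1-based throughout, as R users expect.
The block/frame-in-block/presentation fields inside the frame-info table
are also 1-based, matching the conventions of the acquisition metadata
model it mirrors. External *files* (shifts CSV, RoiSet JSON, CLI
arguments) use 0-based indices, which is the convention of the
surrounding tool ecosystem; conversion happens only at the file boundary.

# Sub-pixel registration

`estimate_shift()` implements two-stage Fourier cross-correlation
matching (the efficient subpixel image registration scheme):

1. the cross-power spectrum \(R = \overline{F_1}\,F_2\), normalised by
   total spectral energy, is inverse-transformed on a 2× zero-padded grid,
   giving a global correlation peak at half-pixel resolution;
2. a matrix-multiply DFT evaluates the correlation surface on a
   1.5 px × 1.5 px neighbourhood of that peak at 1/κ px steps
   (`upsample = κ`, default 20), and the argmax is the shift, wrapped to
   \((-n/2, n/2]\) per axis.

A design note on normalisation: classical *phase* correlation whitens the
spectrum per frequency. On smooth, noisy fluorescence images whitening
gives signal-free high frequencies the same weight as the informative
band, and sub-pixel accuracy collapses (measured mean error ≈ 0.6 px at
20:1 signal-to-noise on Gaussian-soma images, versus ≈ 0.02 px for the
energy-normalised correlation used here). The whole-pixel stage is also
more robust un-whitened. Constant images have no defined shift and raise a
degenerate-input error.

`align_stack()` wraps this per frame with three regularisers, each off by
default: a Gaussian low-pass (`prefilter_sigma`, px) applied to both the
reference and the moving frame; sliding-window averaging of the *moving*
frame with its `window_len − 1` neighbours (centered, truncated at stack
ends — applying the window to the reference as well would double-smooth
the estimate); and single-frame shift-size rejection: estimates whose
magnitude exceeds `max_shift` (default 10 px) are discarded and repaired
by linear interpolation between the nearest accepted frames (nearest
value at the ends). Reference modes: `"fixed"` (a chosen frame),
`"external"` (a supplied image), or `"progressive"`, where each frame is
registered against its predecessor and the per-step estimates are summed
into frame 1's coordinate system — appropriate when the field drifts far
from any single reference.

The stored shift convention: `shifts[f, ] = (dy, dx)` is the displacement
of frame `f`'s *content* relative to the reference. Re-registration
(`apply_shift()`) therefore samples the frame at `(r + dy, c + dx)` with
bilinear interpolation, undoing the motion. Bilinear interpolation was
chosen over Fourier-domain shifting because it cannot ring and because
border bookkeeping is exact: output pixels whose sample point falls
outside the frame are marked invalid (`NA`) and excluded from all
downstream ROI averages rather than zero-filled, which would otherwise
correlate motion with apparent fluorescence. The near-inverse property
`apply_shift(apply_shift(x, d), -d) ≈ x` holds on the interior to the
interpolation error of the image's curvature (below 1% of range for
soma-scale structure), not to machine precision — the price of the
no-ringing choice.

Re-registered frames are cached on disk (`cached_aligned_frame()`), keyed
by frame index, channel, the shift values and the frame's black level, so
a second access returns bit-identical data without recomputation and any
metadata change automatically invalidates the entry. An unwritable cache
directory degrades to uncached computation with a warning.

# Black level and baseline distribution

Response quantification is a two-stage affair. First the instrument
offset: `define_black_region()` takes pixel indices of a region known to
have zero fluorescence (classically a blood-vessel lumen) and records the
per-frame mean as the black trace, subtracted from everything downstream.
The per-frame trace exists to track slow set-point drift; when the
recording is drift-free, re-estimating it every frame only injects
region-sampling noise into every \(\Delta F/F_0\) value, so
`statistic = "constant"` assigns the median of the per-frame means as a
single set-point instead. Negative black-subtracted values are kept, not
clipped — clipping would bias the baseline noise statistics.

Second, the baseline distribution: `assign_blank_frames()` estimates a
per-pixel mean frame \(\bar F_0\) and sample (n−1) standard deviation
frame \(\sigma_{F_0}\) from chosen source frames (aligned,
black-subtracted; at least 2, typically blank periods), and attaches them
to a half-open target frame range per channel. Ranges must not overlap
within a channel and are not interpolated between; `get_blank_frames()`
resolves a frame to its covering entry or fails naming the frame. The API
accepts any source frames — blank-period frames are the sensible default
and what the command-line `extract --dff` uses — because protocols differ
in where clean baseline epochs live.

Response transforms: \(\Delta F/F_0 = (F - F_0)/F_0\) with both terms
black-subtracted; FRET-style readout is the channel ratio \(F_a/F_b\).
Non-positive denominators make the value undefined: the element becomes
`NA` and a warning summarises the count.

# ROI detection and import

The two bundled detectors share one pipeline: mean the processed frames
over a frame range into a detection image; smooth with a Gaussian
(`smooth_sigma`, default 2 px); find 8-neighbour local maxima above
`median + threshold_z × spread`, where spread is the MAD floored at 1% of
the image's dynamic range (the floor keeps noise-free images, whose MAD
is zero, from admitting quantisation ripples as peaks); accept peaks
greedily in decreasing height while suppressing any candidate within
`min_separation` of an accepted one; and place a disc ROI of
`cell_radius` (clipped to the image) at each accepted peak.
`find_cells_g()` detects on channel 1 — suited to indicators that
brightly label somata or nuclei; `find_cells_gr()` detects on
mean(channel 1) − mean(channel 2), which cancels structures present in
both channels such as a vessel or astrocyte counterstain. Defaults
(`smooth_sigma` 2 px, `cell_radius` 6 px, `min_separation` 12 px,
`threshold_z` 4) suit soma-scale objects on 128 × 128 px fields; all four
are exposed because they are resolution-dependent.

ROIs are stored as connected-region pixel-index lists (1-based,
column-major) with the image dimensions — the region-structure style that
connected-component labelling returns — serialised to JSON with 0-based
indices externally. `import_imagej()` reads the ImageJ `.roi` binary
format ("Iout" magic, big-endian) and `.zip` containers for the
rectangle, oval, polygon and freehand types, rasterising each shape with
the pixel-centre-inside rule from the format's top-left origin;
unsupported types are skipped with a warning. `write_imagej_fixture()`
emits the same subset (with a store-only ZIP writer) for round-trip
testing and interchange.

# Derandomised response extraction

`extract_region_traces()` averages processed pixels within each ROI into
per-frame traces, excluding invalid (shift-border) pixels; a frame in
which an ROI has no valid pixel is `NA`. Frames are processed in bounded
chunks so memory stays flat in stack length.

`derandomize()` inverts the randomised presentation order: trials of each
stimulus are numbered by presentation time, and the resulting
(stimulus, trial, frame-in-trial) → global-frame mapping is injective;
composing it with the recorded presentation order reproduces the original
acquisition sequence exactly.

`extract_region_responses()` then computes, per (ROI, stimulus, trial):
restrict the trial to frames inside the stimulus's `use_times` window;
if `scale = "dff"`, convert each frame with the baseline entry covering
it (the conversion is per frame, *before* the measure — \(\Delta F/F_0\)
is a trace transform, not a summary transform); and summarise with the
measure: `"mean"` (window average), `"peak"` (window maximum of the
unsmoothed trace; optional smoothing is deliberately not applied) or
`"ratio"` (mean of the `ratio_channels` channel-ratio trace). Trials with
no usable frames yield `NA` with a warning. The result carries the
trial-resolved response array, the trial-averaged matrix (mean over
non-`NA` trials), the single-trial segments, and PSTHs: per stimulus, the
frame-wise mean across trials after truncating every trial of that
stimulus to the minimum trial frame count, covering the whole
presentation rather than only the use window.

For ROI-level \(\Delta F/F_0\), the ROI's trace and its baseline are
averaged over pixels first and divided second. For a cell whose transient
scales its own fluorescence profile this equals the per-pixel conversion
exactly; under partial-volume contamination it weights pixels by
brightness, which is the conventional choice.

# Example analyses

* `rf_map()` builds a smoothed receptive-field estimate from a coarse
  stimulus grid by summing circular Gaussian fields at the grid-pixel
  centres, each weighted by that pixel's trial-averaged response. The
  Gaussian width is set so its FWHM equals the stated stimulus pixel
  diameter (\(\sigma = d / (2\sqrt{2\ln 2}\))) — the conventional reading
  of "diameter" for overlapping visual-field pixels. The RF centre is the
  field's argmax; an all-zero response vector gives a flat field and an
  undefined (`NA`) centre. The map is linear in the responses.
* `tuning_curve()` returns trial-averaged mean ± s.e.m. per drift
  direction in direction order (s.e.m. 0 where fewer than 2 trials).
* `sparseness()` measures lifetime (per neuron over time) or population
  (per time point over neurons) sparseness as the biased divisor-*n*
  skewness \(g_1 = m_3 / m_2^{3/2}\), the default of the numerical
  environment the measure was defined in. Units with fewer than 3 finite
  values or zero variance give `NA`. Population sparseness is reported
  per time point; how to summarise the distribution is left to the user.

# The synthetic experiment generator

`generate_experiment()` writes complete experiments to disk in the
package's own formats, with ground truth sufficient to compute every
expected analysis output in closed form — the foundation of the test
suite, which never derives an expected value from the pipeline under
test. Channel-1 pixel model:

\[
I(x, t) = B + b(x) + \sum_i F_{0,i}(x)\,\bigl(1 + s_i(t)\bigr) + \varepsilon
\]

with black level \(B\), optional constant background \(b\), Gaussian soma
profiles \(F_{0,i}\), transients \(s_i(t)\) summing one kernel per
presentation — instantaneous rise at stimulus onset, exponential decay
\(\tau\), amplitude \(a \cdot \max(0, \cos(\theta - \theta_i))\) for drift
direction \(\theta\) and preferred direction \(\theta_i\) — and i.i.d.
Gaussian noise \(\varepsilon\). The composed frame is rigidly displaced
along the motion path by the same bilinear operator the aligner inverts
(which makes shift recovery well-posed), then quantised to the output
dtype with clipping. Identical configuration and seed give byte-identical
files.

Because the transient multiplies the cell's own fluorescence profile, the
planted peak \(\Delta F/F_0\) at the preferred direction equals the
amplitude parameter exactly wherever somata do not overlap — the
closed-form anchor for amplitude-recovery checks. A 10 × 10 px corner
patch is carved to the black level (a vessel-lumen-sized
zero-fluorescence region at the default calibration) and its indices
recorded for black-level estimation.

Default conditions and their rationale:

| parameter | default | why |
|---|---|---|
| frame geometry / rate | 128 × 128 px at 7.81 Hz | the reference acquisition scale |
| protocol | 16 directions × 2 s, randomised per block, 5 blocks | the reference drifting-grating experiment (5 trials) |
| inter-stimulus blank | 2 s | ≥ 3 decay constants, so successive trials are independent; a 1 s gap leaves ~19% of the previous transient in the next window, larger than the 22.5° tuning gap |
| decay constant τ | 0.6 s | GCaMP6m-like kinetics |
| soma σ | 4 px | ≈ 6 µm FWHM at the default 1.5 px/µm — a realistic cell-body cross-section; smaller somata starve ROI averages of pixels |
| dtype / black / F0 | u8, 10, 60 | 8-bit detector with offset, signal in the upper half of the range |
| stimulus-free tail per block | 3 s | lets transients decay below 0.2% so clean blank frames exist for baseline estimation |

The generator emulates randomised episodic protocols, motion, detector
offset and quantisation. It deliberately does **not** emulate
photobleaching or slow drift, neuropil contamination, Poisson (as opposed
to Gaussian) photon statistics, non-rigid motion, or indicator
saturation; passing tests therefore demonstrate correctness of the
pipeline's bookkeeping and estimators under controlled conditions, not
robustness to every artefact of real tissue.

One genuine sampling effect is worth knowing about: with a 7.81 Hz frame
clock and a 4 s presentation period the grid is incommensurate, so each
trial samples the decaying transient at a different onset phase. This
contributes ~1% multiplicative trial-to-trial variability to window-mean
responses — real, irreducible at the analysis stage, and present in
actual recordings whenever stimulus timing is not frame-locked.

# Numerical choices and degenerate inputs

* Ties in peak detection and response argmaxes resolve to the first
  maximum in scan order (deterministic).
* Timeline and use-window comparisons use half-open intervals with a
  10⁻¹² s guard against floating-point boundary jitter.
* The detection threshold's robust spread is the MAD floored at 1% of the
  smoothed image's range (degenerate-noise guard, above).
* Constant images: shift estimation errors; an empty timeline tags
  nothing; an all-zero RF field flags its centre undefined; zero-variance
  sparseness is `NA`.
* Integer-dtype writes clip with a warning; reads never clip.
* Shift estimates are reported at 1/κ px resolution; the recovery
  contract (mean error < 1/κ at ≥ 20:1 signal-to-noise) is verified on
  seeded synthetic stacks.

# Validation problem sizes

The test suite and the acceptance script regenerate all inputs from the
synthetic module: the full-scale 7-file, 7378-frame two-channel stack for
byte accounting; 64 × 64 × 200 × 2 stacks with 1000 random region reads
for lazy/eager equivalence; 100-frame drift recovery at κ = 20; 50
randomised block orders for derandomisation; 10 seeded 20-cell fixtures
at 5:1 brightness-to-noise for detection; and the 16-direction × 5-trial
experiment at transient SNR 5 for end-to-end preference recovery. These
sizes were chosen as the smallest that exercise every code path at the
reference experiment's scale.

# Known limitations

Rigid translation only (no rotation or non-rigid warping); single-plane
timelines (the z-step field is carried but no volumetric segmentation is
attempted); TIFF support is limited to baseline grayscale files; spike
inference is out of scope by design — response matrices and traces are
plain R structures ready for external deconvolution tools.
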