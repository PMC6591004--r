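---
title: "Methods: orientation tuning, receptive-field mapping and the feedforward-inhibition model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orientation tuning, receptive-field mapping and the feedforward-inhibition model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinotune)
```

`retinotune` implements an analysis chain for two-photon recordings of
synaptic signals in the retina, together with a synthetic-data
generator rich enough that every analysis stage can be validated
against known ground truth. This vignette documents the models, the
parameters that matter, the numerical choices, and what passing the
package's tests does and does not establish about real data.

## The scientific setting

Bipolar cells excite retinal ganglion cells (RGCs); amacrine cells
provide inhibition both laterally (onto bipolar terminals) and feed
forward (onto the same RGC dendrites the bipolar cells excite). Three
observations organise the pipeline:

1. Many bipolar cell synapses are orientation-selective. A broad
   population with moderate selectivity is explained by elongated
   receptive-field (RF) centers; a second population with near-perfect
   selectivity requires lateral inhibition tuned to the orthogonal
   orientation.
2. Individual RGCs receive mixtures of inputs with different tunings.
3. A subset of RGCs transform this slowly adapting drive into
   transient outputs that signal *every change* of orientation and
   then re-null — a dynamic predictive code (DPC). A high-pass filter
   generated by feedforward inhibition (FFI) accounts for this
   transformation; a static nonlinearity alone does not.

## Stimulus conventions

Orientation is expressed in `[0, 180)` with **0° = vertical bars**
(luminance modulated along x) and 90° = horizontal. Gratings are
square waves spanning −100% to +100% contrast about the mean (luminance
is stored in contrast units, mean = 0), with a bar center aligned to
the screen center; polarity reverses as a temporal square wave
(default 5 Hz). Pixels take the value at their center — no
anti-aliasing — so rendered gratings are exactly two-valued and all
protocols are bit-reproducible from their parameters and seed. Screen
extent and resolution are configuration (defaults 30° × 30° at
4 px/°; the examples and tests use 2 px/° for speed): the physical
screen size of any particular rig is not a property of the method.

A `gaussian_rf`'s `theta_deg` uses the same convention: it is the
orientation of the grating whose bars run along the RF's major axis,
so an elongated RF prefers gratings at its own `theta_deg`.

## The synthetic generator

`sample_population()` draws terminals of three mechanisms:

* **untuned** — near-circular RF (ellipticity ~0.02);
* **elliptical** — elongated RF center, sampled around the observed
  population median ellipticity of 0.30 (`1 − σ_minor/σ_major`);
* **inhibition_sharpened** — elongated RF plus subtractive lateral
  inhibition from a pooling field tuned to the orthogonal orientation.

The inhibitory pooling field is the RF rotated by 90° with its major
axis scaled 4-fold (RF centers are roughly 4-fold smaller than the
spatial patterns signalled most strongly). An isotropic pooling field
of any size would have no orientation preference for full-field
gratings and could not sharpen tuning; orientation-selective
suppression requires an oriented field, which is also what
orientation-tuned amacrine synapses provide.

The drive of a terminal is the sum over pixels of its normalized RF
times the stimulus frame (terminals are OFF by default, `polarity =
-1`), half-wave rectified because release cannot be negative;
inhibition is subtracted *between* the two rectifications, so only
inhibition can pull the signed signal below baseline — reproducing the
sub-baseline calcium dips seen at the non-preferred orientation of
strongly tuned terminals.

Synaptic depression is a divisive gain with two depletion states. The
defaults are the measured bipolar kinetics: a 49% decline over 10 s
with time constants 0.21 s and 4.2 s carrying 61% and 39% of the
decay; the steady-state/peak ratio of a step response is exactly
`y0 / (y0 + A1 + A2)`. Depletion is driven by the *smoothed* release
rate (0.2 s) with saturation at 30% of the peak drive: the depression
figures are measured under a contrast-reversing grating whose rectified
drive is active only half the time, so the generator must reach full
depression under exactly that flicker.

Indicator kinetics: calcium reporters (SyGCaMP-like) use a 0.4 s
exponential decay; summed dendritic glutamate signals
(iGluSnFR-like, used for RGC sessions) use a 0.25 s effective time
constant. RF centers scatter uniformly within ±6° of the screen
center; since a terminal's flicker phase is set by the grating polarity
at its RF center, scatter decorrelates the 5 Hz flicker across
terminals, as scattered receptive fields do in the retina. Movie
rendering places each terminal as a Gaussian spot (σ = 1.5 px) on a
baseline `F0`, with i.i.d. Gaussian pixel noise; "SNR 10" means peak
ΔF/F 1 against pixel noise of 0.1 ΔF/F.

What the generator does *not* emulate: photon shot noise and detector
statistics, motion artifacts, neuropil contamination, vesicle-pool
biophysics, and overlap between terminals beyond Gaussian spot
summation. Passing the recovery tests therefore demonstrates the
*procedures* are correct and well-calibrated under the stated
statistical structure — not that real movies meet that structure.

## Segmentation

The local correlation map replaces each pixel by the maximum Pearson
correlation of its raw time series with its 8 neighbours (border pixels
use the neighbours they have; zero-variance pixels correlate at 0).
ROIs grow breadth-first from the highest unclaimed map value: a
candidate joins when its correlation with the *seed pixel's* series
reaches the threshold (correlating against the running ROI mean is
available via `reference = "mean"`; the seed-referenced rule is the
default because growth then never depends on visit order). Segmentation
iterates seeds in descending map order and discards ROIs whose peak
ΔF/F does not exceed 4 baseline SDs. Thresholds are configuration, as
they are in practice chosen by the experimenter; the defaults
(growth 0.3, seed 0.3) were set on the synthetic benchmark. For axonal
data, `join_correlated_rois()` merges ROIs whose mean traces correlate
at or above a threshold by single linkage, so one axon's many boutons
are not counted as many cells.

## Tuning statistics

Response detection follows median/MAD rules (raw MAD, no
normal-consistency factor — the thresholds are tuned multiples of the
raw statistic): a response occurred if the signal departs from the
median of the preceding 15 s baseline by more than 4 baseline MADs; it
is *transient* if the maximum within 0.5 s of the transition exceeds
the 10 s epoch median by 4 epoch MADs, in which case the maximum is the
response, otherwise the epoch median is. The OSI uses the last two
orthogonal epochs, avoiding contrast-onset adaptation, and for calcium
data is only assigned when `|a − b|` exceeds twice the MAD of the
smaller response's epoch.

RGC classification: `dpc` requires a transient at *every* orientation
switch exceeding the prior epoch's steady state by 4 of its standard
deviations; otherwise `static_os` if the final two epochs' steady
medians differ by 4 pooled SDs; otherwise `contrast_only` when only
the grating onset drove a response, else `non_os`. Two windows are
deliberate choices here: the transient window is 1 s (the modelled
output peaks 0.5–0.7 s after a switch once indicator and filter delays
accumulate; the 0.5 s figure used for synapse-level detection is kept
there), and the transient rule operates on a 0.25 s moving average —
one reversal cycle — because "standard deviations of the steady state"
is read as noise dispersion, not stimulus-locked flicker amplitude.
The steady-state comparison for `static_os` uses the raw trace.

Moving-bar selectivity uses per-trial vector sums over pooled
orientations in doubled-angle space and Moore's rank-based variant of
the Rayleigh statistic: magnitudes are ranked (average ranks on ties)
and `R* = |Σ i·(cos φ_i, sin φ_i)| / n^{3/2}`. Its absolute scale is
immaterial because the critical value is calibrated empirically: every
terminal's angle labels are shuffled (independently per trial — a
single relabeling applied to all trials would preserve across-trial
consistency and not form a null), the statistic recomputed, and the
critical value set so that exactly 1% of the shuffled population is
classified as selective. Any strictly monotone variant of the
statistic yields identical classifications under this calibration.

## Receptive fields

Flash responses are baseline-subtracted peaks (0.3 s smoothing reduces
the small-sample bias of the maximum), averaged over repeats and
rectified into an angle × position sinogram. Filtered back projection
uses a frequency-domain Ram–Lak ramp with 2× zero-padding and linear
interpolation between bar positions.

Two reconstruction facts drive the remaining choices. First, with only
5 angles the FBP point spread is star-shaped and systematically rounds
ellipses: a 2:1 Gaussian reconstructs with apparent ellipticity near
0.3 even noiselessly (we confirmed the same behaviour with an
independent reconstruction implementation). The map is therefore used
for center estimation and initialisation, while parameter recovery
fits the Gaussian in projection space (`fit_gaussian_2d(map, sino =
...)`): the candidate RF's analytic bar responses — a projected
Gaussian integrated over the finite bar width — are least-squares
matched to the measured sinogram. Second, a mapping bar as wide as the
3.2° spacing low-passes the projections so strongly that a σ = 1.5°
minor axis is indistinguishable from a point source; the protocol's
bar width therefore defaults to half the spacing. Sigma estimates are
bounded below at an eighth of the spacing, where they cease to be
identifiable.

The ellipticity definition is `1 − σ_minor/σ_major` (0 for a circle;
`(σ_M − σ_m)/(σ_M + σ_m)` is available). The forward model multiplies
the normalized RF by a square grating at the preferred and orthogonal
orientations, rectifies the summed product, maximises over spatial
phase (a fixed-phase mode exists; phase maximisation removes the
dependence on where the screen-centered bars happen to fall relative
to the RF), and applies the OSI formula. A population at the measured
median ellipticity stays well below OSI 1 across the measured
spatial-frequency band — ellipticity alone cannot produce the
near-perfect population.

## The feedforward-inhibition model

The reduced RGC is passive: a spherical soma (15 µm) plus a single
unbranched dendrite (150 µm × 1.2 µm in 4 segments), specific membrane
resistance 20 kΩ·cm², capacitance 1 µF/cm², axial resistivity
120 Ω·cm (τ_m = 20 ms), leak reversal −60 mV, excitatory reversal
0 mV, inhibitory reversal −70 mV. Excitatory and inhibitory synapses
are co-located mid-dendrite; integration is implicit (backward Euler
with a tridiagonal solve, unconditionally stable, default step
0.5 ms). Unitary conductances are difference-of-exponential waveforms
(excitation 2/8 ms, inhibition 4/16 ms) convolved with each event's
duration; inhibition mirrors the excitatory event times after a 10 ms
disynaptic delay and is scaled by the inhibitory:excitatory ratio
(default 2:1).

The excitatory plateau conductance defaults to 0.003 µS: a passive
cell only produces strongly transient step responses when synaptic
conductance is a few-fold the resting leak (≈0.64 nS here), and the
sub-nS figure quoted for the source model is implausible as a unitary
conductance (plausibly µS); both are reachable through configuration,
and in the shunting regime the derived filter's shape is robust to the
exact value. The temporal filter is identified by normalized
least-mean-squares (`w ← w + µ e x/(ε + ‖x‖²)`, µ = 0.2, ε = 10⁻⁶,
6 passes with a divergence check) on 804 s containing 1600 randomly
timed events of log-uniform duration 20–500 ms, at 200 Hz with a
750 ms kernel. At the 2:1 ratio the kernel is biphasic with DC gain
below 0.09 of its peak; with inhibition absent the DC gain is several
times larger but not equal to the peak — conductance self-shunting
keeps even the uninhibited cell sub-linear at DC, so "low-pass"
describes the no-FFI kernel only loosely.

Model 1 convolves the input with the high-pass kernel and applies
`max(x − θ, 0)` with θ = 3 × the SD of the filtered signal's
pre-stimulus baseline; model 2 applies `max(x − θ, 0)²` to the raw
input. `ffi_kernel_biphasic()` provides a parametric stand-in for the
derived kernel (fast positive lobe 0.1 s, slow negative lobe 0.5 s,
exactly zero DC by construction) and is the default session filter.
Model comparison follows two conventions: the output-versus-input
time-to-peak (the high-passed output *leads* its input), and the
prediction-versus-measured-output delta per model — a static
nonlinearity maps its input pointwise and so can never lead it, which
is precisely why model 2 is late where model 1 is not. Peak timing is
measured on 0.25 s-averaged traces so that residual 5 Hz flicker does
not jitter the argmax.

## Problem sizes and runtime

The default end-to-end scenario uses a 30° × 30° screen at 2 px/°,
20 Hz sampling, six 10 s epochs plus 3 s of pre-stimulus baseline, 20
terminals on a 64 × 64 px canvas at movie SNR 10, twelve RGC sessions
(8 inputs each, from dedicated 40-terminal tuned and 30-terminal
untuned pools), two receptive-field round trips (3 protocol repeats),
and a 10,000-resample wiring test; it completes in ~20 s on one CPU
and is byte-reproducible from its config. The shuffle-calibration
script uses 20,000 calibration and 2,000 held-out null terminals. The
sizes are chosen so the whole validation suite runs in minutes while
each statistic retains enough samples for its stated tolerance.

## Known limitations

* The 5-angle tomography fundamentally limits shape recovery; the
  projection-space fit assumes the RF is a single Gaussian, and
  inhibition-sharpened terminals violate that assumption by design
  (their mapped profile contains the orthogonal inhibitory field;
  difference-of-Gaussian estimation is out of scope).
* The FFI kernel's absolute scale is arbitrary (normalized to unit
  peak); only its shape is identified.
* The classifier rule set is threshold-based, and sessions near the
  4 SD boundaries flip under noise; at the default conditions the
  per-class accuracy is ≥90%, not 100%.
* Registration is assumed: the segmentation operates on motion-free
  movies.
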