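# retinotune

Analysis pipeline for two-photon imaging of synaptic signals in the
retina, built around the question of how retinal ganglion cells (RGCs)
signal *changes* in stimulus orientation while suppressing unchanging
input — a dynamic predictive code. The package targets analysts working
with fluorescence reporters of synaptic activity (iGluSnFR glutamate
signals on RGC dendrites and axons, SyGCaMP calcium signals in bipolar
and amacrine cell terminals) in larval zebrafish or comparable
preparations, and it ships a fully synthetic data generator so that
every stage of the analysis can be validated against ground truth
without any recordings.

## What it computes

* **Stimuli** — contrast-reversing square-wave gratings whose
  orientation switches between vertical (0°) and horizontal (90°),
  moving bars (4.1° wide, 18.6°/s, 8 directions), and flashed-bar
  receptive-field mapping protocols (3.2° spacing, 5 angles), all
  rendered in visual-degree coordinates with exact event logs.
* **Synthetic ground truth** — populations of synaptic terminals whose
  orientation tuning arises from receptive-field ellipticity, from
  orthogonally tuned lateral inhibition, or from neither; synaptic
  depression with double-exponential kinetics (τ = 0.21 s and 4.2 s
  carrying 61%/39% of a 49% decline); indicator kinetics; rendered
  fluorescence movies with controlled SNR.
* **Segmentation** — correlation-seeded ROI extraction: a local
  correlation map (each pixel replaced by the maximum Pearson
  correlation with its 8 neighbours) seeds iterative region growing;
  strongly correlated ROIs can be joined for axonal (tectal) data.
* **Tuning statistics** — event-aligned response detection with
  median/MAD thresholds, the orientation selectivity index
  `OSI = |a − b| / (|a| + |b|)` for responses to the last two
  orthogonal gratings, RGC classification (dynamic predictive coding /
  statically tuned / contrast-only / non-selective), and, for
  moving-bar data, per-trial vector sums in doubled-angle orientation
  space tested with the rank-based Moore–Rayleigh statistic
  `R* = |Σ_i i·(cos φ_i, sin φ_i)| / n^{3/2}`, whose critical value is
  calibrated by shuffling angle labels so that exactly 1% of a null
  population is classified as orientation-selective.
* **Receptive fields** — sinograms of flashed-bar responses,
  filtered back projection (Ram–Lak), rotated 2D-Gaussian fits
  (optionally fitted in projection space, which undoes the
  ellipse-rounding bias of a 5-angle reconstruction), ellipticity
  `1 − σ_minor/σ_major`, and a forward model predicting the OSI a
  purely elliptical receptive field would produce at any spatial
  frequency.
* **Feedforward inhibition (FFI) model** — a passive compartmental RGC
  (soma + single dendrite) with co-located excitatory and inhibitory
  synapses; NLMS system identification of the excitation-to-voltage
  kernel (750 ms, trained on 804 s with 1600 random events); model 1
  (high-pass filter + threshold-linear nonlinearity) versus model 2
  (threshold + squaring, no filter); time-to-peak, R², band-power and
  spectrogram comparisons.
* **Wiring statistics** — the vertical-preferring input fraction
  R_0/90 per RGC and a permutation test (draws of N synapses from the
  recorded population) for non-random wiring.

## Worked example

```r
library(retinotune)
res <- run_pipeline(pipeline_config(seed = 1))
```

The end-to-end run (≈20 s) generates a 20-terminal synthetic movie at
movie SNR 10 under the orientation-switch protocol, segments it, scores
tuning, classifies simulated RGC sessions, and reconstructs receptive
fields. With seed 1 it prints, via `str(res)`:

* `segmentation`: 20 ROIs, recovery fraction **1.0** — every ground
  truth terminal matched within 3 px;
* `tuning`: median OSI **1.0** for inhibition-sharpened terminals,
  **0.42** for purely elliptical ones (the two tuned populations), with
  88.9% of preferred orientations recovered exactly;
* `rgc_classification$accuracy`: **1.0** across dynamic-predictive,
  statically tuned and orientation-insensitive sessions;
* `model_comparison`: the high-pass session output retains only
  **1.3%** of the input's 0–5 Hz band power (`band_power_ratio_output
  = 0.0128`) and correlates weakly with its input
  (`r2_input_output = 0.037`) while model 1 explains it
  (`r2_model1_output = 0.75`);
* `rf_recovery`: receptive-field centers recovered to **0.17°** (bar
  spacing 3.2°) and ellipticity to within **0.037**.

Single components are just as direct:

```r
compute_osi(0.75, 0.25)          # 0.5
f <- derive_ffi_filter(seed = 2) # ~1 s, compiled membrane + NLMS
filter_gain(f)                   # $dc/$peak = 0.090: strongly high-pass
```

A thin command-line front end over the same functions is installed at
`system.file("cli/retinotune.R", package = "retinotune")` with
`run`, `generate`, `segment`, `tune`, `rfmap` and `ffi` subcommands.

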