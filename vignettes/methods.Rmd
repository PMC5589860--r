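---
title: "Models and methods behind enigo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind enigo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`enigo` implements a complete electrical-neuroimaging analysis chain for
two-group Go/NoGo ERP experiments — behavioral signal-detection statistics,
mass-univariate sensor statistics with sustained-effect criteria, and
distributed source estimation with cluster-extent correction — together with
a synthetic-data generator that emulates the class of study the chain is
designed for: two instruction groups (standard instructions, SI, vs
implementation intentions, II), twelve 60-trial blocks with 30 Go and 30
NoGo trials each, 64-channel EEG at 1024 Hz, and epochs from 100 ms before
to 500 ms after stimulus onset. This vignette documents the models, the
tunable parameters, the numerical choices, and what the synthetic world
does and does not establish.

## 1. The task simulator

`generate_schedule()` produces the block structure: blocks come in pairs
sharing a NoGo criterion, alternating letter-based and color-based pairs,
with per-block random Go/NoGo orderings. Only the criterion label is kept;
individual letter/color tokens never enter any analysis, so they are not
modeled.

`simulate_behavior()` draws Go reaction times from an ex-Gaussian
distribution (normal component of SD `rt_sd` = 20 ms plus an exponential
tail of mean `rt_tau` = 55 ms, truncated at a 100 ms floor). The
ex-Gaussian is the standard empirical RT model, and at these parameters
the classical "discard beyond 2 SD from the subject mean" rule removes
about 4.7% of trials, matching the few-percent removal rates typical of
speeded Go/NoGo data. Misses occur with probability `miss_prob` (default
0.02; hit/miss rates are a free choice of the generator since they are not
otherwise constrained) and false alarms with `fa_prob`; FA reaction times
reuse the Go model shifted 30 ms earlier — only the outcome label matters
downstream.

The adaptive response-time threshold (RTt) is reproduced exactly: 380 ms
in block 1, then 90% of the preceding block's mean responded-Go RT;
responses above threshold are flagged `too_late` but remain hits.

`group_profiles()` states the emulated world: SI subjects average ~23%
false alarms and ~337 ms Go RT in the first four blocks (BEG), II subjects
~16% and ~357 ms, with SDs of 11.3/6.8 percentage points and ~30 ms; the
faster SI group speeds up more with practice (−3.5 vs −0.9 ms/block). Two
calibration details are folded in *a priori*: (i) the targets are
post-outlier-rejection means, and trimming an ex-Gaussian at 2 SD lowers
the mean by ≈8.5 ms, so raw means are offset accordingly; (ii)
between-subject variability is injected by drawing each subject's
`rt_mean` and `fa_prob` around the group means (`fa_prob` truncated to
[0.005, 0.95]).

## 2. The EEG generator

Each correct trial yields one epoch built from four ingredients
(`eeg_sim_config()`):

* **Canonical components.** An N2-like fronto-central negativity
  (Gaussian time course centered at 200 ms, SD 25 ms, −4 µV) and a
  P3-like centro-parietal positivity (350 ms, SD 45 ms, +6 µV), projected
  through the head model from single radial dipoles, slightly larger for
  correct rejections (×1.3 / ×1.15), with subject-level amplitude jitter
  (SD 0.2 of the multiplier). These give the data a realistic ERP skeleton
  and a within-factor main effect without touching the interactions.
* **The planted effect.** A compact superficial patch of source nodes
  (right parieto-occipital by default, `default_effect_nodes()`) active
  during 218–245 ms with a Hann time course, added only to the configured
  design cell (II × CR by default, optionally restricted to blocks).
  `effect_amplitude` is calibrated at the scalp — the pattern is scaled so
  its peak deflection equals this many microvolts — because source-moment
  units are not comparable across stand-in head geometries. The default of
  4 µV peak (≈1.7 µV averaged over the window at the peak electrode) is in
  the range of robust group-level Go/NoGo ERP modulations and makes the
  planted interaction recoverable end-to-end in this world; weaker
  settings let users study power.
* **Correlated noise.** Forty random source-grid dipoles per subject are
  projected to the scalp and driven by independent 1/f (pink) time series,
  spectrally shaped by a 40 Hz second-order low-pass so the synthetic
  epochs mimic recordings that were already band-limited the way the
  analysis chain expects. Channel RMS is `pink_sd` = 7 µV.
* **Sensor noise and artifacts.** White noise of 3 µV per sample; with
  probability 0.2 an epoch receives a 120 µV transient (guaranteeing
  rejection at the ±80 µV criterion, producing realistic ~20–30% rejection
  rates); with probability 0.03 a subject has one corrupted channel,
  which is excluded from the rejection criterion and interpolated after
  averaging, as in practice.

`simulate_null_erps()` generates subject-level ERPs directly (noise scaled
by `1/sqrt(n_epochs)`), exploiting the linearity of averaging; this is
what makes 500-replicate calibration experiments affordable, and is exact
for every noise ingredient (only artifacts and trial-count variation are
absent from that shortcut).

## 3. Behavioral statistics

All estimators are closed-form and oracle-tested to 1e-10: pooled and
Welch/Satterthwaite t tests (from summaries or raw samples), the 2×2
split-plot ANOVA (Type-III / unweighted-marginal sums of squares, which
coincide with the classical decomposition for balanced groups; with two
within levels sphericity is automatic), mean-centered Levene tests,
Pearson speed–accuracy correlations with Holm–Bonferroni step-down, and a
Kolmogorov–Smirnov normality test with estimated parameters. For the
latter the nominal KS distribution would be anticonservative, so p-values
come from a Monte-Carlo (Lilliefors-style) null; the null table is
reusable across calls via `lilliefors_null()`.

Signal detection follows d′ = z(hit) − z(fa) with the 1/(2N) boundary
correction. The criterion is computed as printed in the source formula,
C = (z(hit) + z(fa))/2; because published tables are sometimes
inconsistent with that formula's sign for plausible rates, a
`c_sign = "standard"` switch returns the negated (conventional) value.
Neither sign is asserted as ground truth. d′/C are computed from rates
aggregated over each session's four blocks (not per-block averaged).

## 4. Preprocessing

Second-order Butterworth filters are designed by bilinear transform with
prewarped cutoffs (0.1 Hz high-pass, 40 Hz low-pass, 48–52 Hz band-stop
notch) and applied forward–backward. Zero-phase filtering is a choice the
original acquisition chain leaves open; it preserves peak latencies (the
property the tests check) at the cost of squaring the magnitude response,
which is documented rather than hidden. Epochs follow a half-open sample
convention — sample *j* covers `[t0 + (j−1)/fs, t0 + j/fs)` — so a
(−100, 500) ms window at 1024 Hz holds exactly 614 samples and the
218–245 ms period 28 frames. Baseline subtraction is off by default (the
emulated chain does not state it) and available as a flag.

Artifact rejection removes epochs with any sample strictly exceeding
80 µV. Trial counts are matched per block *before* rejection (the first
*n* epochs in presentation order are kept, *n* the smaller condition's
count), so final per-condition counts still differ — which is why the
epoch-count control ANOVA (`epoch_count_control()`) exists. Bad channels
are input metadata (from the generator or the user), not auto-detected;
they are interpolated on the averaged ERP with Perrin-style spherical
splines (order m = 4, 7 Legendre terms). With 64 electrodes the 7-term
expansion is borderline rank-deficient, so a 1e-6 ridge stabilizes the
spline system; smooth-field reconstruction error stays below 5%.

## 5. Sensor-space mass-univariate statistics

`pointwise_interaction()` runs the 2×2 mixed ANOVA at every electrode ×
time frame (vectorized closed forms, identical to the scalar routine).
A frame is *marked* when at least `ceiling(0.10 × 64) = 7` electrodes are
significant at α = 0.05; maximal runs of marked frames at least
`min_frames` long become sustained periods. The duration criterion is
defined as a duration (≈10.7 ms, i.e. 11 frames at 1024 Hz) so it scales
correctly when tests run at reduced sampling rates.

`permutation_duration_threshold()` calibrates `min_frames`: group labels
are permuted between subjects (the exchangeable units under the
no-group-effect null, respecting within-subject pairing), the marked
sequence is recomputed, and the criterion is the 95th percentile of null
maximum run lengths plus one frame (ties round up). White-noise inputs
yield thresholds ≤4 frames; low-pass-filtered noise yields strictly
larger ones.

**A property users should know.** The fixed 7-electrode/11-frame criterion
cannot control the family-wise error at 0.05 under temporally smooth
noise: even with 64 *independent* electrodes, P(≥7 significant at a fixed
frame) ≈ 0.046, and band-limited noise keeps the marked state for longer
than 11 frames, so the per-epoch family-wise rate approaches 1 (measured
≈0.93 at the generator defaults). This matches the criterion's original
billing as sensitive rather than specific: it localizes *when* an effect
occurs, while specificity is delegated to the source-level cluster
correction and, in this package, to the permutation calibration — with the
calibrated `min_frames` the measured family-wise rate is 0.05. The
calibrated criterion is opt-in (`calibrate = TRUE` in the run
configuration) because the fixed numbers are the documented defaults of
the emulated chain.

## 6. Head model and source grid

The source space is a cubic 6-mm grid clipped to a spherical shell. The
outer radius is fixed at 0.80 × 85 mm and the inner radius is tuned by
bisection until the node count is within 10% of the 3005-node target; the
result (2972 nodes between 54 and 68 mm) is a cortex-like crust. An
anatomy-accurate gray-matter mask would require MRI data that a synthetic
world cannot supply, so all node "labels" are geometric coordinates. At
8.5 mm connection radius the grid's neighborhood is the 18-neighborhood
(face + edge neighbors; the 10.39 mm corner diagonal is excluded).

The forward model is the classical concentric-spheres solution: the
dipole potential is expanded in Legendre polynomials, each degree is
propagated through brain/skull/scalp shells (radii 0.87/0.92/1.00 of
85 mm, conductivities 0.33/0.0041/0.33 S/m — the conventional 1 : 1/80 : 1
ratio) by solving a small boundary-condition system with row/column
equilibration, and the series is truncated at a 1e-6 geometric tolerance
(~160 terms for the most superficial nodes). Gains are average-referenced
by construction. The homogeneous limit reproduces the textbook
(2n+1)/n series to 1e-4, central radial dipoles give axially symmetric
topographies, and deeper sources produce lower-norm, smoother maps. The
montage is a synthetic 64-channel 10-10-style cap generated from a
documented ring construction (`make_montage_64()`), shipped as
`extdata/montage64_synthetic.sfp`; it is *not* a measured coordinate set.

## 7. LAURA inverse

The inverse is a weighted minimum norm. Neighbor weights fall off with
inverse squared distance (exponent configurable; 2 is the potential-field
law, 3 the vector-field convention) within the 26-cell neighborhood, rows
are normalized, and the constraint matrix is `W = I − ρA` with ρ = 0.95.
With ρ = 1 exactly (a literal "source equals neighbor average"
constraint) `W` annihilates constant fields and `WᵀW` is singular; ρ
slightly below 1 restores strict diagonal dominance while keeping the
local autoregressive-average reading. The metric `M = (WᵀW)⁻¹` is applied
identically per moment component (no orientation coupling), and the
kernel is `K = M Lᵀ (L M Lᵀ + λI)⁻¹` with the deterministic SNR rule
λ = trace(L M Lᵀ)/(64 × SNR²), SNR = 3. Scalar current density is the
moment-vector norm per node.

On the noiseless single-dipole battery the median peak-localization error
is ~10 mm for superficial sources beneath the sensor array (≤20 mm is the
documented accuracy of this class of inverse at 64 channels), grows with
sensor noise, and LAURA beats the unweighted minimum norm for deep
sources — the property that motivates the neighborhood constraint. The
battery excludes sources below the electrode cap: with no sensors
underneath, inferior sources are geometrically unconstrained in a
spherical stand-in (errors there reach 40–60 mm), which is a property of
the coverage, not of the estimator.

## 8. Source statistics and cluster calibration

`nodewise_interaction()` applies the same 2×2 design to per-node current
densities. Clusters are connected components of `p < 0.05` nodes at
8.5 mm connectivity, kept when they reach the spatial-extent criterion
k_E ≥ 15. The Monte-Carlo calibration draws white node noise, smooths it
with a 6-mm-FWHM Gaussian distance kernel (rows scaled to unit L2 norm,
so smoothed values are exactly standard normal — the re-standardization
that makes the voxel threshold well-defined), thresholds two-sided at
α = 0.05, and records maximum cluster sizes. On this grid
P(max cluster > 15) ≈ 5e-4 < 0.005 at 2000 iterations; with no smoothing
the calibrated extent collapses to ≤4 nodes, and it grows monotonically
with FWHM. Two-sided thresholding on z is the convention of this
calibration even though the F maps are one-sided; the achieved false-positive
probability is what the acceptance check verifies at the fixed k = 15.

Note that LAURA current-density maps are much smoother than a 6-mm-FWHM
field, so k_E = 15 does **not** control node-wise false positives for
direct inverse outputs; in the full pipeline specificity comes from the
sensor-space gate (sources are only analyzed inside detected sensor
periods).

## 9. Pipeline and reproducibility

`run_all()` chains the stages with one seed: simulate behavior →
behavioral battery (Welch replaces the pooled t when Levene's p < 0.05,
mirroring the emulated analysis) → head model → per-subject epoch
simulation, matching, rejection, averaging, interpolation → epoch-count
control ANOVAs → interaction maps and sustained periods for Group ×
Stimulus (BEG) and Group × Session (CR) → a source analysis per detected
period. Every stochastic stage receives a seed derived from the run seed,
so the full report is a pure function of (configuration, seed); reruns
produce byte-identical artifacts. Configurations are JSON (the
environment provides no YAML parser); epoch containers are in-memory
arrays with TSV/JSON serialization (no HDF5 library in the target
environment, and the deliverable is text-only).

## 10. What a green test establishes — and what it does not

The synthetic world reproduces the *statistical structure* the analysis
assumes: group-dependent behavioral magnitudes, an adaptive threshold,
band-limited spatially correlated EEG noise with realistic amplitudes and
rejection rates, a plantable interaction, and a spherical stand-in head
model. It does not emulate real anatomy (no MRI, no gray-matter mask, no
anatomical labels), real artifact physics (no ocular ICA), electrode
bridging, or reference-electrode idiosyncrasies; data-dependent published
quantities (exact sustained windows, MNI peak coordinates, specific F
values) are properties of real recordings and are deliberately not
reproduction targets. Green tests establish internal correctness
(estimators match oracles; procedures are calibrated in their own world),
not external fidelity to any particular dataset.

## Known limitations

* The LAURA weight construction approximates the published description of
  the regularization; the reference implementation's exact normalization
  is not public, so ρ, the falloff exponent, and the SNR rule are
  documented knobs rather than faithful copies.
* The spherical montage and head model make localization results
  geometric, not anatomical.
* The Monte-Carlo cluster calibration smooths over node distances, an
  approximation of volume-based smoothing on an irregular node set.
* `simulate_eeg()` at full scale holds all epochs of all subjects in
  memory; batch pipelines should simulate and average per subject (as
  `run_all()` does).
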