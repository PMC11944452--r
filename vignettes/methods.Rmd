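---
title: "Predicting GC-MS composition from TGA and FT-IR: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting GC-MS composition from TGA and FT-IR: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lignocomp` estimates the group composition of hydrothermally depolymerized
lignin from two inexpensive measurements: a TGA thermogram and an FT-IR
transmittance spectrum. This vignette explains the models, the tunable
parameters, what the bundled simulator does and does not emulate, and the
design decisions taken where the procedure was genuinely open.

## Data model

One HTL condition contributes a *sample triplet*:

* a thermogram resampled to 1 °C bins over 40–760 °C (721 values, % mass);
* a 3476-point preprocessed FT-IR vector on the fixed wavenumber grid
  649.8934–4000.6047 cm⁻¹;
* a composition on the 10-simplex: nine compound groups plus an "Other"
  class that absorbs mass undetected by GC-MS.

All tabular I/O is plain CSV (UTF-8, dot decimal, one header row) with a
JSON manifest; numbers are written at 17 significant digits so write→read
round-trips are exact to double precision.

## Preprocessing

**TGA.** Points outside the 40–760 °C window are discarded and the value at
integer temperature *t* is the arithmetic mean of raw mass over the
centered bin [*t* − 0.5, *t* + 0.5). Centered bins make each bin value an
unbiased local mean; the procedure is idempotent on already-binned data.
Bins left empty by sparse scans are filled by linear interpolation between
their non-empty neighbours — dense instrument exports never need this, but
robustness on degraded inputs does. A scan qualifies if it reaches within
half a bin of both window edges, since real scans can start slightly above
40 °C. The information lost by binning is audited as the Wasserstein-1
distance between the raw and resampled mass-fraction distributions; on
noiseless simulated scans it is on the order of 10⁻³–10⁻⁴.

**FT-IR.** Replicates are averaged per wavenumber, clipped at 100 %
(instrument noise can push recorded transmittance slightly above 100 %),
subtracted from 101, floored at 10⁻⁶ and log-transformed. The clip
guarantees the log argument is ≥ 1, so outputs lie in [0, log₁₀ 101]. Two
choices deserve note: the logarithm base is not dictated by the transform
itself; base 10 is used because transmittance/absorbance conventions are
decimal, and the base is configurable. The 10⁻⁶ floor is unreachable after
clipping (101 − min(·, 100) ≥ 1) but is retained verbatim rather than
simplified away, so the configured transform is exactly the documented one.

**GC-MS.** Group fractions are the sums of *detected* derivative
percentages divided by 100; undetected compounds contribute nothing and are
the source of the "Other" class, which closes the composition to exactly 1.

## Conditional generators

Each modality has a decoder-style 1-D CNN that maps the scalar normalized
condition τ = (T − 250)/150 — anchors at 250/300/350/400 °C map to 0, ⅓,
⅔, 1 — to a full modality vector:

* TGA: Conv(1→16)+ReLU, Conv(16→32)+ReLU, Flatten, Linear(32→1024)+ReLU,
  Linear(1024→721);
* FT-IR: three conv blocks (16/32/64), Flatten, Linear(64→1024)+ReLU,
  Dropout 0.3, Linear(1024→3476);
* GC-MS: three 64-channel conv blocks, global average pooling,
  Linear(64→128)+ReLU, Linear(128→10), softmax.

All convolutions use kernel 3, stride 1, padding 1. The conditioning input
is deterministic (no noise channel) because one dataset is generated per
temperature; its length of 1 is forced by the FT-IR head's 64 × 1 flatten
width. Targets are scaled so that squared-error magnitudes are comparable
across modalities: TGA mass is divided by 100, FT-IR log-absorbance values
are used as-is, compositions are already on [0, 1].

Training uses Adam (initial learning rate 0.001), a step schedule that
multiplies the rate by 0.1 after 75 epochs, batch size 32 and 100 epochs.
With four anchor pairs each epoch is a single saturated batch. Weight
initialization is He-scaled and seeded; a fixed seed reproduces the loss
trajectory bit for bit.

## The MVAE–MoE predictor

Two convolutional encoders (channels 16/32, average pooling by 4 after each
block, a 256-wide dense layer) map the TGA and FT-IR vectors to
diagonal-Gaussian posteriors (μ, log σ²) over a 16-dimensional latent
space. The posteriors are fused by a product of experts that includes a
standard-normal prior expert: precisions add, the fused mean is the
precision-weighted mean. A latent sample z = μ + σ ⊙ ε (reparameterization
trick) feeds two reconstruction decoders (mirroring the generator heads,
including the FT-IR dropout) and a mixture-of-experts head: a gating
network (softmax over 4 experts) convexly combines softmax experts
(16→64→10), so every prediction is on the simplex by construction.

The composite loss is the unweighted sum

L = L_recon^TGA + L_recon^FTIR + L_pred + L_KL,

where the squared-error terms are summed over each sample's vector elements
and averaged over the batch, and L_KL = −½ Σ (1 + log σ² − μ² − σ²) is
summed over latent dimensions and averaged over the batch, on the *fused*
posterior. The per-sample-sum convention matters: it keeps the
reconstruction terms (721- and 3476-dimensional) dominant over the KL term,
which is what lets the latent stay informative on a 10-sample training set.
Under a per-element-mean convention the KL term outweighs the data terms by
three orders of magnitude and the posterior collapses to the prior within
the 100-epoch regime.

Three further choices address the tiny-data setting:

* **Input standardization.** Modality vectors share most of their shape
  across conditions; the between-condition contrast that carries the signal
  is two orders of magnitude smaller than the common profile. Encoders
  therefore standardize each input element by the training-set mean and a
  floored standard deviation (floor: 5 % of the largest element SD, to
  avoid amplifying flat regions). Decoders invert the transform, so
  reconstruction targets are the standardized vectors and the decoder's
  zero output corresponds to the training mean profile.
* **Base-rate initialization.** Every expert's final-layer bias starts at
  the (centered) log of the mean training composition, so the mixture opens
  at the best constant prediction and training spends its 100 steps
  learning condition-dependent deviations.
* **Posterior-head initialization.** The μ head uses He-scaled weights (the
  latent inherits input contrast immediately); the log σ² head starts near
  zero weights, i.e. near-unit expert variances.

Inference is deterministic: both modalities are encoded, fused, and the
fused mean (not a sample) drives the mixture head. The model always
receives both modalities; modality dropout at the fusion stage is out of
scope.

Defaults held fixed and exposed in `mvae_moe_config()`: latent_dim 16,
4 experts (hidden 64), gating hidden 32, encoder hidden 256 — small,
because ten training samples cannot support more capacity.

## The simulator

`simulate_study()` generates study-like raw data at any condition in
[240, 410] °C and returns a noiseless oracle for evaluation:

* **TGA**: 100 % minus three logistic mass-loss steps (moisture ≈ 3 % near
  80 °C; main devolatilization ≈ 36 % near 335 °C, drifting with τ; slow
  char ≈ 16 % near 550 °C) above a ≈ 45 % residue plateau, sampled every
  0.034 °C (≈ 22,000 points) with Gaussian point noise (SD 0.05 %) and a
  seeded sub-degree start/end jitter mimicking run-to-run variability. Step
  amplitudes are tied so they sum to 100 − residue at every τ, which keeps
  the noiseless curve non-increasing.
* **FT-IR**: a 98.5 % baseline minus Gaussian dips at 3400 (O–H), 2930
  (C–H), 1730 (C=O), 1600/1510 (aromatic skeletal), 1215 and 1030 cm⁻¹,
  with depths linear in τ (carbonyl grows, O–H and aromatic bands shrink
  with severity). Three replicates share the noiseless spectrum and differ
  by a baseline offset (SD 0.5 %), point noise (SD 0.3 %) and sparse
  outlier spikes — so a few recorded points exceed 100 % transmittance, as
  in real exports, exercising the preprocessing clip.
* **GC-MS**: nine group fractions follow a softmax of quadratic-in-τ
  logits (syringyl/guaiacyl decline with severity, alkanes, fatty acids and
  glycerol-derived compounds rise, polycyclic aromatics peak mid-range),
  split over 114 compound rows by fixed geometric within-group weights. The
  undetected fraction varies smoothly inside (0.08, 0.14) across τ; a
  seeded subset of rows is flagged undetected and the detected remainder is
  renormalized per group, so detected totals land in 86–92 % and the oracle
  composition is exact.

Noise magnitudes are artifact choices (the source study does not describe
its noise distributions) and are exposed as parameters. The simulator does
**not** emulate calibrated decomposition kinetics, baseline drift or
scatter in FT-IR, mass-spectral fragmentation, or inter-batch effects —
passing tests demonstrate that the pipeline recovers structure of this
smooth, low-noise kind, not instrument-grade robustness on real lab data.

## Evaluation protocol

Conditions without measurements are scored against linear interpolation
between the two nearest bracketing anchors (260 and 280 °C against
250/300; 315 and 345 against 300/350; 365 and 390 against 350/400).
Curve metrics treat each vector element as one observation. The Pearson
correlation uses population moments in numerator and denominator (the ratio
is convention-invariant). R² may be negative when a prediction does worse
than the reference mean. Wasserstein-1 between 1-D empirical distributions
is the mean absolute difference of sorted samples at equal sizes and the
integral of the absolute ECDF difference otherwise. The simulator oracle is
available as a stronger reference mode than interpolation; the package's
baseline comparison (`compare_to_baselines()`) scores the predictor against
the oracle next to a constant mean-composition baseline and the
interpolation baseline.

One caveat is inherited from the study design: the default workflow
evaluates predictions at the same six conditions the generators synthesized
for training. The test suite therefore also scores the predictor at six
conditions held out of all training (265/290/320/340/370/385 °C), which is
the honest generalization check.

## Numerical choices and degenerate inputs

* Problem sizes: the bundled experiments use 4 anchors, 6 generated
  conditions, 721/3476/10-dimensional vectors and the full 100-epoch
  regime; unit tests use reduced epochs since they check mechanics, not
  quality.
* Metric guards: R² requires a non-constant reference; Pearson requires
  both vectors non-constant; interpolation refuses extrapolation and
  degenerate intervals; all failures are named errors, not NaNs.
* Composition closure tolerances: constructors accept sums within 10⁻⁶ of
  1; simulator and aggregation produce closure exact to ~10⁻¹².
* Ties in the gating/softmax need no special handling (softmax is smooth);
  empty batches, missing generators and untrained models raise state
  errors.
* Seeds: every stochastic step (simulation noise, weight init, shuffling,
  dropout, reparameterization draws) flows from an explicit integer seed;
  the workflow derives per-stage seeds from a global seed by a fixed affine
  scheme (`stage_seed()`), keeping all seeds below 2³¹.

## Known limitations

* With four anchors the generators are smooth interpolators in τ; they
  cannot reveal sharper-than-linear composition changes between anchors,
  and the interpolation references share the same blindness.
* The 100-step optimization budget means results depend visibly on
  initialization; three seeds are used wherever a claim rests on training.
* Compositions are treated in the Euclidean geometry of the simplex (MSE,
  MAE), not in log-ratio geometry; with fractions spanning two orders of
  magnitude a compositional-data treatment could weight small groups
  differently.
* Per-compound (114-dimensional) prediction, attention-based variants and
  transfer to other biomass types are out of scope.
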