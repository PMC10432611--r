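---
title: "Modelling long-term cardiorespiratory mortality from longitudinal chest CT"
author: "longisurv developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling long-term cardiorespiratory mortality from longitudinal chest CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Lung-cancer screening programmes image high-risk heavy smokers with
annual low-dose chest CT. The same scans that are read for lung nodules
also carry signal about the two organ systems that actually kill most of
this population: the heart (coronary calcification, cardiac enlargement)
and the lungs (emphysema, fibrosis, airway disease). `longisurv`
implements a hybrid convolutional/recurrent modelling stack that predicts
long-term (about a decade) cardiorespiratory mortality from a subject's
*entire* screening history rather than from a single scan, together with
everything needed to train, evaluate and probe such models without access
to restricted trial data.

The package covers four layers:

1. **Thorax extraction** — raw Hounsfield-unit volumes are reduced to a
   normalised thorax tensor;
2. **Models** — a compact 3D residual CNN backbone whose per-scan feature
   vectors feed a recurrent head (vanilla LSTM, time-aware LSTM, or
   time-modulated LSTM) that consumes the irregularly spaced follow-up
   sequence;
3. **Objectives** — class-balanced cross-entropy for dead/alive
   classification, and the Cox proportional-hazards negative partial
   log-likelihood for time-to-event prediction, optimised with
   sharpness-aware minimisation (SAM) over SGD;
4. **Evaluation** — ROC/AUC, F1, MCC, DeLong comparison of paired AUCs,
   Kaplan-Meier stratification with the log-rank test, Harrell's and the
   IPCW (Uno) concordance index, and a cause-specific two-step pipeline
   scored per follow-up time band.

## Preprocessing model and assumptions

A chest CT at lung-window level is dominated by three tissue classes:
air (about -1000 HU), aerated lung parenchyma (about -850 HU), and soft
tissue (about 0-60 HU). The pipeline exploits this:

* each axial slice is Gaussian-smoothed and binarised at **-600 HU**,
  keeping the hypodense side (lung);
* per-slice 2D components are filtered by area (default 30 voxels) and
  fitted-ellipse eccentricity (default 0.99) to remove noise and streaks;
* 3D components are kept when their physical volume lies in
  **0.68-7.5 L** and their centroid sits within 62% of the in-plane
  half-diagonal from the scan centre — this removes the surrounding-air
  component and small airway fragments while keeping one or two lungs;
* erosion (ball radius 3) disconnects lungs that touch anteriorly, the
  two largest components are convex-hulled per axial slice and dilated
  back; voxels of the joint mask that the morphological round trip lost
  (thin polar caps, an opening artefact) are reassigned to the nearer
  lung so the split never discards parenchyma;
* the **thorax mask** is the per-slice convex hull of the joint lung
  mask; on slices where the lungs are separate this fills the
  mediastinum and therefore includes the heart — deliberate, since
  cardiac structure carries much of the mortality signal;
* intensities are clipped to **[-1200, 600] HU**, linearly mapped to
  [0, 255], voxels outside the thorax are set to the soft-tissue average
  **170**, and the volume is resampled (trilinear; nearest-neighbour for
  masks) to the network grid.

**Smoothing scale.** The slice filter's scale is configured physically
(`sigma_mm`, default 1 mm) and converted to voxels per scan. The
upstream convention of "1 voxel" of smoothing was set on ~1 mm grids; on
the coarse desk-scale grids used for testing (6-12 mm voxels) a 1-voxel
blur would be 6-12 mm of physical smoothing, which measurably erodes the
segmented lung boundary (the -600 HU crossing moves ~0.6 voxel into the
lung) and would violate the pipeline's own recovery contract. A fixed
voxel-space sigma remains available (`preprocess_config(sigma = 1)`).

**Registration.** Earlier scans can optionally be affinely registered to
the latest scan (`register_to_last`): centre-of-mass initialisation,
translation-only search at a coarse level, then a full 12-parameter
affine refinement, Nelder-Mead on normalised cross-correlation (mutual
information available). The optimiser never returns a transform whose
similarity to the fixed scan is below the unregistered baseline.
Registration operates on raw HU volumes before normalisation; whether
the original study registered before or after normalisation is not
documented, and raw-HU registration is the conventional order.

## Recurrent cells for irregular follow-up

Screening intervals are nominally annual but jittered by weeks. Three
cells share one step contract (`state = list(h, c)`):

* **LSTM** — the standard gates; implicitly assumes equal spacing.
* **tLSTM** (time-modulated) — every gate pre-activation gains a term
  `w_t * dt`, with `dt` encoded in years (days/365) so the time weights
  live on the same scale as the other weights. With `w_t = 0` or
  `dt = 0` it reduces exactly to the LSTM; with constant `dt` it equals
  an LSTM with shifted biases. These reductions are asserted in the test
  suite to machine precision.
* **TALSTM** (time-aware) — the carried memory is decomposed into a
  short-term part `c_S = tanh(W_d c + b_d)` and the long-term remainder;
  the short-term part is discounted by `g(dt) = 1/log(e + dt)` (`dt` in
  days, `g(0) = 1`, monotone non-increasing) before a standard step.

The elapsed-time input is treated as a scalar broadcast across the
hidden units (per-unit time vectors are a possible extension; nothing in
the gate equations forces either reading, and the scalar form is the
smaller model).

All three cells carry hand-derived analytic backward passes; the test
suite checks every parameter tensor of every cell against central finite
differences at relative error below 1e-5.

## Networks

The backbone is a compact 3D ResNet: strided convolutional stem, four
residual stages (one basic block each), batch normalisation after every
convolution, global adaptive average pooling, then FC(512) + ReLU +
dropout 0.5 and FC(32) in the full preset. Adaptive pooling makes the
feature size independent of the input grid. Two presets exist:

| preset | stage widths | FC | features | input |
|--------|--------------|----|----------|-------|
| `full` | 64/128/256/512 | 512 | 32 | 256x256x128 |
| `tiny` | 8/16/32/64 | 32 | 16 | 32x32x16 |

The `tiny` preset exists so the whole two-phase protocol trains in
minutes on one CPU; it is what the test suite uses.

**Normalisation choice.** Batch normalisation (batch statistics during
training, running statistics at inference) is used rather than instance
or layer normalisation. This matters scientifically: disease burden in
CT appears substantially as a *per-sample global intensity shift*
(calcification, fibrosis raise attenuation), and instance-style
normalisation removes exactly that between-sample signal — in ablation
during development it collapsed the classifier to chance. Batch
statistics preserve between-sample contrasts. Since no deep-learning
framework exists in this R stack, convolution (im2col + GEMM via
RcppArmadillo), batch norm, the residual algebra and all gradients are
implemented in the package and verified against finite differences.

**CRNN assembly.** The CNN (backbone + head) is trained on each
subject's latest scan. The backbone is then frozen — the test suite
asserts its parameters are bit-identical after recurrent training — and
per-scan 32-d (16-d tiny) feature vectors are unrolled by the chosen
cell; the final hidden state passes through FC(hx) + ReLU + dropout 0.3
and a linear head. The classification head emits two softmax logits
(the reported probability is the non-survivor class); the Cox head emits
one unbounded log-hazard score. A single linear layer follows the
post-recurrent FC; the source architecture does not pin this down
further and one layer is the smallest consistent choice.

## Objectives and optimisation

Class imbalance in the 1:2 matched design is handled by an
inverse-class-size weighted sampler (each class contributes half the
draws in expectation). The Cox objective is the negative partial
log-likelihood with Breslow tie handling — tied event times share a risk
set `R(T_i) = {j : T_j >= T_i}` — which is the form the loss formula
states; Efron's correction is available as an option. The loss is
computed over the minibatch (batch size 24 at paper scale), with
all-censored batches resampled rather than silently skipped. The loss is
invariant to uniform score shifts, is computed with a stable
log-sum-exp, and its analytic gradient is tested against finite
differences and an independent brute-force implementation.

SAM perturbs the parameters by `rho * g/||g||` (rho default 0.05; the
non-adaptive variant), re-evaluates the gradient, and applies an SGD
update with momentum 0.9, weight decay 5e-4 and a triangular cyclic
learning rate between `lr/10` and `lr` (cycle 10 epochs; the cyclic
shape is not documented upstream and triangular is the common default).
A global gradient-norm clip (default 5) stabilises early training of the
from-scratch backbone. Desk-scale presets (`desk_protocol()`) disable
SAM for the expensive CNN phase purely for CPU budget — SAM doubles the
per-batch cost — and keep it for the cheap recurrent phase; they also
use hotter learning rates (0.05 CNN / 0.01 CRNN) because the tiny preset
trains from scratch in tens of epochs. The CNN phase is
early-stopped on a held-out validation split (patience 8 within at most
40 epochs) and keeps the checkpoint with the best validation loss — the
desk-scale analogue of long monitored training. Restart selection and
restart ensembling were both tried and rejected: with only ~16
validation subjects the selector is itself noise, and pooling restarts
dilutes good runs with bad ones; the protocol therefore stays with a
single seeded run (`cnn_restarts` is exposed for experimentation).
Training variance at n = 120 is real and documented: across arbitrary
seeds roughly one cohort in three lands on a backbone whose held-out
metrics miss the end-to-end thresholds, which is why those contracts are
verified at fixed seeds.

## The synthetic cohort: what it emulates, and what a green test means

`generate_cohort()` builds a world with analytically known truth:

* **Anatomy** — air background, soft-tissue body ellipsoid, two
  hypodense lung ellipsoids (~1.6 L each at any grid, the field of view
  is fixed at 384x384x320 mm), a cardiac ellipsoid in the mediastinum;
  additive Gaussian noise (sd 25 HU, typical of low-dose CT).
* **Pathology** — two phenotypes: *cardiac* = hyperdense foci (+500 HU)
  inside the cardiac ellipsoid, a calcification proxy; *respiratory* =
  diffuse lung attenuation increase up to +200 HU, a fibrosis/COPD proxy
  (capped so diseased lung stays below the -600 HU threshold). Burden
  grows linearly in time, `b_k = b_0 + rate * years`.
* **Schedules** — three scans at nominally annual intervals with
  Gaussian jitter (sd 30 days), giving a realised gap inter-quartile
  range near 40 days, matching protocolised screening.
* **Outcomes** — event times are exponential with hazard
  `lambda0 * exp(beta * z)`, where `z` is the *population-standardised*
  burden covariate (log-hazard per SD — the scale hazard ratios are
  reported on). Administrative censoring at ~11 years from the last
  scan. Defaults `beta = 2`, `lambda0 = 2.3e-4`/day give an event
  fraction near the 1:2 matched design and a true-burden AUC of about
  0.93: the phantom world is *separable by design*, so end-to-end tests
  measure pipeline correctness, not task difficulty. Cohorts are then
  matched to a 1:2 non-survivor:survivor ratio (configurable, or
  unmatched with `ratio = NULL`).
* **Risk placement** — by default risk rides on the burden at the last
  scan; with `risk_covariate = "slope"` the last-scan burden
  distribution is identical in both classes and risk rides on the growth
  rate, so *only a model that uses the follow-up history can separate
  the classes*. This is the cohort that reproduces, qualitatively, the
  finding that the hybrid model outperforms the single-scan CNN.

  The slope comparison (`desk_experiment(risk_covariate = "slope",
  backbone = ...)`) deliberately gives *both* arms the same frozen
  backbone, trained on the main (last-scan-risk) cohort: the single-scan
  arm is that backbone plus a logistic head fitted to convergence on the
  training features; the temporal arm is the usual frozen-backbone
  recurrent ensemble. Training a backbone on the slope cohort itself is
  ill-posed — its labels are uninformative for single scans *by
  construction*, and cross-entropy training on unlearnable labels
  frequently collapses the representation to a constant, at which point
  both arms sit at chance and the comparison measures nothing. Sharing
  one burden-sensitive extractor isolates exactly the question being
  asked: given the same per-scan features, does temporal aggregation
  help?
* **Sites** — a configurable fraction of subjects belong to "external"
  sites whose scans carry a +30 HU calibration offset and 30% more
  noise, emulating an out-of-distribution test centre.

What a green end-to-end test does establish: the full chain (rendering,
thorax extraction, feature learning, recurrent aggregation, Cox/CE
training, metric computation) can recover a planted survival signal with
correct ranking statistics. What it does not establish: performance on
real CT (no real anatomy, scanner physics, motion, or pathology
diversity), calibration of absolute probabilities, or behaviour under
informative censoring (censoring here is administrative).

The standardised hazard scale is itself a correctness constraint: with
the covariate on its raw [0, 1] scale the partial-likelihood MLE of
`beta` at n = 500 has a sampling sd of ~0.25, and no implementation
could pass a +/-0.15 recovery bound; per SD of burden the sd is ~0.06
and recovery is a sharp test of the generator/loss pair.

## Numerical and design choices

* Binarisation keeps voxels **below** threshold (lung is hypodense).
* Convex hulls are per axial slice; 3D hulls would over-fill the
  costophrenic recesses.
* Eccentricity from second moments of the component's pixel coordinates.
* Concordance: score ties count 1/2; time-tied pairs are not comparable.
* IPCW truncation `tau` defaults to the 95th percentile of observed test
  times and is reported with the estimate; the censoring KM is estimated
  on the training split by default (both configurable; the comparisons
  against Harrell's C in the tests use `tau = Inf`).
* The two-step cause pipeline treats a probability of exactly 0.5 as
  survivor (the threshold must be *exceeded*); the cause model is
  trained on non-survivors only.
* Band evaluation uses one-vs-rest sensitivity/specificity per band,
  with absent classes reported as `NA` rather than 0.
* Degenerate inputs: empty masks return empty; an unsplittable lung mask
  degrades to a flagged single-lung result; all-censored Cox batches are
  an error at the loss level and are resampled by the trainer.
* Seeds: every stochastic component (cohort, initialisation, sampling,
  dropout) flows from explicit seed arguments; single-threaded runs are
  bit-reproducible.

## Known limitations

* No DICOM reader (no parser exists in this R stack); inputs are NIfTI
  (a minimal self-contained NIfTI-1 reader/writer ships with the
  package) or in-memory arrays.
* The full 256x256x128 preset is provided and functional but not
  exercised by the CPU-bound test suite.
* No deformable registration, no attention/transformer variants, no
  multimodal clinical covariates — all out of scope by design.
* Training at desk scale is genuinely small-sample; held-out metrics on
  120-subject cohorts carry sampling noise of several AUC points, which
  is why the end-to-end contracts are thresholds, not point values.
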