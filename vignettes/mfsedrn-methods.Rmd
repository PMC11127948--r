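---
title: "Model and methods: multifeature SE-dilated residual networks for longitudinal AD prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfsedrn)
```

## The prediction problem

Alzheimer's disease progresses through a long prodromal stage (mild
cognitive impairment, MCI) during which intervention is most valuable. Two
longitudinal prediction tasks matter clinically: forecasting a patient's
cognitive scores (MMSE, on 0–30 where lower is worse; ADAS-11, on 0–70
where higher is worse) at 6, 12, 24 and 36 months from baseline data, and
predicting whether an MCI patient will convert to AD (progressive MCI,
pMCI) within 12, 24 or 36 months.

The model in this package attacks both tasks with a single multimodal
architecture: a 3D convolutional network over structural MRI combined with
a tabular vector of baseline clinical scores (MMSE, ADAS-11, CDRSB, RAVLT
immediate), genetics (ApoE4 allele count) and fluid biomarkers (Aβ42/Aβ40
ratio, t-tau, p-tau).

## The architecture

Three bespoke operators distinguish the network from a plain 3D residual
network.

**Multifusion pooling (MF-Pool).** Each pooling layer computes both a max
pool and an average pool over the same window and stride and returns their
elementwise mean,

$$Y = \tfrac{1}{2}\,(Y_{\max} + Y_{\mathrm{avg}}),$$

retaining the strongest local response (sensitive to focal atrophy) and
the local average (robust to noise) simultaneously. We extend the window
to three spatial axes $(k_d, k_h, k_\omega)$, the two-axis form being the
$k_d = 1$ special case. Pooling uses floor division for output extents,
and padded cells never enter a window: the max is over covered cells only
and the average divisor is the covered-cell count.

**Dilated residual blocks with squeeze-and-excitation (SE-DRB).** Each
block is

Conv(3³, dilated, rate 2) → BN → ReLU → Conv(3³) → BN → SE → (+ shortcut) → ReLU.

The dilated first convolution has effective kernel
$k' = k + (k-1)(d-1) = 5$ at $k = 3, d = 2$, so one block grows the
receptive field from 1 to 7 voxels while keeping the parameter count of a
3³ kernel. Padding is $d(k-1)/2$, so dilation never changes shapes. The
squeeze-and-excitation stage global-average-pools each channel, passes the
channel vector through a bottleneck (fully connected to $C/r$, ReLU, fully
connected back, sigmoid) and rescales the channels by the resulting
weights in $(0,1)$. The bottleneck ratio is $r = 16$ by default — the
standard squeeze-and-excitation choice, configurable because slim test
models need smaller widths. The shortcut is the identity when shapes
agree and a 1×1×1 projection convolution otherwise.

**Multifeature fusion.** After the trunk, a global MF-Pool (mean of the
global max and global average per channel) reduces the image pathway to a
fixed-length vector, which is concatenated with the z-scored tabular
vector and passed through a fully connected layer with an ELU activation
into the task head (one output for score regression; two logits for
conversion classification).

The default assembly is a 7×7×7 stem convolution (stride 2), a 3×3×3
MF-Pool (stride 2, padding 1), sixteen SE-DRBs in four stages, the global
MF-Pool and the fusion layer. Counting the stem, the 32 block
convolutions, the two MF-Pools and the fusion layer gives the 36-layer
census that `layer_census()` reports; batch normalization, activations,
SE bottleneck layers, projection shortcuts and the head are tallied
separately in its `aux` field. The stage plan (3/4/6/3 blocks at widths
64/128/256/512) is the conventional residual-network layout consistent
with 16 blocks; it is fully configurable, and tests use slim variants
(e.g. widths 8/16/32/64 with one block per stage) for speed.

```{r census}
layer_census(model_config())
```

### Ablation variants

Five ablation groups are built into the configuration: removing dilation
(`d = 1`), removing the SE stages, replacing MF-Pool with max pooling
only, removing the tabular fusion branch, and the triple ablation of the
first three. `run_ablation_suite()` runs all five plus the full model on
identical folds, which makes the comparison controlled: any difference
between rows is attributable to the architecture, not the split.

## Training

The engine is written in R with compiled direct convolution and pooling
kernels (batch-contiguous inner loops, no im2col intermediates), and
backpropagation is hand-derived per layer (it is verified against finite
differences in the test suite). Optimization is Adam at learning rate 1e-4 with L1 and L2
penalties on the convolution and fully connected weight matrices
(defaults 1e-5 and 1e-4; the recipe names both penalties but not their
coefficients, so these are configurable). Score regression trains for 150
rounds with batch size 8 under mean-square error; conversion
classification trains for 100 rounds with batch size 4 under
cross-entropy. Evaluation uses five-fold cross-validation with repeated
random sampling; splits are stratified by label for classification. The
repeat count is configurable (default 1). There is no early stopping:
final-epoch weights are evaluated.

Tabular features are z-scored with training-fold statistics only, and the
statistics are reused verbatim on the held-out fold — a leakage mutation
test asserts that altering held-out values cannot change the applied
statistics. Whether a cross-validated metric should be pooled over all
validation predictions or averaged across folds is a genuine ambiguity;
the package emits both (`glance()` reports the pooled value, `tidy()` the
per-fold values). Pooled ROC statistics mix fold models whose probability
calibrations differ, which biases pooled AUC below the fold-mean AUC for
lightly trained models; `run_experiment()` therefore applies a logistic
(Platt) recalibration of each fold's scores by default, fitted on the
training fold only. The transform is monotone — per-fold ranking metrics
are unchanged — and only aligns the probability scales across folds so
the pooled ROC mixes comparable scores.

## Preprocessing

Registration, skull stripping and tissue segmentation belong to external
anatomical pipelines and are out of scope. The in-scope image enhancement
is a three-stage intensity pipeline, each stage independently toggleable:
histogram equalization towards a uniform CDF (256 bins) computed over
brain-mask voxels, isotropic Gaussian smoothing (σ = 0.5 voxel), and a
monotone nonlinear rescale. The named stage families come without
parameters or functional forms, so each default is the simplest member of
its class; in particular the "nonlinear transformation" is implemented as
a gamma curve, which is our stand-in. A constant image is defined to pass
through unchanged (equalization of a degenerate histogram is the
identity, and rescaling guards against amplifying floating-point dust).

## The synthetic cohort

Real data for this problem is access-controlled, so the package ships a
fully synthetic generator that emulates a realistic cohort structure: 138
normal controls, 238 MCI and 111 AD subjects by default (487 in total).
Everything derives from a latent per-subject severity $s$ on a 0–10
scale, drawn from per-group truncated normals (means 1/3/6, SDs
0.8/1.2/1.5) that overlap deliberately so classification is non-trivial.

**Tabular features.** Within each group, a feature with configured mean
$\mu$, SD $\sigma$ and severity correlation $\lambda$ is generated as
$\mathrm{clip}(\mu^* + \sigma(\lambda Z_s + \sqrt{1-\lambda^2}\,Z_\varepsilon))$,
where $Z_s$ is the standardized within-group severity. Because clinical
scores live on bounded scales, the reported group means are means of
*bounded* values; the generator therefore solves for the pre-clip
location $\mu^*$ by exact quadrature (truncated-normal severity mixed
with Gaussian noise, closed-form inner clipped mean) so that the realized
clipped mean equals the configured mean. At $n = 10{,}000$ the group
means land within sampling error of their targets. SDs are matched on the
pre-clip scale and are therefore only approximate where a bound is close
(CDRSB in controls, whose configured mean of 0.03 sits essentially on the
floor). ApoE4 allele counts come from an ordered-logit link on severity;
biomarkers are lognormal with severity-linked location. These biomarker
and genetic links are qualitative, directionally matching AD biology, and
claim no distributional realism.

**Volumes.** Each phantom is an ellipsoidal "brain" of tissue-like
intensity bands containing a bright focal sub-region (two small spheres
standing in for the medial-temporal structures that atrophy earliest).
The sub-region keeps $\mathrm{round}(B(1-\beta \tilde s))$ of its $B$
baseline voxels, where $\tilde s$ is severity normalized to $[0,1]$ and
$\beta = 0.4$ is the fractional loss at maximal severity; shed voxels
turn fluid-dark from the rim outward, so the voxel count is exactly
monotone in severity before noise. Additive Gaussian noise (SD 0.1) is
applied last. A one-number threshold count inside the baseline sub-region
correlates with severity at $|r| > 0.8$ under defaults, guaranteeing the
images carry learnable signal. The phantoms are deliberately simple: they
emulate a severity-linked focal signal, not brain anatomy, scanner
physics or registration artifacts — so green tests certify the pipeline's
mechanics and learnability on signal-bearing images, not clinical
performance.

**Longitudinal targets.** Severity progresses linearly,
$s(t) = s_0 + \mathrm{rate}\cdot t/12$, with nonnegative per-subject
yearly rates (truncated normals; group means 0.05/0.5/0.7). Longitudinal
scores follow the severity trajectory with subject-specific intercepts
anchored at the calibrated baseline value (MMSE falls by 1.5 points per
severity unit, ADAS-11 rises by 2.5, plus noise, clipped to their
scales). An MCI subject is labelled pMCI at horizon $t$ iff
$s(t) \ge \theta$ with $\theta = 4.5$; because rates are nonnegative,
pMCI labels are monotone across horizons by construction. The real
criteria defining conversion visits are not specified for this cohort;
this threshold rule is our construct and is documented as such. With the
defaults the pMCI fractions at M12/M24/M36 are roughly 0.21/0.37/0.49 —
in the ballpark of the reference pattern (0.14/0.44/0.53) without exact
matching, which would be a calibration exercise rather than a modelling
one. Missingness mimics the declining follow-up counts: per-horizon
observation probabilities (0.94/0.90/0.73/0.41) with monotone dropout (a
subject lost at one horizon stays lost).

## Numerical choices and problem sizes

- Pooling boundary behavior: floor division, no implicit padding in the
  user API; the stem pool uses stride 2 with padding 1, and padding is
  capped at half the window so no window can lie entirely in padding.
- Batch normalization uses biased batch variance, ε = 1e-5 and momentum
  0.1 for the running statistics; evaluation uses the running statistics.
- ROC ties are grouped at one threshold (step-function convention), which
  makes the trapezoid AUC equal the Mann–Whitney pair statistic with ties
  at one half — an identity the tests check on random instances.
- Undefined classification ratios (e.g. precision with no predicted
  positives) are reported as missing with a reason, never silently zero.
- Weight initialization is He-style, seeded; training is bitwise
  reproducible on a fixed seed in single-threaded BLAS (with threaded
  BLAS, reductions may reorder and reproducibility is to numerical
  tolerance).
- Test-scale runs use 32³ phantoms and slim stage plans (one block per
  stage, widths 8/16/32/64, SE ratio 4); the learnability check trains on
  a 300-subject MCI cohort with amplified severity correlations and runs
  twelve epochs at a raised learning rate (1e-3), which is enough for the
  fold models to converge to consistent probability calibrations.
  The full-scale defaults (96³ inputs, 150/100 epochs, learning rate
  1e-4) are what a study-scale run would use.

## Known limitations

- The phantom generator makes no claim of anatomical realism; effect
  sizes for biomarkers and genetics are plausible in direction only.
- The training engine is CPU-only and single-threaded by design; it is
  meant for method development, testing and small studies, not for
  training the full-width model on study-scale imaging.
- The 36-layer census reflects one particular accounting convention
  (excluding normalization, activations, SE internals, shortcuts and the
  head); other conventions would count differently, which is why the
  census reports those layers in a separate field rather than hiding
  them.
- Reported receptive-field arithmetic uses the within-block composition
  reading (dilated 3³ then standard 3³ from a single voxel); other
  compositions reaching the same number exist, and the impulse-response
  test pins down exactly the one implemented.
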