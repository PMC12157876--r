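---
title: "Gait classification and severity estimation from VGRF signals via Gramian Angular Fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait classification and severity estimation from VGRF signals via Gramian Angular Fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(gaitgaf)
```

## The problem

Parkinsonian gait differs from healthy gait in ways that are visible in the
vertical ground reaction force (VGRF) measured by pressure-sensing insoles:
cycles are slower, stride-to-stride variability is higher, and the left and
right feet become more asymmetric. `gaitgaf` implements a pipeline that turns
per-foot VGRF sums into images and lets small convolutional networks do the
pattern recognition:

1. **read** per-walk insole recordings (8 sensors per foot plus per-foot
   totals at 100 Hz) and a demographics table;
2. **window** the per-foot force sums into overlapping segments (10–60 s,
   20% overlap);
3. **encode** each window as a Gramian Angular Summation Field (GASF) image;
4. **classify** windows as parkinsonian vs. control, or **regress** clinical
   severity scores (Hoehn & Yahr, UPDRS, UPDRS motor, Timed Up and Go),
   with subject-grouped cross-validation and per-subject aggregation.

A synthetic gait generator emulates the statistical structure of such
cohorts so that every stage is testable without any external data.

## The GASF encoding

A window $s(t) = [t_1, \dots, t_m]$ is min–max rescaled to $[-1, 1]$:

$$\tilde t_i = \frac{(t_i - \max s) + (t_i - \min s)}{\max s - \min s},$$

mapped to polar angles on the principal branch,
$\theta_i = \arccos \tilde t_i \in [0, \pi]$ with radius $r_i = i/m$, and
assembled into the Gram-like matrix

$$G_{ij} = \cos(\theta_i + \theta_j)
         = \tilde t_i \tilde t_j - \sqrt{1-\tilde t_i^2}\sqrt{1-\tilde t_j^2}.$$

$G$ is symmetric with entries in $[-1,1]$ and diagonal $2\tilde t_i^2 - 1$.
Because the angular map is injective on $[-1,1]$ and the radius preserves
sample order, the encoding is bijective and order-sensitive: reversing a
non-palindromic window changes the image. Because the rescale absorbs any
positive affine transform, the image is invariant to gain and offset of the
force signal — sensor calibration drops out.

Two numerical notes. The rescaling formula is sometimes printed in
equivalent-looking but algebraically inconsistent forms in the literature;
we implement the standard min–max map above, which attains $-1$ and $+1$
exactly at the window extremes. Values that spill outside $[-1,1]$ by
floating-point error (up to $10^{-12}$) are clamped before `acos`; anything
larger is an error. A constant window has no scale: it raises a
`degenerate_window` condition and the encoder drops and counts it rather
than imputing.

```{r gasf-example}
gaf_transform(c(1, 2, 3))
```

### From 1000 samples to a 64-pixel image

A 10 s window at 100 Hz has 1000 samples, but the classifier consumes
64×64×3 images. We reduce **before** the Gram construction with piecewise
aggregate approximation (PAA): bin $i$ (0-based) of $k$ averages sample
indices $[\lfloor im/k \rfloor, \lfloor (i+1)m/k \rfloor)$. This matches the
behaviour of the standard time-series imaging tools, preserves the global
mean when $k$ divides $m$, and refuses to upsample. The alternative —
building the full $1000 \times 1000$ Gram matrix and resampling the image —
was rejected: it is ~250× more arithmetic for an equivalent result. The same
rule applies to every window length, so longer windows simply compress more
gait cycles into the same image side (with the attendant loss of
resolution).

### Three channels

The published input depth of 3 is not explained by its source material; we
resolve it as (left-foot GASF, right-foot GASF, GASF of the mean of the two
PAA-reduced foot series), which keeps left/right asymmetry visible to the
network. A `replicate-mean` policy (one combined channel copied three
times) is available for comparison.

```{r gaf-image, fig.height = 3.2}
rec <- generate_subject(gait_profile(), duration_s = 10, seed = 1)
img <- window_to_image(rec$total_left, rec$total_right, side = 64)
op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
plot(rec$time_s, rec$total_left, type = "l", xlab = "time (s)",
     ylab = "VGRF (N)", main = "left-foot sum")
plot(img, channel = 1)
par(op)
```

## The networks

Two variants share one engine:

* **classifier** — 64×64×3 input, three 3×3 ReLU convolution blocks with
  32, 64, 128 filters, each followed by 2×2 max-pooling; flatten; a
  128-unit fully connected hidden layer; 2-way softmax output.
* **regressor** — 128×128×3 input by convention (any side divisible by 8
  works and smaller sides are used for desk-scale runs), the same three
  blocks, a 512-unit hidden layer, one linear output.

Training uses Adam with initial learning rate $10^{-3}$, dropout 0.5 on the
hidden layer, and an L2 penalty of $10^{-4}$ on all weight matrices. A
plateau scheduler multiplies the learning rate by 0.1 whenever the
monitored loss (a stratified 10–15% validation split by default) fails to
improve for 5 epochs; training stops early after 15 such epochs. The
patience values, epoch cap (100), batch size (32) and the classifier's
hidden width are configuration choices exposed in `cnn_spec()`; they are
not pinned by the published description of the architecture, and our
defaults are documented assumptions.

The engine itself is written against base R linear algebra: convolutions
are im2col patch extraction (compiled C++) followed by one BLAS GEMM per
layer, which is exact (gradients verify against central differences to
machine precision) and fast enough for cohort-scale experiments on one CPU.
Everything is seeded and single-threaded, so a fitted model is bitwise
reproducible: same data, spec and seed give the same weights and training
log. The regressor's output bias is initialized at the mean training
target, which removes the long burn-in a randomly initialized scalar output
would need.

```{r cnn-arch}
summary(build_gait_cnn(cnn_spec(), "classify"))
```

## Evaluation design

**Grouped folds.** Windows of one subject are strongly correlated, so
window-level cross-validation leaks identity and inflates accuracy. Folds
are therefore assigned at the subject level, stratified by group, with a
greedy smallest-fold rule that keeps fold sizes within one subject of each
other. The naive window-level mode exists behind
`cv = list(grouping = "window")` for replication studies only.

**Metrics.** PD is the positive class: TPR is sensitivity to disease, TNR
specificity. AUC is the midrank Mann–Whitney statistic, so tied scores
contribute ½. Regression reports $R^2 = 1 - SS_{res}/SS_{tot}$, MAE, RMSE
and MSE; predictions of one subject's windows are averaged into a single
subject-level score before the headline $R^2$ is computed. Window-level
pooled metrics and per-fold metrics are reported alongside.

**Perturbation arms.** Noise robustness adds $N(0, \sigma^2)$ to the
*unit-normalized* per-foot sums ($\sigma$ on the raw Newton scale would be
physically negligible against ~700 N stance peaks); the $\sigma = 0$ arm is
bit-identical to the baseline because the noise stream is a separate seeded
substream. Sensor ablation re-forms the per-foot sums from a keep-set of
sensor channels; the full keep-set reproduces the baseline bitwise because
the pipeline always sums sensor channels rather than trusting the stored
total column. SMOTE balancing, when enabled, interpolates flattened GAF
vectors of the *training split only*. The Wilcoxon signed-rank test for
comparing paired per-fold metrics is exact (dynamic-programming
enumeration with midrank ties) up to 25 pairs and a tie-corrected normal
approximation beyond; no multiple-testing correction is applied across
arms, and raw p-values are reported with their n.

## The synthetic generator

The generator is a statistical emulator, not a biomechanical model. Each
foot produces M-shaped stance episodes — two Gaussian bumps (heel-strike
and toe-off peaks at 28% and 72% of a stance occupying 62% of the cycle,
width 16% of stance) — at heel-strike times accumulated from i.i.d. cycle
durations with the profile's mean and coefficient of variation. Feet are
anti-phase; the asymmetry parameter scales the right foot's amplitude by
$1-a$ and shifts its phase offset. The 8 sensor channels split the foot
total with base spatial weights modulated by the heel/toe bump balance
(heel-side sensors load early in stance, toe-side late), renormalized per
sample so the channels sum exactly to the total — this keeps the
sensor-ablation arm non-trivial, since a constant-weight split would be a
pure gain change that the affine-invariant GASF would erase.

Group defaults place controls at cycle mean 1.1 s (CV 0.03, asymmetry
0.02) and patients at 1.35 s (CV 0.10, asymmetry 0.12) — separable but
overlapping, consistent in direction with the published walking-speed gap
between groups (1.24 vs 1.04 m/s); no quantitative stride-variability
figures are published for such cohorts, so these defaults are illustrative
and labelled as such. Patients draw a latent severity $z \sim U(0,1)$ that
drives both the gait profile (cycle mean $1.2 + 0.3z$ s, CV $0.05 + 0.10z$,
asymmetry $0.05 + 0.15z$) and the scores: TUG $= 8 + 8z + N(0, 0.5^2)$ s
(strictly increasing in $z$ before noise), UPDRS $= 15 + 40z + N(0, 6^2)$
rounded and clamped to its scale, UPDRS-motor a noisy 0.6 fraction of UPDRS
clamped to never exceed it, and Hoehn & Yahr by thresholding $z$ at
0.55/0.85 into stages {2, 2.5, 3} — mirroring the stage mix of ambulatory
insole cohorts, which contain no stage-0/1 or stage-4/5 walkers. Controls
receive mild per-subject jitter (cycle mean SD 0.06 s, lognormal CV
jitter, amplitude SD 70 N) so they are not clones.

One master seed fans out to per-subject substreams through a counter
scheme, so cohorts are reproducible under reordering, and every stage of an
experiment (generator, noise, folds, per-fold model) draws from its own
derived stream.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: tremor, festination, dual-task effects, sensor
drift, inter-laboratory differences, or realistic correlations between
scores beyond the single latent severity. Classification accuracy on this
synthetic family is an internal-consistency check of the pipeline, not a
claim about clinical performance. Reproducing published real-data numbers
requires the external accession; the reader and the experiment runner
accept such data directly (see `read_cohort()`), and walks recorded under
altered-gait conditions (identified by walk index) are excluded by default.

## Problem sizes and runtimes

Experiments in the test-suite and acceptance script are sized for a single
CPU: recordings of 30–40 s (3–4 windows of 10 s at 20% overlap per
subject), cohorts of 40–80 subjects, image side 64 for both tasks (the
regressor's published 128-pixel input is scaled down accordingly), 12–25
training epochs. Cross-validated runs at these cohort sizes use batch
size 16 rather than the default 32: with under 300 training images per
fold, halving the batch doubles the number of Adam updates at identical
arithmetic cost, which is what the softmax calibration needs to converge.
At these sizes a classification fold trains in about one to two minutes. All sizes are stated in the
acceptance script and tests and can be scaled up freely.

## Known limitations

* The CNN engine is deliberately minimal: no GPU, no data augmentation, no
  batch normalization, no attention variants.
* `hoehn_yahr` regression treats an ordinal stage as a continuous target
  (evaluated by MSE), matching common practice for this pipeline family.
* The exact Wilcoxon enumeration is limited to 25 pairs; beyond that the
  normal approximation is used.
* How multiple walks per subject should be pooled is unspecified in the
  source material; all windows of all retained walks are pooled by default,
  and attributed to their subject for fold assignment either way.
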