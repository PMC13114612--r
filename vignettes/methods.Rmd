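---
title: "Selective state-space and Kolmogorov-Arnold modeling of dynamic functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective state-space and Kolmogorov-Arnold modeling of dynamic functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfcmamba)
```

## The problem

Resting-state fMRI yields, per scan session, one mean BOLD time series per
anatomical region of interest (ROI; 116 regions under the AAL atlas). Static
functional connectivity — one correlation matrix per session — discards the
temporal reorganization of coupling that is believed to carry disease-stage
information in neurodegeneration. `dfcmamba` implements an end-to-end,
interpretable classifier of *dynamic* functional connectivity (dFC)
sequences, together with a synthetic cohort generator that lets every stage
be validated without access-controlled clinical data.

The pipeline has four stages:

1. **dFC construction.** Each ROI series is z-scored across time
   (population standard deviation — this is a normalization, not a variance
   estimate). Overlapping windows of `Lw = 30` time points at step `s = 2`
   (93% overlap) yield `K = floor((T - Lw)/s) + 1` windows; for the
   reference acquisition (140 volumes, 3 discarded, T = 137) that is
   K = 54. Each window's Pearson correlation matrix is vectorized to its
   `D = N(N-1)/2` upper-triangular entries (6670 for N = 116) and affinely
   rescaled to `[0, 1]` via `(r + 1)/2`, the minimal invertible map onto the
   range of the sigmoid-bounded decoder.
2. **Per-window variational autoencoding.** An MLP encoder with two
   parallel affine heads produces a diagonal-Gaussian posterior per window;
   training samples `z = mu + sigma * eps` (reparameterization), evaluation
   uses the posterior mean. The ELBO is the batch-mean squared
   reconstruction error (summed over features) plus `kl_weight` times the
   batch-mean KL divergence to the standard-normal prior. Windows are
   encoded independently — row k of the latent sequence derives only from
   window k.
3. **Selective state-space temporal encoding.** A stack of Mamba blocks:
   LayerNorm, parallel input/gate projections to `d_inner = 2 * d_model`
   channels, a causal depthwise convolution (kernel 4, left-padded), SiLU,
   an S6 selective scan, a multiplicative SiLU gate, an output projection
   and a residual connection. The scan is a per-channel diagonal recurrence
   `h_k = exp(Delta_k A) h_{k-1} + (Delta_k B_k) u_k`, `y_k = <C_k, h_k>`,
   with the time step `Delta` a softplus of a per-channel affine of the
   post-convolution activation, and `B`, `C` per-channel linear maps of the
   layer-normalized block input. Large `Delta` forgets history and
   prioritizes the current window; small `Delta` carries state forward —
   the recorded `Delta` values are therefore a per-window importance
   measure. The final block's outputs are mean-pooled into a context
   vector.
4. **Kolmogorov-Arnold classification.** A two-layer KAN maps the context
   to class logits. Every edge carries its own learnable univariate
   function `phi(x) = w_b * SiLU(x) + sum_i c_i B_i(x)` with `G + p = 8`
   cubic B-spline coefficients on a uniform grid; node outputs are plain
   sums of edge activations. After training, each curve can be read
   directly from the parameters — the classifier's decision logic is
   inspectable without post-hoc approximation.

Training is two-phase: the VAE is first pre-trained alone on
training-partition windows (no labels; validation and test windows never
enter) keeping the lowest-validation-reconstruction checkpoint; the full
pipeline is then fine-tuned under `alpha * L_VAE + L_cls` with differential
learning rates (1e-5 for the VAE, 1e-3 for Mamba and KAN) and the VAE
bit-frozen for the first 15 warmup epochs. Splits are at the subject level
throughout — a subject's sessions never span partitions — and evaluation
aggregates session probabilities by averaging within subject (argmax,
first-index tie-break).

## Interpretability stack

Three complementary read-outs:

* **When** — class temporal-importance profiles: the per-window mean of the
  recorded `Delta` values (final block by default; which layer feeds the
  profile is configurable because the choice is not canonical), averaged
  over a class's sessions and optionally z-scored across windows.
* **How** — activation-curve ranking: first-layer KAN inputs ranked by the
  mean absolute edge activation over probe contexts (the test partition by
  default), with the top curves extracted for plotting.
* **Where** — Jacobian attribution: the gradient of a class logit with
  respect to every window's input features, averaged over windows and over
  the class's sessions, mapped back to a symmetric zero-diagonal N x N
  matrix. A flag converts scores to per-correlation units (chain-rule
  factor 1/2 through the unit rescaling). Connections are thresholded to
  the top 1% of `|a_ij|` (ties broken lexicographically) and regions ranked
  by node strength `sum_j |a_ij|` — the strength definition is ours; the
  ranking figure it supports defines none.

## What the synthetic generator emulates

`generateSession()` draws piecewise-stationary multivariate normal series:
a block-structured SPD correlation template (4 equal blocks, within-block
r = 0.3 — a coarse stand-in for modular network structure), per-class
whole-session edge shifts, window-indexed temporal shifts (ranges map to
time as `[k1*s, k2*s + Lw)`), and independent Gaussian observation noise
(sd 0.2, mild relative to the unit-variance signals). Edits are applied in
correlation space and re-projected to the nearest valid correlation matrix
(eigenvalue clipping at 1e-6, rescaling to unit diagonal); target
magnitudes beyond 0.95 are rejected. Piecewise stationarity was chosen over
continuously varying coupling because it gives exact, analyzable per-window
targets for recovery tests.

What it deliberately does **not** emulate: hemodynamic filtering and
realistic BOLD spectra, motion artifacts, scanner/site effects,
subject-level random effects, or spatially correlated parcellation noise.
Passing the recovery study therefore demonstrates that the pipeline's
machinery is correct and that planted statistical structure of realistic
magnitude is recoverable — not that comparable accuracy would be obtained
on clinical cohorts.

## Desk-scale study conditions

The published architecture (D = 6670, latent 128, encoder
[6670, 2048, 1024, 512, 256]) targets GPU-scale training. All contracts are
width-agnostic, and the validation study runs a desk-scale configuration
chosen once and used everywhere (`defaultConfig(2, "desk")`):

* Cohorts: N = 20 ROIs (D = 190), T = 137 (K = 54), 2 classes x 60
  subjects, 1-2 sessions per subject, subject-level 70/10/20 split
  (84/12/24 subjects). The planted effect size is `delta_r = 0.4`.
* VAE: encoder [190, 128], latent 32, `kl_weight = 0.003`. The down-weighted
  KL term deserves a note: at desk scale most window-to-window variance is
  *correlation-estimation noise* (windowed Pearson estimates at Lw = 30
  have a sampling sd of roughly 0.18), which no finite code can compress.
  The reconstruction gain from encoding the informative features is then
  smaller than the unit-weight KL cost, and the ELBO optimum is posterior
  collapse — the encoder outputs the prior and downstream stages receive
  constants. Scaling the KL weight down restores an informative latent
  space; at the published D = 6670 the balance differs and the unit weight
  is appropriate. A shallow-wide encoder is used for the same reason: deep
  funnels destroy the (single-feature) planted signal at desk scale.
* Mamba: `d_model = 32`, `d_state = 4`, `d_conv = 4`, expansion 2, two
  blocks, dropout 0.15. KAN head: hidden 8, G = 5, p = 3, grid refresh
  every 10 epochs from a 1024-sample activation buffer.
* Schedules: phase 1, 30 epochs at batch 32; phase 2, 60 epochs at batch 8
  sessions; warmup freeze 15 epochs; Adam (0.9, 0.999, 1e-8); five fixed
  training seeds. The ablation comparison uses a 40-epoch phase 2,
  identical across variants.

These sizes keep a five-seed study on one CPU core in the tens of minutes
while leaving every mechanism (compression, selectivity, spline
classification, two-phase optimization) non-trivially exercised.

### The three benchmark tasks

`deskPreset("desk2")` plants one whole-session discriminative edge per
non-reference class plus an additional informative window range
(windows 10-20) on class 1's edge. It is the classification benchmark:
the study requires subject-level test accuracy at or above 90% in the
majority of seeds, and the planted edge inside the top 1% of absolute
attributions.

`deskPreset("desk2w")` is the planted-window recovery experiment: class
1's signal exists *only* inside windows 10-20 (a +0.4 shift on five
between-block edges), so those windows are the sole distinctive content
of the sequence. The study requires the z-scored class temporal profile,
averaged over the five seeds, to be elevated over the planted windows
(one-sided rank test). On desk2 this test would be confounded: the
static edge makes every window informative, so the model has no reason
to modulate its time steps at the planted range.

`deskPreset("desk2t")` is the *temporal-only* comparison task: no
whole-session effects; class 1 carries a balanced biphasic signature
(+0.4 on the five edges in windows 10-20, -0.4 in windows 30-40), so the
session-mean connectivity is matched across classes by construction and
unweighted window averaging is uninformative. On desk2 itself a
mean-pooling model is sufficient — any whole-session contrast is visible
to it — so desk2t is where the contribution of selective temporal
modeling is measured: the mean-pooling (`no_mamba`) and no-pretraining
ablations must not exceed the full model's mean accuracy there. This
cohort uses 40 subjects per class (the comparison needs less statistical
power than the recovery studies).

### Which block's time steps feed the temporal profile

The choice is not canonical, and it matters. Empirically, the *first*
block's time steps track window content: on desk2w its z-scored profile
is elevated at the planted windows in every seed, including runs whose
classifier failed to converge — the response is largely input-driven.
Deeper blocks are free to develop position-dependent gating strategies
(e.g. resetting state late in the sequence regardless of which windows
carry signal), and their profiles are not reproducible across training
runs: on biphasic inputs the final block consistently concentrates its
large time steps on the *later* informative range whatever its sign.
`classTemporalProfile()` therefore defaults to the first block
(`trace_block = "first"`), with `"last"` and `"mean"` available.

## Numerical choices

* **Discretization.** The simplified per-channel rule
  (`Abar = exp(Delta A)`, `Bbar = Delta B`) is the default; exact
  zero-order hold (`Bbar = (Abar - 1)/A * B`) is selectable. The two agree
  to first order in `Delta`, and the selective-scan equations govern the
  default.
* **B/C source.** `B` and `C` are computed from the layer-normalized block
  input and `Delta` from the post-convolution activation (the literal
  reading of the selective equations); a switch derives all three from the
  convolution output as in the original S6 derivation.
* **A initialization.** `A[d, n] = -n`, stored as `log(-A)` — the standard
  real-diagonal simplification of HiPPO-style initialization. The `Delta`
  bias is initialized so `softplus(bias)` is uniform in `[0.001, 0.1]`.
* **Scan.** A sequential recurrence compiled from C++ (no parallel-scan
  kernel): at K = 54 the sequence is short and the contract is the
  recurrence itself.
* **Grid refresh.** Every 10 epochs the KAN grids are re-fit to the
  observed activation range (1% margin) by least squares on probes over
  the *new* domain, with the old spline clamp-extrapolated beyond its old
  domain. Probing only the old domain makes the refit ill-conditioned when
  activations drift and can destabilize training; the clamped-target
  variant preserves in-domain behavior (gap below 1e-3 where the spline is
  representable) and is stable.
* **Degenerate inputs.** Globally flat ROI rows are rejected by the
  z-scoring precondition (naming the row); a zero-variance row inside a
  single window zeroes that row's correlations with a warning rather than
  propagating NaN. Correlations are clamped to `[-1, 1]` against
  floating-point overshoot. Ties in subject-level argmax go to the first
  class index; ties in best-checkpoint selection go to the lower validation
  loss.
* **Determinism.** Every stochastic step (initialization, shuffling,
  reparameterization noise, dropout, cohort generation, splits) draws from
  a seed derived from one run seed and a stream tag; identical seeds give
  bit-identical runs on a given platform.

## Design decisions on open points

* The KL weight and the classification-loss weight are distinct
  configuration fields (`kl_weight`, `cls_weight`) even though both default
  to 1.0 at full scale.
* Phase 1 uses training-partition windows only — "unsupervised" never means
  validation or test exposure.
* One probability vector is produced per *session* (the sequence model
  consumes all windows); subject-level predictions average across a
  subject's sessions. Window-level voting would contradict the
  architecture.
* The per-sample KL is averaged (not summed) over the batch so the
  `alpha`-weighting of the joint loss is batch-size invariant.
* The temporal-importance trace defaults to the final block (configurable
  to the across-block mean); z-scoring of class profiles defaults to
  across-windows-within-class.
* The five training seeds default to consecutive integers from the run
  seed; the published experiments do not print theirs.
* Parameter counts itemize KAN spline coefficients (G + p per edge) and
  per-edge base weights separately; total-parameter reproduction of the
  published table is not attempted because its stated increment matches no
  obvious counting convention.

## Known limitations

* The full-scale architecture (33M parameters) is supported by the code but
  not validated here; desk-scale results do not transfer claims to it.
* The generator's Gaussian, piecewise-stationary world is much cleaner than
  rs-fMRI; planted-signal recovery is a necessary, not sufficient,
  condition for clinical utility.
* Selectivity profiles are descriptive: a seed whose trained `Delta`
  profile *de-emphasizes* the planted windows (sign inversion) is
  possible, which is why the recovery test operates on the seed-averaged
  first-block profile and on a cohort whose planted windows are the sole
  distinctive content. When other discriminative structure is present
  (as on desk2), the direction of the profile at the planted range is
  not identified.
* `no_mamba`/`mean_pool` ablations change the parameter count as well as
  the mechanism; comparisons are of configurations, not of matched-capacity
  models.
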