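---
title: "Diffusion-based deconvolution of bulk RNA-seq: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-based deconvolution: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A bulk RNA-seq profile is an average over an unknown mixture of cell
types. Given a cell-type-annotated single-cell reference, deconvolution
asks for the mixture weights: a vector $p$ on the probability simplex
with one entry per cell type. DiffDeconv treats this as *conditional
generation*: instead of regressing $p$ on the bulk profile directly, it
learns the conditional distribution $P(p \mid \text{bulk})$ with a
denoising diffusion probabilistic model (DDPM) and reads predictions off
the reverse process.

## Forward process and training objective

The forward process corrupts a clean proportion vector $x_0 = p$ over
$T$ timesteps with Gaussian noise,
$$q(x_t \mid x_{t-1}) = \mathcal{N}\!\big(x_t;\ \sqrt{1-\beta_t}\,x_{t-1},\ \beta_t I\big),$$
where $\beta_t$ follows a linear schedule from $10^{-4}$ to $0.02$ over
$T = 1000$ steps (`makeSchedule()`). Writing
$\bar\alpha_t = \prod_{s\le t}(1-\beta_s)$, the marginal has the closed
form $x_t = \sqrt{\bar\alpha_t}\,x_0 + \sqrt{1-\bar\alpha_t}\,\epsilon$
(`forwardNoise()`), which is what training uses. A denoiser network
$\epsilon_\theta(x_t, t, c)$ is trained to predict the injected noise
given the noisy vector, the timestep and the conditioning bulk profile
$c$, minimising
$$L = \mathbb{E}_{t, x_0, \epsilon}\big[\lVert \epsilon - \epsilon_\theta(x_t, t, c) \rVert^2\big]$$
with timesteps drawn uniformly from $1..T$ per batch — the standard DDPM
recipe.

At inference, ancestral sampling starts from $x_T \sim \mathcal{N}(0,I)$
and iterates
$x_{t-1} = \tfrac{1}{\sqrt{\alpha_t}}\big(x_t - \tfrac{\beta_t}{\sqrt{1-\bar\alpha_t}}\epsilon_\theta(x_t,t,c)\big) + \sigma_t z$,
with $z = 0$ at the last step (`ddpmSample()`).

Numerical choices made here, where the framework leaves them open:

* **Reverse-process variance.** $\sigma_t^2 = \beta_t$, the simpler of
  the two classical choices; the posterior variance
  $\tilde\beta_t = \beta_t (1-\bar\alpha_{t-1})/(1-\bar\alpha_t)$ is
  available via `sigmaStyle = "betaTilde"`.
* **Simplex constraint.** The raw sample is clipped at zero and
  renormalised (`projectToSimplex()`), falling back to uniform if
  everything clips. Clip-and-renormalise preserves exact zeros for
  absent cell types, which a softmax cannot produce. An all-zero fall
  back is uniform $1/K$.
* **Draw averaging.** `nDraws = 1` is the default (single-pass
  inference); averaging independent draws before projection is exposed
  for variance reduction and is what the analytic-oracle test uses.
* **Timestep indexing.** 1-based, $t \in [1, T]$; stored schedule arrays
  are indexed the same way.

## The two denoisers

Both denoisers embed each input modality separately with an affine map
into a shared $d$-dimensional space ($d = 128$ by default): proportions
$K \to d$, timestep $1 \to d$, bulk profile $G \to d$. The timestep
enters as $t/T$; a raw index in the hundreds makes the scalar embedding
dominate early training. The two architectures differ only in how the
three embeddings are *fused*:

* **DiffFormer** arranges them as a 3-token sequence
  `[proportion, time, bulk]`, adds learnable positional embeddings
  (initialised $\mathcal{N}(0, 0.02^2)$), and runs a pre-norm
  Transformer encoder: 3 layers, 4 softmax-attention heads,
  feed-forward dimension 256 with GELU, dropout 0.1 on the attention
  weights and the feed-forward activations (exactly those two places;
  token embeddings are not dropped). A final layer normalisation closes
  the pre-norm stack, and the first token is projected $d \to K$ with no
  output activation so the full noise range is reachable.
* **DiffMLP**, the ablation baseline, concatenates the three embeddings
  and applies a GELU MLP with hidden widths `[256, 256]` (the depth is
  configurable; widths are a package choice since only "multiple hidden
  layers" is prescribed), sharing every other hyperparameter with
  DiffFormer so the comparison isolates token fusion versus
  concatenation fusion.

The forward and backward passes are written in base-R matrix code; every
analytic gradient is validated against central finite differences in the
test suite, and the default parameter counts (1,040,391 for DiffFormer,
807,559 for DiffMLP at $K=7$, $G=5000$) are regression-tested so
architecture drift cannot pass silently.

## Training loop

`trainModel()` uses AdamW (decoupled weight decay) with learning rate
$10^{-4}$, weight decay 0.01, betas (0.9, 0.999), eps $10^{-8}$, batch
size 64, and cosine learning-rate annealing to `etaMin` $=10^{-6}$.
The cosine is parameterised so epoch 1 runs exactly at `lr` and epoch
`tMaxLR` exactly at `etaMin` (some common implementations reach the
floor one step later); both endpoints are unit-tested in closed form.
Early stopping watches a held-out validation split — 10% of the training
samples by seeded shuffle, a package choice since only "validation loss"
is prescribed — with patience 20, and the returned parameters are those
of the lowest-validation epoch (ties to the earlier epoch). The
validation loss is computed on a *fixed* noise/timestep draw so epochs
are comparable. Gradient clipping is off by default (a flag exists).
A single config seed fixes the split, the batching, the noise, the
dropout and the weight initialisation.

## Pseudo-bulk simulation

Ground-truth data are simulated from the processed reference
(`generateDataset()`): a proportion vector is drawn from a symmetric
Dirichlet with $\alpha = 1$ (uniform over the simplex), 2000 cells are
allocated to types by a single multinomial draw, sampled with
replacement within each type, and their log-normalised profiles are
averaged. Two design decisions worth stating:

* **Realized truth.** The recorded ground truth is the *realized*
  fraction (multinomial counts / 2000), not the latent Dirichlet draw —
  the profile was built from the realized cells, so that is the
  recoverable quantity. `latentTruth = TRUE` switches to the latent
  draw for sensitivity analyses.
* **Averaging scale.** Mixing happens on the log-normalised (CP10K +
  log1p) profiles because normalisation precedes simulation in the
  processing pipeline. Mixing raw counts and renormalising is a
  reasonable alternative not taken here.

One RNG stream drives proportions and cell sampling in a documented
order (proportion first, then cells, per sample), so one seed fixes the
whole dataset; train and test are a prefix/suffix split of a single
generation-ordered stream and therefore disjoint by construction.

## Reference preprocessing

`buildAtlas()` runs, in a fixed order: cell QC (keep cells with 200–5000
detected genes and mitochondrial count fraction ≤ 20%; mitochondrial
genes are recognised by the conventional "MT-"/"mt-" name prefix), gene
QC (drop genes detected in fewer than 3 retained cells — the count is a
package choice, configurable), CP10K + log1p, and dispersion-based HVG
selection. Cell filters run before the gene filter so gene prevalence is
measured on surviving cells. HVG selection computes per-gene mean and
dispersion (variance/mean) on the expm1 scale, z-scores log dispersions
within 20 *equal-frequency* bins of log-mean, applies the mean window
(0.0125, 3) and dispersion cutoff 0.5 on the normalised dispersion, and
ranks by normalised dispersion with ties broken lexicographically — so
the selected gene order is deterministic. If fewer genes pass than
requested, all passers are returned with a warning rather than an error.
Cell-type names are sorted lexicographically, fixing the index order of
every proportion vector downstream. HVG selection runs on the reference
alone: pseudo-bulk samples are derived from the reference, so the gene
space is shared by construction.

## The synthetic reference generator

`simulateReference()` emulates an annotated scRNA-seq counts matrix with
$K$ cell types: each type owns a disjoint block of marker genes whose
negative-binomial mean is `markerFold` times the baseline, all genes
share an NB dispersion $\phi$ (variance $\mu + \phi\mu^2$), and each
cell has a lognormal library-size multiplier with a given CV. Defaults —
5 types, 300 genes, 100 cells/type, 10 markers/type at 20-fold,
baseline mean 5, $\phi = 0.1$, library CV 0.2 — give a clearly separable
reference of the kind the method is designed for; `markerFold = 1`
removes all signal, and `overlapFrac` shares a leading fraction of each
type's markers with its neighbour to emulate overlapping signatures.
The generator is deliberately idealised: it has NB overdispersion but no
ambient RNA, doublets, batch effects or dropout beyond NB sampling
zeros. Tests passing on it demonstrate that the machinery recovers
mixtures when the reference assumptions hold; they say nothing about
robustness to real-data pathologies.

## Reduced CPU-scale study

The package's self-contained benchmark (`reducedStudyConfig()`, also the
protocol behind `scripts/acceptance.R`) is sized for minutes on one CPU
core: the default synthetic reference, 1000 training and 100 test
pseudo-bulk samples, a $T = 200$ schedule, 50 epochs. Two deviations
from the full-scale defaults follow from that sizing and are deliberate:
the learning rate rises to $10^{-3}$ (the optimisation budget is roughly
ten times fewer steps, so the lr–steps trade-off is rebalanced; the
cosine floor scales along to $10^{-5}$), and the HVG mean window's upper
bound is lifted because with only 300 genes the per-gene CP10K means sit
far above a window calibrated for genome-scale references (the
dispersion cutoff still applies, typically retaining ~95 of 300 genes).
On this benchmark the Transformer denoiser reaches mean per-sample RMSE
below 0.05 with per-type correlations above 0.9 and significantly lower
per-sample error than the MLP ablation under a paired t-test — the same
qualitative ordering the full-scale method reports, at desk scale.

## Evaluation conventions

* Per-sample RMSE over the $K$ components; the scalar "overall RMSE" is
  the mean of per-sample RMSE (an alternative — RMSE over the flattened
  matrices — is exposed via `overallRMSEMode`, since the aggregation is
  not uniquely defined).
* Per-type Pearson correlation across samples; a constant truth or
  prediction column yields an explicit `NA` marker recorded in
  `failedTypes`, never a crash, and undefined entries are excluded from
  any averaging.
* Overall PCC flattens both matrices row-major into single $N\cdot K$
  vectors and correlates those — a deliberately holistic score that is
  not the mean of per-type correlations.
* Paired two-tailed t-test on per-sample RMSE differences with
  $N-1$ degrees of freedom; Cohen's $d$ uses the paired-differences
  convention $\bar d / s_d$ (sample sd), so a negative $d$ means the
  first method is better. Quartiles use the linear-interpolation
  convention (R type 7).

## Known limitations

* Pseudo-bulk mixing is linear in log-normalised profiles; real bulk
  data add platform noise and compositional effects the simulator does
  not model.
* The NNLS baseline is a sanity oracle for the simulator's linear
  regime, not a re-implementation of any published deconvolution tool.
* Training is CPU-oriented base-R; it is sized for the reduced study
  and for references in the few-thousand-gene range, not for
  atlas-scale sweeps.
* Rare cell types (few reference cells) inherit the usual instability:
  their centroids are noisy and their per-type correlations degrade
  first.
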