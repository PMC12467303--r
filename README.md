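# DiffDeconv

Cell-type deconvolution of bulk RNA-seq by conditional denoising
diffusion, with a Transformer denoiser.

## What problem this solves

Bulk RNA-seq measures the average expression of a tissue sample and
hides its cellular composition. Given a cell-type-annotated single-cell
reference, *deconvolution* estimates the fraction of each cell type in a
bulk profile. Linear methods model the bulk as a non-negative
combination of per-type signatures; they are fast but brittle when
signatures overlap. DiffDeconv instead frames deconvolution as
conditional generation: a denoising diffusion probabilistic model (DDPM)
learns the conditional distribution of the proportion vector
$p \in \Delta^{K-1}$ given the bulk profile $c \in \mathbb{R}^G$.

The forward process corrupts a clean proportion vector over $T$ steps,
$q(x_t \mid x_{t-1}) = \mathcal{N}(x_t;\ \sqrt{1-\beta_t}\,x_{t-1},\ \beta_t I)$,
with $\beta_t$ linear from $10^{-4}$ to $0.02$, $T = 1000$. A denoiser
$\epsilon_\theta(x_t, t, c)$ is trained to predict the injected noise by
minimising $\mathbb{E}\lVert\epsilon - \epsilon_\theta(x_t,t,c)\rVert^2$;
inference runs ancestral sampling from pure noise, conditioned on the
bulk profile, and projects the result onto the simplex.

Two denoisers are provided:

* **DiffFormer** — embeds the noisy proportions, the timestep and the
  bulk profile as a 3-token sequence and fuses them with a pre-norm
  Transformer encoder (d = 128, 4 heads, 3 layers, FF 256, GELU,
  dropout 0.1); the first token's output predicts the noise.
* **DiffMLP** — the ablation baseline: same embeddings, concatenated
  and passed through a GELU MLP. Isolates the value of attention-based
  token fusion.

Around the core model the package carries the full supporting pipeline:
single-cell QC and CP10K/log1p normalisation, dispersion-based highly
variable gene selection, Dirichlet pseudo-bulk simulation with known
ground truth, a seeded AdamW + cosine-annealing trainer with early
stopping, an NNLS linear baseline on cell-type centroids, and an
evaluation suite (per-sample RMSE, per-type and flattened overall
Pearson correlation, paired t-tests with Cohen's d). A negative-binomial
synthetic reference generator makes everything runnable offline.

## Worked example

The reduced CPU-scale study (about 4 minutes on one core) simulates a
5-type, 300-gene single-cell reference, builds 1000 training and 100
test pseudo-bulk samples, trains both denoisers (T = 200, 50 epochs) and
evaluates them on the held-out samples:

```r
library(DiffDeconv)

res <- runPipeline(reducedStudyConfig(seed = 42, outDir = "run42"))
res$reports$diffformer
#> EvalReport: mean RMSE 0.0343 (IQR 0.0209), overall PCC 0.9745
#>   per-type PCC:
#>  type1  type2  type3  type4  type5
#> 0.9842 0.9794 0.9670 0.9766 0.9725
res$reports$diffmlp@overallRMSE
#> [1] 0.05087299
res$pairedTest
#> Paired RMSE test diffformer vs diffmlp: mean diff -0.01661, t = -7.051,
#> p = 2.421e-10, d = -0.7051 (n = 100)
```

Reading the output: mean per-sample RMSE of 0.035 means the Transformer
denoiser recovers each sample's 5 proportions to within a few percentage
points on average; per-type PCC near 1 means every cell type's predicted
fraction tracks its true fraction across samples; and the paired t-test
shows the Transformer's per-sample error is systematically lower than
the MLP ablation's on the same test samples, not just lower on average.

Artifacts land in `outDir`: the simulated datasets, model checkpoints,
prediction CSVs, `report.json` and a provenance record. The same
machinery accepts real references — a 10x-style matrix-market triplet
plus a barcode/type annotation TSV (`readReference10x()`), or a dense
TSV (`readReferenceDense()`) — through `buildAtlas()` and the same
`runPipeline()` configuration surface. A thin command-line wrapper with
`simulate-reference / build-atlas / simulate-bulk / train / infer /
evaluate / run` subcommands is installed at `inst/cli/diffdeconv.R`.

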