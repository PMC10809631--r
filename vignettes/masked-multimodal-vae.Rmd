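---
title: "Masked conditional VAEs for mosaic multimodal integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked conditional VAEs for mosaic multimodal integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicvae)
```

## The problem

Single-cell experiments increasingly measure different molecular layers —
gene expression, surface-protein abundance, chromatin accessibility — in
different cells, different batches, and different combinations. A CITE-seq
run yields paired RNA + protein; an ASAP-seq run yields paired protein +
ATAC; a MERFISH panel measures only a few hundred genes of the transcriptome;
a plain scRNA-seq run measures one modality in yet other cells. The analyst
wants all of these cells in one latent space, free of batch and modality
effects, with missing genes imputed and whole missing modalities generated
where a reference makes that possible, and with labels carried from
annotated to unannotated cells.

`mosaicvae` addresses this with a single conditional variational autoencoder
augmented by two binary mask modules. The key idea is that *one*
encoder/decoder pair can serve all datasets and all modalities if (i) all
modalities are stacked along one feature axis and (ii) binary masks gate
which features enter the encoder and which features the reconstruction loss
supervises. Nothing else in the architecture changes between tasks; only the
masks and the training schedule do.

## Model

Cells are rows of a stacked matrix $x \in \mathbb{R}^{n \times D}$, where
$D$ is the sum of the per-modality block widths. One forward pass computes

$$
\begin{aligned}
x_{\mathrm{in}} &= x \odot m_{\mathrm{in}} \\
h_2 &= \mathrm{relu}(W_2\,\mathrm{relu}(W_1 x_{\mathrm{in}} + b_1) + b_2) \\
\mu_z = W_\mu h_2 + b_\mu,\quad
\log\sigma_z &= W_\Sigma h_2 + b_\Sigma \\
z_1 &= \mu_z + e^{\log\sigma_z} \odot \varepsilon,\qquad
\varepsilon \sim \mathcal{N}(0, I) \\
\hat{x} &= \mathrm{relu}(W_{\mathrm{out}}\,\mathrm{relu}(W_3 z_1 + b_3)
           + b_{\mathrm{out}}) \odot m_{\mathrm{out}} \\
E &= W_E[c],\qquad z_2 = \mu_z - E \\
p &= \mathrm{softmax}(W_C z_2 + b_C)
\end{aligned}
$$

with $m_{\mathrm{in}}, m_{\mathrm{out}} \in \{0,1\}^D$ the input and output
masks, $c$ the integer covariate code of the cell (its dataset of origin),
$W_E$ a learned embedding table, and $p$ a $K$-cluster classifier over the
covariate-free latent $z_2$. Subtracting the covariate embedding from the
posterior mean ("latent vector arithmetic") is the batch/modality-removal
step: $z_1$ retains covariate content and feeds the decoder, $z_2$ is the
integrated representation used for clustering, visualisation and label
transfer.

The variance head is parameterised as $\log\sigma$ and exponentiated at
sampling time. An unconstrained linear "standard deviation" head can go
negative; the log parameterisation is the numerically stable equivalent and
recovers the same sampler with $\sigma = e^{\log\sigma}$.

The training objective per minibatch is

$$
\mathcal{L} = \underbrace{\frac{\sum_{ij} m^{\mathrm{out}}_{j}
  (x_{ij} - \hat{x}_{ij})^2}{\sum_{ij} m^{\mathrm{out}}_{j}}}_{\text{masked MSE}}
 + \beta\, \mathrm{KL}\!\left(\mathcal{N}(\mu_z, \sigma_z^2)\,\|\,
   \mathcal{N}(0, I)\right)
 + \gamma\, \mathrm{CE}(p, y_{\text{labeled}})
$$

where the reconstruction term averages over *supervised positions only*
(masked positions contribute nothing, by construction and by gradient — see
the mask-isolation tests), the KL term is averaged over cells and summed
over latent dimensions, and the cross-entropy runs over labeled cells only,
making the classifier semi-supervised: cells with `NA` labels contribute
zero. Gradients are computed analytically (`loss_and_grads()`) and verified
against central finite differences in the test suite; optimisation is Adam.

### Why `beta = "auto"`

The reconstruction term is a *per-position mean* while the KL sums over all
$d_z$ latent dimensions. With $\beta = 1$ the KL term outweighs
reconstruction by roughly a factor of $D$ and the posterior collapses to the
prior before the decoder learns anything. The default `beta = "auto"` sets
$\beta = 1/D$, which restores the balance of the standard (summed) ELBO; any
fixed numeric value can be supplied instead. `beta_warmup` optionally ramps
$\beta$ linearly over the first epochs. $\gamma$ defaults to 1.

### Defaults and their reasoning

| parameter | default | why |
|---|---|---|
| `h1`, `h2` | 256, 128 | encoder widths sized for stacked axes of a few hundred features; widen for thousands of genes |
| `d_z` | 32 | enough for tens of cell states; the classifier and arithmetic both live here |
| `h3` | 128 | decoder width, mirroring the encoder |
| `beta` | `"auto"` = 1/D | see above |
| `gamma` | 1 | cross-entropy of order $\ln K$ is comparable to early reconstruction error |
| `lr`, `batch_size`, `epochs` | 1e-3, 256, 100 | ordinary Adam practice at this scale |

## Masks and training phases

Two mask builders cover the three workflows:

* **Unpaired integration with specific genes** (`build_unpaired_masks()`):
  both datasets are encoded from the *common* genes only, so the shared
  weights are the conduit of knowledge transfer. The reference's output mask
  is all-ones — the decoder is supervised on common *and*
  reference-specific genes — while the query's output mask covers common
  genes only, because its specific positions hold zero padding, not truth.
  After training, the decoder output at the query's specific positions *is*
  the imputation. A symmetric variant (`own_specific_idx`) lets every
  dataset keep its own specific genes supervised, for the situation where
  each dataset should impute the other's.
* **Stacked-modality phases** (`build_phase_masks()`): one input block, one
  output block. Equal blocks give *self-reconstruction*; different blocks
  give *alternative-reconstruction*, i.e. cross-modal translation trained on
  cells where both blocks are genuinely measured.

`fit_mosaic()` cycles through all phases *within* each epoch rather than
running them as a sequential curriculum: the phases are parts of one
training, and joint cycling avoids catastrophic forgetting of earlier
phases. For the tri-modal case (RNA+protein in dataset 1, protein+ATAC in
dataset 2) the default schedule is six phases — four self-reconstructions
(RNA|d1, protein|d1, protein|d2, ATAC|d2) and two translations from the
bridge modality (protein→RNA in d1, protein→ATAC in d2). For generation from
paired references, the schedule is source-modality self-reconstruction in
every dataset plus source→target translation in the references.

Unavailable blocks are zero-filled at dataset assembly and *flagged*; masks
gate computation, and phase construction refuses cells that lack ground
truth for the phase's output block. A phase never supervises padding.

### Inference readout

Imputation and generation read the decoder on a *noise-free* pass
($z_1 := \mu_z$, $\varepsilon = 0$) for determinism. For multimodal
integration each cell is embedded from the bridge modality when it measures
it (its first measured block otherwise), so all cells pass through the same
encoder sublayer and land in a common frame. Cluster assignment is the
classifier argmax. Label transfer gives each unlabeled cell the majority
label among labeled cells in its cluster; ties break to the smallest label
code, and clusters with no labeled members yield `"unassigned"`.

## What the synthetic generator emulates — and what it does not

`simulate_multimodal()` draws each cell's latent state
$z_c \sim \mathcal{N}(m_{\mathrm{type}(c)} + \delta_{\mathrm{batch}(c)}, I)$
in `d_sim = 8` dimensions and observes modality $m$ as
$\mathrm{softplus}(A_m z_c) + \varepsilon$, clipped at zero, with
$A_m$ a random linear map and $\varepsilon$ Gaussian with `sigma = 0.1`.
Type means sit on a randomly rotated regular simplex with edge length
`delta_type = 6`, so the separation parameter is a *guaranteed* pairwise
distance (in units of the within-type standard deviation), not merely an
expected one — this keeps the documented monotonic relationship between
`delta_type` and downstream cluster recovery well defined, and it requires
`n_types <= d_sim`. Batch shifts are random unit vectors scaled to
`batch_shift_norm = 1`: batch effects smaller than cell-type differences,
as is typical of replicate-donor or platform effects. By default 20% of
cells carry a type label (the semi-supervised regime in which the classifier
— and hence the covariate embedding it trains — operates); the generation
scenario uses fully labeled references and an unlabeled query.

This generator matches the model's own assumptions: shared latent states,
near-linear nonnegative observation, additive Gaussian noise, MSE-friendly
scales. Passing the packaged benchmarks therefore demonstrates that the
implementation recovers the structure its model class posits — it does
*not* demonstrate robustness to count overdispersion, zero inflation,
library-size variation, nonlinear batch distortions, or imbalanced and
hierarchical cell-type compositions found in real data. A Poisson-like
regime can be approximated by raising `sigma`, but real-data validation is
the user's responsibility.

The packaged scenarios (`make_fixture()`) are sized `tiny` (300
cells/dataset, for fast checks) and `small` (2000 cells/dataset, the scale
at which the package's own acceptance metrics are computed):

* `fig2`: two unpaired expression datasets, 100 genes, a random 20% withheld
  from the query for imputation (the 80/20 common/specific split follows the
  usual held-out-gene evaluation design for panel imputation);
* `fig4`: tri-modal — RNA(100)+protein(30) and protein(30)+ATAC(100) with
  distinct batch shifts;
* `fig6`: two labeled RNA+protein references plus an unlabeled RNA-only
  query whose protein block is withheld as generation truth.

## Evaluation metrics

* `correlation_suite()` — per-feature Pearson/Spearman correlations between
  predicted and true matrices, summarised as median and mean over features
  (mPCC/aPCC, mSCC/aSCC); zero-variance features are excluded and counted.
* `batch_entropy()` — mean normalized Shannon entropy of batch composition
  among each cell's `k = 30` nearest neighbours, over 10 subsamples of 100
  cells (seeded); 1 = perfect mixing. Invariant to rotation/translation.
* `silhouette_norm()` — mean silhouette width mapped to $[0,1]$ via
  $(s+1)/2$, so "no structure" reads 0.5; singleton groups score 0.
* `ari()` / `nmi()` — chance-adjusted Rand index and mutual information
  normalized by the arithmetic mean of the marginal entropies (both verified
  against brute-force oracles in the tests).
* `label_accuracy()` — confusion-matrix trace with per-class recall;
  `"unassigned"` counts as an error.

Centroid-shrinkage comparisons use `relative_batch_distance()` — inter-batch
centroid distance divided by mean within-batch RMS spread — because raw
feature space and the latent space have incommensurable units; the
dimensionless ratio is comparable across spaces.

## Numerical choices and degenerate inputs

* Softmax and softplus are computed in overflow-safe forms; classifier
  probabilities are floored at $10^{-12}$ inside the cross-entropy.
* An all-zero output mask (no supervised positions) is an error at phase
  construction and in the loss.
* Cluster ties in the argmax resolve to the first (lowest-index) cluster;
  label-transfer ties to the smallest label code.
* Empty specific-gene sets degrade to plain integration with an empty
  imputation matrix; an empty query dataset yields empty generated output;
  fully unlabeled data trains unsupervised given an explicit `n_clusters`.
* Training aborts with a diagnostic naming the phase and step if the loss
  becomes non-finite.
* All randomness — initialisation, shuffling, reparameterization noise,
  metric subsampling — flows from explicit integer seeds; on a
  single-threaded BLAS two runs with the same seed are identical.

## Design choices where the design was open

* **Depth.** "Three-layer" encoder/decoder is counted as two hidden relu
  layers plus the linear latent (respectively output) head.
* **No decoder re-conditioning.** The decoder consumes $z_1$ only; no
  target-covariate embedding is re-added before decoding. Cross-batch
  outputs arise from output masking and phase design, not decoder
  conditioning. Consequently the covariate embedding $W_E$ is trained
  solely through the classifier branch, which is why the workflows operate
  semi-supervised by default.
* **Likelihood.** Masked MSE on (log-scale) nonnegative values; biases are
  included in all dense layers.
* **Label transfer** is majority vote within classifier clusters, not kNN
  in the latent space.
* **Covariate code** indexes the dataset of origin; modality is encoded by
  the phase masks, not by the covariate.

## Known limitations

* Gaussian/MSE likelihood only; no negative-binomial or ZINB decoder.
* The classifier width $K$ must be supplied (or derivable from labels);
  there is no automatic model selection over $K$.
* H5AD files are not read directly (no HDF5 interface); use MTX or CSV.
* Minibatch training on CPU: practical up to ~$10^5$ cells and a few
  thousand stacked features, not beyond.
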