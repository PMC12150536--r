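---
title: "Identifying spatial domains from spatial multi-omics data with spaFuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying spatial domains from spatial multi-omics data with spaFuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spaFuse)
```

## The problem

Spatial omics assays measure molecular profiles — transcript counts,
antibody-derived tag (ADT) counts for surface proteins, chromatin
accessibility peaks — at barcoded capture locations ("spots") whose 2-D
tissue coordinates are known. A *spatial domain* is a region of tissue with a
coherent molecular identity: a cortical layer, a follicle, a tumor margin.
Two properties make domain calling hard. First, some domains are only
distinguishable when two modalities are read jointly — a region may look like
background in RNA but carry a protein signature, or vice versa. Second, a
single functional domain may be *discretely distributed*: several
spatially separated islands (T cell zones, follicles) that share one
molecular signature and should receive one label.

spaFuse addresses both by learning, per modality, two complementary feature
sets and fusing them:

* **attribute features** from a graph-free autoencoder, which preserve each
  spot's own molecular identity (this is what lets discrete islands of the
  same domain cluster together), and
* **structural features** from a multi-scale graph convolution over the
  spatial neighbor graph, which pull spatially coherent regions together
  and sharpen domain boundaries.

## Model

### Spatial neighbor graph

Coordinates are converted to a K-nearest-neighbor graph (`buildKnnGraph()`,
default `k = 3`): `A_ij = 1` if j is among the k Euclidean-nearest
neighbors of i, symmetrized by logical OR (the losses and the normalization
assume an undirected graph; a directed variant is available via
`symmetrize = FALSE`). Distance ties are broken by ascending spot index so
builds are deterministic. Self-loops enter only through the normalization

$$\bar A = D^{-1/2} (A + I) D^{-1/2},$$

which bounds the spectral radius by 1 and keeps deep propagation stable.
Multi-slice datasets get one graph per slice, assembled block-diagonally
(`assembleMultislice()`) — no cross-slice edges, so slices are analyzed in
parallel in a single training run.

### Multi-scale adaptive convolution (MACM)

One MACM layer computes, for scales $k = 1 \dots K$ (default $K = 4$),

$$h_k = \bar A^{\,k}\,\tanh(X W^{(k)}),$$

pools each scale over spots (column means), concatenates the pooled
summaries, and feeds them to a small MLP whose softmax output gives one
importance weight per scale; the layer output is the importance-weighted sum
$\sum_k w_k h_k$. Different tissues need different neighborhood ranges —
the attention lets the model choose. $\bar A^k$ is never materialized:
`h_k` is computed by k successive sparse products (a compiled kernel), and a
dense matrix-power oracle in the test suite pins the equivalence.

Design choices the source description leaves open, and what this package
does: scale weights are a global K-vector shared across spots (matching the
scalar products in the fusion sum); the importance MLP has one tanh hidden
layer of width `ceiling(K * dOut / 2)`; each scale applies its own
$W^{(k)}$ to the *layer input* (not chained across scales).

### Per-modality branch and multi-step fusion

Each modality branch contains:

* an autoencoder — encoder FC(d→d1)–LeakyReLU–FC(d1→d2)–LeakyReLU–FC(d2→d3)
  with a linear latent, and a mirrored decoder producing the reconstruction
  `x'`;
* a graph encoder of three MACM layers with the *same* widths, fused
  step-wise with the autoencoder's intermediate features via the mixing
  coefficient `a` (the "sigma" presets):

$$H_1 = \mathrm{MACM}_1(x), \quad
H_i = \mathrm{MACM}_i(a H_{i-1} + (1-a) h_{i-1}), \quad
H = a H_3 + (1-a) h_{\mathrm{latent}};$$

* a graph decoder of three MACM layers with mirrored widths mapping `H`
  back to the input width.

At `a = 0` the branch degenerates to the autoencoder; at `a = 1` attribute
fusion is disabled (the structure-only ablation). Branch embeddings are
concatenated across modalities (RNA first) into `Z`; with one modality the
pipeline runs unchanged on the single branch.

### Losses

Training minimizes the unweighted sum `L = L_R + L_G + L_S + L_con`:

* `L_R`: entry-mean MSE of each autoencoder reconstruction, summed over
  modalities. (A per-spot Frobenius²/n variant is selectable via
  `perSpot`; the entry-mean default keeps magnitudes comparable across
  modalities of different width.)
* `L_G`: entry-mean MSE of each graph-decoder output against the
  neighbor-aggregated input $\bar A x$.
* `L_S`: binary cross-entropy between $\sigma(Z Z^\top)$ and the binary
  adjacency over all $N^2$ ordered pairs (diagonal included with target 0;
  probabilities clamped at $10^{-7}$).
* `L_con`: a spatial InfoNCE in which a spot's positives are its graph
  neighbors. The default form puts *only non-neighbors* in the
  denominator, so the log-ratio can exceed zero and the loss can be
  negative; `standardInfonce = TRUE` switches to the textbook denominator
  (all spots except the anchor).

All four losses (and the full backward pass) are validated against scalar
double-loop oracles and finite-difference gradients in the test suite.

### Optimization, seeding, batching

The model is trained with Adam (learning rate 1e-3) for a fixed number of
epochs (default 200) under Glorot-uniform initialization; there is no early
stopping. Every stochastic component — initialization, batch partitioning,
K-means restarts — derives from the single `seed` in `trainConfig()`, and
runs are bit-reproducible under a fixed seed.

For datasets too large for the $O(N^2)$ pairwise losses, `fitBatched()`
partitions spots each epoch into random blocks of at most `batchSize`
(the reference regime uses 5000); each block trains on its induced
subgraph, re-normalized so isolated spots keep valid self-loop degrees, and
the pairwise terms cost $O(\mathrm{batchSize}^2)$. Blocks without edges are
skipped with a warning. At `batchSize >= N` batched training is exactly the
full fit.

### Domain calling and evaluation

Domains are called by seeded K-means (10 restarts) on `Z`; the domain count
is supplied by the user, as in the reference workflow (no automatic model
selection). Evaluation uses the pair-count ARI (the
`2(ad-bc)/((a+b)(b+d)+(a+c)(c+d))` form, verified equivalent to the
Hubert–Arabie formulation), NMI with the arithmetic-mean normalizer, AMI
with the exact hypergeometric expected-MI, homogeneity/completeness, optimal
cluster-to-domain assignment by a Hungarian solver (shortest augmenting
path), per-domain F1 after matching, and one-vs-rest Wilcoxon rank-sum
marker ranking with Benjamini–Hochberg q-values (top 3 per domain by
default). AMI uses the standard arithmetic-mean normalizer
`mean(H)-E[MI]`, under which AMI = 1 on identical partitions; the
sum-form denominator `H(U)+H(V)-2E[MI]` seen in some write-ups evaluates
to 0.5 there and is deliberately not used.

## Preprocessing pipelines

* **RNA (high gene coverage):** drop genes detected in fewer than 10 spots;
  library-size normalize each spot to 1e4 and `log1p` (the scanpy-style
  convention — the target sum is a tool convention, not a stated value);
  keep the top 3000 highly variable genes by bin-standardized dispersion
  (Seurat-flavor, 20 mean bins); PCA to the partner modality's dimension,
  or no PCA in single-omics mode (work at HVG dimension).
* **Protein (ADT):** per-spot centered log-ratio with pseudocount 1
  (`y = log1p(p) - mean(log1p(p))`; per-spot keeps rows comparable and is
  zero-safe), then PCA to n−1 components for an n-protein panel.
* **Chromatin peaks:** TF-IDF then truncated SVD (LSI) to 200 dimensions.
* **Low-coverage panels / generic features:** log-normalize then PCA
  (default 20 components); CLR is not applied to RNA-type panels.

Every step preserves spot count and order and advances an explicit
raw → normalized → reduced state machine, so pipelines cannot be composed
out of order. `runPipeline()` additionally rescales each processed matrix
by one global factor to unit overall standard deviation — relative
component variances are preserved (no whitening) while the tanh layers stay
out of saturation.

## The synthetic data generators

The package ships generators that emulate the qualitative regimes the
method targets, with full ground truth; they are first-class, tested code.
The count model is shared: feature f in domain d has log-mean
$\mu_{fd}$ (baseline 0; markers — a random 20% subset per domain —
baseline + 1.5), and a spot's count is
$\mathrm{Poisson}(\exp(\mu_{fd} + \varepsilon))$,
$\varepsilon \sim N(0, \mathrm{noise})$ with noise 0.3 by default
("moderate": marker log-effect five times the jitter SD). At `noise = 0`
counts are `round(exp(mu))`, so the noiseless datasets are exactly
separable. Geometry is a regular square grid in arbitrary units.

* `makeLayered()`: horizontal bands — the contiguous, layered-tissue
  regime.
* `makeCross()`: four bands plus a plus-shaped Domain 0 whose horizontal
  bar is marked only in modality 1 and vertical bar only in modality 2
  (`signalSplit` apportions the total signal). Either modality alone sees
  just one arm as a marked region; recovering the full cross as one domain
  requires joint analysis — the regime in which multi-omics methods are
  claimed to win.
* `makeDiscrete()`: one domain realized as several separated circular blobs
  sharing a signature, on two contiguous background domains — the
  discretely distributed regime.
* `makeMultislice()`: replicates a base dataset across slices with a
  per-slice scalar log-offset (slice s shifted by
  `batchScale * (s - (nSlices+1)/2)`), i.e. capture-efficiency batch
  effects. This is deliberately the *removable* kind of batch effect:
  per-spot library-size normalization eliminates it, which is the regime
  under which multi-slice parity is a meaningful claim for a model with no
  explicit batch-correction component. Feature-specific batch shifts are
  *not* modeled — a model of this family cannot remove them, and passing
  tests here say nothing about such data.

What the generators do **not** emulate: hexagonal Visium geometry, spot
deconvolution mixtures, zero-inflation beyond Poisson sampling, mean–
variance trends, or segmentation errors of single-cell-resolution assays.
Passing the recovery studies shows the architecture and losses do what they
claim on clean, well-specified signal; it does not certify performance on
real tissue.

## Numerical and design choices

* **Hidden widths** default to (256, 128, 64); the only hard constraint is
  that autoencoder and graph-encoder widths match layer-for-layer, which
  the fusion equations require. The synthetic studies in the tests and the
  acceptance script use (32, 16, 8) after 20-dimensional PCA — ample for
  50-feature synthetic modalities and 5 domains.
* **InfoNCE temperature.** tau defaults to 1.0. At tau = 0.5 the
  contrastive gradient is sharp enough to dominate the other three losses
  on the synthetic studies: the embedding then encodes spatial *position*
  (neighbors similar, distant spots dissimilar) rather than domain
  identity, and clustering quality drops below that of the raw input
  features. tau = 1.0 softens the pairwise gradients to the point where
  the contrastive term regularizes instead of dominating. The temperature
  remains a config knob.
* **Study sizes.** The cross study uses a 30×30 grid (900 spots, 200
  epochs, seeds 2020–2024); the ablation and discrete-domain studies use
  24×24/20×20 grids at 100 epochs; batched-training parity uses a 45×45
  grid (2025 spots, batch 500). These sizes give stable medians across the
  five seeds while keeping the full suite runnable on a laptop CPU.
* **Ties and degenerate inputs.** KNN distance ties break by spot index;
  all-zero spots stay all-zero through normalization (with a warning);
  constant features are skipped by the marker test; single-cluster
  degenerate metric cases follow documented conventions (ARI 1 with a
  warning, NMI/AMI 1 iff both partitions are single-cluster).
* **Gradient of the clamped BCE** uses the exact unclamped derivative
  `sigmoid(s) - a` (bounded, standard practice); clamping affects only the
  reported loss value.

## Known limitations

* The pairwise losses are dense $O(N^2)$; full-graph training beyond
  ~10⁴ spots should use `fitBatched()`.
* The negatives-only InfoNCE denominator is the default; its value is
  not comparable to standard InfoNCE implementations (it can be
  negative). `standardInfonce = TRUE` selects the textbook form.
* Three-or-more-modality fusion by plain concatenation is out of scope, as
  is H&E image integration and any feature-space (expression) neighbor
  graph.
* K-means requires the user to supply the domain count.

## A minimal run

```{r example, eval = FALSE}
ds <- makeCross(nSide = 30, seed = 2020)
cfg <- trainConfig(epochs = 200, layerDims = c(32, 16, 8), seed = 2020)
res <- runPipeline(ds, nClusters = 5, config = cfg)
res$metrics
head(rankMarkersWilcoxon(logNormalize(modalities(ds)[[1]]), res$labels))
```
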