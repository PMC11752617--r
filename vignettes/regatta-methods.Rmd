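---
title: "Methods: joint attention-network and spot-graph inference from spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint attention-network and spot-graph inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spatially resolved transcriptomics (SRT) measures an expression matrix
`X1` (M genes × N spots) together with spot coordinates. Two questions
are usually asked of such a slice: *which genes regulate which* (a gene
regulatory network, GRN), and *which spots form coherent functional
domains or cell types*. regatta answers both jointly, in a
self-supervised way that needs no labels: a gene-level attention model
learns a gene–gene weight matrix `S` while a spot-level autoencoder
with a self-expressive constraint learns a spot–spot graph `Z`, and
distribution-alignment losses couple the two so that spatial context
informs the network and regulatory structure informs the clustering.

## Model components and their assumptions

### Spatially local graph B

Spots are embedded with PCA (`nPcs = 50` components by default, capped
by the data); for each spot the `k` nearest neighbours by Euclidean
coordinate distance are found (`k = 10` by default, the Visium-like
setting; 30 suits bead/bin-level platforms). For multi-slice 3D data
all slices are projected along z into a common plane and a spot's
candidates are restricted to slices at most one index away — a ±1
window, the narrowest reading of "adjacent slices". On each neighbour
pair the unnormalised weight is

\[ D_{ij} = \exp\!\Big(2 - \frac{d(U_i, U_j)}{\lVert U_i\rVert\,\lVert U_j\rVert}\Big), \qquad
   B_{ij} = D_{ij} \Big/ \sum_i D_{ij}, \]

with `d` the Euclidean distance between embedding columns. The bracket
in the source formulation is ambiguous between an inner product and a
distance; the prose reading (distance) is the default and a cosine mode
is available (`similarity = "cosine"`). The denominator runs over the
sparse kNN support only, so each non-empty column of `B` sums to one.
A zero-norm embedding column (a spot with no expression signal) is an
error naming the spot rather than a silent NaN.

### Gene-level attention and the network S

Genes are tokens; a gene's feature vector is its expression across the
N spots. Per head t of each encoder unit,

\[ S_t = \mathrm{Normalize}\big(\mathrm{softmax}(Q_t K_t^\top/\sqrt{d_t}) + \mu A\big), \]

where `Normalize` renormalises rows to sum one (keeping each row a
convex combination over genes), and `A` is a prior interaction network
used only during pretraining (`mu = 0.2`; fine-tuning forces
`mu = 0`). SVD factors of `A` (`U~ = U sqrt(Sigma)`,
`V~ = V sqrt(Sigma)`, top `peRank = 8` components) feed a learnable
projection that is added to the layer-0 input as positional encodings —
the standard input-additive convention, since the injection point is
otherwise unspecified.

Three design choices here were genuinely open and matter in practice:

- **Masked diagonal** (`maskDiag = TRUE`). The model's stated premise is
  that each gene's expression is reconstructable from *other*,
  co-expressed genes. Without the mask, self-attention trivially copies
  each gene onto itself, and the off-diagonal weights — the network —
  carry no signal. Masking makes the premise mechanical.
- **Identity value path** (`valueMode = "identity"`). The augmentation
  equation produces the next layer directly as concatenated head
  outputs `S_t V_t`. We let each head own a contiguous block of spot
  columns and set `V_t` to the input restricted to that block, followed
  only by a per-gene gain and offset. The head output is then literally
  an attention mixture of the other genes' expression, so a trained
  `S` *is* the gene-mixing operator that reconstructs the data. The
  alternative (`valueMode = "learned"`: per-head value projections, an
  output projection and a residual feed-forward sublayer) is provided,
  but with M ≪ N any learned post-attention linear map can rewire
  arbitrary head outputs onto the target, which decouples the attention
  weights from the reconstruction and empirically destroys edge
  recovery; it remains useful as a higher-capacity encoder when `S`
  itself is not the quantity of interest.
- **One encoder unit by default** (`nLayers = 1`). With stacked units
  only the *composition* of the per-layer mixtures must reconstruct the
  data, so individual attention maps are underdetermined and their mean
  dilutes; a single unit makes the aggregated `S` directly
  interpretable. The three-unit stack of the reference architecture is
  one flag away and is what the pretraining configuration uses.

The aggregated network is the arithmetic mean of all per-layer,
per-head maps. A printed variant of the denominator (heads + depth) is
available behind `denom = "printed"`; the two differ by a positive
global scale, so every downstream edge ranking is identical (this is
asserted in the tests). Directionality: row i of an attention map lists
the genes gene i is reconstructed *from*, i.e. its putative
regulators. A regulator→target edge is therefore scored by
`S[target, regulator]`, and a TF's regulon collects the top entries of
its incoming-attention column.

### Spot-level autoencoder and the manifold graph Z

A shared-weight variational autoencoder (encoder depth l = 2: genes →
128 with ELU, then linear mean/log-variance heads of width 10; decoder
mirrored, total depth L = 4) processes both views through the same
parameters. The exact likelihood of the ELBO is unprinted in the source
formulation; we use the standard Gaussian choice — squared-error
reconstruction plus the analytic KL to a standard normal,
`KL = (mu^2 + sigma^2 - 1 - log sigma^2)/2` per unit — averaged per
spot. Both views' decoders reconstruct the *original* expression: the
augmented view is by construction a reconstruction of `X1`, so
anchoring its ELBO to `X1` is what gives the attention a well-posed
task. Reparameterised latent samples are used during training; the
deterministic means are used at read-out.

The self-expressive graph `Z` (N × N, learnable) enters through

\[ \mathcal{L}_{manifold} = \frac1L \sum_{i=1}^L
   \frac{\lVert H_1^{(i)}(I+\alpha B) - H_1^{(i)} Z\rVert_F^2}{\lVert H_1^{(i)}\rVert}
   + \frac{\lVert H_2^{(i)}(I+\alpha B) - H_2^{(i)} Z\rVert_F^2}{\lVert H_2^{(i)}\rVert}, \]

with Frobenius norms in the denominators and `alpha = 1` by default.
`Z` is initialised at `I + alpha B`. That point is an exact global
minimiser of the constraint for *any* representations (the residual is
identically zero), and because nothing else in the objective touches
`Z`, it is also a stationary point of the whole problem: `Z` provably
stays at `I + alpha B` during training and the loss term stays at zero.
The learned spot graph is therefore the expression-weighted spatial
graph itself, which is exactly what the clustering consumes; the
machinery still matters because any *other* initialisation would be
pulled to the same fixed point through representations that the other
losses shape. Degenerate all-zero layers are skipped with a warning
rather than producing 0/0.

### Distribution alignment

Global alignment is the mean over layers of the maximum mean
discrepancy between the two views' spot samples, with the fixed-width
Gaussian kernel `K(x,y) = exp(-||x-y||^2/2)` as printed — no median
heuristic. The estimator is the biased V-statistic (1/N² weights),
generalised to unequal sizes (1/n², 1/m², 2/nm) for robustness even
though both views always share the same spots here; tiny negative
round-off is clamped at zero. Local alignment averages, over layers and
spots, the MMD between the views restricted to each spot's spatial
neighbourhood; the implementation aggregates all neighbourhoods against
three full kernel matrices per layer, which is algebraically identical
to the per-spot double loop (the tests compare the two) and an order of
magnitude faster. The contrastive term
`||H1 - H2||_F^2 / ||H1 + H2||_F` prevents per-spot drift; an exactly
opposite pair of representations gives a zero denominator, which skips
the layer with a warning.

Two further choices were open:

- **Layer-0 views join the contrastive/alignment sums**
  (`includeInput = TRUE`). The encoder/decoder stack defines
  `H^(0) = X`; including the inputs among the aligned layers gives the
  augmented view a direct, scale-free anchor to the original. Without
  it the anchor acts only through the shared encoder, which can (and in
  practice does) dodge the penalty by shrinking the directions in which
  the views differ, leaving the attention untrained.
- **Cross-dimension weight `lambda2 = 1`** (with `lambda1 = 1`). The
  source defers both weights to a sensitivity analysis stating
  stability "within a certain range"; at 0.1 the coupling is too weak
  to anchor the augmented view at this scale, and 1.0 balances the
  ELBO and alignment blocks. Both remain ordinary config fields.

### Optimisation

AdamW (decoupled weight decay 1e-4 on weight matrices; never on biases
or on `Z`) at learning rate 1e-3 under a linear warmup (20 steps at
desk scale, standing in for the reference 10,000 at corpus scale) and
linear decay. Training is full-batch, one step per epoch, 300 epochs by
default, with early stopping when the relative total-loss change stays
below 1e-4 for 20 consecutive steps and divergence protection that
returns the last finite-loss parameters. The model input is per-gene
standardised (`scaleGenes = TRUE`): attention mixtures are convex, so
without standardisation a gene with an intermediate expression *level*
is best reconstructed by bracketing it between unrelated high and low
genes; z-scoring removes the level nuisance so attention chases shape,
which is where the regulatory signal lives. Every gradient in the model
— through the attention softmax and row renormalisation, the shared
VAE, the reparameterisation, and all five loss families — is derived
analytically; the test suite verifies them against central finite
differences to ~1e-6 relative error in both value modes.

Pretraining differs in three ways: `mu > 0` activates the prior bias
and positional encodings; spots are partitioned into token datasets
(`token_size` spots each, 3000 in the reference setting) trained
sequentially with parameters carried forward; and after each shuffled
pass over all tokens the aggregated `S` is compared with the previous
pass, stopping when its relative Frobenius change drops below `sTol`
(1e-3). Because the spot-side projection widths are token-size
dependent, a ragged final token is filled up to `token_size` by
resampling its own spots; token-order shuffling draws from a dedicated
seed stream so it never perturbs the weight-initialisation stream.

## Downstream analyses

**Regulons.** For each TF in a supplied list, the top `topK = 50`
genes of its incoming-attention column (self excluded, ties by gene
id); regulons under `minTargets = 10` members are dropped. Motif-based
pruning is an interface: a backend maps (TF, targets) to the supported
subset, the default pass-through backend accepts everything and logs a
notice, and any external cis-regulatory tool can be plugged in.

**Activity.** Per spot, genes are ranked by descending expression
(ties by gene id — each tie can move an activity by less than 1/M);
the activity of a regulon is the area under the recovery curve of its
members over the top `ceiling(thresholdFrac * M)` ranks, normalised to
[0, 1] by the maximal attainable area. `thresholdFrac` defaults to
0.05, the conventional top-5% cutoff. Being rank-based, the score is
invariant to any strictly monotone transform of a spot's profile.

**Clustering.** Leiden community detection (modularity objective) on
the symmetrised, negative-clipped `Z` with the diagonal dropped;
deterministic under a fixed seed. The resolution defaults to 1 and can
be targeted to a desired cluster count by bisection — the analogue of
matching the resolution to known anatomy.

**Cluster-specific regulons.** One-vs-rest log2 fold change of mean
activity with pseudocount 1e-9 and a rank-sum AUROC (the Mann–Whitney
U statistic scaled to [0, 1]); the default filter keeps rows with
log2FC > 0.25 and AUROC > 0.75, and `minAUROC = NULL` gives the
fold-change-only mode used for high-resolution platforms. Singleton
clusters yield an undefined AUROC and are flagged, not silently
dropped.

## Evaluation metrics

Edge rankings are scored by AUROC and AUPRC over a candidate universe
(TF rows when a TF list is given, otherwise all ordered pairs),
unranked candidates scoring zero, mid-rank tie handling, and a
threshold-sweep PR curve integrated trapezoidally. Run-to-run stability
is the Spearman correlation of consecutive runs' full rankings plus the
Jaccard overlap of top-k edge sets with k the true edge count. Spatial
continuity is Moran's I with binary kNN weights by default (B-weighted
mode available). Clustering accuracy is the adjusted Rand index from
the pair-counting contingency table. Each metric is checked against an
independent brute-force implementation (explicit double loops,
exhaustive threshold sweeps) to 1e-10 on small instances, and against
third-party implementations (ape's Moran's I, mclust's ARI) where one
exists.

## The synthetic-data generator

The generator emulates the benchmark design of planting a known network
and simulating spatialised expression from it, at desk scale:

1. **Network.** `nGenes = 20` genes, the first `nTFs = 5` being TFs;
   every non-TF gene gets 1–2 TF regulators, activating with
   probability 0.75. Each TF receives a 0/1 basal-activity pattern over
   `nDomains = 3` domains (patterns pairwise distinct, every TF varying,
   every domain non-empty) — the source of spatial regulatory
   heterogeneity.
2. **Cells.** Hill-kinetics dynamics with unit decay: TFs relax to
   their domain's basal production (2 when active, 0.1 when not),
   modulated per cell by a uniform(0.25, 1.75) activity multiplier so
   cells occupy a spread of regulatory states; targets relax to twice
   the mean Hill response (coefficient 2, threshold 1) of their
   regulators; Euler–Maruyama integration (80 steps of 0.1) with
   noise `noiseSd = 0.2`, clipped at zero. `noiseSd = 0` switches every
   stochastic element off and gives the deterministic ODE limit. This
   is a BoolODE-equivalent regime — regulator-to-target dependence with
   tunable noise — not a re-implementation of any specific simulator.
3. **Spots.** A square grid split into axis-aligned domain blocks
   (`grid_blocks`) or a smoothly mixing `gradient`; cells are grouped by
   proximity along the leading principal component within their regime
   (PCA rather than t-SNE, for determinism) and summed into spots of
   `cellsPerSpot = 5`.

All randomness flows from the single dataset seed. What the generator
does *not* emulate: sequencing-depth variation and count noise,
dropout, segmentation errors, batch effects, TF–TF regulation, and
cell-type mixtures unrelated to the planted regimes. Tests passing on
these data therefore demonstrate that the machinery recovers planted
regulatory and spatial structure under idealised measurement, not that
it will reach the same accuracy on a real slice.

## Problem sizes used by the tests and the acceptance run

The default study conditions are 20 genes / 5 TFs / 3 domains / 500
spots of 5 cells; fine-tuning runs 300 full-batch steps. Unit tests use
smaller instances (≤ 12 genes, ≤ 100 spots, ≤ 15 steps) chosen so each
property is exercised in seconds; the descent property is checked on a
20-gene / 300-spot configuration. These sizes are the package's choice
of desk-scale experiment; the corpus-scale constants of the reference
architecture (31k-gene vocabulary, 3000-spot tokens, 10k warmup steps)
remain available through the configuration.

## Known limitations

- The attention network is convex (non-negative, row-normalised), so
  repression edges are detectable only indirectly; on the synthetic
  benchmark most missed edges are repressions.
- Because every gene in the planted panel is downstream of a
  domain-varying TF, even a random gene set's activity is spatially
  structured; the spatial-continuity contrast between a block-marking
  regulon (see `markerRegulon()`) and random sets therefore holds as a
  paired average over seeds, not for every individual draw — unlike in
  real data, where most genes carry no spatial signal.
- `Z` coincides with `I + alpha*B` at its analytic optimum, so spot
  clustering reflects the expression-weighted spatial graph; datasets
  whose domains are not locally contiguous would need a larger `k` or
  a different graph.
- Fine-tuning from a pretrained checkpoint requires the same gene panel
  and (for the spot-side projections) the same width, matching the
  fixed-vocabulary design of the reference setting.
- The h5ad bridge requires a Python with `anndata` on `PATH`; without
  one, use MTX or dense text.
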