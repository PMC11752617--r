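# regatta

Joint inference of a **gene–gene regulatory attention network** and a
**spot–spot similarity graph** from spatially resolved transcriptomics
(SRT), with the downstream regulon toolkit (activity scoring, spatial
clustering, marker filtering) and a benchmarking suite.

## Who this is for

Computational biologists who have an SRT slice — an expression matrix of
M genes × N spots plus spot coordinates — and want to know *which genes
regulate which* in a way that respects spatial context, and *which spots
belong together* as functional domains or cell types, without requiring
cluster annotations up front.

## The model

Two coupled learners share one self-supervised objective:

- **Gene dimension.** A multi-head self-attention encoder over genes
  (gene tokens, spot-feature columns) rebuilds an augmented expression
  matrix `X2` from the original `X1`: per head t,

  `S_t = Normalize( softmax(Q_t K_t' / sqrt(d_t)) + mu * A )`,

  where the diagonal is masked so every gene is reconstructed as an
  attention-weighted mixture of *other* genes' expression — the working
  assumption being that a gene's expression is predictable from its
  (co-)regulators. `A` is an optional prior interaction network whose
  weight `mu` is active only in pretraining (default 0.2; 0 during
  fine-tuning); SVD factors of `A` provide learnable positional
  encodings. The mean attention map over layers and heads is the
  inferred gene–gene network `S`.

- **Spot dimension.** A shared-weight variational autoencoder (2-layer
  encoder and decoder, hidden 128, latent 10) embeds both views, with a
  learnable self-expressive spot graph `Z` tied to the spatially local
  kNN graph `B` through the manifold constraint

  `L_manifold = (1/L) * sum_i ||H^(i)(I + alpha*B) - H^(i) Z||_F^2 / ||H^(i)||`.

  `B` has weights `B_ij = D_ij / sum_i D_ij` with
  `D_ij = exp(2 - d(U_i,U_j)/(||U_i|| ||U_j||))` on kNN pairs in PCA
  space (3D multi-slice data: neighbours restricted to adjacent slices).

- **Coupling.** Maximum mean discrepancy alignment of the two views'
  layer representations, globally and within each spot's spatial
  neighbourhood (Gaussian kernel `exp(-||x-y||^2/2)`), plus a
  contrastive term `||H1 - H2||_F^2 / ||H1 + H2||`; the total objective

  `L = L_ELBO1 + L_ELBO2 + lambda1 * L_manifold + lambda2 * (L_CL + L_GD + L_SLD)`

  is minimised with AdamW under a linear-warmup schedule, all gradients
  derived analytically in plain R matrix algebra (verified against
  finite differences in the test suite).

Downstream, `S` is decomposed into **regulons** (a TF plus its top
targets by incoming attention), per-spot regulon activity is the
normalised area under the recovery curve of regulon members across each
spot's expression ranking, spot clusters come from Leiden community
detection on the symmetrised `Z`, and cluster-specific regulons are
filtered at AUROC > 0.75 and log2 fold change > 0.25.

## Worked example

```r
library(regatta)

# a synthetic slice with a planted 20-gene / 5-TF network, 3 spatial
# domains, 500 spots of 5 cells each
syn <- simulateSRTDataset(nGenes = 20, nTFs = 5, nSpots = 500,
                          cellsPerSpot = 5, seed = 7)
se  <- preprocessExpression(syn@experiment)      # log1p
fit <- fineTune(se, trainConfig(mode = "finetune", seed = 7))

grn   <- truthNetwork(syn)
edges <- exportEdges(fit@network, tfList = grn@tfs)
edgePredictionScores(edges, truthEdges(grn),
                     edgeUniverse(grn@genes, grn@tfs))
#> $auroc
#> [1] 0.7323944
#> $auprc
#> [1] 0.53849

lab <- clusterSpots(fit, seed = 7, nClusters = 3)
clusteringARI(lab, domainLabels(syn))
#> [1] 1
```

So on this seed the fitted attention network ranks the planted
regulator–target edges at AUROC 0.73 over the 95-pair TF×gene universe
(a shuffled-truth control sits near 0.5; `scripts/acceptance.R` prints
0.82 on its seed-1 run), and Leiden on the learned spot graph recovers
the three planted domains exactly (ARI = 1).

Regulons and their spatial activity:

```r
rs  <- extractRegulons(fit@network, grn@tfs, topK = 5, minTargets = 3)
act <- aucellActivity(se, rs, thresholdFrac = 0.3)
specificRegulons(act, lab)        # cluster-specific regulons table
```

A thin CLI over the same functions ships at `inst/cli/regatta.R`
(subcommands `simulate`, `graph`, `fit`, `grn`, `activity`, `cluster`,
`markers`, `evaluate`).

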