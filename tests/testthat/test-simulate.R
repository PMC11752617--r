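test_that("planted networks satisfy their structural contract", {
  grn <- simulatePlantedGRN(nGenes = 15, nTFs = 4, nDomains = 3, seed = 2)
  expect_s4_class(grn, "PlantedGRN")
  expect_length(grn@genes, 15)
  expect_length(grn@tfs, 4)
  nontf <- setdiff(grn@genes, grn@tfs)
  expect_true(all(nontf %in% grn@edges$target))
  expect_false(any(grn@edges$regulator == grn@edges$target))
  # domain patterns distinct, every TF varies, every domain has a TF on
  act <- grn@tfActivity
  expect_equal(anyDuplicated(t(act)), 0L)
  expect_true(all(colSums(act) > 0))
  # identical seed, identical network
  expect_identical(grn, simulatePlantedGRN(15, 4, 3, seed = 2))
})

test_that("noise-free dynamics reach the activated fixed point", {
  # single activator edge A -> B, A held high
  edges <- data.frame(regulator = "A", target = "B", sign = 1)
  grn <- PlantedGRN(edges, tfs = "A", genes = c("A", "B"),
                    tfActivity = matrix(1, 1, 1, dimnames = list("A", NULL)))
  sim <- simulateCells(grn, nCells = 4, noiseSd = 0, seed = 1,
                       nSteps = 400, dt = 0.1)
  # A relaxes to its production rate aHigh = 2; B to aHigh * hill(2)
  expect_equal(unname(sim$cells["A", ]), rep(2, 4), tolerance = 1e-3)
  hill2 <- 2^2 / (1 + 2^2)
  expect_equal(unname(sim$cells["B", ]), rep(2 * hill2, 4), tolerance = 1e-3)
})

test_that("simulation is byte-identical under a fixed seed", {
  grn <- simulatePlantedGRN(seed = 3)
  a <- simulateCells(grn, 50, seed = 9)
  b <- simulateCells(grn, 50, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a$cells,
                         simulateCells(grn, 50, seed = 10)$cells))
})

test_that("activation edges induce positive dependence (permutation test)", {
  edges <- data.frame(regulator = "A", target = "B", sign = 1)
  grn <- PlantedGRN(edges, tfs = "A", genes = c("A", "B"),
                    tfActivity = matrix(1, 1, 1, dimnames = list("A", NULL)))
  sim <- simulateCells(grn, 500, noiseSd = 0.2, seed = 21)
  x <- sim$cells["A", ]; y <- sim$cells["B", ]
  obs <- cor(x, y, method = "spearman")
  set.seed(22)
  perm <- replicate(999, cor(x, sample(y), method = "spearman"))
  p <- (1 + sum(perm >= obs)) / 1000
  expect_gt(obs, 0)
  expect_lt(p, 0.01)
})

test_that("binning conserves mass and keeps domains contiguous", {
  syn <- simulateSRTDataset(nGenes = 10, nTFs = 3, nDomains = 3,
                            nSpots = 36, cellsPerSpot = 2, seed = 13)
  se <- syn@experiment
  # column sums conserved: sum of spot totals = sum of binned cell totals
  used <- unlist(syn@spotMembers)
  expect_equal(sum(exprValues(se)), sum(syn@cells[, used]))
  expect_equal(length(used), ncol(se) * 2)
  expect_equal(anyDuplicated(used), 0L)
  # spots of each domain form one contiguous block of grid columns
  co <- spotCoords(syn)
  dom <- domainLabels(syn)
  for (d in unique(dom)) {
    xs <- range(co[dom == d, "x"])
    others <- co[dom != d, "x"]
    expect_false(any(others >= xs[1] & others <= xs[2]))
  }
  # each spot's member cells carry the spot's regime
  for (s in c(1, 10, 30))
    expect_true(all(syn@cellDomain[syn@spotMembers[[s]]] == dom[s]))
})

test_that("one cell per spot is a permutation of the cell columns", {
  syn <- simulateSRTDataset(nGenes = 8, nTFs = 2, nDomains = 2,
                            nSpots = 16, cellsPerSpot = 1, seed = 14)
  used <- unlist(syn@spotMembers)
  expect_equal(sort(used), seq_len(16))
  expect_equal(exprValues(syn@experiment),
               syn@cells[, used], ignore_attr = TRUE)
})

test_that("insufficient cells are refused", {
  grn <- simulatePlantedGRN(nGenes = 8, nTFs = 2, nDomains = 2, seed = 5)
  sim <- simulateCells(grn, 10, seed = 5,
                       cellDomain = rep(1:2, each = 5))
  expect_error(binToSpots(sim$cells, sim$cellDomain, grn, nSpots = 16,
                          cellsPerSpot = 2, seed = 5), "insufficient")
})

test_that("gradient layout mixes regimes but labels the majority", {
  syn <- simulateSRTDataset(nGenes = 10, nTFs = 3, nDomains = 3,
                            nSpots = 25, cellsPerSpot = 4,
                            layout = "gradient", seed = 15)
  dom <- domainLabels(syn)
  expect_gte(length(unique(dom)), 2L)
  for (s in seq_along(syn@spotMembers)) {
    tab <- tabulate(syn@cellDomain[syn@spotMembers[[s]]], 3)
    expect_equal(which.max(tab), dom[s])
  }
})

test_that("a full dataset writes to plain-text files", {
  syn <- simulateSRTDataset(nGenes = 8, nTFs = 2, nDomains = 2,
                            nSpots = 9, cellsPerSpot = 2, seed = 16)
  d <- tempfile("simout")
  writeDataset(syn, d)
  expect_true(all(file.exists(file.path(d, c(
    "expression/matrix.mtx", "coords.tsv", "truth_edges.tsv",
    "domains.tsv", "tfs.txt")))))
  back <- readExpression(file.path(d, "expression"), "mtx")
  expect_equal(exprValues(back), exprValues(syn@experiment),
               tolerance = 1e-12, ignore_attr = TRUE)
})
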