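test_that("regulon extraction sorts the TF's incoming weights", {
  genes <- c("TF1", "TF2", "a", "b", "c")
  S <- matrix(0, 5, 5, dimnames = list(genes, genes))
  # gene 'a' attends TF1 strongly, 'b' moderately, 'c' weakly
  S["a", "TF1"] <- 0.9; S["b", "TF1"] <- 0.5; S["c", "TF1"] <- 0.1
  S["a", "TF2"] <- 0.2; S["c", "TF2"] <- 0.8
  rs <- extractRegulons(S, c("TF1", "TF2"), topK = 2, minTargets = 1)
  expect_named(regulons(rs), c("TF1(+)", "TF2(+)"))
  expect_equal(regulons(rs)[["TF1(+)"]]$targets, c("a", "b"))
  expect_equal(regulons(rs)[["TF2(+)"]]$targets, c("c", "a"))
  # dominant single entry with topK = 1
  r1 <- extractRegulons(S, "TF1", topK = 1, minTargets = 1)
  expect_equal(regulons(r1)[["TF1(+)"]]$targets, "a")
  # all-zero column: deterministic lexicographic tie-break
  S0 <- S; S0[, "TF2"] <- 0
  r0 <- extractRegulons(S0, "TF2", topK = 2, minTargets = 1)
  expect_equal(regulons(r0)[["TF2(+)"]]$targets, c("TF1", "a"))
  # minTargets filter drops small regulons
  expect_length(regulons(extractRegulons(S, "TF1", topK = 2,
                                         minTargets = 3)), 0L)
  expect_error(extractRegulons(S, "nope"), "overlap")
})

test_that("pruning honours the backend verdicts and min size", {
  genes <- c("TF1", "a", "b", "c")
  S <- matrix(runif(16), 4, 4, dimnames = list(genes, genes))
  rs <- extractRegulons(S, "TF1", topK = 3, minTargets = 1)
  # pass-through: unchanged
  expect_message(out <- pruneRegulons(rs), "pass-through")
  expect_equal(regulons(out), regulons(rs))
  # mock backend rejecting one named target
  drop_b <- function(tf, targets) setdiff(targets, "b")
  pr <- suppressMessages(pruneRegulons(rs, drop_b))
  expect_false("b" %in% regulons(pr)[["TF1(+)"]]$targets)
  expect_setequal(regulons(pr)[["TF1(+)"]]$targets,
                  setdiff(regulons(rs)[["TF1(+)"]]$targets, "b"))
  # rejecting everything drops the regulon via the size rule
  none <- function(tf, targets) character(0)
  expect_length(regulons(suppressMessages(pruneRegulons(rs, none))), 0L)
  boom <- function(tf, targets) stop("db missing")
  expect_error(suppressMessages(pruneRegulons(rs, boom)), "backend failed")
})

test_that("recovery-curve activity hits its extremes and matches brute force", {
  M <- 10
  genes <- sprintf("g%02d", 1:M)
  x <- matrix(0, M, 1, dimnames = list(genes, "s1"))
  x[, 1] <- M:1                      # g01 highest ... g10 lowest
  mk <- function(tf, tg) new("RegulonSet", regulons = setNames(list(
    list(tf = tf, targets = tg, weights = rep(1, length(tg)))),
    paste0(tf, "(+)")), geneUniverse = genes)
  # members occupy exactly the top ranks: activity 1
  a1 <- SummarizedExperiment::assay(
    aucellActivity(x, mk("g01", "g02"), 0.5), "activity")
  expect_equal(unname(a1[1, 1]), 1)
  # members all below the threshold: activity 0
  a0 <- SummarizedExperiment::assay(
    aucellActivity(x, mk("g09", "g10"), 0.3), "activity")
  expect_equal(unname(a0[1, 1]), 0)
  # ranks {1, 4} at threshold 0.5 vs exhaustive rank walk
  am <- SummarizedExperiment::assay(
    aucellActivity(x, mk("g01", "g04"), 0.5), "activity")
  expect_equal(unname(am[1, 1]),
               bruteAUCell(x[, 1], genes, c("g01", "g04"), 0.5),
               tolerance = 1e-12)
  # many random regulons against the brute-force oracle
  set.seed(71)
  xr <- matrix(rnorm(M * 4), M, 4, dimnames = list(genes, paste0("s", 1:4)))
  for (rep in 1:10) {
    mem <- sample(genes, 3)
    act <- SummarizedExperiment::assay(
      aucellActivity(xr, mk(mem[1], mem[-1]), 0.4), "activity")
    for (j in 1:4)
      expect_equal(unname(act[1, j]),
                   bruteAUCell(xr[, j], genes, mem, 0.4), tolerance = 1e-12)
  }
})

test_that("activity is invariant to monotone transforms of a spot", {
  set.seed(72)
  M <- 12
  genes <- sprintf("g%02d", 1:M)
  x <- matrix(abs(rnorm(M * 3)) + 0.1, M, 3,
              dimnames = list(genes, paste0("s", 1:3)))
  rs <- new("RegulonSet", regulons = list(
    "g01(+)" = list(tf = "g01", targets = c("g05", "g07", "g09"),
                    weights = 1:3)), geneUniverse = genes)
  a <- SummarizedExperiment::assay(aucellActivity(x, rs, 0.5), "activity")
  xm <- x; xm[, 2] <- exp(3 * xm[, 2]) + 1   # strictly monotone per spot
  am <- SummarizedExperiment::assay(aucellActivity(xm, rs, 0.5), "activity")
  expect_equal(a, am)
})

test_that("clustering recovers planted blocks and is deterministic", {
  # exact block-diagonal Z with 3 blocks
  Z <- matrix(0, 30, 30)
  truth <- rep(1:3, each = 10)
  for (d in 1:3) Z[truth == d, truth == d] <- 1
  lab <- clusterSpots(Z, seed = 3)
  expect_equal(clusteringARI(lab, truth), 1)
  # determinism under the same seed
  expect_identical(lab, clusterSpots(Z, seed = 3))
  # tiny resolution on a connected graph: a single cluster
  W <- matrix(1, 10, 10)
  expect_equal(length(unique(clusterSpots(W, resolution = 1e-6, seed = 1))),
               1L)
  expect_error(clusterSpots(matrix(0, 5, 5)), "all-zero")
  # permutation equivariance
  perm <- sample(30)
  labp <- clusterSpots(Z[perm, perm], seed = 3)
  expect_equal(clusteringARI(labp, truth[perm]), 1)
})

test_that("specificity filter reproduces the marker thresholds", {
  act <- rbind(
    perfect = c(1, 1, 1, 0, 0, 0),     # all-on in cluster A
    uniform = rep(0.5, 6),             # identical across clusters
    partial = c(0.9, 0.8, 0.4, 0.45, 0.3, 0.2))
  colnames(act) <- paste0("s", 1:6)
  labels <- c("A", "A", "A", "B", "B", "B")
  all <- specificRegulons(act, labels, keepAll = TRUE)
  # perfectly separated regulon: AUROC 1, passes the default filter
  pa <- all[all$regulon == "perfect" & all$cluster == "A", ]
  expect_equal(pa$auroc, 1)
  expect_true(pa$pass)
  # identical activity: log2FC 0, filtered out
  expect_false(any(all$pass[all$regulon == "uniform"]))
  filt <- specificRegulons(act, labels)
  expect_false("uniform" %in% filt$regulon)
  # hand-computed log2FC for the perfect regulon
  eps <- 1e-9
  expect_equal(pa$log2FC, log2((1 + eps) / (0 + eps)))
  # rank-sum AUROC equals the scaled Mann-Whitney U statistic
  set.seed(81)
  v <- runif(12)
  lab2 <- rep(c("A", "B"), each = 6)
  a2 <- specificRegulons(matrix(v, 1, dimnames = list("r", NULL)),
                         lab2, keepAll = TRUE)
  U <- wilcox.test(v[1:6], v[7:12], exact = TRUE)$statistic
  expect_equal(a2$auroc[a2$cluster == "A"], unname(U) / 36,
               tolerance = 1e-12)
  # AUROC-off mode keeps rows on fold change alone
  off <- specificRegulons(act, labels, minAUROC = NULL, keepAll = TRUE)
  expect_true(off$pass[off$regulon == "partial" & off$cluster == "A"])
  # singleton cluster flagged
  s <- specificRegulons(act[, 1:4], c("A", "B", "B", "B"), keepAll = TRUE)
  expect_true(all(s$flag[s$cluster == "A"] == "singleton-cluster"))
  expect_error(specificRegulons(act, rep("A", 6)), "two clusters")
})

test_that("GMT export writes one parsable line per regulon", {
  rs <- new("RegulonSet", regulons = list(
    "TF1(+)" = list(tf = "TF1", targets = c("a", "b"), weights = c(2, 1))),
    geneUniverse = c("TF1", "a", "b"))
  f <- tempfile(fileext = ".gmt")
  exportRegulonsGMT(rs, f)
  ln <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(ln[1], "TF1(+)")
  expect_equal(ln[3:4], c("a", "b"))
})
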