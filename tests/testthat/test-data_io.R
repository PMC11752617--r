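test_that("dense CSV reads back exactly what was written", {
  x <- matrix(c(0, 1.5, 2, 3.25, 4, 5), 3, 2,
              dimnames = list(c("GA", "GB", "GC"), c("s1", "s2")))
  f <- tempfile(fileext = ".csv")
  writeExpression(x, f, "csv")
  back <- readExpression(f, "csv")
  expect_equal(exprValues(back), x, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(dim(back), c(3L, 2L))
  expect_false(S4Vectors::metadata(back)$isLog)
})

test_that("round-trips are lossless in every format", {
  set.seed(90)
  x <- matrix(exp(rnorm(30, sd = 3)), 5, 6,
              dimnames = list(paste0("G", 1:5), paste0("s", 1:6)))
  x[sample(30, 8)] <- 0
  # csv / tsv
  for (fmt in c("csv", "tsv")) {
    f <- tempfile(fileext = paste0(".", fmt))
    writeExpression(x, f, fmt)
    expect_equal(exprValues(readExpression(f, fmt)), x,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # mtx with sidecars, checked against the dense reconstruction of the
  # triplets as an independent oracle
  d <- tempfile("mtx")
  writeExpression(x, d, "mtx")
  back <- readExpression(d, "mtx")
  expect_equal(exprValues(back), x, tolerance = 1e-12, ignore_attr = TRUE)
  tri <- read.table(file.path(d, "matrix.mtx"), skip = 2)
  dense <- matrix(0, 5, 6)
  for (r in seq_len(nrow(tri))) dense[tri[r, 1], tri[r, 2]] <- tri[r, 3]
  expect_equal(unname(exprValues(back)), dense, tolerance = 1e-12)
})

test_that("h5ad round-trips through the anndata bridge with coordinates", {
  x <- matrix(c(1.25, 0, 2, 3, 4.5, 0), 3, 2,
              dimnames = list(c("GA", "GB", "GC"), c("s1", "s2")))
  se <- SpatialExpression(x, cbind(c(0, 1), c(2, 3)))
  f <- tempfile(fileext = ".h5ad")
  writeExpression(se, f, "h5ad")
  back <- readExpression(f, "h5ad")
  expect_s4_class(back, "SpatialExpression")
  expect_equal(exprValues(back), x, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(spotCoords(back)), cbind(c(0, 1), c(2, 3)))
})

test_that("transposed matrices and duplicate symbols are repaired on read", {
  # mtx stored spots x genes: orientation resolved by the id sidecars
  d <- tempfile("mtxT"); dir.create(d)
  x <- matrix(1:6, 3, 2, dimnames = list(c("GA", "GB", "GC"), c("s1", "s2")))
  sm <- Matrix::Matrix(t(x), sparse = TRUE)
  tri <- Matrix::summary(sm)
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 3 6", sprintf("%d %d %g", tri$i, tri$j, tri$x)),
             file.path(d, "matrix.mtx"))
  writeLines(rownames(x), file.path(d, "genes.tsv"))
  writeLines(colnames(x), file.path(d, "barcodes.tsv"))
  expect_equal(exprValues(readExpression(d, "mtx")), x,
               tolerance = 1e-12, ignore_attr = TRUE)
  # missing sidecars: explicit ambiguity error
  file.remove(file.path(d, "genes.tsv"))
  expect_error(readExpression(d, "mtx"), "ambiguous orientation")
  # duplicated gene symbols collapse by summation (brute-force row merge)
  f <- tempfile(fileext = ".csv")
  writeLines(c("gene,s1,s2", "GeneA,1,2", "geneA ,10,20", "GeneB,5,6"), f)
  got <- readExpression(f, "csv")
  expect_equal(nrow(got), 2L)
  expect_equal(unname(exprValues(got)["GENEA", ]), c(11, 22))
})

test_that("malformed files fail with a parse error naming the file", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("gene,s1,s2", "GA,1,2", "GB,3"), f)
  expect_error(readExpression(f, "csv"), "malformed")
})

test_that("preprocessing: log base, pseudocount, idempotence guard", {
  x <- matrix(c(0, exp(1) - 1, 1, 2), 2, 2,
              dimnames = list(c("GA", "GB"), c("s1", "s2")))
  se <- SpatialExpression(x, cbind(1:2, 1))
  pp <- preprocessExpression(se)
  # natural-log convention: 0 -> 0 and e-1 -> 1
  expect_equal(unname(exprValues(pp)[, 1]), c(0, 1), tolerance = 1e-12)
  expect_true(isLogged(pp))
  expect_error(preprocessExpression(pp), "already log-transformed")
  expect_error(preprocessExpression(se, nHVG = 5), "exceeds")
})

test_that("HVG selection ranks by normalised dispersion with stable ties", {
  set.seed(91)
  base <- matrix(rpois(4 * 30, 10), 4, 30)
  x <- rbind(base, matrix(rep(c(3, 9), each = 15), 2, 30, byrow = FALSE))
  rownames(x) <- c("GD1", "GD2", "GD3", "GD4", "TIE2", "TIE1")
  colnames(x) <- paste0("s", 1:30)
  x["TIE1", ] <- x["TIE2", ]              # exact tie pair
  se <- SpatialExpression(x, cbind(seq_len(30), 1))
  # all-equal scores: selection falls back to lexicographic gene order
  flat <- matrix(rep(x[1, ], each = 4), 4, 30,
                 dimnames = list(c("B", "A", "D", "C"), paste0("s", 1:30)))
  seF <- SpatialExpression(flat, cbind(seq_len(30), 1))
  kept <- rownames(preprocessExpression(seF, nHVG = 2))
  expect_equal(sort(kept), c("A", "B"))
  # selection is deterministic and keeps the requested count
  k1 <- rownames(preprocessExpression(se, nHVG = 3))
  k2 <- rownames(preprocessExpression(se, nHVG = 3))
  expect_identical(k1, k2)
  expect_length(k1, 3L)
})

test_that("prior networks are restricted, max-normalised and symmetric", {
  genes <- c("G1", "G2", "G3", "G4")
  f <- tempfile(fileext = ".tsv")
  writeLines(c("geneA\tgeneB\tconfidence", "G1\tG2\t0.5"), f)
  pn <- readPriorNetwork(f, genes)
  expect_equal(pn$A["G1", "G2"], 1)       # max-normalised
  expect_equal(pn$A["G2", "G1"], 1)       # symmetrised
  expect_equal(sum(pn$A), 2)
  # 3-edge toy vs hand-built adjacency
  writeLines(c("G1\tG2\t2", "G2\tG3\t1", "G1\tG3\t4", "GX\tGY\t9"), f)
  pn3 <- readPriorNetwork(f, genes)
  hand <- matrix(0, 4, 4, dimnames = list(genes, genes))
  hand["G1", "G2"] <- hand["G2", "G1"] <- 2 / 4
  hand["G2", "G3"] <- hand["G3", "G2"] <- 1 / 4
  hand["G1", "G3"] <- hand["G3", "G1"] <- 4 / 4
  expect_equal(pn3$A, hand)
  # empty file: zero adjacency with a warning
  writeLines(character(0), f)
  expect_warning(pe <- readPriorNetwork(f, genes), "empty")
  expect_true(all(pe$A == 0))
  # disjoint gene sets: error
  writeLines(c("ZZ\tYY\t1"), f)
  expect_error(readPriorNetwork(f, genes), "overlap")
})

test_that("TF lists and coordinates read with standardisation", {
  f <- tempfile()
  writeLines(c(" tf1", "TF2", "", "tf1"), f)
  expect_equal(readTFList(f), c("TF1", "TF2"))
  fc <- tempfile()
  writeLines(c("spot\tx\ty\tz\tslice", "s1\t0\t0\t1\t1", "s2\t1\t0\t2\t2"), fc)
  co <- readCoordinates(fc)
  expect_equal(dim(co), c(2L, 3L))
  expect_equal(attr(co, "slice"), c(1L, 2L))
})

test_that("the container validates its invariants", {
  x <- matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  expect_error(SpatialExpression(x, cbind(1, 1)), "one row per spot")
  expect_error(SpatialExpression(x, cbind(c(1, NA), c(1, 2))), "finite")
  dup <- x; rownames(dup) <- c("A", "a ", "C")
  expect_error(SpatialExpression(dup, cbind(1:2, 1)), "unique")
  se <- SpatialExpression(x, cbind(c(0, 1), c(0, 0), c(0, 5)))
  expect_equal(SummarizedExperiment::colData(se)$slice, c(1L, 2L))
})
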