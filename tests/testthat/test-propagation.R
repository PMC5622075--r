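test_that("column normalization is stochastic, zero-preserving and idempotent", {
  M <- matrix(c(1, 1, 0, 0, 2, 6), 2)
  W <- columnNormalize(M)
  expect_equal(W[, 1], c(0.5, 0.5))
  expect_equal(W[, 2], c(0, 0))           # zero column stays zero
  expect_equal(W[, 3], c(0.25, 0.75))
  expect_equal(columnNormalize(W), W)      # idempotent
  expect_error(columnNormalize(matrix(c(-1, 2), 1)), "nonnegative")
})

test_that("Laplacian scores match the Neumann series and reduce correctly", {
  # inverse form on a 3-node chain equals the truncated series
  W <- columnNormalize(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3))
  for (b in c(0.1, 0.5, 0.9)) {
    got <- laplacianScore(W, 2, balance = b)
    expect_equal(got, oracleNeumann(W, b, 2), tolerance = 1e-10)
    expect_true(all(got >= 0))
  }
  # identity network: the indicator survives unscaled
  expect_equal(laplacianScore(diag(4), 3, balance = 0.4),
               c(0, 0, 1, 0))
  # literal form is the plain product as printed
  lit <- laplacianScore(W, 2, balance = 0.5, form = "literal")
  e <- c(0, 1, 0)
  expect_equal(lit, drop(0.5 * (diag(3) - 0.5 * W) %*% e))
  expect_true(any(lit < 0))  # the behavior motivating the inverse default
  # both forms converge to the indicator as the balance vanishes
  expect_equal(laplacianScore(W, 1, balance = 1e-9), c(1, 0, 0),
               tolerance = 1e-6)
})

test_that("seed vectors blend the Laplacian image with the query column", {
  WA <- columnNormalize(matrix(c(1, 1, 0, 0, 0, 3), 2))
  lap <- c(0, 1, 0)                        # indicator on column 2
  v <- initialVector(WA, lap, 2)
  expect_equal(v, c(0, 0))                 # column 2 entirely zero
  v3 <- initialVector(WA, c(0, 0, 1), 3)
  expect_equal(v3, c(0, 1))                # doubled column renormalizes
  # isolated query with similar neighbors still gets a nonzero seed
  vIso <- initialVector(WA, c(0.5, 0.5, 0), 2)
  expect_equal(sum(vIso), 1)
  expect_true(all(vIso > 0))
})

test_that("the iterative walk matches the closed-form solve", {
  for (seed in 1:20) {
    W <- randomStochastic(15, seed)
    set.seed(seed + 500)
    p0 <- stats::runif(15); p0 <- p0 / sum(p0)
    gamma <- stats::runif(1, 0.1, 0.9)
    it <- rwr(W, p0, gamma, tol = 1e-12)
    expect_equal(it, rwrSolve(W, p0, gamma), tolerance = 1e-8)
    expect_equal(sum(it), 1, tolerance = 1e-9)   # conservation
  }
  W <- randomStochastic(6, 99)
  p0 <- c(1, 0, 0, 0, 0, 0)
  expect_equal(rwr(W, p0, gamma = 1), p0)        # restart-only walk
  expect_equal(rwr(W, numeric(6), gamma = 0.5), numeric(6))
  expect_error(rwr(W, p0, gamma = 0.001, tol = 0, maxIter = 3L),
               "did not converge")
})

test_that("score matrices are probabilistic, eta-linear and label-invariant", {
  bench <- tinyBench(3)
  dd <- benchDD(bench)
  ll <- lncrnaSimilarity(bench$dataset, dd)
  sp <- grwldaScores(bench$dataset, ll, dd)
  FS <- finalScores(sp)
  expect_true(all(FS >= 0 & FS <= 1))
  expect_equal(FS, 0.7 * walkScores(sp, "lncrna") +
                 0.3 * walkScores(sp, "disease"), tolerance = 1e-12)

  # eta endpoints and exact linearity in between
  sp1 <- grwldaScores(bench$dataset, ll, dd, grwParams(eta = 1))
  sp0 <- grwldaScores(bench$dataset, ll, dd, grwParams(eta = 0))
  expect_equal(finalScores(sp1), walkScores(sp1, "lncrna"))
  expect_equal(finalScores(sp0), walkScores(sp0, "disease"))
  expect_equal(FS, 0.7 * finalScores(sp1) + 0.3 * finalScores(sp0),
               tolerance = 1e-9)

  # steady columns sum to 1 when their seeds do
  expect_equal(unname(colSums(walkScores(sp, "lncrna"))),
               rep(1, ncol(FS)), tolerance = 1e-6)

  # permuting entity labels permutes the scores identically
  pl <- sample(nrow(FS)); pd <- sample(ncol(FS))
  dsP <- associationDataset(assocMatrix(bench$dataset)[pl, pd])
  llP <- similarityMatrix(simValues(ll)[pl, pl], role = "LL")
  ddP <- similarityMatrix(simValues(dd)[pd, pd], role = "DD")
  spP <- grwldaScores(dsP, llP, ddP)
  expect_equal(finalScores(spP), FS[pl, pd], tolerance = 1e-9)

  # iterative and solve engines agree on the whole pipeline
  spS <- grwldaScores(bench$dataset, ll, dd, grwParams(engine = "solve"))
  expect_equal(finalScores(spS), FS, tolerance = 1e-5)

  # determinism: identical inputs give bit-identical scores
  expect_identical(FS, finalScores(grwldaScores(bench$dataset, ll, dd)))
})

test_that("a two-by-two toy concentrates the walk on the associated lncRNA", {
  m <- matrix(c(1, 0, 0, 0), 2,
              dimnames = list(c("L1", "L2"), c("D1", "D2")))
  ds <- associationDataset(m)
  eye <- function(ids) similarityMatrix(
    matrix(diag(2), 2, dimnames = list(ids, ids)))
  sp <- grwldaScores(ds, eye(c("L1", "L2")), eye(c("D1", "D2")))
  FS <- finalScores(sp)
  expect_equal(unname(which.max(FS[, "D1"])), 1L)
  expect_gt(FS["L1", "D1"], FS["L2", "D1"])
})

test_that("transfer matrices keep their stochastic structure on random inputs", {
  for (seed in 1:10) {
    bench <- tinyBench(seed + 20)
    dd <- benchDD(bench)
    ll <- lncrnaSimilarity(bench$dataset, dd)
    model <- buildPropagationModel(bench$dataset, ll, dd)
    for (nm in c("WL", "WD", "WA1", "WA2")) {
      W <- methods::slot(model, nm)
      expect_true(all(W >= 0))
      cs <- colSums(W)
      expect_true(all(abs(cs - 1) < 1e-12 | cs == 0))
    }
  }
})
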