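test_that("ROC AUC equals brute-force concordant-pair counting", {
  expect_equal(rocAuc(c(0.9, 0.4), c(0.8, 0.1))$auc, 0.75)
  expect_equal(rocAuc(c(1, 1), c(0, 0))$auc, 1)
  expect_equal(rocAuc(rep(0.5, 3), rep(0.5, 4))$auc, 0.5)  # all ties
  for (seed in 1:30) {
    set.seed(seed)
    pos <- round(stats::runif(sample(2:10, 1)), 2)  # rounding forces ties
    neg <- round(stats::runif(sample(2:10, 1)), 2)
    got <- rocAuc(pos, neg)
    expect_equal(got$auc, oracleAuc(pos, neg), tolerance = 1e-12)
    pts <- got$points
    expect_equal(pts[1, ], data.frame(fpr = 0, tpr = 0),
                 ignore_attr = TRUE)
    expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  }
  expect_error(rocAuc(numeric(), 1), "nonempty")
})

test_that("AUPR follows the step-wise rule on enumerable rankings", {
  # ranking P,N,N: full recall at rank 1 with precision 1
  expect_equal(prAupr(0.9, c(0.8, 0.1))$aupr, 1)
  # perfect separation and the no-negative limit
  expect_equal(prAupr(c(0.9, 0.8), c(0.2, 0.1))$aupr, 1)
  expect_equal(prAupr(c(0.5, 0.4), numeric())$aupr, 1)
  # ranking N,P: recall 1 only reached at precision 1/2
  expect_equal(prAupr(0.3, 0.7)$aupr, 0.5)
  # ranking P,N,P: area = 1/2 * 1 + 1/2 * 2/3
  expect_equal(prAupr(c(0.9, 0.5), 0.7)$aupr, 0.5 + 0.5 * 2 / 3)
  expect_error(prAupr(numeric(), 1), "nonempty")
})

test_that("a perfect scorer yields AUC exactly 1 and a random scorer about 0.5", {
  bench <- tinyBench(5)
  AS <- assocMatrix(bench$dataset)
  pos <- which(AS == 1); neg <- which(AS == 0)
  # perfect-scorer stub in place of the propagation engine
  expect_equal(rocAuc(rep(1, length(pos)), rep(0, length(neg)))$auc, 1)
  set.seed(42)
  aucs <- replicate(20, rocAuc(stats::runif(length(pos)),
                               stats::runif(length(neg)))$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("LOOCV masks evidence and degenerate datasets are rejected", {
  bench <- tinyBench(2)
  dd <- benchDD(bench)
  cv <- loocv(bench$dataset, dd)
  AS <- assocMatrix(bench$dataset)
  expect_equal(nrow(positiveScores(cv)), sum(AS))
  expect_equal(nrow(negativeScores(cv)), sum(AS == 0))
  expect_true(cvAuc(cv) >= 0 && cvAuc(cv) <= 1)

  # leakage tripwire: restoring the held-out cell must change the score
  # and a pair scored with its own evidence present never scores lower
  pos <- which(AS == 1, arr.ind = TRUE)
  llFull <- lncrnaSimilarity(bench$dataset, dd)
  fsFull <- finalScores(grwldaScores(bench$dataset, llFull, dd))
  for (k in c(1L, 5L, 9L)) {
    cell <- pos[k, , drop = FALSE]
    masked <- AS; masked[cell] <- 0
    dsm <- associationDataset(masked)
    fsM <- finalScores(grwldaScores(dsm, lncrnaSimilarity(dsm, dd), dd))
    expect_false(isTRUE(all.equal(fsM[cell], fsFull[cell])))
    expect_gte(fsFull[cell], fsM[cell] - 1e-9)
  }

  # all-known dataset: no negative class, AUC undefined
  tiny <- associationDataset(matrix(1, 1, 2,
    dimnames = list("L1", c("D1", "D2"))))
  expect_error(loocv(tiny, randomDD(2, 1, ids = c("D1", "D2"))),
               "negative")
  expect_error(loocv(bench$dataset, dd, mode = "nonsense"))
})

test_that("novel and isolated modes pool positives and negatives per masked run", {
  bench <- tinyBench(4)
  dd <- benchDD(bench)
  AS <- assocMatrix(bench$dataset)
  cvi <- loocv(bench$dataset, dd, mode = "isolated_disease")
  expect_equal(nrow(positiveScores(cvi)), sum(AS))
  expect_equal(nrow(negativeScores(cvi)), sum(AS == 0))
  # with leakage-free LL an emptied lncRNA row carries no evidence at all
  cvn <- loocv(bench$dataset, dd, mode = "novel_lncrna")
  expect_true(all(positiveScores(cvn)$score == 0))
  expect_equal(cvAuc(cvn), 0.5)
  # the static-LL variant keeps the similarity links and discriminates
  cvns <- loocv(bench$dataset, dd, mode = "novel_lncrna", staticLL = TRUE)
  expect_gt(cvAuc(cvns), 0.6)
})

test_that("k-fold CV is seeded, partitions cover every association once", {
  bench <- tinyBench(6)
  dd <- benchDD(bench)
  expect_error(kfoldCV(bench$dataset, dd), "seed")
  cv1 <- kfoldCV(bench$dataset, dd, k = 5, reps = 2, seed = 11)
  cv2 <- kfoldCV(bench$dataset, dd, k = 5, reps = 2, seed = 11)
  expect_identical(perRepAuc(cv1), perRepAuc(cv2))
  expect_length(perRepAuc(cv1), 2)
  expect_equal(cvAuc(cv1), mean(perRepAuc(cv1)))
  # every association is scored exactly once per repetition
  npos <- sum(assocMatrix(bench$dataset))
  expect_equal(nrow(positiveScores(cv1)), 2 * npos)

  # k equal to the association count reduces to per-cell masking:
  # the positives match overall LOOCV's
  cvL <- kfoldCV(bench$dataset, dd, k = npos, reps = 1, seed = 3)
  cvO <- loocv(bench$dataset, dd)
  o <- function(df) df[order(df$lncrna, df$disease), "score"]
  expect_equal(o(positiveScores(cvL)), o(positiveScores(cvO)),
               tolerance = 1e-9)
})

test_that("pair ranking uses per-disease candidate lists and rejects known pairs", {
  m <- matrix(0, 4, 2, dimnames = list(paste0("L", 1:4), c("D1", "D2")))
  m["L1", "D1"] <- 1
  ds <- associationDataset(m)
  fs <- matrix(c(0.9, 0.8, 0.3, 0.5, 0.1, 0.2, 0.2, 0.4), 4, 2,
               dimnames = dimnames(m))
  rk <- rankOfPairs(fs, ds, data.frame(l = c("L2", "L3", "L4"),
                                       d = c("D1", "D1", "D2")))
  expect_equal(rk$ranks$rank, c(1L, 3L, 1L))
  expect_equal(rk$meanRank, mean(c(1, 3, 1)))
  expect_equal(rankOfPairs(fs, ds, data.frame(l = c("L3", "L2", "L1"),
    d = rep("D2", 3)))$meanRank, mean(c(4, 3, 2)))
  expect_error(rankOfPairs(fs, ds, data.frame(l = "L1", d = "D1")),
               "known association")
})
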