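test_that("DAG contributions follow the decayed max-over-children rule", {
  dag <- buildDiseaseDAG("d", "C04.588", decay = 0.5)
  expect_equal(dagContributions(dag)[["C04.588"]], 1)
  expect_equal(dagContributions(dag)[["C04"]], 0.5)
  expect_equal(semanticValue(dag), 1.5)

  # decay 0: only the disease's own positions contribute
  dag0 <- buildDiseaseDAG("d", c("C04.588.274", "C06.301"), decay = 0)
  cn <- dagContributions(dag0)
  expect_equal(sort(unname(cn[cn > 0]), decreasing = TRUE), c(1, 1))
  expect_equal(semanticValue(dag0), 2)

  # shared ancestor reachable at distances 1 and 2 takes the max
  dag2 <- buildDiseaseDAG("d", c("A.x", "A.y.z"), decay = 0.5)
  expect_equal(dagContributions(dag2)[["A"]], 0.5)  # max(0.5, 0.25)

  # a full position that is also an ancestor keeps contribution 1
  dag3 <- buildDiseaseDAG("d", c("A.b", "A.b.c"), decay = 0.5)
  expect_equal(dagContributions(dag3)[["A.b"]], 1)

  expect_error(buildDiseaseDAG("d", character()), "tree code")
  expect_error(buildDiseaseDAG("d", "A.b", decay = 1.5), "decay")
})

test_that("disease similarity matches its defining formula", {
  a <- buildDiseaseDAG("A", "C04.588", decay = 0.5)
  b <- buildDiseaseDAG("B", "C04", decay = 0.5)
  expect_equal(diseaseSimilarity(a, b), 0.6)   # (0.5+1)/(1.5+1)
  expect_equal(diseaseSimilarity(a, a), 1)
  c <- buildDiseaseDAG("C", "F01.145", decay = 0.5)
  expect_equal(diseaseSimilarity(a, c), 0)     # disjoint DAGs
  b2 <- buildDiseaseDAG("B", "C04", decay = 0.7)
  expect_error(diseaseSimilarity(a, b2), "decay")

  dd <- diseaseSimilarityMatrix(list(a, b))
  expect_equal(unname(simValues(dd)),
               matrix(c(1, 0.6, 0.6, 1), 2))

  # all-pairs agrees with the pairwise oracle on random DAG sets
  set.seed(11)
  for (rep in 1:5) {
    dags <- lapply(seq_len(6), function(k) {
      codes <- replicate(sample(1:3, 1), paste(
        sample(c("A", "B", "C", "x1", "x2", "y1", "y2"),
               sample(2:4, 1), replace = TRUE), collapse = "."))
      buildDiseaseDAG(sprintf("d%d", k), unique(codes))
    })
    dd <- simValues(diseaseSimilarityMatrix(dags))
    for (i in 1:6) for (j in 1:6)
      expect_equal(dd[i, j], if (i == j) 1 else
        oracleDiseaseSim(dags[[i]], dags[[j]]), tolerance = 1e-12)
  }
})

test_that("adding a shared ancestor term never decreases disease similarity", {
  # a shared extra term adds the same mass to numerator and
  # denominator, and n <= d implies (n+x)/(d+x) >= n/d
  addTerm <- function(dag, term, contribution) {
    methods::new("DiseaseDAG", diseaseId = dag@diseaseId,
                 terms = c(dagTerms(dag), term),
                 edges = dagEdges(dag),
                 contributions = c(dagContributions(dag),
                                   stats::setNames(contribution, term)),
                 decay = dag@decay)
  }
  set.seed(7)
  for (rep in 1:20) {
    a1 <- buildDiseaseDAG("A", paste(c("R", sample(letters[1:3],
          sample(2:4, 1), replace = TRUE)), collapse = "."))
    b1 <- buildDiseaseDAG("B", paste(c("R", sample(letters[1:3],
          sample(2:4, 1), replace = TRUE)), collapse = "."))
    before <- diseaseSimilarity(a1, b1)
    ca <- stats::runif(1); cb <- stats::runif(1)
    expect_gte(diseaseSimilarity(addTerm(a1, "SHARED", ca),
                                 addTerm(b1, "SHARED", cb)) + 1e-12,
               before)
  }
})

test_that("group similarity is the best match over the group", {
  a <- buildDiseaseDAG("A", "C04.588")
  b <- buildDiseaseDAG("B", "C04")
  c <- buildDiseaseDAG("C", "F01.145")
  dd <- diseaseSimilarityMatrix(list(a, b, c))
  expect_equal(groupSimilarity("A", c("A", "B"), dd), 1)   # self in group
  expect_equal(groupSimilarity("C", "B", dd),
               simValues(dd)["C", "B"])                    # singleton group
  expect_equal(groupSimilarity("A", c("B", "C"), dd), 0.6)
  expect_error(groupSimilarity("A", character(), dd), "empty")
})

test_that("lncRNA similarity matches the literal nested-loop evaluation", {
  # exhaustive over random small instances, including empty profiles
  for (seed in 1:100) {
    set.seed(seed)
    nl <- sample(2:5, 1); nd <- sample(2:5, 1)
    AS <- randomAssoc(nl, nd, seed + 1000, density = stats::runif(1, 0.2, 0.8))
    dd <- randomDD(nd, seed + 2000)
    ll <- simValues(lncrnaSimilarity(associationDataset(AS), dd))
    expect_equal(unname(ll), unname(oracleLncsim(AS, simValues(dd))),
                 tolerance = 1e-12)
  }
})

test_that("lncRNA similarity handles the defining special cases", {
  dd <- randomDD(4, seed = 5)
  AS <- matrix(0, 3, 4, dimnames = list(c("u", "v", "w"), simIds(dd)))
  AS["u", c(1, 3)] <- 1
  AS["v", c(1, 3)] <- 1          # identical disease groups
  ll <- simValues(lncrnaSimilarity(AS, dd))
  expect_equal(ll["u", "v"], 1)
  expect_equal(ll["w", "w"], 0)  # empty profile: no functional evidence
  expect_equal(ll["u", "w"], 0)

  # one association each: LL = DD of the two diseases
  AS2 <- matrix(0, 2, 4, dimnames = list(c("u", "v"), simIds(dd)))
  AS2["u", 1] <- 1; AS2["v", 2] <- 1
  ll2 <- simValues(lncrnaSimilarity(AS2, dd))
  expect_equal(ll2["u", "v"], simValues(dd)[1, 2])
})

test_that("similarity matrices are symmetric, bounded, unit-diagonal on random inputs", {
  for (seed in 1:10) {
    bench <- tinyBench(seed)
    dd <- benchDD(bench)
    ll <- lncrnaSimilarity(bench$dataset, dd)
    for (sm in list(dd, ll)) {
      v <- simValues(sm)
      expect_equal(v, t(v))
      expect_true(all(v >= 0 & v <= 1))
    }
    expect_true(all(diag(simValues(dd)) == 1))
    deg <- rowSums(assocMatrix(bench$dataset))
    expect_true(all(diag(simValues(ll))[deg > 0] == 1))
  }
})
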