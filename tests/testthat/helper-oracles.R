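# Independent brute-force oracles and small fixture builders.
# These deliberately mirror the defining formulas as literal loops,
# not the vectorized implementation paths they are used to check.

# group-wise best-match-average lncRNA similarity, literal nested loops
oracleLncsim <- function(AS, DD) {
  nl <- nrow(AS)
  LL <- matrix(0, nl, nl, dimnames = list(rownames(AS), rownames(AS)))
  bestMatch <- function(d, grp) {
    best <- -Inf
    for (g in grp) if (DD[d, g] > best) best <- DD[d, g]
    best
  }
  for (u in seq_len(nl)) for (v in seq_len(nl)) {
    Du <- which(AS[u, ] == 1); Dv <- which(AS[v, ] == 1)
    if (!length(Du) || !length(Dv)) next
    s <- 0
    for (d in Du) s <- s + bestMatch(d, Dv)
    for (d in Dv) s <- s + bestMatch(d, Du)
    LL[u, v] <- s / (length(Du) + length(Dv))
  }
  LL
}

# pairwise disease similarity via explicit shared-term summation
oracleDiseaseSim <- function(a, b) {
  shared <- intersect(dagTerms(a), dagTerms(b))
  if (!length(shared)) return(0)
  num <- 0
  for (t in shared)
    num <- num + dagContributions(a)[[t]] + dagContributions(b)[[t]]
  num / (sum(dagContributions(a)) + sum(dagContributions(b)))
}

# AUC by counting concordant pairs with half credit for ties
oracleAuc <- function(pos, neg) {
  conc <- 0
  for (p in pos) for (n in neg)
    conc <- conc + (p > n) + 0.5 * (p == n)
  conc / (length(pos) * length(neg))
}

# truncated Neumann series for the smoothed-seed operator
oracleNeumann <- function(W, balance, idx, terms = 400L) {
  e <- numeric(nrow(W)); e[idx] <- 1
  acc <- e; v <- e
  for (k in seq_len(terms)) {
    v <- balance * drop(W %*% v)
    acc <- acc + v
  }
  (1 - balance) * acc
}

# random column-stochastic matrix without zero columns
randomStochastic <- function(n, seed) {
  set.seed(seed)
  M <- matrix(stats::runif(n * n), n) *
    matrix(stats::runif(n * n) < 0.7, n)
  M <- M + diag(stats::runif(n, 0.1, 1))  # keeps every column nonzero
  columnNormalize(M)
}

# random binary association matrix with named axes
randomAssoc <- function(nl, nd, seed, density = 0.35) {
  set.seed(seed)
  m <- matrix(as.numeric(stats::runif(nl * nd) < density), nl, nd,
              dimnames = list(sprintf("L%02d", seq_len(nl)),
                              sprintf("D%02d", seq_len(nd))))
  m
}

# random valid disease similarity matrix (symmetric, unit diagonal)
randomDD <- function(nd, seed, ids = sprintf("D%02d", seq_len(nd))) {
  set.seed(seed)
  v <- matrix(stats::runif(nd * nd), nd)
  v <- (v + t(v)) / 2
  diag(v) <- 1
  dimnames(v) <- list(ids, ids)
  similarityMatrix(v, role = "DD")
}

# small planted benchmark for fast pipeline tests
tinyBench <- function(seed = 1L) {
  generateSyntheticData(synthConfig(nLncrna = 12L, nDisease = 15L,
                                    nBlocks = 3L, treeDepth = 3L,
                                    assocPerBlock = 8L, noiseAssoc = 3L,
                                    seed = seed))
}

benchDD <- function(bench, decay = 0.5) {
  dags <- lapply(diseaseIds(bench$dataset), function(d)
    buildDiseaseDAG(d, bench$treeNumbers[[d]], decay = decay))
  diseaseSimilarityMatrix(dags)
}
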