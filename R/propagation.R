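#' Column-normalize a nonnegative matrix into a probability transfer matrix
#'
#' Divides every column by its sum; a column summing to zero is left
#' all-zero.  This is the normalization applied to the lncRNA
#' similarity, disease similarity, association and transposed
#' association matrices before the walk.
#'
#' @param M Nonnegative numeric matrix.
#' @return Matrix of the same shape whose nonzero columns sum to 1.
#' @examples
#' columnNormalize(matrix(c(1, 1, 0, 0), 2))
#' @export
columnNormalize <- function(M) {
  if (any(M < 0))
    stop("column normalization requires a nonnegative matrix")
  .colNorm(M)
}

# Eq.-6-style normalization without the sign guard; the literal
# Laplacian form can hand this signed seed columns.
.colNorm <- function(M) {
  cs <- colSums(M)
  nz <- cs != 0
  M[, nz] <- sweep(M[, nz, drop = FALSE], 2, cs[nz], "/")
  M
}

#' Laplacian-smoothed relevance scores of a query entity
#'
#' Spreads an indicator vector over a column-normalized similarity
#' network so that entities connected to the query receive similar
#' scores.  The default \code{"inverse"} form evaluates
#' \eqn{(1-b)(I - b W)^{-1} e}, the standard graph-regularization
#' score, which is nonnegative for a column-stochastic \code{W} and
#' \eqn{b < 1}.  The \code{"literal"} form evaluates the plain product
#' \eqn{(1-b)(I - b W) e}; it yields negative entries off the query and
#' is retained only for fidelity experiments (see the methods
#' vignette).
#'
#' @param W Square column-normalized similarity matrix.
#' @param index Query entity index (or name).
#' @param balance Balance parameter in (0, 1).
#' @param form \code{"inverse"} (default) or \code{"literal"}.
#' @return Numeric score vector of length \code{nrow(W)}.
#' @export
laplacianScore <- function(W, index, balance,
                           form = c("inverse", "literal")) {
  form <- match.arg(form)
  stopifnot(nrow(W) == ncol(W), balance > 0, balance < 1)
  e <- numeric(nrow(W))
  if (is.character(index)) index <- match(index, rownames(W))
  e[index] <- 1
  drop(.laplacianAll(W, balance, form) %*% e)
}

# All-queries Laplacian operator: column j is the score vector of
# query j (the indicator matrix is the identity).
.laplacianAll <- function(W, balance, form) {
  A <- diag(nrow(W)) - balance * W
  if (form == "inverse") (1 - balance) * solve(A)
  else (1 - balance) * A
}

#' Initial probability vector of a walk
#'
#' Combines the transfer-matrix image of the Laplacian score vector with
#' the query's own transfer column, then normalizes the result as a
#' single column (an all-zero result stays all-zero).  Because the
#' Laplacian scores are nonzero for similar neighbors, an isolated
#' entity (all-zero transfer column) still receives a usable seed.
#'
#' @param WA Cross transfer matrix (\code{WA1} for a disease query,
#'   \code{WA2} for a lncRNA query).
#' @param lap Laplacian score vector of the query.
#' @param index Query column index in \code{WA}.
#' @return Probability vector summing to 1, or all-zero.
#' @export
initialVector <- function(WA, lap, index) {
  stopifnot(ncol(WA) == length(lap))
  v <- drop(WA %*% lap) + WA[, index]
  s <- sum(v)
  if (s == 0) v else v / s
}

#' Random walk with restart
#'
#' Iterates \eqn{p_{t+1} = (1-\gamma) W p_t + \gamma p_0} until the L1
#' change between successive vectors is at most \code{tol}, and returns
#' the steady vector.  \code{p0} may be a matrix, in which case each
#' column is walked independently (all columns must converge).  With a
#' column-stochastic \code{W}, a seed summing to 1 yields a steady
#' vector summing to 1.
#'
#' @param W Square column-stochastic transition matrix.
#' @param p0 Seed probability vector (or matrix of seed columns); each
#'   column sums to 1 or is all-zero.
#' @param gamma Restart probability in (0, 1\] (1 returns the seed).
#' @param tol L1 convergence threshold (default 1e-6).
#' @param maxIter Iteration cap; exceeding it without convergence is an
#'   error carrying the last residual.
#' @return Steady vector (or matrix) of the same shape as \code{p0}.
#' @examples
#' W <- columnNormalize(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
#' rwr(W, c(1, 0, 0), gamma = 0.9)
#' @export
rwr <- function(W, p0, gamma, tol = 1e-6, maxIter = 1000L) {
  stopifnot(nrow(W) == ncol(W), gamma > 0, gamma <= 1)
  p0 <- as.matrix(p0)
  p <- p0
  for (it in seq_len(maxIter)) {
    pn <- (1 - gamma) * (W %*% p) + gamma * p0
    resid <- max(colSums(abs(pn - p)))
    p <- pn
    if (resid <= tol) return(if (ncol(p) == 1L) drop(p) else p)
  }
  stop(sprintf("random walk did not converge in %d iterations (residual %.3g)",
               maxIter, resid))
}

#' Closed-form steady state of the restart walk
#'
#' Solves \eqn{\gamma (I - (1-\gamma) W)^{-1} p_0} directly.  Used as
#' the alternative engine and as the oracle the iterative walk is tested
#' against.
#'
#' @inheritParams rwr
#' @return Steady vector (or matrix) of the same shape as \code{p0}.
#' @export
rwrSolve <- function(W, p0, gamma) {
  stopifnot(nrow(W) == ncol(W), gamma > 0, gamma <= 1)
  p0 <- as.matrix(p0)
  out <- gamma * solve(diag(nrow(W)) - (1 - gamma) * W, p0)
  if (ncol(out) == 1L) drop(out) else out
}

#' Build the column-normalized propagation model
#'
#' Normalizes the lncRNA similarity, disease similarity, association
#' matrix and its transpose into the four transfer matrices of the dual
#' walk.
#'
#' @param dataset An [AssociationDataset-class].
#' @param ll lncRNA functional [SimilarityMatrix-class] (or matrix).
#' @param dd Disease semantic [SimilarityMatrix-class] (or matrix).
#' @param params A [GrwParams-class].
#' @return A [PropagationModel-class].
#' @export
buildPropagationModel <- function(dataset, ll, dd, params = grwParams()) {
  AS <- assocMatrix(dataset)
  LLm <- if (methods::is(ll, "SimilarityMatrix")) simValues(ll) else ll
  DDm <- if (methods::is(dd, "SimilarityMatrix")) simValues(dd) else dd
  LLm <- LLm[rownames(AS), rownames(AS), drop = FALSE]
  DDm <- DDm[colnames(AS), colnames(AS), drop = FALSE]
  methods::new("PropagationModel",
               WL = columnNormalize(LLm), WD = columnNormalize(DDm),
               WA1 = columnNormalize(AS), WA2 = columnNormalize(t(AS)),
               params = params)
}

#' Dual restart-walk prediction scores for every lncRNA-disease pair
#'
#' Runs the two restart walks of the model and blends them.  For every
#' disease \code{j}, a walk over the lncRNA similarity network is
#' seeded from the Laplacian-smoothed disease query combined with
#' disease \code{j}'s known lncRNAs; its steady vector gives column
#' \code{j} of \code{S1}.  Symmetrically, for every lncRNA \code{i} a
#' walk over the disease similarity network gives row \code{i} of
#' \code{S2}.  The final score is
#' \code{FS = eta * S1 + (1 - eta) * S2}.  An entity whose seed vector
#' is all-zero (disconnected from everything) simply keeps an all-zero
#' score column/row, so whole-matrix prediction never aborts.
#'
#' @inheritParams buildPropagationModel
#' @return A [ScorePair-class] whose matrices carry the dataset's
#'   dimnames.
#' @examples
#' as <- matrix(c(1, 0, 0, 0), 2, dimnames = list(c("L1", "L2"),
#'                                                c("D1", "D2")))
#' ds <- associationDataset(as)
#' I2 <- diag(2)
#' sp <- grwldaScores(ds, similarityMatrix(`dimnames<-`(I2, list(
#'   c("L1", "L2"), c("L1", "L2")))), similarityMatrix(`dimnames<-`(
#'   I2, list(c("D1", "D2"), c("D1", "D2")))))
#' finalScores(sp)
#' @export
grwldaScores <- function(dataset, ll, dd, params = grwParams()) {
  model <- buildPropagationModel(dataset, ll, dd, params)
  p <- params
  WL <- model@WL; WD <- model@WD; WA1 <- model@WA1; WA2 <- model@WA2

  # lncRNA-side walk: one seed column per disease
  LPD <- .laplacianAll(WD, p@alpha, p@laplacianForm)
  P0L <- .colNorm(WA1 %*% LPD + WA1)
  S1 <- if (p@engine == "solve") rwrSolve(WL, P0L, p@gamma)
        else rwr(WL, P0L, p@gamma, p@tol, p@maxIter)

  # disease-side walk: one seed column per lncRNA
  LPL <- .laplacianAll(WL, p@beta, p@laplacianForm)
  P0D <- .colNorm(WA2 %*% LPL + WA2)
  S2t <- if (p@engine == "solve") rwrSolve(WD, P0D, p@gamma)
         else rwr(WD, P0D, p@gamma, p@tol, p@maxIter)
  S2 <- t(S2t)

  dimnames(S1) <- dimnames(S2) <- dimnames(assocMatrix(dataset))
  FS <- p@eta * S1 + (1 - p@eta) * S2
  methods::new("ScorePair", S1 = S1, S2 = S2, FS = FS, eta = p@eta)
}
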