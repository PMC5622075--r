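#' ROC curve and AUC from pooled scores
#'
#' Sweeps a threshold over all distinct scores, computing the true- and
#' false-positive rates at each, and integrates the curve by the
#' trapezoidal rule, which equals the Mann-Whitney statistic with half
#' credit for ties.
#'
#' @param positives Numeric scores of the known (held-out) associations.
#' @param negatives Numeric scores of the unknown pairs.
#' @return List with \code{points} (data frame \code{fpr}, \code{tpr}
#'   from (0,0) to (1,1)) and \code{auc}.
#' @examples
#' rocAuc(c(0.9, 0.4), c(0.8, 0.1))$auc   # 0.75
#' @export
rocAuc <- function(positives, negatives) {
  if (!length(positives) || !length(negatives))
    stop("both score classes must be nonempty to compute an ROC curve")
  np <- length(positives); nn <- length(negatives)
  r <- rank(c(positives, negatives))
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)

  sc <- c(positives, negatives)
  lab <- rep(c(1, 0), c(np, nn))
  ord <- order(sc, decreasing = TRUE)
  tp <- cumsum(lab[ord]); fp <- cumsum(1 - lab[ord])
  keep <- c(sc[ord][-1L] != sc[ord][-length(sc)], TRUE)  # last index of each tie group
  pts <- data.frame(fpr = c(0, fp[keep] / nn, 1),
                    tpr = c(0, tp[keep] / np, 1))
  pts <- unique(pts)
  list(points = pts, auc = auc)
}

#' Precision-recall curve and AUPR from pooled scores
#'
#' Sweeps a threshold over all distinct scores and integrates precision
#' against recall by the step-wise rule (no interpolation between
#' points), the conservative convention.  With no negatives the
#' precision is identically 1 and the AUPR is 1.
#'
#' @inheritParams rocAuc
#' @return List with \code{points} (data frame \code{recall},
#'   \code{precision}) and \code{aupr}.
#' @export
prAupr <- function(positives, negatives) {
  if (!length(positives))
    stop("the positive score class must be nonempty to compute a PR curve")
  np <- length(positives); nn <- length(negatives)
  sc <- c(positives, negatives)
  lab <- rep(c(1, 0), c(np, nn))
  ord <- order(sc, decreasing = TRUE)
  tp <- cumsum(lab[ord]); fp <- cumsum(1 - lab[ord])
  keep <- c(sc[ord][-1L] != sc[ord][-length(sc)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  recall <- tp / np
  precision <- tp / (tp + fp)
  aupr <- sum(diff(c(0, recall)) * precision)
  list(points = data.frame(recall = recall, precision = precision),
       aupr = aupr)
}

.maskedDataset <- function(AS, cells) {
  ASm <- AS
  ASm[cells] <- 0
  associationDataset(ASm)
}

.foldScores <- function(AS, cells, dd, params, staticLL, llFull) {
  dsm <- .maskedDataset(AS, cells)
  ll <- if (staticLL) llFull else lncrnaSimilarity(dsm, dd)
  finalScores(grwldaScores(dsm, ll, dd, params))
}

.cvResult <- function(mode, positives, negatives, perRepAuc = numeric()) {
  roc <- rocAuc(positives$score, negatives$score)
  pr <- prAupr(positives$score, negatives$score)
  auc <- if (length(perRepAuc)) mean(perRepAuc) else roc$auc
  methods::new("CvResult", mode = mode,
               positives = positives, negatives = negatives,
               rocPoints = roc$points, prPoints = pr$points,
               auc = auc, aupr = pr$aupr, perRepAuc = perRepAuc)
}

#' Leave-one-out cross-validation of the predictor
#'
#' Masks known associations one at a time and asks the model to recover
#' them.  Three masking modes mirror the three evaluation settings:
#' \describe{
#'   \item{overall}{only the evaluated cell is set to 0;}
#'   \item{novel_lncrna}{the evaluated lncRNA's entire association row
#'     is set to 0, emulating a lncRNA with no known disease;}
#'   \item{isolated_disease}{the evaluated disease's entire association
#'     column is set to 0, emulating a disease with no known lncRNA.}
#' }
#' The held-out pair's score under the masked model is a positive.  In
#' overall mode the negatives are all unknown pairs scored once under
#' the full model (masking a single cell leaves the rest of the score
#' matrix essentially unchanged, so recomputing the negatives for every
#' left-out cell would cost a quadratic number of runs for no gain).
#' In the novel-lncrna and isolated-disease modes each masked run
#' already rescores the entity's entire row or column, so the unknown
#' pairs of that row/column are taken from the same masked run;
#' positives and negatives then share one calibration, which keeps
#' these harder modes comparable to the overall mode.
#' By default the lncRNA functional similarity is recomputed from the
#' masked association matrix inside every fold, so no information about
#' the held-out association leaks through the similarity network;
#' \code{staticLL = TRUE} restores the naive variant that keeps the
#' full-data similarity throughout.
#'
#' @param dataset An [AssociationDataset-class] with at least two
#'   associations and at least one unknown pair.
#' @param dd Disease semantic [SimilarityMatrix-class].
#' @param params A [GrwParams-class].
#' @param mode One of \code{"overall"}, \code{"novel_lncrna"},
#'   \code{"isolated_disease"}.
#' @param staticLL Keep the full-data lncRNA similarity in every fold.
#' @return A [CvResult-class].
#' @export
loocv <- function(dataset, dd, params = grwParams(),
                  mode = c("overall", "novel_lncrna", "isolated_disease"),
                  staticLL = FALSE) {
  mode <- match.arg(mode)
  AS <- assocMatrix(dataset)
  pos <- which(AS == 1, arr.ind = TRUE)
  if (nrow(pos) < 2)
    stop("LOOCV needs at least two known associations")
  if (!any(AS == 0))
    stop("no unknown pairs: the negative class is empty and the AUC is undefined")

  llFull <- lncrnaSimilarity(dataset, dd)

  asDf <- function(cells, score)
    data.frame(lncrna = rownames(AS)[cells[, 1]],
               disease = colnames(AS)[cells[, 2]],
               score = score, stringsAsFactors = FALSE)

  if (mode == "overall") {
    fsFull <- finalScores(grwldaScores(dataset, llFull, dd, params))
    neg <- which(AS == 0, arr.ind = TRUE)
    negatives <- asDf(neg, fsFull[neg])
    score <- vapply(seq_len(nrow(pos)), function(k) {
      fs <- .foldScores(AS, pos[k, , drop = FALSE], dd, params,
                        staticLL, llFull)
      fs[pos[k, , drop = FALSE]]
    }, numeric(1))
    positives <- asDf(pos, score)
  } else {
    posParts <- list(); negParts <- list()
    if (mode == "novel_lncrna") {
      for (i in seq_len(nrow(AS))) {
        fs <- .foldScores(AS, cbind(i, seq_len(ncol(AS))), dd, params,
                          staticLL, llFull)
        known <- AS[i, ] == 1
        if (any(known))
          posParts[[length(posParts) + 1L]] <-
            asDf(cbind(i, which(known)), fs[i, known])
        negParts[[length(negParts) + 1L]] <-
          asDf(cbind(i, which(!known)), fs[i, !known])
      }
    } else {
      for (j in seq_len(ncol(AS))) {
        fs <- .foldScores(AS, cbind(seq_len(nrow(AS)), j), dd, params,
                          staticLL, llFull)
        known <- AS[, j] == 1
        if (any(known))
          posParts[[length(posParts) + 1L]] <-
            asDf(cbind(which(known), j), fs[known, j])
        negParts[[length(negParts) + 1L]] <-
          asDf(cbind(which(!known), j), fs[!known, j])
      }
    }
    positives <- do.call(rbind, posParts)
    negatives <- do.call(rbind, negParts)
  }
  .cvResult(mode, positives, negatives)
}

#' Repeated k-fold cross-validation
#'
#' Randomly partitions the known associations (at the cell level) into
#' \code{k} folds; within each repetition every fold is masked jointly,
#' scores are regenerated from the remaining associations, and the
#' held-out scores are pooled over the folds into one per-repetition
#' AUC.  The reported AUC/AUPR are the means over repetitions.
#'
#' @inheritParams loocv
#' @param k Number of folds (at least 2, at most the association count).
#' @param reps Number of random repetitions.
#' @param seed Mandatory integer seed for the fold partitions.
#' @return A [CvResult-class] with \code{perRepAuc} filled; its
#'   positives pool all repetitions.
#' @export
kfoldCV <- function(dataset, dd, params = grwParams(), k = 5L,
                    reps = 10L, seed, staticLL = FALSE) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required so the fold partition is reproducible")
  AS <- assocMatrix(dataset)
  pos <- which(AS == 1, arr.ind = TRUE)
  npos <- nrow(pos)
  if (k < 2 || k > npos)
    stop("k must lie between 2 and the number of known associations")
  llFull <- lncrnaSimilarity(dataset, dd)
  fsFull <- finalScores(grwldaScores(dataset, llFull, dd, params))
  neg <- which(AS == 0, arr.ind = TRUE)
  negatives <- data.frame(lncrna = rownames(AS)[neg[, 1]],
                          disease = colnames(AS)[neg[, 2]],
                          score = fsFull[neg],
                          stringsAsFactors = FALSE)

  set.seed(seed)
  perRepAuc <- numeric(reps); perRepAupr <- numeric(reps)
  allPos <- vector("list", reps)
  for (r in seq_len(reps)) {
    fold <- sample(rep_len(seq_len(k), npos))
    repScores <- numeric(npos)
    for (f in seq_len(k)) {
      cells <- pos[fold == f, , drop = FALSE]
      fs <- .foldScores(AS, cells, dd, params, staticLL, llFull)
      repScores[fold == f] <- fs[cells]
    }
    perRepAuc[r] <- rocAuc(repScores, negatives$score)$auc
    perRepAupr[r] <- prAupr(repScores, negatives$score)$aupr
    allPos[[r]] <- data.frame(lncrna = rownames(AS)[pos[, 1]],
                              disease = colnames(AS)[pos[, 2]],
                              score = repScores, rep = r,
                              stringsAsFactors = FALSE)
  }
  positives <- do.call(rbind, allPos)
  res <- .cvResult("kfold", positives[, c("lncrna", "disease", "score")],
                   negatives, perRepAuc = perRepAuc)
  res@aupr <- mean(perRepAupr)
  res
}

#' Ranks of candidate pairs among the unknown pairs of their disease
#'
#' For each queried (lncRNA, disease) pair - which must be unknown under
#' the training data - computes the rank of its score among all unknown
#' pairs of the same disease (1 = best), with ties broken by ascending
#' lncRNA identifier, and the mean rank over the queried pairs.
#'
#' @param FS Final score matrix (dimnames as the dataset).
#' @param dataset The training [AssociationDataset-class].
#' @param pairs Data frame (or 2-column matrix) of lncRNA and disease
#'   identifiers.
#' @return List with \code{ranks} (data frame \code{lncrna},
#'   \code{disease}, \code{rank}) and \code{meanRank}.
#' @export
rankOfPairs <- function(FS, dataset, pairs) {
  AS <- assocMatrix(dataset)
  pairs <- as.data.frame(pairs)[, 1:2]
  names(pairs) <- c("lncrna", "disease")
  pairs[] <- lapply(pairs, as.character)
  rk <- integer(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs$lncrna[p]; j <- pairs$disease[p]
    if (!i %in% rownames(AS) || !j %in% colnames(AS))
      stop(sprintf("unknown identifiers in pair (%s, %s)", i, j))
    if (AS[i, j] == 1)
      stop(sprintf("pair (%s, %s) is already a known association", i, j))
    cand <- rownames(AS)[AS[, j] == 0]
    ord <- cand[order(-FS[cand, j], cand)]
    rk[p] <- match(i, ord)
  }
  list(ranks = data.frame(pairs, rank = rk, stringsAsFactors = FALSE),
       meanRank = mean(rk))
}
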