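#' AssociationDataset: known lncRNA-disease associations
#'
#' Holds the binary adjacency matrix \code{AS} of experimentally verified
#' lncRNA-disease associations, with lncRNAs as rows and diseases as
#' columns.  Row and column names carry the ordered identifier lists; the
#' order is the first-appearance order of identifiers in the source file,
#' so matrix indices are reproducible from the file alone.
#'
#' @slot assoc Binary numeric matrix, \code{nl} lncRNA rows by \code{nd}
#'   disease columns; \code{assoc[i, j] == 1} iff lncRNA \code{i} is
#'   associated with disease \code{j}.
#'
#' @seealso [readAssociations()], [associationDataset()]
#' @export
setClass("AssociationDataset", slots = c(assoc = "matrix"))

setValidity("AssociationDataset", function(object) {
  m <- object@assoc
  msgs <- character()
  if (!is.numeric(m))
    msgs <- c(msgs, "association matrix must be numeric")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msgs <- c(msgs, "association matrix must have row and column names")
  if (!is.null(rownames(m)) && anyDuplicated(rownames(m)))
    msgs <- c(msgs, "duplicate lncRNA identifiers")
  if (!is.null(colnames(m)) && anyDuplicated(colnames(m)))
    msgs <- c(msgs, "duplicate disease identifiers")
  if (is.numeric(m) && !all(m %in% c(0, 1)))
    msgs <- c(msgs, "association matrix entries must be 0 or 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct an AssociationDataset
#'
#' @param assoc Binary matrix with lncRNA row names and disease column
#'   names, or a two-column data frame / matrix of (lncRNA, disease) pairs.
#' @return An [AssociationDataset-class] object.
#' @examples
#' pairs <- data.frame(lncrna = c("H19", "H19", "HOTAIR"),
#'                     disease = c("colon cancer", "gastric cancer",
#'                                 "colon cancer"))
#' associationDataset(pairs)
#' @export
associationDataset <- function(assoc) {
  if (is.data.frame(assoc) ||
      (is.matrix(assoc) && is.character(assoc) && ncol(assoc) >= 2)) {
    pairs <- as.data.frame(assoc)[, 1:2]
    names(pairs) <- c("lncrna", "disease")
    pairs[] <- lapply(pairs, as.character)
    pairs <- unique(pairs)
    lids <- unique(pairs$lncrna)
    dids <- unique(pairs$disease)
    m <- matrix(0, nrow = length(lids), ncol = length(dids),
                dimnames = list(lids, dids))
    m[cbind(match(pairs$lncrna, lids), match(pairs$disease, dids))] <- 1
    assoc <- m
  }
  storage.mode(assoc) <- "double"
  methods::new("AssociationDataset", assoc = assoc)
}

#' DiseaseDAG: a disease and its MeSH ancestors
#'
#' Directed acyclic graph G(D) of one disease: the disease itself plus all
#' ancestor terms obtained by dot-segment prefix truncation of the
#' disease's tree numbers, with the per-term semantic contribution of each
#' node.  The disease node contributes exactly 1; every ancestor
#' contributes the decay factor times the maximum contribution over its
#' children, so terms reachable along several paths receive the maximum.
#'
#' @slot diseaseId Identifier of the disease the DAG describes.
#' @slot terms Character vector of node identifiers (tree codes, plus the
#'   disease's own node).
#' @slot edges Two-column character matrix of parent-to-child edges.
#' @slot contributions Named numeric vector in \[0, 1\], one entry per term.
#' @slot decay Semantic contribution decay factor in \[0, 1\].
#'
#' @seealso [buildDiseaseDAG()]
#' @export
setClass("DiseaseDAG",
         slots = c(diseaseId = "character",
                   terms = "character",
                   edges = "matrix",
                   contributions = "numeric",
                   decay = "numeric"))

setValidity("DiseaseDAG", function(object) {
  msgs <- character()
  cn <- object@contributions
  if (!setequal(names(cn), object@terms))
    msgs <- c(msgs, "contributions must be named by the DAG terms")
  # the disease's own tree positions are the terms contributing exactly 1
  if (length(cn) && max(cn) != 1)
    msgs <- c(msgs, "the disease's own contribution must equal 1 exactly")
  if (any(cn < 0) || any(cn > 1))
    msgs <- c(msgs, "contributions must lie in [0, 1]")
  if (length(object@decay) != 1 || object@decay < 0 || object@decay > 1)
    msgs <- c(msgs, "decay must be a single value in [0, 1]")
  if (nrow(object@edges) > 0 && .hasCycle(object@edges))
    msgs <- c(msgs, "edge set contains a cycle")
  if (length(msgs)) msgs else TRUE
})

# Kahn-style cycle check on a parent->child edge matrix.
.hasCycle <- function(edges) {
  nodes <- unique(c(edges[, 1], edges[, 2]))
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(edges[, 2])
  indeg[names(tab)] <- as.integer(tab)
  active <- rep(TRUE, nrow(edges))
  queue <- nodes[indeg == 0]
  removed <- 0L
  while (length(queue)) {
    n <- queue[[1]]; queue <- queue[-1]; removed <- removed + 1L
    out <- which(active & edges[, 1] == n)
    for (e in out) {
      active[e] <- FALSE
      child <- edges[e, 2]
      indeg[child] <- indeg[child] - 1L
      if (indeg[child] == 0L) queue <- c(queue, child)
    }
  }
  removed < length(nodes)
}

#' SimilarityMatrix: square labeled similarity scores
#'
#' A symmetric nonnegative matrix of pairwise similarity scores in
#' \[0, 1\], labeled by entity identifiers.  Used for disease semantic
#' similarity (role \code{"DD"}) and lncRNA functional similarity (role
#' \code{"LL"}).  The diagonal is 1 for every entity with a nonempty
#' profile; an entity with no evidence (e.g. a lncRNA with no known
#' disease after masking) may carry a zero diagonal.
#'
#' @slot values Square numeric matrix with identical row and column names.
#' @slot role Character tag, one of \code{"DD"}, \code{"LL"} or \code{""}.
#'
#' @export
setClass("SimilarityMatrix",
         slots = c(values = "matrix", role = "character"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (nrow(v) != ncol(v))
    msgs <- c(msgs, "similarity matrix must be square")
  if (is.null(rownames(v)) || is.null(colnames(v)) ||
      !identical(rownames(v), colnames(v)))
    msgs <- c(msgs, "row and column names must be present and identical")
  else if (anyDuplicated(rownames(v)))
    msgs <- c(msgs, "duplicate identifiers")
  if (any(v < -1e-12) || any(v > 1 + 1e-12))
    msgs <- c(msgs, "similarity values must lie in [0, 1]")
  if (nrow(v) > 0 && max(abs(v - t(v))) > 1e-8)
    msgs <- c(msgs, "similarity matrix must be symmetric")
  if (!object@role %in% c("DD", "LL", ""))
    msgs <- c(msgs, "role must be \"DD\", \"LL\" or \"\"")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimilarityMatrix
#'
#' @param values Square numeric matrix with identical row/column names.
#' @param role Optional role tag: \code{"DD"} (disease semantic) or
#'   \code{"LL"} (lncRNA functional).
#' @return A [SimilarityMatrix-class] object.
#' @export
similarityMatrix <- function(values, role = "") {
  storage.mode(values) <- "double"
  # clamp away numerical fuzz from vectorized arithmetic
  values[values < 0 & values > -1e-12] <- 0
  values[values > 1 & values < 1 + 1e-12] <- 1
  methods::new("SimilarityMatrix", values = values, role = role)
}

#' GrwParams: propagation parameters
#'
#' Parameter bundle for the dual random walk.  Defaults are the optimal
#' values reported for the benchmark: restart probability
#' \code{gamma = 0.9}, balance parameters \code{alpha = beta = 0.1},
#' integration weight \code{eta = 0.7}, convergence threshold
#' \code{tol = 1e-6}.
#'
#' @slot gamma Restart probability of the random walk, in (0, 1\].
#' @slot alpha Disease-side balance parameter of the Laplacian seed
#'   smoothing, in (0, 1).
#' @slot beta lncRNA-side balance parameter, in (0, 1).
#' @slot eta Weight of the lncRNA-side walk in the final score blend,
#'   in \[0, 1\].
#' @slot tol Convergence threshold on the L1 change between successive
#'   probability vectors.
#' @slot maxIter Iteration cap for the walk.
#' @slot laplacianForm \code{"inverse"} (default) evaluates the seed
#'   smoothing as \eqn{(1-a)(I - a W)^{-1} e}; \code{"literal"} evaluates
#'   the plain product \eqn{(1-a)(I - a W) e}.  See the methods vignette.
#' @slot engine \code{"iterative"} (default) iterates the walk to the
#'   stated tolerance; \code{"solve"} uses the closed-form linear solve.
#'
#' @export
setClass("GrwParams",
         slots = c(gamma = "numeric", alpha = "numeric", beta = "numeric",
                   eta = "numeric", tol = "numeric", maxIter = "integer",
                   laplacianForm = "character", engine = "character"))

setValidity("GrwParams", function(object) {
  msgs <- character()
  chk1 <- function(x, nm) {
    if (length(x) != 1 || !is.finite(x))
      msgs <<- c(msgs, sprintf("%s must be a single finite value", nm))
  }
  chk1(object@gamma, "gamma"); chk1(object@alpha, "alpha")
  chk1(object@beta, "beta");   chk1(object@eta, "eta")
  chk1(object@tol, "tol")
  if (length(object@gamma) == 1 &&
      (object@gamma <= 0 || object@gamma > 1))
    msgs <- c(msgs, "gamma must lie in (0, 1]")
  if (length(object@alpha) == 1 &&
      (object@alpha <= 0 || object@alpha >= 1))
    msgs <- c(msgs, "alpha must lie in (0, 1)")
  if (length(object@beta) == 1 &&
      (object@beta <= 0 || object@beta >= 1))
    msgs <- c(msgs, "beta must lie in (0, 1)")
  if (length(object@eta) == 1 && (object@eta < 0 || object@eta > 1))
    msgs <- c(msgs, "eta must lie in [0, 1]")
  if (length(object@tol) == 1 && object@tol <= 0)
    msgs <- c(msgs, "tol must be positive")
  if (object@maxIter < 1L)
    msgs <- c(msgs, "maxIter must be at least 1")
  if (!object@laplacianForm %in% c("inverse", "literal"))
    msgs <- c(msgs, "laplacianForm must be \"inverse\" or \"literal\"")
  if (!object@engine %in% c("iterative", "solve"))
    msgs <- c(msgs, "engine must be \"iterative\" or \"solve\"")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GrwParams object
#'
#' @param gamma Restart probability, in (0, 1\] (1 is allowed as a
#'   degenerate case where the walk returns its seed).
#' @param alpha,beta Balance parameters of the disease- and lncRNA-side
#'   seed smoothing, each in (0, 1).
#' @param eta Integration weight of the lncRNA-side walk, in \[0, 1\].
#' @param tol L1 convergence threshold of the iterative walk.
#' @param maxIter Iteration cap.
#' @param laplacianForm \code{"inverse"} or \code{"literal"}; see
#'   [GrwParams-class].
#' @param engine \code{"iterative"} or \code{"solve"}.
#' @return A [GrwParams-class] object.
#' @examples
#' grwParams()              # benchmark-optimal defaults
#' grwParams(eta = 1)       # lncRNA-side walk only
#' @export
grwParams <- function(gamma = 0.9, alpha = 0.1, beta = 0.1, eta = 0.7,
                      tol = 1e-6, maxIter = 1000L,
                      laplacianForm = c("inverse", "literal"),
                      engine = c("iterative", "solve")) {
  methods::new("GrwParams", gamma = gamma, alpha = alpha, beta = beta,
               eta = eta, tol = tol, maxIter = as.integer(maxIter),
               laplacianForm = match.arg(laplacianForm),
               engine = match.arg(engine))
}

#' PropagationModel: column-normalized transfer matrices
#'
#' The four column-stochastic transfer matrices driving the dual walk:
#' \code{WL} (normalized lncRNA functional similarity), \code{WD}
#' (normalized disease semantic similarity), \code{WA1} (normalized
#' association matrix) and \code{WA2} (normalized transposed association
#' matrix), together with the walk parameters.  Every nonzero column of
#' each matrix sums to 1; zero columns stay all-zero.
#'
#' @slot WL nl x nl column-normalized lncRNA similarity.
#' @slot WD nd x nd column-normalized disease similarity.
#' @slot WA1 nl x nd column-normalized association matrix.
#' @slot WA2 nd x nl column-normalized transpose of the association matrix.
#' @slot params A [GrwParams-class] object.
#'
#' @seealso [buildPropagationModel()]
#' @export
setClass("PropagationModel",
         slots = c(WL = "matrix", WD = "matrix",
                   WA1 = "matrix", WA2 = "matrix", params = "GrwParams"))

setValidity("PropagationModel", function(object) {
  msgs <- character()
  checkW <- function(W, nm) {
    if (any(W < 0))
      msgs <<- c(msgs, sprintf("%s has negative entries", nm))
    cs <- colSums(W)
    bad <- abs(cs - 1) > 1e-9 & cs != 0
    if (any(bad))
      msgs <<- c(msgs, sprintf("%s has non-stochastic nonzero columns", nm))
  }
  checkW(object@WL, "WL"); checkW(object@WD, "WD")
  checkW(object@WA1, "WA1"); checkW(object@WA2, "WA2")
  if (nrow(object@WL) != ncol(object@WL))
    msgs <- c(msgs, "WL must be square")
  if (nrow(object@WD) != ncol(object@WD))
    msgs <- c(msgs, "WD must be square")
  if (nrow(object@WA1) != nrow(object@WL) ||
      ncol(object@WA1) != nrow(object@WD))
    msgs <- c(msgs, "WA1 dimensions inconsistent with WL/WD")
  if (nrow(object@WA2) != nrow(object@WD) ||
      ncol(object@WA2) != nrow(object@WL))
    msgs <- c(msgs, "WA2 dimensions inconsistent with WL/WD")
  if (length(msgs)) msgs else TRUE
})

#' ScorePair: the two walk score matrices and their blend
#'
#' Prediction scores for every lncRNA-disease pair: \code{S1} from the
#' walk over the lncRNA similarity network (one steady vector per
#' disease), \code{S2} from the walk over the disease similarity network
#' (one steady vector per lncRNA), and the final score
#' \code{FS = eta * S1 + (1 - eta) * S2}.
#'
#' @slot S1 nl x nd matrix of lncRNA-walk scores.
#' @slot S2 nl x nd matrix of disease-walk scores.
#' @slot FS nl x nd matrix of integrated final scores.
#' @slot eta The integration weight used for the blend.
#'
#' @seealso [grwldaScores()]
#' @export
setClass("ScorePair",
         slots = c(S1 = "matrix", S2 = "matrix", FS = "matrix",
                   eta = "numeric"))

setValidity("ScorePair", function(object) {
  msgs <- character()
  if (!identical(dim(object@S1), dim(object@S2)) ||
      !identical(dim(object@S1), dim(object@FS)))
    msgs <- c(msgs, "S1, S2 and FS must share dimensions")
  rng <- range(object@S1, object@S2, object@FS, 0)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    msgs <- c(msgs, "scores must lie in [0, 1]")
  if (max(abs(object@FS -
              (object@eta * object@S1 + (1 - object@eta) * object@S2))) >
      1e-9)
    msgs <- c(msgs, "FS must equal eta * S1 + (1 - eta) * S2")
  if (length(msgs)) msgs else TRUE
})

#' CvResult: pooled cross-validation scores and summary curves
#'
#' Result container for the cross-validation protocols: the held-out
#' (positive) and unknown (negative) pair scores, the ROC and
#' precision-recall curve points, the areas under both curves, and for
#' k-fold runs the per-repetition AUC values.
#'
#' @slot mode One of \code{"overall"}, \code{"novel_lncrna"},
#'   \code{"isolated_disease"}, \code{"kfold"}.
#' @slot positives Data frame (lncrna, disease, score) of held-out known
#'   associations, one row per evaluated association.
#' @slot negatives Data frame (lncrna, disease, score) of unknown pairs.
#' @slot rocPoints Data frame (fpr, tpr), starting at (0, 0) and ending
#'   at (1, 1).
#' @slot prPoints Data frame (recall, precision).
#' @slot auc Area under the ROC curve.
#' @slot aupr Area under the precision-recall curve (step-wise rule).
#' @slot perRepAuc Per-repetition AUCs (k-fold only; otherwise empty).
#'
#' @export
setClass("CvResult",
         slots = c(mode = "character",
                   positives = "data.frame", negatives = "data.frame",
                   rocPoints = "data.frame", prPoints = "data.frame",
                   auc = "numeric", aupr = "numeric",
                   perRepAuc = "numeric"))

setValidity("CvResult", function(object) {
  msgs <- character()
  if (!object@mode %in%
      c("overall", "novel_lncrna", "isolated_disease", "kfold"))
    msgs <- c(msgs, "invalid mode")
  if (length(object@auc) == 1 &&
      (object@auc < 0 || object@auc > 1))
    msgs <- c(msgs, "auc must lie in [0, 1]")
  rp <- object@rocPoints
  if (nrow(rp) > 0) {
    if (abs(rp$fpr[1]) > 1e-12 || abs(rp$tpr[1]) > 1e-12 ||
        abs(rp$fpr[nrow(rp)] - 1) > 1e-12 ||
        abs(rp$tpr[nrow(rp)] - 1) > 1e-12)
      msgs <- c(msgs, "ROC curve must run from (0,0) to (1,1)")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn AssociationDataset-class Compact summary.
#' @param object An object of the documented class.
#' @export
setMethod("show", "AssociationDataset", function(object) {
  m <- object@assoc
  cat(sprintf("AssociationDataset: %d lncRNAs x %d diseases, %d associations\n",
              nrow(m), ncol(m), sum(m)))
})

#' @describeIn DiseaseDAG-class Compact summary.
#' @export
setMethod("show", "DiseaseDAG", function(object) {
  cat(sprintf("DiseaseDAG '%s': %d terms, %d edges, decay = %g\n",
              object@diseaseId, length(object@terms),
              nrow(object@edges), object@decay))
})

#' @describeIn SimilarityMatrix-class Compact summary.
#' @export
setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix%s: %d x %d, range [%.3f, %.3f]\n",
              if (nzchar(object@role))
                sprintf(" (role %s)", object@role) else "",
              nrow(object@values), ncol(object@values),
              min(object@values), max(object@values)))
})

#' @describeIn GrwParams-class Compact summary.
#' @export
setMethod("show", "GrwParams", function(object) {
  cat(sprintf(paste0("GrwParams: gamma=%g alpha=%g beta=%g eta=%g ",
                     "tol=%g maxIter=%d form=%s engine=%s\n"),
              object@gamma, object@alpha, object@beta, object@eta,
              object@tol, object@maxIter, object@laplacianForm,
              object@engine))
})

#' @describeIn PropagationModel-class Compact summary.
#' @export
setMethod("show", "PropagationModel", function(object) {
  cat(sprintf("PropagationModel: %d lncRNAs, %d diseases\n",
              nrow(object@WL), nrow(object@WD)))
})

#' @describeIn ScorePair-class Compact summary.
#' @export
setMethod("show", "ScorePair", function(object) {
  cat(sprintf("ScorePair: %d x %d scores, eta = %g\n",
              nrow(object@FS), ncol(object@FS), object@eta))
})

#' @describeIn CvResult-class Compact summary.
#' @export
setMethod("show", "CvResult", function(object) {
  cat(sprintf("CvResult [%s]: %d positives, %d negatives, AUC = %.4f, AUPR = %.4f\n",
              object@mode, nrow(object@positives), nrow(object@negatives),
              object@auc, object@aupr))
  if (length(object@perRepAuc))
    cat(sprintf("  per-rep AUC: %s\n",
                paste(sprintf("%.4f", object@perRepAuc), collapse = " ")))
})
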