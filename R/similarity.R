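#' Build the semantic DAG of one disease
#'
#' Constructs the directed acyclic graph of a disease from its
#' MeSH-style tree numbers.  Ancestor terms are obtained by repeatedly
#' truncating the last dot-delimited segment; the DAG is the union over
#' all of the disease's codes.  Each of the disease's own tree positions
#' contributes exactly 1; an ancestor term contributes the decay factor
#' times the maximum contribution over its children, so a term reachable
#' along several paths receives the maximum.
#'
#' @param diseaseId Disease identifier.
#' @param treeCodes Character vector of dot-delimited tree codes.
#' @param decay Semantic contribution decay factor in \[0, 1\]
#'   (default 0.5, the conventional choice for this measure).
#' @return A [DiseaseDAG-class].
#' @examples
#' dag <- buildDiseaseDAG("colon cancer", "C04.588", decay = 0.5)
#' dagContributions(dag)   # C04.588 -> 1, C04 -> 0.5
#' @export
buildDiseaseDAG <- function(diseaseId, treeCodes, decay = 0.5) {
  treeCodes <- unique(as.character(treeCodes))
  if (!length(treeCodes) || any(!nzchar(treeCodes)))
    stop("disease '", diseaseId, "' needs at least one nonempty tree code")
  if (length(decay) != 1 || is.na(decay) || decay < 0 || decay > 1)
    stop("decay must be a single value in [0, 1]")
  bad <- !grepl("^[A-Za-z0-9]+(\\.[A-Za-z0-9]+)*$", treeCodes)
  if (any(bad))
    stop("invalid tree code: ", treeCodes[bad][1])

  segs <- strsplit(treeCodes, ".", fixed = TRUE)
  terms <- character(); edges <- NULL
  for (s in segs) {
    chain <- vapply(seq_along(s), function(k)
      paste(s[seq_len(k)], collapse = "."), character(1))
    terms <- union(terms, chain)
    if (length(chain) > 1)
      edges <- rbind(edges,
                     cbind(chain[-length(chain)], chain[-1]))
  }
  if (is.null(edges))
    edges <- matrix(character(), ncol = 2)
  edges <- unique(edges)
  colnames(edges) <- c("parent", "child")
  if (nrow(edges) > 0 && .hasCycle(edges))
    stop("cyclic edge set for disease '", diseaseId, "'")

  # contribution recursion, children-first (deeper terms first)
  depth <- lengths(strsplit(terms, ".", fixed = TRUE))
  contrib <- stats::setNames(rep(NA_real_, length(terms)), terms)
  for (t in terms[order(depth, decreasing = TRUE)]) {
    children <- edges[edges[, "parent"] == t, "child"]
    val <- if (length(children)) decay * max(contrib[children]) else 0
    if (t %in% treeCodes) val <- max(val, 1)
    contrib[[t]] <- val
  }
  methods::new("DiseaseDAG", diseaseId = diseaseId, terms = terms,
               edges = edges, contributions = contrib, decay = decay)
}

#' Disease semantic similarity between two DAGs
#'
#' The similarity is the summed contribution of the terms the two DAGs
#' share, from both sides, divided by the sum of the two semantic values
#' (the total contribution of each DAG).  It is symmetric, lies in
#' \[0, 1\], equals 1 for identical DAGs and 0 for disjoint ones.
#'
#' @param a,b [DiseaseDAG-class] objects built with the same decay.
#' @return Similarity score in \[0, 1\].
#' @examples
#' a <- buildDiseaseDAG("A", "C04.588")
#' b <- buildDiseaseDAG("B", "C04")
#' diseaseSimilarity(a, b)   # (0.5 + 1) / (1.5 + 1) = 0.6
#' @export
diseaseSimilarity <- function(a, b) {
  if (a@decay != b@decay)
    stop("DAGs were built with different decay factors")
  shared <- intersect(a@terms, b@terms)
  if (!length(shared)) return(0)
  num <- sum(a@contributions[shared]) + sum(b@contributions[shared])
  num / (semanticValue(a) + semanticValue(b))
}

#' All pairwise disease semantic similarities
#'
#' Vectorized all-pairs version of [diseaseSimilarity()].  The diagonal
#' is exactly 1.
#'
#' @param dags List of [DiseaseDAG-class] objects with unique disease
#'   identifiers and a common decay factor.
#' @return A [SimilarityMatrix-class] with role \code{"DD"}.
#' @export
diseaseSimilarityMatrix <- function(dags) {
  ids <- vapply(dags, function(d) d@diseaseId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate disease identifiers")
  decays <- vapply(dags, function(d) d@decay, numeric(1))
  if (length(unique(decays)) > 1)
    stop("DAGs were built with different decay factors")
  allTerms <- unique(unlist(lapply(dags, function(d) d@terms)))
  nT <- length(allTerms); nD <- length(dags)
  C <- matrix(0, nT, nD, dimnames = list(allTerms, ids))  # contributions
  Z <- matrix(0, nT, nD, dimnames = list(allTerms, ids))  # membership
  for (k in seq_len(nD)) {
    C[dags[[k]]@terms, k] <- dags[[k]]@contributions[dags[[k]]@terms]
    Z[dags[[k]]@terms, k] <- 1
  }
  num <- crossprod(C, Z) + crossprod(Z, C)
  Tv <- colSums(C)
  dd <- num / outer(Tv, Tv, "+")
  diag(dd) <- 1
  dd[dd > 1] <- 1   # guard against last-bit overshoot
  similarityMatrix((dd + t(dd)) / 2, role = "DD")
}

#' Similarity between one disease and a disease group
#'
#' The best-match rule: the maximum semantic similarity between the
#' disease and any member of the group.
#'
#' @param disease Disease identifier or index.
#' @param group Nonempty vector of disease identifiers or indices.
#' @param dd A [SimilarityMatrix-class] with role \code{"DD"}.
#' @return The maximum similarity score.
#' @export
groupSimilarity <- function(disease, group, dd) {
  if (!length(group))
    stop("disease group is empty; group similarity is undefined")
  max(simValues(dd)[disease, group])
}

#' lncRNA functional similarity (group-wise best-match average)
#'
#' Computes the functional similarity of every lncRNA pair from the
#' semantic similarity of their associated disease groups: each disease
#' of one group is matched to its most similar disease in the other
#' group, and the matched scores from both directions are averaged over
#' the two group sizes.  Two lncRNAs with identical disease groups score
#' 1; a lncRNA with an empty disease profile (possible after
#' cross-validation masking) scores 0 against everything, including
#' itself, since there is no functional evidence to compare.
#'
#' @param dataset An [AssociationDataset-class] (or a binary association
#'   matrix with dimnames) defining each lncRNA's disease group.
#' @param dd Disease semantic [SimilarityMatrix-class]; its identifiers
#'   must cover the dataset's diseases.
#' @return A [SimilarityMatrix-class] with role \code{"LL"}.
#' @export
lncrnaSimilarity <- function(dataset, dd) {
  AS <- if (methods::is(dataset, "AssociationDataset"))
    assocMatrix(dataset) else dataset
  D <- simValues(dd)
  if (!all(colnames(AS) %in% rownames(D)))
    stop("disease similarity matrix does not cover the dataset's diseases")
  D <- D[colnames(AS), colnames(AS), drop = FALSE]
  nl <- nrow(AS); nd <- ncol(AS)
  deg <- rowSums(AS)

  # bestMatch[u, d] = max over d' in D(u) of DD(d', d)
  bestMatch <- matrix(0, nl, nd)
  for (u in seq_len(nl)) {
    grp <- which(AS[u, ] == 1)
    if (length(grp) == 1L) bestMatch[u, ] <- D[grp, ]
    else if (length(grp) > 1L)
      bestMatch[u, ] <- apply(D[grp, , drop = FALSE], 2, max)
  }
  B <- tcrossprod(bestMatch, AS)   # B[u, v] = sum_{d in D(v)} bestMatch[u, d]
  ll <- (B + t(B)) / outer(deg, deg, "+")
  ll[deg == 0, ] <- 0
  ll[, deg == 0] <- 0
  ll[is.nan(ll)] <- 0
  diag(ll)[deg > 0] <- 1
  ll[ll > 1] <- 1
  dimnames(ll) <- list(rownames(AS), rownames(AS))
  similarityMatrix((ll + t(ll)) / 2, role = "LL")
}
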