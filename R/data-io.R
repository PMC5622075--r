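#' Read an lncRNA-disease association edge list
#'
#' Parses a tab-separated edge list with one association per line (lncRNA
#' identifier, disease identifier), skipping blank lines and lines
#' starting with \code{#}.  Duplicate pairs are collapsed; identifier
#' order along each axis is first-appearance order, so the adjacency
#' matrix is reproducible from the file alone.
#'
#' Files written by [writeAssociations()] carry two directive lines
#' (\code{## lncrnas:} and \code{## diseases:}) pinning the identifier
#' order explicitly; when present they take precedence, which makes the
#' read/write round trip an exact identity even for datasets whose
#' stored order is not the first-appearance order of any pair sequence.
#'
#' @param path Path to the edge-list TSV file.
#' @param quiet Suppress the parsed-counts message.
#' @return An [AssociationDataset-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("# pairs", "H19\tgastric cancer", "HOTAIR\tcolon cancer"), f)
#' readAssociations(f)
#' @export
readAssociations <- function(path, quiet = FALSE) {
  if (!file.exists(path))
    stop("association file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx))
    stop("association file contains no data lines: ", path)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(vapply(fields, function(f)
    length(f) < 2 || !nzchar(f[1]) || !nzchar(f[2]), logical(1)))
  if (length(bad))
    stop(sprintf("malformed association line %d: %s",
                 idx[bad[1]], lines[idx[bad[1]]]))
  pairs <- data.frame(
    lncrna = vapply(fields, `[[`, character(1), 1L),
    disease = vapply(fields, `[[`, character(1), 2L),
    stringsAsFactors = FALSE)
  ds <- associationDataset(pairs)
  # order directives written by writeAssociations() override
  # first-appearance order and may add association-free entities
  lid <- .readDirective(lines, "lncrnas")
  did <- .readDirective(lines, "diseases")
  if (!is.null(lid) || !is.null(did)) {
    lid <- if (is.null(lid)) lncrnaIds(ds) else lid
    did <- if (is.null(did)) diseaseIds(ds) else did
    if (!all(lncrnaIds(ds) %in% lid) || !all(diseaseIds(ds) %in% did))
      stop("order directives do not cover all identifiers in ", path)
    m <- matrix(0, length(lid), length(did), dimnames = list(lid, did))
    m[lncrnaIds(ds), diseaseIds(ds)] <- assocMatrix(ds)
    ds <- associationDataset(m)
  }
  if (!quiet)
    message(sprintf("read %d associations: %d lncRNAs, %d diseases",
                    sum(assocMatrix(ds)), nrow(ds), ncol(ds)))
  ds
}

#' Write an AssociationDataset as an edge-list TSV
#'
#' Pairs are emitted row-major (lncRNA order, then disease order),
#' preceded by order-directive comment lines so a read/write round trip
#' reproduces the identical matrix and identifier order, including
#' entities that currently have no association.
#'
#' @param dataset An [AssociationDataset-class].
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeAssociations <- function(dataset, path) {
  m <- assocMatrix(dataset)
  idx <- which(t(m) == 1)  # transpose: row-major over lncRNAs
  dis <- colnames(m)[(idx - 1) %% ncol(m) + 1]
  lnc <- rownames(m)[(idx - 1) %/% ncol(m) + 1]
  writeLines(c("# lncRNA\tdisease",
               paste(c("## lncrnas:", rownames(m)), collapse = "\t"),
               paste(c("## diseases:", colnames(m)), collapse = "\t"),
               paste(lnc, dis, sep = "\t")), path)
  invisible(path)
}

.readDirective <- function(lines, what) {
  hit <- grep(sprintf("^## %s:", what), lines, value = TRUE)
  if (!length(hit)) return(NULL)
  f <- strsplit(hit[[1]], "\t", fixed = TRUE)[[1]][-1]
  f[nzchar(f)]
}

#' Read disease MeSH-style tree numbers
#'
#' Each non-comment line holds a disease identifier followed by one or
#' more dot-delimited tree codes (e.g. \code{C04.588.274}), all
#' tab-separated.  Lines sharing a disease identifier have their codes
#' unioned.  Ancestor terms are derivable from a code by dot-segment
#' prefix truncation.
#'
#' @param path Path to the record TSV file.
#' @return Named list mapping disease identifier to a character vector of
#'   tree codes.
#' @export
readTreeNumbers <- function(path) {
  if (!file.exists(path))
    stop("tree-number file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx))
    stop("tree-number file contains no data lines: ", path)
  out <- list()
  for (k in seq_along(idx)) {
    f <- strsplit(lines[idx[k]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2 || !nzchar(f[1]))
      stop(sprintf("malformed tree-number line %d: %s",
                   idx[k], lines[idx[k]]))
    codes <- f[-1]
    if (any(!nzchar(codes)))
      stop(sprintf("empty tree code on line %d (disease %s)", idx[k], f[1]))
    bad <- !grepl("^[A-Za-z0-9]+(\\.[A-Za-z0-9]+)*$", codes)
    if (any(bad))
      stop(sprintf("invalid tree code '%s' on line %d", codes[bad][1], idx[k]))
    out[[f[1]]] <- union(out[[f[1]]], codes)
  }
  out
}

#' Write a disease tree-number file
#'
#' @param treeNumbers Named list mapping disease identifier to tree codes.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeTreeNumbers <- function(treeNumbers, path) {
  lines <- vapply(names(treeNumbers), function(d)
    paste(c(d, treeNumbers[[d]]), collapse = "\t"), character(1))
  writeLines(c("# disease\ttree numbers...", lines), path)
  invisible(path)
}

#' Read a labeled square similarity matrix
#'
#' Expects a TSV with a header row of identifiers and the same
#' identifiers in the first column.
#'
#' @param path Path to the matrix TSV.
#' @param role Optional role tag passed to [similarityMatrix()].
#' @return A [SimilarityMatrix-class].
#' @export
readSimilarityMatrix <- function(path, role = "") {
  if (!file.exists(path))
    stop("similarity matrix file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1,
                          comment.char = "#")
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop("similarity matrix is not square: ", path)
  if (!identical(rownames(m), colnames(m)))
    stop("row and column identifiers disagree: ", path)
  similarityMatrix(m, role = role)
}

#' Write a labeled matrix as TSV
#'
#' Accepts a [SimilarityMatrix-class] or any named numeric matrix (e.g. a
#' score matrix), and writes it with an identifier header row and
#' identifier first column.
#'
#' @param x Matrix or [SimilarityMatrix-class].
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeLabeledMatrix <- function(x, path) {
  if (methods::is(x, "SimilarityMatrix")) x <- simValues(x)
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rank candidate partners of a query entity
#'
#' Ranks the unknown partners of one disease (candidates are lncRNAs) or
#' one lncRNA (candidates are diseases) by descending final score.  Known
#' associations are excluded.  Ties are broken by ascending identifier so
#' the output is deterministic.
#'
#' @param scores nl x nd score matrix (e.g. \code{finalScores(sp)}).
#' @param dataset The [AssociationDataset-class] defining known pairs.
#' @param query A known disease or lncRNA identifier.
#' @param topK Number of rows to return; capped at the candidate count.
#' @return Data frame with columns \code{rank}, \code{candidate},
#'   \code{score}.
#' @export
rankPredictions <- function(scores, dataset, query, topK = 5L) {
  m <- assocMatrix(dataset)
  stopifnot(identical(dim(scores), dim(m)))
  if (query %in% colnames(m)) {          # disease query: rank lncRNAs
    known <- m[, query] == 1
    cand <- rownames(m)[!known]
    sc <- scores[!known, query]
  } else if (query %in% rownames(m)) {   # lncRNA query: rank diseases
    known <- m[query, ] == 1
    cand <- colnames(m)[!known]
    sc <- scores[query, !known]
  } else {
    near <- utils::head(c(rownames(m), colnames(m))[
      order(utils::adist(query, c(rownames(m), colnames(m))))], 3)
    stop(sprintf("unknown query '%s'; nearest identifiers: %s",
                 query, paste(near, collapse = ", ")))
  }
  ord <- order(-sc, cand)
  n <- min(as.integer(topK), length(cand))
  data.frame(rank = seq_len(n), candidate = cand[ord][seq_len(n)],
             score = unname(sc[ord][seq_len(n)]),
             stringsAsFactors = FALSE)
}

#' Write a ranked-prediction table
#'
#' @inheritParams rankPredictions
#' @param path Output TSV path.
#' @return Invisibly, the ranked data frame.
#' @export
writeRankedPredictions <- function(scores, dataset, query, topK, path) {
  tab <- rankPredictions(scores, dataset, query, topK)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Write a cross-validation metrics report as JSON
#'
#' Records the AUC/AUPR summary together with the parameters and seed so
#' a run can be reproduced exactly.
#'
#' @param cv A [CvResult-class].
#' @param params The [GrwParams-class] used.
#' @param path Output JSON path.
#' @param seed Seed used for any stochastic step (or \code{NULL}).
#' @return Invisibly, \code{path}.
#' @export
writeMetricsReport <- function(cv, params, path, seed = NULL) {
  rep <- list(
    mode = cv@mode,
    auc = cv@auc,
    aupr = cv@aupr,
    n_positives = nrow(cv@positives),
    n_negatives = nrow(cv@negatives),
    per_rep_auc = cv@perRepAuc,
    params = list(gamma = params@gamma, alpha = params@alpha,
                  beta = params@beta, eta = params@eta, tol = params@tol,
                  max_iter = params@maxIter,
                  laplacian_form = params@laplacianForm,
                  engine = params@engine),
    seed = seed)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
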