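#' SynthConfig: synthetic benchmark configuration
#'
#' Configuration of the synthetic benchmark generator.  The defaults
#' emulate the statistical shape of the curated benchmark: 78 lncRNAs,
#' 113 diseases and 210 associations in a sparse bipartite graph whose
#' diseases cluster into co-modules sharing deep MeSH ancestors.
#'
#' @slot nLncrna Number of lncRNAs.
#' @slot nDisease Number of diseases.
#' @slot nBlocks Number of planted lncRNA/disease co-modules.
#' @slot treeDepth Number of segments of the shared block ancestor
#'   chain; deeper chains give stronger within-block semantic
#'   similarity.
#' @slot assocPerBlock Associations planted inside each block.
#' @slot noiseAssoc Random off-block associations sprinkled uniformly.
#' @slot seed Integer seed; identical seeds give identical output.
#'
#' @export
setClass("SynthConfig",
         slots = c(nLncrna = "integer", nDisease = "integer",
                   nBlocks = "integer", treeDepth = "integer",
                   assocPerBlock = "integer", noiseAssoc = "integer",
                   seed = "integer"))

setValidity("SynthConfig", function(object) {
  msgs <- character()
  if (object@nBlocks > min(object@nLncrna, object@nDisease))
    msgs <- c(msgs, "nBlocks must not exceed min(nLncrna, nDisease)")
  if (object@treeDepth < 2)
    msgs <- c(msgs, "treeDepth must be at least 2")
  if (any(c(object@nLncrna, object@nDisease, object@nBlocks,
            object@assocPerBlock) < 1))
    msgs <- c(msgs, "sizes must be positive")
  if (object@noiseAssoc < 0)
    msgs <- c(msgs, "noiseAssoc must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SynthConfig
#'
#' @param nLncrna,nDisease,nBlocks,treeDepth,assocPerBlock,noiseAssoc,seed
#'   See [SynthConfig-class].  Defaults:
#'   \code{78 x 113}, 6 blocks, tree depth 4, 33 associations per block
#'   plus 12 noise associations (210 in total), seed 1.
#' @return A [SynthConfig-class].
#' @export
synthConfig <- function(nLncrna = 78L, nDisease = 113L, nBlocks = 6L,
                        treeDepth = 4L, assocPerBlock = 33L,
                        noiseAssoc = 12L, seed = 1L) {
  methods::new("SynthConfig", nLncrna = as.integer(nLncrna),
               nDisease = as.integer(nDisease),
               nBlocks = as.integer(nBlocks),
               treeDepth = as.integer(treeDepth),
               assocPerBlock = as.integer(assocPerBlock),
               noiseAssoc = as.integer(noiseAssoc),
               seed = as.integer(seed))
}

# deterministic substream: each generation phase reseeds from the
# config seed and a phase offset, so adding phases never shifts the
# earlier streams
.phaseSeed <- function(seed, phase) (seed * 131L + phase) %% 2147483647L

#' Generate a synthetic benchmark with planted block structure
#'
#' Builds a tree-number file, an association edge list, and the
#' ground-truth block labels.  Diseases of one block share a deep
#' common ancestor chain (high within-block semantic similarity);
#' lncRNAs of a block associate mostly with that block's diseases;
#' noise associations are sprinkled uniformly over the remaining
#' cells.  Every lncRNA and every disease receives at least one
#' association, so the edge list alone reproduces the configured
#' dimensions.
#'
#' @param config A [SynthConfig-class].
#' @param dir Optional output directory; when given, writes
#'   \code{associations.tsv}, \code{tree_numbers.tsv} and
#'   \code{block_labels.tsv} in the package's file formats.
#' @return List with \code{dataset} ([AssociationDataset-class]),
#'   \code{treeNumbers} (named list of tree codes), \code{blocks}
#'   (list of named integer vectors \code{lncrna}, \code{disease}) and
#'   \code{files} (paths, when \code{dir} was given).
#' @examples
#' bench <- generateSyntheticData(synthConfig(nLncrna = 10, nDisease = 12,
#'                                            nBlocks = 2, assocPerBlock = 8,
#'                                            noiseAssoc = 2, seed = 42))
#' bench$dataset
#' @export
generateSyntheticData <- function(config = synthConfig(), dir = NULL) {
  methods::validObject(config)
  nl <- config@nLncrna; nd <- config@nDisease; nb <- config@nBlocks
  lids <- sprintf("lnc%03d", seq_len(nl))
  dids <- sprintf("dis%03d", seq_len(nd))
  lBlock <- stats::setNames(rep_len(sort(rep_len(seq_len(nb), nl)), nl), lids)
  dBlock <- stats::setNames(rep_len(sort(rep_len(seq_len(nb), nd)), nd), dids)

  total <- nb * config@assocPerBlock + config@noiseAssoc
  if (total > nl * nd)
    stop("infeasible config: more requested associations than matrix cells")
  for (b in seq_len(nb)) {
    need <- max(sum(lBlock == b), sum(dBlock == b))
    if (config@assocPerBlock < need)
      stop("assocPerBlock too small to cover every entity of block ", b)
    if (config@assocPerBlock > sum(lBlock == b) * sum(dBlock == b))
      stop("assocPerBlock exceeds the cell count of block ", b)
  }

  # tree numbers: a shared ancestor chain per block plus a private leaf
  set.seed(.phaseSeed(config@seed, 1L))
  treeNumbers <- vector("list", nd); names(treeNumbers) <- dids
  for (b in seq_len(nb)) {
    chain <- c("C", sprintf("B%02d", b),
               sprintf("N%03d", sample.int(999, config@treeDepth - 2L,
                                           replace = TRUE)))
    prefix <- paste(chain[seq_len(config@treeDepth)], collapse = ".")
    members <- names(dBlock)[dBlock == b]
    leaves <- sample.int(999, length(members))
    for (k in seq_along(members))
      treeNumbers[[members[k]]] <- paste0(prefix, sprintf(".L%03d", leaves[k]))
  }

  # planted associations: cover every entity of the block, then fill
  set.seed(.phaseSeed(config@seed, 2L))
  AS <- matrix(0, nl, nd, dimnames = list(lids, dids))
  for (b in seq_len(nb)) {
    lb <- sample(which(lBlock == b)); db <- sample(which(dBlock == b))
    ncov <- max(length(lb), length(db))
    cover <- cbind(rep_len(lb, ncov), rep_len(db, ncov))
    AS[cover] <- 1
    sub <- AS[lb, db, drop = FALSE]
    extra <- sample(which(sub == 0), config@assocPerBlock - sum(sub))
    sub[extra] <- 1
    AS[lb, db] <- sub
  }
  set.seed(.phaseSeed(config@seed, 3L))
  zero <- which(AS == 0)
  AS[sample(zero, config@noiseAssoc)] <- 1

  dataset <- associationDataset(AS)
  out <- list(dataset = dataset, treeNumbers = treeNumbers,
              blocks = list(lncrna = lBlock, disease = dBlock))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- file.path(dir, "associations.tsv")
    ft <- file.path(dir, "tree_numbers.tsv")
    fb <- file.path(dir, "block_labels.tsv")
    writeAssociations(dataset, fa)
    writeTreeNumbers(treeNumbers, ft)
    labs <- rbind(data.frame(id = lids, kind = "lncrna",
                             block = unname(lBlock)),
                  data.frame(id = dids, kind = "disease",
                             block = unname(dBlock)))
    utils::write.table(labs, fb, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$files <- c(associations = fa, treeNumbers = ft, blocks = fb)
  }
  out
}

#' Permute association labels (null model)
#'
#' Reassigns the dataset's associations to uniformly random cells,
#' preserving the total association count but destroying any planted
#' block signal.  Used as the empirical null in the recovery tests.
#'
#' @param dataset An [AssociationDataset-class].
#' @param seed Integer seed; identical seeds give identical permutations.
#' @return A permuted [AssociationDataset-class] with the same
#'   identifiers.
#' @export
permuteAssociations <- function(dataset, seed) {
  AS <- assocMatrix(dataset)
  n <- sum(AS)
  set.seed(seed)
  ASp <- matrix(0, nrow(AS), ncol(AS), dimnames = dimnames(AS))
  ASp[sample(length(ASp), n)] <- 1
  associationDataset(ASp)
}
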