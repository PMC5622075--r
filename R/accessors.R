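#' @rdname accessor-generics
#' @export
setMethod("lncrnaIds", "AssociationDataset", function(x) rownames(x@assoc))

#' @rdname accessor-generics
#' @export
setMethod("diseaseIds", "AssociationDataset", function(x) colnames(x@assoc))

#' @rdname accessor-generics
#' @export
setMethod("assocMatrix", "AssociationDataset", function(x) x@assoc)

#' @rdname accessor-generics
#' @export
setMethod("simValues", "SimilarityMatrix", function(x) x@values)

#' @rdname accessor-generics
#' @export
setMethod("simIds", "SimilarityMatrix", function(x) rownames(x@values))

#' @rdname accessor-generics
#' @export
setMethod("simRole", "SimilarityMatrix", function(x) x@role)

#' @rdname accessor-generics
#' @export
setMethod("dagTerms", "DiseaseDAG", function(x) x@terms)

#' @rdname accessor-generics
#' @export
setMethod("dagEdges", "DiseaseDAG", function(x) x@edges)

#' @rdname accessor-generics
#' @export
setMethod("dagContributions", "DiseaseDAG", function(x) x@contributions)

#' @rdname accessor-generics
#' @export
setMethod("semanticValue", "DiseaseDAG", function(x) sum(x@contributions))

#' @rdname accessor-generics
#' @export
setMethod("finalScores", "ScorePair", function(x) x@FS)

#' @rdname accessor-generics
#' @export
setMethod("walkScores", "ScorePair", function(x, which = c("lncrna", "disease")) {
  which <- match.arg(which)
  if (which == "lncrna") x@S1 else x@S2
})

#' @rdname accessor-generics
#' @export
setMethod("cvAuc", "CvResult", function(x) x@auc)

#' @rdname accessor-generics
#' @export
setMethod("cvAupr", "CvResult", function(x) x@aupr)

#' @rdname accessor-generics
#' @export
setMethod("rocPoints", "CvResult", function(x) x@rocPoints)

#' @rdname accessor-generics
#' @export
setMethod("prPoints", "CvResult", function(x) x@prPoints)

#' @rdname accessor-generics
#' @export
setMethod("perRepAuc", "CvResult", function(x) x@perRepAuc)

#' @rdname accessor-generics
#' @export
setMethod("positiveScores", "CvResult", function(x) x@positives)

#' @rdname accessor-generics
#' @export
setMethod("negativeScores", "CvResult", function(x) x@negatives)

#' @rdname accessor-generics
#' @export
setMethod("dim", "AssociationDataset", function(x) dim(x@assoc))
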