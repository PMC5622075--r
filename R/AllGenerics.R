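#' Accessor generics
#'
#' Small family of accessor generics used across the package's S4 classes.
#'
#' @param x An object of one of the package's S4 classes.
#' @param ... Additional arguments passed to methods.
#' @return The slot contents (see the individual methods).
#' @name accessor-generics
NULL

#' @rdname accessor-generics
#' @export
setGeneric("lncrnaIds", function(x, ...) standardGeneric("lncrnaIds"))

#' @rdname accessor-generics
#' @export
setGeneric("diseaseIds", function(x, ...) standardGeneric("diseaseIds"))

#' @rdname accessor-generics
#' @export
setGeneric("assocMatrix", function(x, ...) standardGeneric("assocMatrix"))

#' @rdname accessor-generics
#' @export
setGeneric("simValues", function(x, ...) standardGeneric("simValues"))

#' @rdname accessor-generics
#' @export
setGeneric("simIds", function(x, ...) standardGeneric("simIds"))

#' @rdname accessor-generics
#' @export
setGeneric("simRole", function(x, ...) standardGeneric("simRole"))

#' @rdname accessor-generics
#' @export
setGeneric("dagTerms", function(x, ...) standardGeneric("dagTerms"))

#' @rdname accessor-generics
#' @export
setGeneric("dagEdges", function(x, ...) standardGeneric("dagEdges"))

#' @rdname accessor-generics
#' @export
setGeneric("dagContributions", function(x, ...) standardGeneric("dagContributions"))

#' @rdname accessor-generics
#' @export
setGeneric("semanticValue", function(x, ...) standardGeneric("semanticValue"))

#' @rdname accessor-generics
#' @export
setGeneric("finalScores", function(x, ...) standardGeneric("finalScores"))

#' @rdname accessor-generics
#' @export
setGeneric("walkScores", function(x, which = c("lncrna", "disease"), ...)
  standardGeneric("walkScores"))

#' @rdname accessor-generics
#' @export
setGeneric("cvAuc", function(x, ...) standardGeneric("cvAuc"))

#' @rdname accessor-generics
#' @export
setGeneric("cvAupr", function(x, ...) standardGeneric("cvAupr"))

#' @rdname accessor-generics
#' @export
setGeneric("rocPoints", function(x, ...) standardGeneric("rocPoints"))

#' @rdname accessor-generics
#' @export
setGeneric("prPoints", function(x, ...) standardGeneric("prPoints"))

#' @rdname accessor-generics
#' @export
setGeneric("perRepAuc", function(x, ...) standardGeneric("perRepAuc"))

#' @rdname accessor-generics
#' @export
setGeneric("positiveScores", function(x, ...) standardGeneric("positiveScores"))

#' @rdname accessor-generics
#' @export
setGeneric("negativeScores", function(x, ...) standardGeneric("negativeScores"))
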