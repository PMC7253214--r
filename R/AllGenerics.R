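#' @rdname ConsensusNetwork-class
#' @export
setGeneric("moduleLabels", function(object, ...) standardGeneric("moduleLabels"))

#' @rdname ConsensusNetwork-class
#' @export
setGeneric("moduleEigengenes", function(object, ...)
  standardGeneric("moduleEigengenes"))

#' @rdname ConsensusNetwork-class
#' @export
setGeneric("moduleKME", function(object, ...) standardGeneric("moduleKME"))

#' @rdname ConsensusNetwork-class
#' @export
setGeneric("consensusTOM", function(object, ...)
  standardGeneric("consensusTOM"))

#' @rdname ConsensusNetwork-class
#' @export
setGeneric("populationTOM", function(object, population, ...)
  standardGeneric("populationTOM"))

#' @rdname ConsensusNetwork-class
#' @export
setGeneric("networkProbes", function(object, ...)
  standardGeneric("networkProbes"))

#' @rdname ConsensusNetwork-class
#' @export
setGeneric("networkPopulations", function(object, ...)
  standardGeneric("networkPopulations"))

#' @rdname PreservationReport-class
#' @export
setGeneric("preservationSummary", function(object, ...)
  standardGeneric("preservationSummary"))

#' @rdname PreservationReport-class
#' @export
setGeneric("preservationObserved", function(object, ...)
  standardGeneric("preservationObserved"))

#' @rdname PreservationReport-class
#' @export
setGeneric("preservationZ", function(object, ...)
  standardGeneric("preservationZ"))

#' @rdname PreservationReport-class
#' @export
setGeneric("preservationPValues", function(object, ...)
  standardGeneric("preservationPValues"))

#' @rdname AnnotationBundle-class
#' @export
setGeneric("genePositions", function(object, ...)
  standardGeneric("genePositions"))

#' @rdname AnnotationBundle-class
#' @export
setGeneric("intervalSets", function(object, ...)
  standardGeneric("intervalSets"))

#' @rdname AnnotationBundle-class
#' @export
setGeneric("geneSets", function(object, category = NULL, ...)
  standardGeneric("geneSets"))
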