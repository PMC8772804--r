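#' @rdname AbundanceTable-accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname AbundanceTable-accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname AbundanceTable-accessors
#' @export
setGeneric("taxonIDs", function(x) standardGeneric("taxonIDs"))

#' @rdname AbundanceTable-accessors
#' @export
setGeneric("taxonomyMap", function(x) standardGeneric("taxonomyMap"))

#' @rdname AbundanceTable-accessors
#' @export
setGeneric("taxonRank", function(x) standardGeneric("taxonRank"))

#' @rdname AbundanceTable-accessors
#' @export
setGeneric("isRelative", function(x) standardGeneric("isRelative"))

#' @rdname AbundanceTable-accessors
#' @export
setGeneric("rarefiedDepth", function(x) standardGeneric("rarefiedDepth"))

#' @rdname relativeAbundance
#' @export
setGeneric("relativeAbundance", function(x) standardGeneric("relativeAbundance"))

#' @rdname DMMFit-accessors
#' @export
setGeneric("mixtureWeights", function(object) standardGeneric("mixtureWeights"))

#' @rdname DMMFit-accessors
#' @export
setGeneric("dirichletParams", function(object) standardGeneric("dirichletParams"))

#' @rdname DMMFit-accessors
#' @export
setGeneric("responsibilities", function(object) standardGeneric("responsibilities"))

#' @rdname DMMFit-accessors
#' @export
setGeneric("logEvidence", function(object) standardGeneric("logEvidence"))

#' @rdname DMMFit-accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))
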