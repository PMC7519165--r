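#' @include AllClasses.R
NULL

#' Accessors for MultiOmicCohort and GenomeAnnotation
#'
#' Slot access for the package's containers goes through these accessors.
#'
#' @param x a [MultiOmicCohort-class] or [GenomeAnnotation-class] object.
#' @param layer layer name, one of [omicLayerNames()].
#' @name accessors
#' @return The requested component: a matrix, `DataFrame`, `GRanges`,
#'   `data.frame` or list, depending on the accessor.
NULL

#' @rdname accessors
#' @export
setGeneric("omicLayer", function(x, layer) standardGeneric("omicLayer"))

#' @rdname accessors
#' @export
setMethod("omicLayer", "MultiOmicCohort", function(x, layer) {
    if (!layer %in% names(x@layers))
        stop("unknown layer: ", layer)
    x@layers[[layer]]
})

#' @rdname accessors
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @rdname accessors
#' @export
setMethod("layerNames", "MultiOmicCohort", function(x) names(x@layers))

#' @rdname accessors
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname accessors
#' @export
setMethod("sampleData", "MultiOmicCohort", function(x) x@sampleData)

#' @rdname accessors
#' @export
setGeneric("trueLabels", function(x) standardGeneric("trueLabels"))

#' @rdname accessors
#' @export
setMethod("trueLabels", "MultiOmicCohort", function(x) x@truth)

#' @rdname accessors
#' @export
setGeneric("annotation", function(x) standardGeneric("annotation"))

#' @rdname accessors
#' @export
setMethod("annotation", "MultiOmicCohort", function(x) x@annotation)

#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname accessors
#' @export
setMethod("genes", "GenomeAnnotation", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("probes", function(x) standardGeneric("probes"))

#' @rdname accessors
#' @export
setMethod("probes", "GenomeAnnotation", function(x) x@probes)

#' @rdname accessors
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname accessors
#' @export
setMethod("peaks", "GenomeAnnotation", function(x) x@peaks)

#' @rdname accessors
#' @export
setGeneric("eqtlPairs", function(x) standardGeneric("eqtlPairs"))

#' @rdname accessors
#' @export
setMethod("eqtlPairs", "GenomeAnnotation", function(x) x@eqtl)

#' @rdname accessors
#' @export
setGeneric("hicContacts", function(x) standardGeneric("hicContacts"))

#' @rdname accessors
#' @export
setMethod("hicContacts", "GenomeAnnotation", function(x) x@hic)

#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @rdname accessors
#' @export
setMethod("moduleLabels", "ModuleSet", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("moduleEigengenes", function(x) standardGeneric("moduleEigengenes"))

#' @rdname accessors
#' @export
setMethod("moduleEigengenes", "ModuleSet", function(x) x@eigengenes)

#' @rdname accessors
#' @export
setGeneric("moduleKME", function(x) standardGeneric("moduleKME"))

#' @rdname accessors
#' @export
setMethod("moduleKME", "ModuleSet", function(x) x@kME)
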