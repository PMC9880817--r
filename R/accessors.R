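#' @importFrom BiocGenerics counts
NULL

#' Accessors for CoFracPPI objects
#'
#' Small accessor family: \code{counts} returns the spectral-count matrix of
#' a \linkS4class{ProfileMatrix}; \code{experimentId} and \code{technique}
#' its labels; \code{fractionLabels} its ordered fraction names;
#' \code{proteins} the protein ids of a container; \code{complexes} the
#' member lists of a \linkS4class{GroundTruth},
#' \linkS4class{ReferenceComplexSet} or \linkS4class{PredictedComplexSet};
#' \code{edges} and \code{nodes} the components of a
#' \linkS4class{WeightedPPINetwork}.
#'
#' @param object,x a CoFracPPI object.
#' @param ... ignored.
#' @return The extracted component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("counts", "ProfileMatrix", function(object, ...)
    SummarizedExperiment::assay(object, "counts"))

#' @rdname accessors
#' @export
setGeneric("experimentId", function(x) standardGeneric("experimentId"))

#' @rdname accessors
#' @export
setMethod("experimentId", "ProfileMatrix", function(x) x@experimentId)

#' @rdname accessors
#' @export
setGeneric("technique", function(x) standardGeneric("technique"))

#' @rdname accessors
#' @export
setMethod("technique", "ProfileMatrix", function(x) x@technique)

#' @rdname accessors
#' @export
setGeneric("fractionLabels", function(x) standardGeneric("fractionLabels"))

#' @rdname accessors
#' @export
setMethod("fractionLabels", "ProfileMatrix", function(x) colnames(x))

#' @rdname accessors
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @rdname accessors
#' @export
setMethod("proteins", "ProfileMatrix", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("proteins", "GroundTruth", function(x) x@proteinTable$id)

#' @rdname accessors
#' @export
setGeneric("complexes", function(x) standardGeneric("complexes"))

#' @rdname accessors
#' @export
setMethod("complexes", "GroundTruth", function(x) x@complexes)

#' @rdname accessors
#' @export
setMethod("complexes", "ReferenceComplexSet", function(x) x@complexes)

#' @rdname accessors
#' @export
setMethod("complexes", "PredictedComplexSet", function(x) x@members)

#' @rdname accessors
#' @export
setGeneric("monomerMasses", function(x) standardGeneric("monomerMasses"))

#' @rdname accessors
#' @export
setMethod("monomerMasses", "GroundTruth", function(x) {
    stats::setNames(x@proteinTable$massKda, x@proteinTable$id)
})

#' @rdname accessors
#' @export
setGeneric("degradedProteins", function(x)
    standardGeneric("degradedProteins"))

#' @rdname accessors
#' @export
setMethod("degradedProteins", "GroundTruth", function(x)
    x@proteinTable$id[x@proteinTable$degraded])

#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname accessors
#' @export
setMethod("edges", "WeightedPPINetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname accessors
#' @export
setMethod("nodes", "WeightedPPINetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setGeneric("complexStats", function(x) standardGeneric("complexStats"))

#' @rdname accessors
#' @export
setMethod("complexStats", "PredictedComplexSet", function(x) x@stats)

#' @rdname accessors
#' @export
setMethod("length", "PredictedComplexSet", function(x) length(x@members))

#' @rdname accessors
#' @export
setMethod("length", "ReferenceComplexSet", function(x) length(x@complexes))

#' True within-complex protein pairs of a ground truth
#'
#' Every unordered pair of proteins sharing a planted complex, in canonical
#' (lexicographic) order. These are the positive labels the synthetic study
#' is scored against.
#'
#' @param x a \linkS4class{GroundTruth}.
#' @return data.frame with columns \code{idA}, \code{idB}.
#' @export
setGeneric("truePairs", function(x) standardGeneric("truePairs"))

#' @rdname truePairs
#' @export
setMethod("truePairs", "GroundTruth", function(x) {
    pairs <- lapply(x@complexes, .allPairs)
    out <- unique(do.call(rbind, pairs))
    if (is.null(out)) out <- data.frame(idA = character(), idB = character())
    rownames(out) <- NULL
    out[order(out$idA, out$idB), , drop = FALSE]
})

setMethod("show", "ProfileMatrix", function(object) {
    cat(sprintf("ProfileMatrix '%s' (%s): %d proteins x %d fractions\n",
                object@experimentId, object@technique,
                nrow(object), ncol(object)))
})

setMethod("show", "CalibrationModel", function(object) {
    cat(sprintf(
        "CalibrationModel: log10(kDa) = %.4f * fraction + %.4f (R2 = %.3f, n = %d)\n",
        object@slope, object@intercept, object@rSquared, object@nStandards))
})

setMethod("show", "GroundTruth", function(object) {
    pt <- object@proteinTable
    cat(sprintf(
        "GroundTruth: %d proteins (%d complexed in %d complexes, %d monomers, %d degraded)\n",
        nrow(pt), sum(!is.na(pt$complex)), length(object@complexes),
        sum(is.na(pt$complex)), sum(pt$degraded)))
})

setMethod("show", "ReferenceComplexSet", function(object) {
    cat(sprintf("ReferenceComplexSet: %d complexes, %d distinct members\n",
                length(object@complexes),
                length(unique(unlist(object@complexes)))))
})

setMethod("show", "TrainedPPIModel", function(object) {
    cat(sprintf(
        "TrainedPPIModel: random forest on [%s]; %d positives / %d negatives (seed %d)\n",
        paste(object@featureNames, collapse = ", "),
        object@nPositive, object@nNegative, object@seed))
})

setMethod("show", "WeightedPPINetwork", function(object) {
    cat(sprintf("WeightedPPINetwork: %d nodes, %d edges\n",
                length(object@nodes), nrow(object@edges)))
})

setMethod("show", "PredictedComplexSet", function(object) {
    cat(sprintf("PredictedComplexSet: %d complexes (sizes %s)\n",
                length(object@members),
                if (length(object@members))
                    paste(range(lengths(object@members)), collapse = "-")
                else "NA"))
})
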