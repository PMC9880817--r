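#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' ProfileMatrix: one co-fractionation separation experiment
#'
#' A protein x fraction spectral-count matrix for a single separation
#' experiment (SEC, IEX or SDGC), stored as a
#' \linkS4class{SummarizedExperiment} with a single \code{"counts"} assay.
#' Rows are proteins, columns are ordered fractions; fraction order is the
#' elution order and is never permuted.
#'
#' @slot experimentId single character label, e.g. \code{"SEC24"}.
#' @slot technique one of \code{"SEC"}, \code{"IEX"}, \code{"SDGC"}.
#' @export
setClass("ProfileMatrix",
    contains = "SummarizedExperiment",
    slots = c(experimentId = "character", technique = "character"))

.validProfileMatrix <- function(object) {
    msg <- NULL
    cts <- SummarizedExperiment::assay(object, "counts")
    if (length(object@experimentId) != 1L)
        msg <- c(msg, "'experimentId' must be a single string")
    if (length(object@technique) != 1L ||
        !object@technique %in% c("SEC", "IEX", "SDGC"))
        msg <- c(msg, "'technique' must be one of SEC, IEX, SDGC")
    if (nrow(cts) > 0L &&
        (is.null(rownames(cts)) || anyDuplicated(rownames(cts))))
        msg <- c(msg, "duplicate or missing protein ids")
    if (is.null(colnames(cts)))
        msg <- c(msg, "missing fraction labels")
    if (any(!is.finite(cts)) || any(cts < 0))
        msg <- c(msg, "counts must be finite and non-negative")
    if (any(cts != round(cts)))
        msg <- c(msg, "counts must be integers (spectral counts)")
    if (is.null(msg)) TRUE else msg
}
setValidity("ProfileMatrix", .validProfileMatrix)

#' Construct a ProfileMatrix
#'
#' @param counts non-negative integer matrix, proteins in rows (rownames
#'   required), fractions in columns.
#' @param experimentId label for the separation experiment.
#' @param technique separation technique: \code{"SEC"}, \code{"IEX"} or
#'   \code{"SDGC"}.
#' @param fractionLabels optional column labels; defaults to
#'   \code{<experimentId>_F<index>}.
#' @return A \linkS4class{ProfileMatrix}.
#' @examples
#' m <- matrix(rpois(12, 3), 3, 4, dimnames = list(paste0("P", 1:3), NULL))
#' ProfileMatrix(m, "SEC24", "SEC")
#' @export
ProfileMatrix <- function(counts, experimentId, technique,
                          fractionLabels = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    if (is.null(fractionLabels))
        fractionLabels <- paste0(experimentId, "_F", seq_len(ncol(counts)))
    colnames(counts) <- fractionLabels
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(counts = counts))
    new("ProfileMatrix", se, experimentId = as.character(experimentId),
        technique = as.character(technique))
}

#' CalibrationModel: SEC fraction-to-mass calibration
#'
#' Log-linear mapping \eqn{\log_{10}(mass_{kDa}) = a \cdot fraction + b}
#' fitted by ordinary least squares on protein standards of known molecular
#' mass. Inverts to a peak-fraction prediction used by the simulator.
#'
#' @slot slope fitted slope \eqn{a} (negative: large species elute early).
#' @slot intercept fitted intercept \eqn{b}.
#' @slot rSquared coefficient of determination of the fit.
#' @slot nStandards number of standards used.
#' @export
setClass("CalibrationModel",
    slots = c(slope = "numeric", intercept = "numeric",
              rSquared = "numeric", nStandards = "integer"))

setValidity("CalibrationModel", function(object) {
    if (length(object@slope) != 1L || object@slope == 0)
        return("slope must be a single non-zero number")
    if (object@nStandards < 2L)
        return("calibration requires >= 2 standards")
    TRUE
})

#' GroundTruth: planted composition of a synthetic fractionation study
#'
#' The simulated proteome: monomer masses, planted complexes (with assembly
#' mass equal to the sum of member monomer masses, i.e. stoichiometry 1),
#' free monomers, and a degraded subpopulation that elutes well below its
#' monomer mass and never co-elutes with its complex.
#'
#' @slot proteinTable data.frame with one row per protein: \code{id},
#'   \code{massKda}, \code{complex} (complex name or \code{NA}),
#'   \code{degraded} (logical), \code{abundance} (expected total spectral
#'   counts per experiment).
#' @slot complexes named list of member-id character vectors.
#' @slot complexMass named numeric, assembly mass per complex (kDa).
#' @slot complexAbundance named numeric, abundance scalar per complex.
#' @export
setClass("GroundTruth",
    slots = c(proteinTable = "data.frame", complexes = "list",
              complexMass = "numeric", complexAbundance = "numeric"))

setValidity("GroundTruth", function(object) {
    pt <- object@proteinTable
    msg <- NULL
    if (anyDuplicated(pt$id))
        msg <- c(msg, "duplicate protein ids")
    sizes <- lengths(object@complexes)
    if (any(sizes < 2L))
        msg <- c(msg, "complex sizes must be >= 2")
    for (nm in names(object@complexes)) {
        mem <- object@complexes[[nm]]
        mmax <- max(pt$massKda[match(mem, pt$id)])
        if (object@complexMass[[nm]] < mmax)
            msg <- c(msg, sprintf(
                "complex %s assembly mass below its largest member", nm))
    }
    if (is.null(msg)) TRUE else msg
})

#' ReferenceComplexSet: gold-standard complex membership
#'
#' Named reference ("gold standard") complexes used to derive positive
#' (within-complex) and negative (cross-complex) training pairs for the
#' co-complex classifier.
#'
#' @slot complexes named list of member-id character vectors.
#' @export
setClass("ReferenceComplexSet", slots = c(complexes = "list"))

setValidity("ReferenceComplexSet", function(object) {
    cx <- object@complexes
    if (length(cx) && (is.null(names(cx)) || anyDuplicated(names(cx))))
        return("complex names must be unique and non-empty")
    if (any(lengths(cx) < 2L))
        return("every complex needs >= 2 members")
    TRUE
})

#' TrainedPPIModel: fitted co-complex classifier
#'
#' A bagged ensemble of randomised decision trees (random forest) over the
#' five aggregated co-elution features, with the training metadata needed to
#' score new pairs reproducibly.
#'
#' @slot fit the underlying \code{randomForest} fit.
#' @slot featureNames ordered feature columns the model was trained on.
#' @slot nPositive,nNegative training label counts.
#' @slot seed RNG seed used for training.
#' @export
setClass("TrainedPPIModel",
    slots = c(fit = "ANY", featureNames = "character",
              nPositive = "integer", nNegative = "integer", seed = "integer"))

#' WeightedPPINetwork: classifier-scored interaction network
#'
#' Undirected network whose edges are protein pairs retained at the
#' classifier probability threshold, weighted by that probability.
#'
#' @slot nodes sorted protein ids.
#' @slot edges data.frame \code{idA}, \code{idB}, \code{weight} with
#'   \code{idA < idB}; weights in (0, 1].
#' @slot adjacency dense symmetric weighted adjacency matrix.
#' @export
setClass("WeightedPPINetwork",
    slots = c(nodes = "character", edges = "data.frame",
              adjacency = "matrix"))

setValidity("WeightedPPINetwork", function(object) {
    e <- object@edges
    msg <- NULL
    if (nrow(e)) {
        if (any(e$idA == e$idB)) msg <- c(msg, "self-loops are not allowed")
        if (any(e$weight <= 0)) msg <- c(msg, "edge weights must be positive")
    }
    if (!identical(dim(object@adjacency),
                   rep(length(object@nodes), 2L)))
        msg <- c(msg, "adjacency dimensions disagree with node count")
    if (is.null(msg)) TRUE else msg
})

#' PredictedComplexSet: cohesiveness-derived complexes
#'
#' Output of \code{\link{detectComplexes}}: candidate complexes grown from
#' seeds by greedy cohesiveness optimisation, merged at high overlap, and
#' filtered by size and density.
#'
#' @slot members list of member-id character vectors, one per complex.
#' @slot stats data.frame with per-complex \code{cohesiveness},
#'   \code{density}, \code{size} and \code{seedNode}, aligned with
#'   \code{members} and sorted by decreasing cohesiveness.
#' @export
setClass("PredictedComplexSet",
    slots = c(members = "list", stats = "data.frame"))

setValidity("PredictedComplexSet", function(object) {
    if (length(object@members) != nrow(object@stats))
        return("'members' and 'stats' lengths disagree")
    TRUE
})
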