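#' Construct a reference (gold standard) complex set
#'
#' @param complexes named list of member-id character vectors; names must
#'   be unique and every complex must keep >= 2 members.
#' @param universe optional protein universe to intersect members with;
#'   complexes shrinking below 2 members are dropped with a warning.
#' @return A \linkS4class{ReferenceComplexSet}.
#' @export
referenceComplexSet <- function(complexes, universe = NULL) {
    if (length(complexes) && is.null(names(complexes)))
        names(complexes) <- sprintf("complex%03d", seq_along(complexes))
    if (anyDuplicated(names(complexes)))
        .stopf("duplicate complex name '%s'",
               names(complexes)[duplicated(names(complexes))][1L])
    complexes <- lapply(complexes, function(m) unique(as.character(m)))
    if (!is.null(universe)) {
        complexes <- lapply(complexes, intersect, y = universe)
        small <- lengths(complexes) < 2L
        if (any(small)) {
            .warnf("dropping %d reference complex(es) with < 2 members in the universe: %s",
                   sum(small), paste(names(complexes)[small], collapse = ", "))
            complexes <- complexes[!small]
        }
    }
    if (any(lengths(complexes) < 2L))
        .stopf("every reference complex needs >= 2 members")
    new("ReferenceComplexSet", complexes = complexes)
}

#' Read a reference complex file
#'
#' One complex per line, tab-separated: complex name, then member ids.
#'
#' @param path file path.
#' @param universe optional protein universe (see
#'   \code{\link{referenceComplexSet}}).
#' @return A \linkS4class{ReferenceComplexSet}.
#' @export
readComplexFile <- function(path, universe = NULL) {
    if (!file.exists(path)) .stopf("no such file: %s", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nm <- vapply(parts, `[`, character(1), 1L)
    if (anyDuplicated(nm))
        .stopf("duplicate complex name '%s' in %s",
               nm[duplicated(nm)][1L], path)
    complexes <- lapply(parts, function(p) p[-1L])
    names(complexes) <- nm
    referenceComplexSet(complexes, universe = universe)
}

#' Write a complex set in the one-line-per-complex format
#'
#' @param x a \linkS4class{ReferenceComplexSet} or
#'   \linkS4class{PredictedComplexSet}.
#' @param path file path.
#' @return The path, invisibly.
#' @export
writeComplexFile <- function(x, path) {
    cpx <- complexes(x)
    if (is.null(names(cpx)))
        names(cpx) <- sprintf("complex%03d", seq_along(cpx))
    lines <- vapply(names(cpx), function(nm)
        paste(c(nm, cpx[[nm]]), collapse = "\t"), character(1))
    writeLines(unname(lines), path)
    invisible(path)
}

#' Derive labelled training pairs from a reference complex set
#'
#' A candidate pair is positive when its two members co-occur in at least
#' one reference complex; negative when both members are annotated to
#' reference complexes but never to a common one; unlabelled otherwise.
#' Because cross-complex pairs vastly outnumber positives, negatives are
#' subsampled to \code{negativeRatio} times the positive count (seeded).
#'
#' @param refset a \linkS4class{ReferenceComplexSet}.
#' @param candidatePairs data.frame with columns \code{idA}, \code{idB}
#'   (canonically ordered), e.g. a feature table.
#' @param negativeRatio maximum negatives per positive (\code{Inf} keeps
#'   all).
#' @param seed RNG seed for the subsampling.
#' @return list with data.frames \code{positives}, \code{negatives},
#'   \code{unlabeled} (each \code{idA}, \code{idB}).
#' @export
deriveLabels <- function(refset, candidatePairs, negativeRatio = 5,
                         seed = 1L) {
    cpx <- complexes(refset)
    if (!length(cpx)) .stopf("empty reference set")
    membership <- list()
    for (nm in names(cpx))
        for (id in cpx[[nm]])
            membership[[id]] <- c(membership[[id]], nm)
    annA <- candidatePairs$idA %in% names(membership)
    annB <- candidatePairs$idB %in% names(membership)
    shared <- if (nrow(candidatePairs)) mapply(function(a, b) {
        length(intersect(membership[[a]], membership[[b]])) > 0L
    }, candidatePairs$idA, candidatePairs$idB, USE.NAMES = FALSE)
    else logical()
    shared <- shared & annA & annB
    isPos <- shared
    isNeg <- annA & annB & !shared
    pos <- candidatePairs[isPos, c("idA", "idB"), drop = FALSE]
    neg <- candidatePairs[isNeg, c("idA", "idB"), drop = FALSE]
    unl <- candidatePairs[!isPos & !isNeg, c("idA", "idB"), drop = FALSE]
    if (is.finite(negativeRatio) && nrow(neg) > negativeRatio * nrow(pos)) {
        keep <- withr::with_seed(seed,
            sample(nrow(neg), round(negativeRatio * nrow(pos))))
        neg <- neg[sort(keep), , drop = FALSE]
    }
    rownames(pos) <- rownames(neg) <- rownames(unl) <- NULL
    list(positives = pos, negatives = neg, unlabeled = unl)
}

#' Assign reference complexes to cross-validation folds
#'
#' Whole complexes are assigned to folds so that no reference complex
#' contributes labelled pairs to both the training and the test side of any
#' split. Deterministic under the seed.
#'
#' @param refset a \linkS4class{ReferenceComplexSet}.
#' @param k number of folds (<= number of complexes).
#' @param seed RNG seed.
#' @return Named integer vector: complex name -> fold index in 1..k.
#' @export
complexLevelFolds <- function(refset, k = 5L, seed = 1L) {
    cpx <- complexes(refset)
    if (k > length(cpx))
        .stopf("k = %d exceeds the number of complexes (%d)",
               k, length(cpx))
    withr::with_seed(seed, {
        ord <- sample(length(cpx))
        folds <- rep_len(seq_len(k), length(cpx))
        stats::setNames(folds[order(ord)], names(cpx))
    })
}

#' Assign labelled pairs to folds of a complex-level split
#'
#' A positive pair inherits the fold of a complex containing both members
#' (the lowest fold index when overlapping complexes disagree). A negative
#' pair gets a fold only when every complex containing either member lies
#' in one common fold; negatives straddling folds get \code{NA} and are
#' excluded from cross-validation, which keeps the split leak-free at the
#' complex level.
#'
#' @param labels output of \code{\link{deriveLabels}}.
#' @param refset the \linkS4class{ReferenceComplexSet} the labels came
#'   from.
#' @param folds output of \code{\link{complexLevelFolds}}.
#' @return data.frame \code{idA}, \code{idB}, \code{label}
#'   (\code{"positive"}/\code{"negative"}), \code{fold} (integer or
#'   \code{NA}).
#' @export
assignPairFolds <- function(labels, refset, folds) {
    cpx <- complexes(refset)
    membership <- list()
    for (nm in names(cpx))
        for (id in cpx[[nm]])
            membership[[id]] <- c(membership[[id]], nm)
    posFold <- if (nrow(labels$positives)) mapply(function(a, b) {
        common <- intersect(membership[[a]], membership[[b]])
        min(folds[common])
    }, labels$positives$idA, labels$positives$idB, USE.NAMES = FALSE)
    else integer()
    negFold <- if (nrow(labels$negatives)) mapply(function(a, b) {
        f <- unique(folds[c(membership[[a]], membership[[b]])])
        if (length(f) == 1L) f else NA_integer_
    }, labels$negatives$idA, labels$negatives$idB, USE.NAMES = FALSE)
    else integer()
    rbind(
        data.frame(labels$positives, label = "positive",
                   fold = as.integer(posFold), stringsAsFactors = FALSE),
        data.frame(labels$negatives, label = "negative",
                   fold = as.integer(negFold), stringsAsFactors = FALSE))
}
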