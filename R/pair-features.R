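# Five co-elution features scored per protein pair per experiment:
# Pearson, Jaccard, Apex, mutual information, Bayes correlation.

#' Pearson correlation feature
#'
#' Product-moment correlation of two elution profiles over the fractions of
#' one experiment.
#'
#' @param x,y normalised elution profiles of equal length.
#' @return r in [-1, 1], or \code{NA} when either profile has zero variance
#'   (the pair is skipped for that experiment rather than assigned 0).
#' @export
pearsonFeature <- function(x, y) {
    stopifnot(length(x) == length(y))
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
}

#' Jaccard detection-overlap feature
#'
#' Binarises the raw count vectors at count > 0 and returns the Jaccard
#' index of the two detection sets; 0 when both sets are empty.
#'
#' @param x,y raw count vectors of equal length.
#' @return j in [0, 1].
#' @export
jaccardFeature <- function(x, y) {
    stopifnot(length(x) == length(y))
    a <- x > 0; b <- y > 0
    u <- sum(a | b)
    if (u == 0L) return(0)
    sum(a & b) / u
}

#' Apex co-peak feature
#'
#' 1 when the two profiles peak in the same fraction, else 0. Argmax ties
#' resolve to the earliest fraction before comparison.
#'
#' @param x,y normalised elution profiles of equal length.
#' @return 0/1, or \code{NA} when either profile is all zero in this
#'   experiment.
#' @export
apexFeature <- function(x, y) {
    stopifnot(length(x) == length(y))
    if (all(x == 0) || all(y == 0)) return(NA_real_)
    as.numeric(which.max(x) == which.max(y))
}

# Equal-width discretisation of a profile into nBins bins over [0, max(x)]:
# bin i covers [(i-1)w, iw) with the last bin closed; an all-zero profile
# maps to bin 1 throughout.
.binProfile <- function(x, nBins) {
    mx <- max(x)
    if (mx == 0) return(rep(1L, length(x)))
    pmin(nBins, floor(x / mx * nBins) + 1L)
}

#' Mutual information feature
#'
#' Discretises each profile into \code{nBins} equal-width bins over
#' [0, max] and returns the mutual information of the joint bin
#' distribution in bits, with the convention \eqn{0 \log 0 = 0}.
#'
#' @param x,y normalised elution profiles of equal length (>= \code{nBins}).
#' @param nBins number of equal-width bins.
#' @return MI >= 0, in bits.
#' @export
mutualInformationFeature <- function(x, y, nBins = 5L) {
    stopifnot(length(x) == length(y), length(x) >= nBins)
    bx <- .binProfile(x, nBins)
    by <- .binProfile(y, nBins)
    n <- length(x)
    joint <- tabulate((bx - 1L) * nBins + by, nbins = nBins * nBins) / n
    px <- tabulate(bx, nbins = nBins) / n
    py <- tabulate(by, nbins = nBins) / n
    mi <- 0
    for (i in seq_len(nBins)) for (j in seq_len(nBins)) {
        pij <- joint[(i - 1L) * nBins + j]
        if (pij > 0) mi <- mi + pij * log2(pij / (px[i] * py[j]))
    }
    max(mi, 0)
}

#' Bayes correlation feature
#'
#' Additive (Dirichlet-style) smoothing of the raw counts with pseudocount
#' \code{alpha}, conversion of each vector to proportions of its total, and
#' Pearson correlation of the two proportion vectors. The shrinkage damps
#' spurious similarity between sparse low-count profiles.
#'
#' @param x,y raw count vectors of equal length.
#' @param alpha positive pseudocount.
#' @return r in [-1, 1], or \code{NA} when a smoothed proportion vector is
#'   constant (e.g. both inputs all zero).
#' @export
bayesCorrelationFeature <- function(x, y, alpha = 1) {
    stopifnot(length(x) == length(y), alpha > 0)
    px <- (x + alpha) / sum(x + alpha)
    py <- (y + alpha) / sum(y + alpha)
    pearsonFeature(px, py)
}

# Standardise matrix rows so that cor(row_i, row_j) =
# sum(Z[i,] * Z[j,]) / (ncol - 1); zero-variance rows become NA.
.standardizeRows <- function(m) {
    mu <- rowMeans(m)
    ctr <- m - mu
    s <- sqrt(rowSums(ctr^2) / (ncol(m) - 1L))
    z <- ctr / s
    z[s == 0, ] <- NA_real_
    z
}

#' Build the candidate-pair feature table
#'
#' Scores all unordered pairs of retained proteins, per experiment, with
#' the five co-elution features, applies the elution-similarity pre-filter
#' (pairs are kept only when their best cross-experiment Pearson r is
#' strictly greater than \code{prefilter}), and aggregates each feature
#' across the experiments in which the pair is co-detected.
#'
#' Aggregation is by the mean over shared experiments by default: a true
#' co-complex pair co-elutes in every technique, while a chance co-elution
#' (e.g. two complexes of similar mass on a mass-ordered column) scores
#' highly in some techniques only, so averaging preserves the
#' complementarity between separations. \code{aggregate = "max"} (evidence
#' from the single best technique) is also available. The pre-filter always
#' uses the maximum Pearson so that strong evidence in any one technique
#' nominates a pair.
#'
#' @param matrices named list of \linkS4class{ProfileMatrix} objects.
#' @param retainedProteins ids surviving \code{\link{filterMinPsm}} (and,
#'   in the full pipeline, Rapp-based degradation removal).
#' @param prefilter strict lower bound on the best cross-experiment Pearson
#'   r ("similarity more than 0.5").
#' @param nBins mutual-information bin count.
#' @param alpha Bayes-correlation pseudocount.
#' @param window smoothing window for \code{\link{normalizeAndSmooth}}.
#' @param aggregate cross-experiment aggregation rule for the feature
#'   columns.
#' @return data.frame sorted by pair id with columns \code{idA},
#'   \code{idB}, \code{pearson}, \code{jaccard}, \code{apex}, \code{mi},
#'   \code{bayes}, \code{nExperiments} and \code{pearsonMax} (the
#'   pre-filter statistic).
#' @export
buildFeatureTable <- function(matrices, retainedProteins, prefilter = 0.5,
                              nBins = 5L, alpha = 1, window = 3L,
                              aggregate = c("mean", "max")) {
    aggregate <- match.arg(aggregate)
    if (!length(retainedProteins)) .stopf("no retained proteins")
    universe <- sort(unique(as.character(retainedProteins)))
    nU <- length(universe)
    perExp <- list()
    for (m in matrices) {
        ids <- intersect(universe, proteins(m))
        if (length(ids) < 2L) next
        C <- counts(m)[ids, , drop = FALSE]
        detected <- rowSums(C) > 0
        C <- C[detected, , drop = FALSE]
        if (nrow(C) < 2L) next
        N <- normalizeAndSmooth(C, window = window)
        Z <- .standardizeRows(N)
        P <- tcrossprod(Z) / (ncol(N) - 1L)
        perExp[[experimentId(m)]] <- list(ids = rownames(C), C = C, N = N,
                                          P = P)
    }
    if (!length(perExp)) .stopf("no experiment with >= 2 retained proteins")

    maxP <- matrix(NA_real_, nU, nU, dimnames = list(universe, universe))
    for (e in perExp) {
        idx <- match(e$ids, universe)
        cur <- maxP[idx, idx]
        maxP[idx, idx] <- pmax(cur, e$P, na.rm = TRUE)
    }
    ut <- which(upper.tri(maxP) & !is.na(maxP) & maxP > prefilter,
                arr.ind = TRUE)
    if (!nrow(ut))
        return(data.frame(idA = character(), idB = character(),
                          pearson = numeric(), jaccard = numeric(),
                          apex = numeric(), mi = numeric(),
                          bayes = numeric(), nExperiments = integer(),
                          pearsonMax = numeric(), stringsAsFactors = FALSE))
    idA <- universe[ut[, 1L]]
    idB <- universe[ut[, 2L]]
    nP <- length(idA)

    feat <- array(NA_real_, dim = c(nP, 5L, length(perExp)),
                  dimnames = list(NULL,
                                  c("pearson", "jaccard", "apex", "mi",
                                    "bayes"), names(perExp)))
    for (k in seq_along(perExp)) {
        e <- perExp[[k]]
        ia <- match(idA, e$ids)
        ib <- match(idB, e$ids)
        ok <- which(!is.na(ia) & !is.na(ib))
        if (!length(ok)) next
        ia <- ia[ok]; ib <- ib[ok]
        feat[ok, "pearson", k] <- e$P[cbind(ia, ib)]
        B <- e$C > 0
        inter <- rowSums(B[ia, , drop = FALSE] & B[ib, , drop = FALSE])
        uni <- rowSums(B[ia, , drop = FALSE] | B[ib, , drop = FALSE])
        feat[ok, "jaccard", k] <- ifelse(uni == 0, 0, inter / uni)
        ax <- max.col(e$N, ties.method = "first")
        feat[ok, "apex", k] <- as.numeric(ax[ia] == ax[ib])
        bins <- t(apply(e$N, 1L, .binProfile, nBins = nBins))
        feat[ok, "mi", k] <- vapply(seq_along(ia), function(q)
            .miFromBins(bins[ia[q], ], bins[ib[q], ], nBins), numeric(1))
        Q <- (e$C + alpha) / rowSums(e$C + alpha)
        Zq <- .standardizeRows(Q)
        feat[ok, "bayes", k] <- rowSums(Zq[ia, , drop = FALSE] *
                                        Zq[ib, , drop = FALSE]) /
            (ncol(Q) - 1L)
    }
    aggFun <- if (aggregate == "mean") {
        function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    } else {
        function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    }
    agg <- apply(feat, c(1L, 2L), aggFun)
    nExp <- apply(!is.na(feat[, "pearson", , drop = FALSE]), 1L, sum)
    out <- data.frame(idA = idA, idB = idB,
                      pearson = agg[, "pearson"], jaccard = agg[, "jaccard"],
                      apex = agg[, "apex"], mi = agg[, "mi"],
                      bayes = agg[, "bayes"], nExperiments = as.integer(nExp),
                      pearsonMax = maxP[ut], stringsAsFactors = FALSE)
    out <- out[order(out$idA, out$idB), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# MI in bits from two pre-binned vectors.
.miFromBins <- function(bx, by, nBins) {
    n <- length(bx)
    joint <- tabulate((bx - 1L) * nBins + by, nbins = nBins * nBins) / n
    px <- tabulate(bx, nbins = nBins) / n
    py <- tabulate(by, nbins = nBins) / n
    pxy <- outer(px, py)
    pos <- joint > 0
    max(sum(joint[pos] * log2(joint[pos] / t(pxy)[pos])), 0)
}

#' Write / read a feature table as TSV
#'
#' @param featureTable as returned by \code{\link{buildFeatureTable}}.
#' @param path TSV path.
#' @return \code{writeFeatureTable} the path, invisibly;
#'   \code{readFeatureTable} the table.
#' @export
writeFeatureTable <- function(featureTable, path) {
    .writeTsv(featureTable, path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
    df <- .readTsv(path)
    df$idA <- as.character(df$idA); df$idB <- as.character(df$idB)
    df
}
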