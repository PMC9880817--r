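#' Read a fraction table into a ProfileMatrix
#'
#' Fraction tables are tab-delimited text: first column the protein id,
#' remaining columns the ordered fractions, named
#' \code{<experiment>_F<index>} (1-based). Fraction order is taken from the
#' file and preserved.
#'
#' @param path path to the TSV file.
#' @param experimentId experiment label; defaults to the prefix of the first
#'   fraction column name.
#' @param technique separation technique; defaults to the leading letters of
#'   the experiment label (so \code{SEC24} implies SEC).
#' @return A \linkS4class{ProfileMatrix}.
#' @seealso \code{\link{writeFixture}} for the writer side.
#' @export
readFractionTable <- function(path, experimentId = NULL, technique = NULL) {
    if (!file.exists(path)) .stopf("no such file: %s", path)
    df <- .readTsv(path)
    if (ncol(df) < 2L) .stopf("malformed header in %s: need id + fractions", path)
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        .stopf("duplicate protein id '%s' in %s",
               ids[duplicated(ids)][1L], path)
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (nrow(m) == 0L) storage.mode(m) <- "double"
    if (!is.numeric(m)) .stopf("non-numeric counts in %s", path)
    bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad))
        .stopf("invalid count at row %s (protein %s), column %s in %s",
               bad[1L, 1L], ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]], path)
    rownames(m) <- ids
    if (is.null(experimentId))
        experimentId <- sub("_F[0-9]+$", "", colnames(m)[1L])
    if (is.null(technique))
        technique <- sub("[0-9._].*$", "", experimentId)
    ProfileMatrix(m, experimentId, technique, fractionLabels = colnames(m))
}

#' Filter proteins by minimum peptide-spectrum matches
#'
#' A protein is retained when its maximum single-fraction spectral count,
#' taken across all supplied experiments, is at least \code{minPsm}. The
#' default of 2 reflects the usual requirement of not less than 2 PSMs in at
#' least one experiment.
#'
#' @param matrices list of \linkS4class{ProfileMatrix} objects.
#' @param minPsm minimum peak spectral count (>= 1).
#' @return list with \code{retained} (character vector of ids) and
#'   \code{log} (data.frame \code{id}, \code{maxCount}, \code{retained}).
#' @export
filterMinPsm <- function(matrices, minPsm = 2L) {
    if (!length(matrices)) .stopf("empty matrix list")
    if (minPsm < 1L) .stopf("'minPsm' must be >= 1")
    ids <- sort(unique(unlist(lapply(matrices, proteins))))
    maxCount <- stats::setNames(numeric(length(ids)), ids)
    for (m in matrices) {
        mx <- apply(counts(m), 1L, max)
        maxCount[names(mx)] <- pmax(maxCount[names(mx)], mx)
    }
    keep <- maxCount >= minPsm
    list(retained = ids[keep],
         log = data.frame(id = ids, maxCount = unname(maxCount),
                          retained = unname(keep), stringsAsFactors = FALSE))
}

#' Normalise and smooth an elution profile
#'
#' Divides by the profile maximum (all-zero profiles pass through
#' unchanged), then applies a centred moving average of odd width
#' \code{window}, truncated at the profile edges. The result lies in
#' [0, 1]; zeros are preserved by the scaling, which the Jaccard feature
#' relies on.
#'
#' @param x numeric count vector over ordered fractions, or a protein x
#'   fraction matrix (rows are smoothed independently).
#' @param window odd moving-average width; \code{1} means no smoothing.
#' @return Normalised profile(s), same shape as the input.
#' @examples
#' normalizeAndSmooth(c(0, 4, 0), window = 1)   # 0 1 0
#' @export
normalizeAndSmooth <- function(x, window = 3L) {
    if (window < 1L || window %% 2L == 0L)
        .stopf("'window' must be odd and >= 1")
    if (is.matrix(x)) {
        out <- t(apply(x, 1L, normalizeAndSmooth, window = window))
        dimnames(out) <- dimnames(x)
        return(out)
    }
    mx <- max(x)
    if (mx > 0) x <- x / mx
    if (window == 1L) return(x)
    h <- (window - 1L) %/% 2L
    n <- length(x)
    vapply(seq_len(n), function(i)
        mean(x[max(1L, i - h):min(n, i + h)]), numeric(1))
}

#' Per-protein reproducibility between two replicate experiments
#'
#' Pearson correlation of the raw spectral-count profiles of each protein
#' shared by two replicate separations, the standard replicate-concordance
#' display for co-fractionation data. Proteins with zero variance in either
#' replicate get \code{NA} (undefined), never an imputed 0.
#'
#' @param a,b \linkS4class{ProfileMatrix} objects with equal fraction
#'   counts.
#' @return list with \code{r} (named per-protein correlations) and
#'   \code{medianR} (median over proteins with defined r).
#' @export
replicateCorrelation <- function(a, b) {
    if (ncol(a) != ncol(b))
        .stopf("replicates have different fraction counts (%d vs %d)",
               ncol(a), ncol(b))
    shared <- intersect(proteins(a), proteins(b))
    if (!length(shared)) .stopf("no shared proteins between replicates")
    ca <- counts(a)[shared, , drop = FALSE]
    cb <- counts(b)[shared, , drop = FALSE]
    r <- vapply(shared, function(id) {
        x <- ca[id, ]; y <- cb[id, ]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
        stats::cor(x, y)
    }, numeric(1))
    list(r = r, medianR = stats::median(r, na.rm = TRUE))
}
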