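# Internal helpers shared across modules.

# All unordered pairs of a character vector, canonically ordered
# (idA < idB lexicographically), as a two-column data.frame.
.allPairs <- function(ids) {
    ids <- sort(unique(as.character(ids)))
    n <- length(ids)
    if (n < 2L)
        return(data.frame(idA = character(), idB = character(),
                          stringsAsFactors = FALSE))
    idx <- utils::combn(n, 2L)
    data.frame(idA = ids[idx[1L, ]], idB = ids[idx[2L, ]],
               stringsAsFactors = FALSE)
}

# Canonical single-string key for unordered pairs.
.pairKey <- function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "\r")
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Write a data.frame as plain TSV (no quoting, no row names).
.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

.readTsv <- function(path) {
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
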