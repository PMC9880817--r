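#' Node degrees, optionally split by homolog conservation
#'
#' Degree is the number of retained edges incident to a protein. When a
#' homolog map is supplied, proteins are split into "conserved" (homolog in
#' at least one reference species) versus "unique", and the two degree
#' samples are compared with a rank-sum (Wilcoxon) test, the standard
#' location comparison for skewed degree data.
#'
#' @param network a \linkS4class{WeightedPPINetwork}.
#' @param homologMap optional data.frame with column \code{id} plus one
#'   logical/0-1 flag column per reference species; proteins absent from
#'   the map count as all-false (unique).
#' @return list with \code{table} (data.frame \code{id}, \code{degree} and,
#'   with a map, \code{group}), \code{histogram} (degree frequency table)
#'   and, with a map, \code{comparison} (list \code{medianConserved},
#'   \code{medianUnique}, \code{W}, \code{pValue}).
#' @export
degreeDistribution <- function(network, homologMap = NULL) {
    A <- network@adjacency
    degree <- as.integer(colSums(A > 0))
    tab <- data.frame(id = network@nodes, degree = degree,
                      stringsAsFactors = FALSE)
    out <- list(table = tab, histogram = table(degree))
    if (!is.null(homologMap)) {
        flags <- as.matrix(homologMap[, setdiff(names(homologMap), "id"),
                                      drop = FALSE]) > 0
        conservedIds <- homologMap$id[rowSums(flags) > 0]
        tab$group <- ifelse(tab$id %in% conservedIds, "conserved", "unique")
        out$table <- tab
        dc <- tab$degree[tab$group == "conserved"]
        du <- tab$degree[tab$group == "unique"]
        cmp <- list(medianConserved = stats::median(dc),
                    medianUnique = stats::median(du),
                    W = NA_real_, pValue = NA_real_)
        if (length(dc) && length(du)) {
            wt <- suppressWarnings(stats::wilcox.test(dc, du,
                                                      alternative = "greater"))
            cmp$W <- unname(wt$statistic)
            cmp$pValue <- wt$p.value
        }
        out$comparison <- cmp
    }
    out
}

#' Overlap of predicted edges with a reference pair list
#'
#' @param edges data.frame \code{idA}, \code{idB} (canonical order), e.g.
#'   \code{edges(network)}.
#' @param referencePairs data.frame \code{idA}, \code{idB} of previously
#'   reported pairs.
#' @return list with \code{fraction} (|edges in reference| / |edges|),
#'   \code{nEdges}, \code{nOverlap} and \code{overlap} (the intersection).
#' @export
overlapWithReference <- function(edges, referencePairs) {
    if (!nrow(edges)) .stopf("empty edge set")
    eKey <- .pairKey(edges$idA, edges$idB)
    rKey <- .pairKey(referencePairs$idA, referencePairs$idB)
    hit <- eKey %in% rKey
    list(fraction = mean(hit), nEdges = nrow(edges),
         nOverlap = sum(hit),
         overlap = edges[hit, c("idA", "idB"), drop = FALSE])
}

#' Four-way conservation partition of complex members
#'
#' Assigns every member of every complex to exactly one of four groups by
#' its homology flags in two reference species: \code{both},
#' \code{A_only}, \code{B_only}, or \code{unique} (no homolog in either;
#' proteins absent from a map count as lacking a homolog).
#'
#' @param complexSet a \linkS4class{PredictedComplexSet} or
#'   \linkS4class{ReferenceComplexSet}.
#' @param mapA,mapB data.frames with columns \code{id} and a logical/0-1
#'   \code{hasHomolog}.
#' @return list with \code{members} (data.frame \code{complex}, \code{id},
#'   \code{group}) and \code{byComplex} (count of each group per complex).
#' @export
conservationPartition <- function(complexSet, mapA, mapB) {
    .flag <- function(map, ids) {
        m <- match(ids, map$id)
        f <- map$hasHomolog[m] > 0
        f[is.na(f)] <- FALSE
        f
    }
    cpx <- complexes(complexSet)
    if (is.null(names(cpx)))
        names(cpx) <- sprintf("complex%03d", seq_along(cpx))
    rows <- lapply(names(cpx), function(nm) {
        ids <- cpx[[nm]]
        inA <- .flag(mapA, ids)
        inB <- .flag(mapB, ids)
        group <- ifelse(inA & inB, "both",
                 ifelse(inA, "A_only",
                 ifelse(inB, "B_only", "unique")))
        data.frame(complex = nm, id = ids, group = group,
                   stringsAsFactors = FALSE)
    })
    members <- do.call(rbind, rows)
    lev <- c("both", "A_only", "B_only", "unique")
    members$group <- factor(members$group, levels = lev)
    byComplex <- as.data.frame.matrix(table(members$complex, members$group))
    list(members = members, byComplex = byComplex)
}
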