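#' Construct a weighted PPI network from an edge list
#'
#' @param edges data.frame with columns \code{idA}, \code{idB},
#'   \code{weight} (positive; typically classifier probabilities).
#'   Duplicate unordered pairs keep their maximum weight; self-loops are
#'   rejected.
#' @param nodes optional node set; defaults to the proteins incident to an
#'   edge.
#' @return A \linkS4class{WeightedPPINetwork}.
#' @export
weightedPPINetwork <- function(edges, nodes = NULL) {
    if (!nrow(edges)) {
        nodes <- sort(unique(as.character(nodes)))
        adj <- matrix(0, length(nodes), length(nodes),
                      dimnames = list(nodes, nodes))
        return(new("WeightedPPINetwork", nodes = nodes,
                   edges = data.frame(idA = character(), idB = character(),
                                      weight = numeric()),
                   adjacency = adj))
    }
    a <- pmin(edges$idA, edges$idB)
    b <- pmax(edges$idA, edges$idB)
    if (any(a == b)) .stopf("self-loops are not allowed")
    e <- data.frame(idA = a, idB = b, weight = edges$weight,
                    stringsAsFactors = FALSE)
    e <- e[order(e$idA, e$idB, -e$weight), , drop = FALSE]
    e <- e[!duplicated(paste(e$idA, e$idB)), , drop = FALSE]
    nodes <- sort(unique(c(nodes, e$idA, e$idB)))
    adj <- matrix(0, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
    ia <- match(e$idA, nodes); ib <- match(e$idB, nodes)
    adj[cbind(ia, ib)] <- e$weight
    adj[cbind(ib, ia)] <- e$weight
    rownames(e) <- NULL
    new("WeightedPPINetwork", nodes = nodes, edges = e, adjacency = adj)
}

#' Cohesiveness of a node set
#'
#' The clustering objective \deqn{f(V) = \frac{w_{in}}{w_{in} + w_{bound} +
#' p\,|V|},} where \eqn{w_{in}} is the total weight of edges inside
#' \eqn{V}, \eqn{w_{bound}} the total weight of edges with exactly one
#' endpoint in \eqn{V}, and \eqn{p} a per-node penalty modelling unobserved
#' external connectivity.
#'
#' @param network a \linkS4class{WeightedPPINetwork}.
#' @param nodeSet non-empty character vector of member ids.
#' @param p non-negative penalty per node.
#' @return Cohesiveness in [0, 1].
#' @examples
#' tri <- weightedPPINetwork(data.frame(idA = c("a", "a", "b"),
#'                                      idB = c("b", "c", "c"), weight = 1))
#' cohesiveness(tri, c("a", "b", "c"), p = 2)   # 3 / (3 + 6) = 1/3
#' @export
cohesiveness <- function(network, nodeSet, p = 2) {
    if (!length(nodeSet)) .stopf("empty node set")
    if (!all(nodeSet %in% network@nodes))
        .stopf("node set contains ids absent from the network")
    A <- network@adjacency
    idx <- match(unique(nodeSet), network@nodes)
    wIn <- sum(A[idx, idx]) / 2
    wBound <- sum(A[idx, -idx, drop = FALSE])
    denom <- wIn + wBound + p * length(idx)
    if (denom == 0) return(0)
    wIn / denom
}

#' Overlap score between two node sets
#'
#' \eqn{\omega(A, B) = |A \cap B|^2 / (|A| \cdot |B|)}, the match statistic
#' used both to merge near-duplicate candidate clusters and to compare
#' predicted with reference complexes.
#'
#' @param a,b non-empty id sets.
#' @return Overlap in [0, 1].
#' @export
overlapScore <- function(a, b) {
    a <- unique(a); b <- unique(b)
    if (!length(a) || !length(b)) .stopf("empty set")
    length(intersect(a, b))^2 / (length(a) * length(b))
}

# Weighted density of a node set: 2 * w_in / (|V| (|V|-1)).
.clusterDensity <- function(A, idx) {
    n <- length(idx)
    if (n < 2L) return(0)
    sum(A[idx, idx]) / (n * (n - 1L))
}

#' Grow a candidate complex from a seed node
#'
#' Greedy local search on cohesiveness: starting from the singleton seed,
#' repeatedly apply the single best move -- adding an external node
#' adjacent to the cluster or removing an internal node -- that strictly
#' increases cohesiveness, breaking ties by the smallest node id, until no
#' move improves. Deterministic.
#'
#' @param network a \linkS4class{WeightedPPINetwork}.
#' @param seedNode a node id in the network.
#' @param p cohesiveness penalty.
#' @return list with \code{members}, \code{cohesiveness}, \code{density},
#'   \code{seedNode}.
#' @export
growCluster <- function(network, seedNode, p = 2) {
    if (!seedNode %in% network@nodes)
        .stopf("seed '%s' not in network", seedNode)
    A <- network@adjacency
    nodes <- network@nodes
    deg <- rowSums(A)
    inS <- stats::setNames(rep(FALSE, length(nodes)), nodes)
    inS[seedNode] <- TRUE
    repeat {
        idx <- which(inS)
        kIn <- if (length(idx) == 1L) A[, idx] else rowSums(A[, idx,
                                                              drop = FALSE])
        wIn <- sum(kIn[idx]) / 2
        wBound <- sum(kIn[!inS])
        size <- length(idx)
        cur <- wIn / (wIn + wBound + p * size)
        if (!is.finite(cur)) cur <- 0

        addCand <- which(!inS & kIn > 0)
        addScore <- if (length(addCand)) {
            wIn2 <- wIn + kIn[addCand]
            wB2 <- wBound - kIn[addCand] + (deg[addCand] - kIn[addCand])
            wIn2 / (wIn2 + wB2 + p * (size + 1L))
        } else numeric()
        remCand <- if (size > 1L) idx else integer()
        remScore <- if (length(remCand)) {
            wIn2 <- wIn - kIn[remCand]
            wB2 <- wBound + kIn[remCand] - (deg[remCand] - kIn[remCand])
            s <- wIn2 / (wIn2 + wB2 + p * (size - 1L))
            s[!is.finite(s)] <- 0
            s
        } else numeric()

        cand <- data.frame(
            node = nodes[c(addCand, remCand)],
            score = c(addScore, remScore), stringsAsFactors = FALSE)
        cand <- cand[cand$score > cur + 1e-12, , drop = FALSE]
        if (!nrow(cand)) break
        cand <- cand[order(-cand$score, cand$node), , drop = FALSE]
        best <- cand$node[1L]
        inS[best] <- !inS[best]
    }
    idx <- which(inS)
    list(members = nodes[idx],
         cohesiveness = cohesiveness(network, nodes[idx], p = p),
         density = .clusterDensity(A, idx),
         seedNode = seedNode)
}

#' Detect complexes in a scored interaction network
#'
#' Cohesiveness-based graph clustering: every node, visited in decreasing
#' weighted-degree order and skipped when already inside a grown cluster,
#' seeds a \code{\link{growCluster}} search; candidate clusters whose
#' overlap score \eqn{\omega} reaches \code{mergeThreshold} are merged
#' (union) until a fixed point; clusters smaller than \code{minSize} or
#' with weighted density below \code{minDensity} are discarded. Output is
#' sorted by decreasing cohesiveness. Overlapping complexes are permitted.
#'
#' @param network a \linkS4class{WeightedPPINetwork}.
#' @param p cohesiveness penalty.
#' @param mergeThreshold minimum overlap score for merging.
#' @param minSize minimum complex size.
#' @param minDensity minimum weighted density.
#' @return A \linkS4class{PredictedComplexSet}.
#' @export
detectComplexes <- function(network, p = 2, mergeThreshold = 0.8,
                            minSize = 3L, minDensity = 0.3) {
    nodes <- network@nodes
    if (!length(nodes))
        return(new("PredictedComplexSet", members = list(),
                   stats = data.frame(cohesiveness = numeric(),
                                      density = numeric(), size = integer(),
                                      seedNode = character())))
    A <- network@adjacency
    deg <- rowSums(A)
    order_ <- nodes[order(-deg, nodes)]
    covered <- character()
    clusters <- list()
    seeds <- character()
    for (s in order_) {
        if (s %in% covered) next
        cl <- growCluster(network, s, p = p)
        clusters <- c(clusters, list(sort(cl$members)))
        seeds <- c(seeds, s)
        covered <- union(covered, cl$members)
    }
    dup <- duplicated(vapply(clusters, paste, character(1), collapse = "\r"))
    clusters <- clusters[!dup]; seeds <- seeds[!dup]

    # merge highly overlapping candidates until fixed point
    repeat {
        n <- length(clusters)
        if (n < 2L) break
        bestI <- 0L; bestJ <- 0L; bestW <- -1
        for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
            w <- overlapScore(clusters[[i]], clusters[[j]])
            if (w > bestW + 1e-12) { bestW <- w; bestI <- i; bestJ <- j }
        }
        if (bestW < mergeThreshold) break
        merged <- sort(union(clusters[[bestI]], clusters[[bestJ]]))
        clusters[[bestI]] <- merged
        clusters[[bestJ]] <- NULL
        seeds <- seeds[-bestJ]
        dup <- duplicated(vapply(clusters, paste, character(1),
                                 collapse = "\r"))
        clusters <- clusters[!dup]; seeds <- seeds[!dup]
    }

    stats_ <- data.frame(
        cohesiveness = vapply(clusters, function(m)
            cohesiveness(network, m, p = p), numeric(1)),
        density = vapply(clusters, function(m)
            .clusterDensity(A, match(m, nodes)), numeric(1)),
        size = lengths(clusters),
        seedNode = seeds, stringsAsFactors = FALSE)
    keep <- stats_$size >= minSize & stats_$density >= minDensity
    clusters <- clusters[keep]; stats_ <- stats_[keep, , drop = FALSE]
    ord <- order(-stats_$cohesiveness,
                 vapply(clusters, paste, character(1), collapse = "\r"))
    clusters <- clusters[ord]; stats_ <- stats_[ord, , drop = FALSE]
    names(clusters) <- sprintf("PC%03d", seq_along(clusters))
    rownames(stats_) <- names(clusters)
    new("PredictedComplexSet", members = clusters, stats = stats_)
}

#' Complex-supported interactions
#'
#' Every within-complex pair of a predicted complex set that is present as
#' an edge of the network: the PPI set "inside complexes".
#'
#' @param network a \linkS4class{WeightedPPINetwork}.
#' @param complexSet a \linkS4class{PredictedComplexSet}.
#' @return data.frame \code{idA}, \code{idB}, \code{weight} (unique pairs).
#' @export
complexSupportedPPIs <- function(network, complexSet) {
    pairs <- unique(do.call(rbind, lapply(complexes(complexSet), .allPairs)))
    if (is.null(pairs) || !nrow(pairs))
        return(data.frame(idA = character(), idB = character(),
                          weight = numeric()))
    e <- edges(network)
    m <- match(.pairKey(pairs$idA, pairs$idB), .pairKey(e$idA, e$idB))
    out <- pairs[!is.na(m), , drop = FALSE]
    out$weight <- e$weight[m[!is.na(m)]]
    out <- out[order(out$idA, out$idB), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Match predicted against planted (reference) complexes
#'
#' A reference complex counts as recovered when some predicted complex
#' matches it with member-set Jaccard at least \code{jaccardMin}.
#'
#' @param predicted a \linkS4class{PredictedComplexSet}.
#' @param reference a \linkS4class{ReferenceComplexSet} (or
#'   \linkS4class{GroundTruth}) whose complexes are the truth.
#' @param jaccardMin Jaccard threshold for a match.
#' @param minSize only reference complexes of at least this size enter the
#'   denominator.
#' @return list with \code{recovered} (logical per reference complex),
#'   \code{recoveryRate}, \code{bestJaccard} (numeric per reference
#'   complex).
#' @export
complexRecovery <- function(predicted, reference, jaccardMin = 0.5,
                            minSize = 3L) {
    ref <- complexes(reference)
    ref <- ref[lengths(ref) >= minSize]
    pred <- complexes(predicted)
    bestJ <- vapply(ref, function(r) {
        if (!length(pred)) return(0)
        max(vapply(pred, function(q) {
            i <- length(intersect(r, q))
            i / (length(r) + length(q) - i)
        }, numeric(1)))
    }, numeric(1))
    rec <- bestJ >= jaccardMin
    list(recovered = rec,
         recoveryRate = if (length(rec)) mean(rec) else NA_real_,
         bestJaccard = bestJ)
}
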