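# Independent brute-force / arithmetic oracles. These re-derive expected
# values from first principles and must stay independent of the package's
# implementation paths.

# Pearson r by the explicit sum formula.
oraclePearson <- function(x, y) {
    n <- length(x)
    num <- n * sum(x * y) - sum(x) * sum(y)
    den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
    if (den == 0) return(NA_real_)
    num / den
}

oracleJaccard <- function(x, y) {
    a <- which(x > 0); b <- which(y > 0)
    u <- length(union(a, b))
    if (u == 0) return(0)
    length(intersect(a, b)) / u
}

oracleApex <- function(x, y) {
    if (all(x == 0) || all(y == 0)) return(NA_real_)
    # earliest maximum, by explicit scan
    ax <- min(which(x == max(x)))
    ay <- min(which(y == max(y)))
    as.numeric(ax == ay)
}

# Equal-width binning over [0, max], bin i = [(i-1)w, iw), last bin closed.
oracleBins <- function(x, nBins) {
    mx <- max(x)
    if (mx == 0) return(rep(1L, length(x)))
    w <- mx / nBins
    vapply(x, function(v) {
        b <- as.integer(v %/% w) + 1L
        if (b > nBins) nBins else b
    }, integer(1))
}

# MI in bits by the definitional triple loop over bin pairs.
oracleMI <- function(x, y, nBins) {
    bx <- oracleBins(x, nBins); by <- oracleBins(y, nBins)
    n <- length(x)
    mi <- 0
    for (i in seq_len(nBins)) {
        for (j in seq_len(nBins)) {
            pij <- sum(bx == i & by == j) / n
            if (pij > 0) {
                pi_ <- sum(bx == i) / n
                pj_ <- sum(by == j) / n
                mi <- mi + pij * log2(pij / (pi_ * pj_))
            }
        }
    }
    mi
}

oracleBayes <- function(x, y, alpha = 1) {
    oraclePearson((x + alpha) / sum(x + alpha),
                  (y + alpha) / sum(y + alpha))
}

# AUC by the Mann-Whitney identity: fraction of positive-negative score
# pairs ranked correctly, ties counting one half.
oracleAUC <- function(scores, labels) {
    pos <- scores[as.logical(labels)]
    neg <- scores[!as.logical(labels)]
    cmp <- outer(pos, neg, function(p, q)
        ifelse(p > q, 1, ifelse(p == q, 0.5, 0)))
    mean(cmp)
}

# Cohesiveness from the edge list, by definition.
oracleCohesiveness <- function(edgeDf, nodeSet, p) {
    inA <- edgeDf$idA %in% nodeSet
    inB <- edgeDf$idB %in% nodeSet
    wIn <- sum(edgeDf$weight[inA & inB])
    wBound <- sum(edgeDf$weight[xor(inA, inB)])
    wIn / (wIn + wBound + p * length(nodeSet))
}

# Global optimum over all subsets containing `seed` (exhaustive).
oracleBestSubset <- function(edgeDf, nodes, seed, p) {
    others <- setdiff(nodes, seed)
    best <- NULL; bestScore <- -Inf
    for (mask in 0:(2^length(others) - 1)) {
        subset <- c(seed, others[bitwAnd(mask, 2^(seq_along(others) - 1)) > 0])
        sc <- oracleCohesiveness(edgeDf, subset, p)
        if (sc > bestScore) { bestScore <- sc; best <- sort(subset) }
    }
    list(members = best, cohesiveness = bestScore)
}

# All terminal states reachable by any sequence of strictly improving
# single moves from {seed} (depth-first with memoisation).
oracleGreedyTerminals <- function(edgeDf, nodes, seed, p) {
    nodes <- sort(nodes)
    seen <- new.env(parent = emptyenv())
    terminals <- new.env(parent = emptyenv())
    visit <- function(subset) {
        key <- paste(subset, collapse = ",")
        if (!is.null(seen[[key]])) return(invisible())
        seen[[key]] <- TRUE
        cur <- oracleCohesiveness(edgeDf, subset, p)
        moved <- FALSE
        for (v in nodes) {
            nxt <- if (v %in% subset) setdiff(subset, v) else
                sort(c(subset, v))
            if (!length(nxt)) next
            if (oracleCohesiveness(edgeDf, nxt, p) > cur + 1e-12) {
                moved <- TRUE
                visit(nxt)
            }
        }
        if (!moved) terminals[[key]] <- cur
        invisible()
    }
    visit(seed)
    unlist(as.list(terminals))
}

# Small deterministic fixtures -------------------------------------------

triangleNetwork <- function(w = 1) {
    weightedPPINetwork(data.frame(idA = c("a", "a", "b"),
                                  idB = c("b", "c", "c"), weight = w))
}

# Two unit-weight triangles joined by one weak edge.
barbellNetwork <- function(bridge = 0.1) {
    weightedPPINetwork(data.frame(
        idA = c("a1", "a1", "a2", "b1", "b1", "b2", "a3"),
        idB = c("a2", "a3", "a3", "b2", "b3", "b3", "b1"),
        weight = c(1, 1, 1, 1, 1, 1, bridge)))
}

# canonical pair key for test bookkeeping
.pairKeyTest <- function(a, b) paste(pmin(a, b), pmax(a, b))

# all unordered pairs, canonical order, for test bookkeeping
.allPairsTest <- function(ids) {
    ids <- sort(ids)
    idx <- utils::combn(length(ids), 2)
    data.frame(idA = ids[idx[1, ]], idB = ids[idx[2, ]],
               stringsAsFactors = FALSE)
}
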