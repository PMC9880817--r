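test_that("cohesiveness matches the defining formula on fixtures", {
    tri <- triangleNetwork()
    expect_equal(cohesiveness(tri, c("a", "b", "c"), p = 0), 1)
    expect_equal(cohesiveness(tri, c("a", "b", "c"), p = 2), 1 / 3)
    # single node with one external unit edge
    pair <- weightedPPINetwork(data.frame(idA = "a", idB = "b", weight = 1))
    expect_equal(cohesiveness(pair, "a", p = 0), 0)
    expect_equal(cohesiveness(tri, c("a", "b"), p = 0.5),
                 oracleCohesiveness(edges(tri), c("a", "b"), 0.5))
    expect_error(cohesiveness(tri, character()), "empty")
    expect_error(cohesiveness(tri, "zz"), "absent")
})

test_that("overlap score follows |A int B|^2 / (|A| |B|)", {
    expect_equal(overlapScore(letters[1:4], letters[1:4]), 1)
    expect_equal(overlapScore(letters[1:3], letters[4:6]), 0)
    expect_equal(overlapScore(letters[1:4], letters[3:6]), 4 / 16)
    expect_error(overlapScore(character(), "a"), "empty")
})

test_that("growCluster recovers an isolated triangle from any seed", {
    tri <- triangleNetwork()
    for (s in c("a", "b", "c")) {
        cl <- growCluster(tri, s, p = 0.5)
        expect_setequal(cl$members, c("a", "b", "c"))
        expect_equal(cl$cohesiveness,
                     oracleCohesiveness(edges(tri), c("a", "b", "c"), 0.5))
    }
    lone <- weightedPPINetwork(data.frame(idA = "x", idB = "y",
                                          weight = 1),
                               nodes = c("x", "y", "z"))
    expect_equal(growCluster(lone, "z", p = 1)$members, "z")
})

test_that("growCluster isolates the seeded triangle of the barbell", {
    net <- barbellNetwork()
    cl <- growCluster(net, "a1", p = 0.5)
    expect_setequal(cl$members, c("a1", "a2", "a3"))   # triangle 1, exactly
    # exhaustive replay of every strictly-improving move sequence from the
    # seed: the grown cluster attains the best reachable terminal state
    terminals <- oracleGreedyTerminals(edges(net), nodes(net), "a1", 0.5)
    expect_equal(cl$cohesiveness, max(terminals))
    # crossing the bridge is never an improving move, so the whole-graph
    # optimum of the raw objective is unreachable by single improving moves
    best <- oracleBestSubset(edges(net), nodes(net), "a1", p = 0.5)
    expect_setequal(best$members, nodes(net))
    expect_gt(best$cohesiveness, max(terminals))
})

test_that("grown clusters are deterministic local optima of the move set", {
    set.seed(19)
    for (rep_ in 1:10) {
        n <- sample(4:6, 1)
        ids <- paste0("n", seq_len(n))
        full <- .allPairsTest(ids)
        keep <- runif(nrow(full)) < 0.6
        if (sum(keep) < 2) next
        ed <- data.frame(full[keep, ],
                         weight = round(runif(sum(keep), 0.2, 1), 2))
        net <- weightedPPINetwork(ed, nodes = ids)
        seedNode <- sample(ids, 1)
        cl <- growCluster(net, seedNode, p = 1)
        expect_identical(growCluster(net, seedNode, p = 1), cl)
        # no single add/remove improves the final cohesiveness
        fin <- oracleCohesiveness(ed, cl$members, 1)
        expect_equal(cl$cohesiveness, fin)
        for (v in ids) {
            alt <- if (v %in% cl$members)
                setdiff(cl$members, v) else c(cl$members, v)
            if (!length(alt)) next
            expect_lte(oracleCohesiveness(ed, alt, 1), fin + 1e-12)
        }
        # and the result is a terminal state of the improving-move system
        terminals <- oracleGreedyTerminals(ed, ids, seedNode, 1)
        expect_true(any(abs(terminals - fin) < 1e-12))
    }
})

plantedCliqueNetwork <- function() {
    c1 <- paste0("u", 1:4)
    c2 <- paste0("v", 1:5)
    ed <- rbind(.allPairsTest(c1), .allPairsTest(c2))
    ed$weight <- 1
    weightedPPINetwork(ed, nodes = c(c1, c2, paste0("iso", 1:20)))
}

test_that("detectComplexes recovers two planted disjoint cliques exactly", {
    net <- plantedCliqueNetwork()
    found <- detectComplexes(net, p = 2, minSize = 3L, minDensity = 0.3)
    expect_length(found, 2L)
    expect_setequal(vapply(complexes(found), paste, character(1),
                           collapse = ","),
                    c(paste(paste0("u", 1:4), collapse = ","),
                      paste(paste0("v", 1:5), collapse = ",")))
    st <- complexStats(found)
    expect_true(all(st$density == 1))
    expect_setequal(st$size, c(4L, 5L))
})

test_that("detectComplexes filters, merges and orders deterministically", {
    net <- plantedCliqueNetwork()
    expect_identical(detectComplexes(net), detectComplexes(net))
    # a single-edge network has nothing of size >= 3
    tiny <- weightedPPINetwork(data.frame(idA = "a", idB = "b", weight = 1))
    expect_length(detectComplexes(tiny, minSize = 3L), 0L)
    # mergeThreshold 1 merges only identical clusters: cliques stay apart
    found <- detectComplexes(net, mergeThreshold = 1)
    expect_length(found, 2L)
    # the merge pass has reached a fixed point: all pairwise overlaps are
    # below the merge threshold
    mem <- complexes(found)
    if (length(mem) > 1)
        for (i in seq_len(length(mem) - 1))
            for (j in (i + 1):length(mem))
                expect_lt(overlapScore(mem[[i]], mem[[j]]), 0.8)
    # output sorted by decreasing cohesiveness
    st <- complexStats(detectComplexes(net))
    expect_true(all(diff(st$cohesiveness) <= 0))
})

test_that("merging unions highly overlapping grown clusters", {
    # two 4-cliques sharing 3 nodes: omega = 9/16 < 0.8 keeps them apart;
    # a lower threshold merges them into one 5-set
    a <- c("m1", "m2", "m3", "m4")
    b <- c("m2", "m3", "m4", "m5")
    ed <- unique(rbind(.allPairsTest(a), .allPairsTest(b)))
    ed$weight <- 1
    net <- weightedPPINetwork(ed)
    expect_equal(overlapScore(a, b), 9 / 16)
    merged <- detectComplexes(net, p = 0.5, mergeThreshold = 0.5)
    expect_length(merged, 1L)
    expect_setequal(complexes(merged)[[1]], paste0("m", 1:5))
})

test_that("complex-supported PPIs are the within-complex network edges", {
    net <- plantedCliqueNetwork()
    found <- detectComplexes(net)
    ppis <- complexSupportedPPIs(net, found)
    expect_equal(nrow(ppis), choose(4, 2) + choose(5, 2))
    expect_true(all(ppis$weight == 1))
})

test_that("complexRecovery scores member-set Jaccard matches", {
    pred <- new("PredictedComplexSet",
                members = list(c("a", "b", "c"), c("x", "y", "z")),
                stats = data.frame(cohesiveness = c(0.5, 0.4),
                                   density = 1, size = 3L,
                                   seedNode = c("a", "x")))
    ref <- referenceComplexSet(list(R1 = c("a", "b", "c", "d"),
                                    R2 = c("p", "q", "r")))
    rec <- complexRecovery(pred, ref, jaccardMin = 0.5, minSize = 3L)
    expect_equal(unname(rec$recovered), c(TRUE, FALSE))
    expect_equal(rec$recoveryRate, 0.5)
    expect_equal(unname(rec$bestJaccard), c(3 / 4, 0))
})
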