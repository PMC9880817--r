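test_that("pearson feature matches the sum-formula oracle", {
    expect_equal(pearsonFeature(c(0, 1, 2, 1, 0), c(0, 1, 2, 1, 0)), 1)
    x <- 1:6
    expect_equal(pearsonFeature(x, rev(x)), -1)
    a <- c(0, 1, 2, 1, 0); b <- c(0, 0, 1, 2, 1)
    expect_equal(pearsonFeature(a, b), oraclePearson(a, b))
    expect_true(is.na(pearsonFeature(rep(1, 5), c(1, 2, 3, 4, 5))))
})

test_that("jaccard feature follows set arithmetic on detection supports", {
    expect_equal(jaccardFeature(c(1, 2, 0), c(3, 1, 0)), 1)
    expect_equal(jaccardFeature(c(1, 0, 0), c(0, 0, 2)), 0)
    x <- c(1, 1, 1, 0); y <- c(0, 2, 2, 2)   # supports {1,2,3}, {2,3,4}
    expect_equal(jaccardFeature(x, y), 0.5)
    expect_equal(jaccardFeature(c(0, 0), c(0, 0)), 0)
})

test_that("apex feature compares earliest-tie-resolved argmax fractions", {
    p7 <- rep(0, 10); p7[7] <- 1
    p8 <- rep(0, 10); p8[8] <- 1
    expect_equal(apexFeature(p7, p7), 1)
    expect_equal(apexFeature(p7, p8), 0)
    expect_equal(apexFeature(c(1, 1, 0), c(1, 0, 0)), 1)  # ties -> F1
    expect_true(is.na(apexFeature(rep(0, 3), p7[1:3])))
})

test_that("mutual information matches closed forms", {
    expect_equal(mutualInformationFeature(rep(0.5, 10), runif(10)), 0)
    x <- rep(c(0, 1), 5)   # two symbols, equally occupied, y = x
    expect_equal(mutualInformationFeature(x, x), 1)
})

test_that("bayes correlation shrinks counts then correlates proportions", {
    x <- c(4, 1, 0, 2)
    expect_equal(bayesCorrelationFeature(x, x), 1)
    expect_true(is.na(bayesCorrelationFeature(rep(0, 4), rep(0, 4))))
    a <- c(5, 0, 0); b <- c(0, 0, 5)
    expect_equal(bayesCorrelationFeature(a, b, alpha = 1),
                 oracleBayes(a, b, alpha = 1))
})

test_that("all five features agree with brute-force oracles on exhaustive small instances", {
    # full cross of all length-3 vectors over {0,1,2}
    grid <- as.matrix(expand.grid(0:2, 0:2, 0:2))
    nb <- 3L
    for (i in seq_len(nrow(grid))) {
        x <- grid[i, ]
        for (j in seq_len(nrow(grid))) {
            y <- grid[j, ]
            expect_equal(mutualInformationFeature(x, y, nBins = nb),
                         oracleMI(x, y, nb))
            expect_equal(jaccardFeature(x, y), oracleJaccard(x, y))
            expect_equal(apexFeature(x, y), oracleApex(x, y))
        }
    }
    # seeded random length-8 instances for all five features
    set.seed(8)
    for (rep_ in 1:200) {
        x <- sample(0:2, 8, replace = TRUE)
        y <- sample(0:2, 8, replace = TRUE)
        expect_equal(mutualInformationFeature(x, y, nBins = 5L),
                     oracleMI(x, y, 5L))
        expect_equal(pearsonFeature(x, y), oraclePearson(x, y))
        expect_equal(jaccardFeature(x, y), oracleJaccard(x, y))
        expect_equal(apexFeature(x, y), oracleApex(x, y))
        expect_equal(bayesCorrelationFeature(x, y), oracleBayes(x, y))
    }
})

test_that("features are symmetric and appropriately scale-invariant", {
    set.seed(11)
    for (rep_ in 1:25) {
        x <- rpois(12, 3); y <- rpois(12, 3)
        expect_equal(pearsonFeature(x, y), pearsonFeature(y, x))
        expect_equal(jaccardFeature(x, y), jaccardFeature(y, x))
        expect_equal(apexFeature(x, y), apexFeature(y, x))
        expect_equal(mutualInformationFeature(x, y),
                     mutualInformationFeature(y, x))
        expect_equal(bayesCorrelationFeature(x, y),
                     bayesCorrelationFeature(y, x))
        if (sd(x) > 0 && sd(y) > 0) {
            expect_equal(pearsonFeature(x * 5L, y), pearsonFeature(x, y))
            # Bayes correlation is scale-free only asymptotically
            expect_equal(bayesCorrelationFeature(x * 10L, y * 10L),
                         bayesCorrelationFeature(x, y), tolerance = 0.01)
        }
    }
})

# small two-experiment study for feature-table level checks
featureToyMatrices <- function() {
    m1 <- matrix(c(0, 5, 9, 5, 0, 0,
                   0, 4, 8, 4, 0, 0,
                   5, 9, 5, 0, 0, 0,
                   0, 0, 0, 5, 9, 5), 4, 6, byrow = TRUE,
                 dimnames = list(c("A", "B", "C", "D"), NULL))
    m2 <- matrix(c(0, 0, 6, 9, 6, 0,
                   0, 0, 5, 9, 5, 0,
                   8, 5, 0, 0, 0, 0), 3, 6, byrow = TRUE,
                 dimnames = list(c("A", "B", "D"), NULL))
    list(ProfileMatrix(m1, "SEC6", "SEC"),
         ProfileMatrix(m2, "IEX6", "IEX"))
}

test_that("the feature table aggregates per-experiment scores as documented", {
    mats <- featureToyMatrices()
    ft <- buildFeatureTable(mats, c("A", "B", "C", "D"), prefilter = -1,
                            window = 1L)
    key <- paste(ft$idA, ft$idB)
    # pair (C, D): co-detected only in SEC6, so aggregates are that
    # experiment's values
    cd <- ft[key == "C D", ]
    c1 <- counts(mats[[1]])["C", ]; d1 <- counts(mats[[1]])["D", ]
    expect_equal(cd$nExperiments, 1L)
    expect_equal(cd$pearson, oraclePearson(c1, d1))
    expect_equal(cd$jaccard, oracleJaccard(c1, d1))
    # pair (A, B): shared in both experiments; mean aggregation
    ab <- ft[key == "A B", ]
    pe <- c(oraclePearson(counts(mats[[1]])["A", ], counts(mats[[1]])["B", ]),
            oraclePearson(counts(mats[[2]])["A", ], counts(mats[[2]])["B", ]))
    expect_equal(ab$nExperiments, 2L)
    expect_equal(ab$pearson, mean(pe))
    expect_equal(ab$pearsonMax, max(pe))
    ftMax <- buildFeatureTable(mats, c("A", "B", "C", "D"), prefilter = -1,
                               window = 1L, aggregate = "max")
    abMax <- ftMax[paste(ftMax$idA, ftMax$idB) == "A B", ]
    expect_equal(abMax$pearson, max(pe))
})

test_that("the similarity pre-filter is strict and monotone", {
    mats <- featureToyMatrices()
    all_ <- buildFeatureTable(mats, c("A", "B", "C", "D"), prefilter = -1,
                              window = 1L)
    # a pair sitting exactly at the cut is dropped ("more than", strict)
    cut <- all_$pearsonMax[1L]
    ft <- buildFeatureTable(mats, c("A", "B", "C", "D"), prefilter = cut,
                            window = 1L)
    expect_false(paste(all_$idA[1L], all_$idB[1L]) %in%
                 paste(ft$idA, ft$idB))
    # raising the threshold never grows the candidate set
    prev <- nrow(buildFeatureTable(mats, LETTERS[1:4], prefilter = -1,
                                   window = 1L))
    for (th in c(0, 0.25, 0.5, 0.75, 0.95)) {
        cur <- nrow(buildFeatureTable(mats, LETTERS[1:4], prefilter = th,
                                      window = 1L))
        expect_lte(cur, prev)
        prev <- cur
    }
    expect_error(buildFeatureTable(mats, character()), "retained")
})

test_that("planted co-complex pairs survive the pre-filter in a clean study", {
    cfg <- noiseFreeConfig()
    truth <- noiseFreeTruth()
    mats <- list(simulateExperiment(truth, "SEC", 24L, cfg, seed = 5))
    ft <- buildFeatureTable(mats, proteins(truth), prefilter = 0.5)
    key <- .pairKeyTest(ft$idA, ft$idB)
    tp <- truePairs(truth)
    # degraded members do not co-elute; all other true pairs must survive
    deg <- degradedProteins(truth)
    tp <- tp[!(tp$idA %in% deg | tp$idB %in% deg), ]
    expect_true(all(.pairKeyTest(tp$idA, tp$idB) %in% key))
    surviving <- ft[match(.pairKeyTest(tp$idA, tp$idB), key), ]
    expect_true(all(surviving$pearson > 0.9))
    expect_true(all(surviving$apex == 1))
})

test_that("feature tables round-trip through TSV", {
    mats <- featureToyMatrices()
    ft <- buildFeatureTable(mats, LETTERS[1:4], prefilter = -1,
                            window = 1L)
    p <- withr::local_tempfile(fileext = ".tsv")
    writeFeatureTable(ft, p)
    expect_equal(readFeatureTable(p), ft)
})
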