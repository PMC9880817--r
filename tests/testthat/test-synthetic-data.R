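test_that("ground truth respects counts, sizes and the empty-complex case", {
    cfg <- simulationConfig(nComplexes = 0L, nMonomers = 5L, seed = 1)
    truth <- generateGroundTruth(cfg)
    expect_length(proteins(truth), 5L)
    expect_length(complexes(truth), 0L)
    expect_equal(nrow(truePairs(truth)), 0L)

    cfg3 <- simulationConfig(nComplexes = 1L, complexSizes = 3L,
                             nMonomers = 0L, seed = 2)
    truth3 <- generateGroundTruth(cfg3)
    expect_equal(nrow(truePairs(truth3)), choose(3, 2))

    cfg10 <- simulationConfig(nComplexes = 20L, nMonomers = 10L, seed = 4)
    t10 <- generateGroundTruth(cfg10)
    expect_true(all(lengths(complexes(t10)) >= 2L))
    expect_true(all(lengths(complexes(t10)) <= 10L))
    # assembly mass is the member sum and so bounds every member mass
    mm <- monomerMasses(t10)
    for (nm in names(complexes(t10)))
        expect_equal(t10@complexMass[[nm]],
                     sum(mm[complexes(t10)[[nm]]]))
})

test_that("ground truth generation is deterministic under the seed", {
    cfg <- simulationConfig(seed = 1)
    expect_identical(generateGroundTruth(cfg), generateGroundTruth(cfg))
    altered <- generateGroundTruth(simulationConfig(seed = 2))
    expect_false(identical(generateGroundTruth(cfg)@proteinTable$massKda,
                           altered@proteinTable$massKda))
})

test_that("invalid configurations are rejected", {
    expect_error(simulationConfig(nComplexes = -1), "non-negative")
    expect_error(simulationConfig(dropoutProb = 1.2), "\\[0, 1\\]")
    expect_error(simulationConfig(
        experiments = data.frame(id = "X", technique = "SEC",
                                 nFractions = 5L)), ">= 10")
    expect_error(simulationConfig(
        experiments = data.frame(id = "X", technique = "HPLC",
                                 nFractions = 20L)), "technique")
    truth <- generateGroundTruth(simulationConfig(nMonomers = 5L,
                                                  nComplexes = 0L))
    expect_error(simulateExperiment(truth, "HPLC", 24L,
                                    simulationConfig()), "technique")
})

test_that("total dropout yields an all-zero matrix", {
    cfg <- simulationConfig(nComplexes = 2L, nMonomers = 5L,
                            dropoutProb = 1, backgroundRate = 0, seed = 3)
    truth <- generateGroundTruth(cfg)
    pm <- simulateExperiment(truth, "SEC", 24L, cfg)
    expect_true(all(counts(pm) == 0))
})

test_that("noise-free complex members share their SEC apex fraction", {
    cfg <- noiseFreeConfig()
    truth <- noiseFreeTruth()
    pm <- simulateExperiment(truth, "SEC", 24L, cfg, seed = 5)
    cts <- counts(pm)
    for (mem in complexes(truth)) {
        apexes <- apply(cts[mem, ], 1L, which.max)
        expect_length(unique(apexes), 1L)
    }
})

test_that("planted complex peaks land at the calibration inverse", {
    # a 400 kDa complex: four members of 100 kDa each
    cfg <- simulationConfig(nComplexes = 1L, complexSizes = 4L,
                            nMonomers = 0L, massRangeKda = c(100, 100),
                            dropoutProb = 0, backgroundRate = 0,
                            degradedFraction = 0,
                            meanTotalCounts = 1e4, seed = 7)
    truth <- generateGroundTruth(cfg)
    expect_equal(unname(truth@complexMass), 400)
    pm <- simulateExperiment(truth, "SEC", 24L, cfg, seed = 7)
    cal <- simulatorCalibration(24L)
    expected <- peakFraction(cal, 400)
    apexes <- apply(counts(pm), 1L, which.max)
    expect_true(all(abs(apexes - expected) <= 1))
})

test_that("SEC expected peak fraction is monotone decreasing in mass", {
    cal <- simulatorCalibration(45L)
    masses <- sort(runif(20, 10, 1500))
    pf <- peakFraction(cal, masses)
    expect_true(all(diff(pf) < 0))
})

test_that("IEX places complex members together but ignores mass", {
    cfg <- simulationConfig(nComplexes = 4L, complexSizes = 3L,
                            nMonomers = 0L, dropoutProb = 0,
                            backgroundRate = 0, degradedFraction = 0,
                            meanTotalCounts = 1e4, seed = 9)
    truth <- generateGroundTruth(cfg)
    pm <- simulateExperiment(truth, "IEX", 43L, cfg, seed = 9)
    cts <- counts(pm)
    for (mem in complexes(truth))
        expect_length(unique(apply(cts[mem, ], 1L, which.max)), 1L)
})

test_that("fixtures round-trip losslessly and deterministically", {
    cfg <- simulationConfig(nComplexes = 3L, nMonomers = 6L, seed = 13)
    truth <- generateGroundTruth(cfg)
    mats <- simulateDataset(truth, cfg)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    writeFixture(truth, mats, d1)
    writeFixture(truth, mats, d2)
    for (f in list.files(d1))   # byte-identical re-write
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))

    fx <- readFixture(d1)
    expect_equal(sum(vapply(fx$matrices, ncol, integer(1))), 136L)
    for (nm in names(mats))
        expect_equal(counts(fx$matrices[[nm]]), counts(mats[[nm]]))
    expect_equal(fx$monomerMass, monomerMasses(truth))
    expect_identical(complexes(fx$referenceComplexes), complexes(truth))
    expect_equal(fx$truePairs, truePairs(truth))
})

test_that("an empty ground truth writes valid empty fixtures", {
    cfg <- simulationConfig(nComplexes = 0L, nMonomers = 0L, seed = 1)
    truth <- generateGroundTruth(cfg)
    mats <- simulateDataset(truth, cfg)
    d <- withr::local_tempdir()
    writeFixture(truth, mats, d)
    fx <- readFixture(d)
    expect_null(fx$referenceComplexes)
    expect_equal(nrow(fx$truePairs), 0L)
    expect_length(fx$monomerMass, 0L)
})

test_that("pre-noise expected profiles of co-complex members correlate perfectly", {
    # construction property: same peak, same abundance => identical kernels
    cfg <- noiseFreeConfig()
    truth <- noiseFreeTruth()
    for (tech in c("SEC", "IEX")) {
        pm <- simulateExperiment(truth, tech, 24L, cfg, seed = 21)
        n <- normalizeAndSmooth(counts(pm), window = 3L)
        for (mem in complexes(truth)) {
            prs <- utils::combn(mem, 2)
            for (k in seq_len(ncol(prs)))
                expect_gt(cor(n[prs[1, k], ], n[prs[2, k], ]), 0.99)
        }
    }
})

test_that("every true pair is co-observed in at least one experiment", {
    cfg <- simulationConfig(nComplexes = 10L, nMonomers = 10L, seed = 17)
    truth <- generateGroundTruth(cfg)
    mats <- simulateDataset(truth, cfg)
    tp <- truePairs(truth)
    coDetected <- rep(FALSE, nrow(tp))
    for (m in mats) {
        det <- rowSums(counts(m)) > 0
        coDetected <- coDetected | (det[tp$idA] & det[tp$idB])
    }
    expect_true(all(coDetected))
})
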