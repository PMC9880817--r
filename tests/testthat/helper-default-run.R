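# Shared study fixtures, computed lazily once per test session.

.cofracCache <- new.env(parent = emptyenv())

# The default synthetic benchmark: 50 complexes, 150 monomers, four
# experiments (SEC 24/45, IEX 43, SDGC 24), default noise, seed 11.
defaultRun <- function() {
    if (is.null(.cofracCache$default)) {
        cfg <- pipelineConfig(sim = simulationConfig(seed = 11), seed = 11)
        .cofracCache$default <- runPipeline(cfg, verbose = FALSE)
    }
    .cofracCache$default
}

# A reduced study for cheap structural tests.
smallConfig <- function(seed = 3L) {
    simulationConfig(
        nComplexes = 15L, nMonomers = 40L,
        experiments = data.frame(
            id = c("SEC24", "IEX20"),
            technique = c("SEC", "IEX"),
            nFractions = c(24L, 20L), stringsAsFactors = FALSE),
        seed = seed)
}

smallPipelineConfig <- function(seed = 3L, ...) {
    pipelineConfig(sim = smallConfig(seed), kFolds = 3L, ntree = 100L,
                   seed = seed, ...)
}

# A hand-built noise-free SEC study with safe Rapp margins: complexes at
# >= 2.6x each member's monomer mass, degraded at 0.4x, monomers at 1x.
# Margins absorb the <= 1-fraction apex rounding of the 24-fraction
# calibration (one fraction is a mass factor of ~1.3).
noiseFreeTruth <- function() {
    proteins <- data.frame(
        id = sprintf("T%02d", 1:11),
        massKda = c(60, 70, 80, 35, 40, 45, 30, 90, 25, 55, 110),
        complex = c("C1", "C1", "C1", "C2", "C2", "C2", NA, NA, NA, NA, NA),
        degraded = c(rep(FALSE, 8), TRUE, TRUE, FALSE),
        abundance = rep(1e5, 11),
        stringsAsFactors = FALSE)
    new("GroundTruth",
        proteinTable = proteins,
        complexes = list(C1 = c("T01", "T02", "T03"),
                         C2 = c("T04", "T05", "T06")),
        complexMass = c(C1 = 210, C2 = 120),         # sums of member masses
        complexAbundance = c(C1 = 1e5, C2 = 1e5))
}

# States the Rapp rule should observe for noiseFreeTruth under the
# 24-fraction calibration: every complex member has true Rapp >= 2.6,
# degraded proteins 0.4, monomers 1.
noiseFreeExpectedStates <- function() {
    c(T01 = "complexed", T02 = "complexed", T03 = "complexed",
      T04 = "complexed", T05 = "complexed", T06 = "complexed",
      T07 = "monomeric", T08 = "monomeric", T09 = "degraded",
      T10 = "degraded", T11 = "monomeric")
}

noiseFreeConfig <- function(seed = 5L) {
    simulationConfig(
        nComplexes = 2L, nMonomers = 5L,
        experiments = data.frame(id = "SEC24", technique = "SEC",
                                 nFractions = 24L, stringsAsFactors = FALSE),
        meanTotalCounts = 1e5, dropoutProb = 0, backgroundRate = 0,
        degradedFraction = 0, seed = seed)
}
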