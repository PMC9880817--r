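#' Configuration for the synthetic fractionation study
#'
#' Defines the conditions of a simulated co-fractionation experiment set:
#' how many complexes and free monomers to plant, the complex-size
#' distribution, the separation experiments (technique and fraction counts),
#' and the count-noise model. Defaults emulate a four-experiment design
#' (SEC with 24 and 45 fractions, IEX with 43, SDGC with 24) at reduced
#' proteome scale.
#'
#' @param nComplexes number of planted complexes.
#' @param nMonomers number of free monomeric proteins.
#' @param complexSizeRange inclusive size support of the truncated geometric
#'   complex-size distribution.
#' @param complexSizeGeomP success probability of the geometric size law;
#'   larger values favour small complexes.
#' @param complexSizes optional explicit vector of complex sizes, overriding
#'   the distribution (recycled to \code{nComplexes}).
#' @param massRangeKda uniform sampling interval for monomer masses (kDa).
#' @param experiments data.frame with columns \code{id}, \code{technique}
#'   (\code{SEC}/\code{IEX}/\code{SDGC}) and \code{nFractions}.
#' @param elutionSigma Gaussian elution-peak width, in fractions.
#' @param meanTotalCounts expected total spectral counts per protein per
#'   experiment (log-normal abundances, \code{sdlog = 1}).
#' @param dropoutProb per-cell probability that an observation is zeroed
#'   (stochastic missingness of low-abundance peptides).
#' @param degradedFraction proportion of proteins degraded during
#'   extraction; degraded proteins elute at 0.4x their monomer mass and
#'   never co-elute with their complex.
#' @param backgroundRate expected stray (contaminant) counts per cell,
#'   Poisson.
#' @param calMassRangeKda mass range spanned by the simulator's SEC/SDGC
#'   calibration line, from the first to the last fraction.
#' @param seed integer RNG seed; all generator randomness derives from it.
#' @return A validated list of class \code{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nComplexes = 5, nMonomers = 10, seed = 1)
#' @export
simulationConfig <- function(nComplexes = 50L,
                             nMonomers = 150L,
                             complexSizeRange = c(2L, 10L),
                             complexSizeGeomP = 0.35,
                             complexSizes = NULL,
                             massRangeKda = c(20, 150),
                             experiments = defaultExperiments(),
                             elutionSigma = 1.5,
                             meanTotalCounts = 100,
                             dropoutProb = 0.1,
                             degradedFraction = 0.05,
                             backgroundRate = 0.1,
                             calMassRangeKda = c(5, 2000),
                             seed = 1L) {
    cfg <- list(nComplexes = as.integer(nComplexes),
                nMonomers = as.integer(nMonomers),
                complexSizeRange = as.integer(complexSizeRange),
                complexSizeGeomP = complexSizeGeomP,
                complexSizes = complexSizes,
                massRangeKda = massRangeKda,
                experiments = experiments,
                elutionSigma = elutionSigma,
                meanTotalCounts = meanTotalCounts,
                dropoutProb = dropoutProb,
                degradedFraction = degradedFraction,
                backgroundRate = backgroundRate,
                calMassRangeKda = calMassRangeKda,
                seed = as.integer(seed))
    class(cfg) <- "SimulationConfig"
    .validateSimulationConfig(cfg)
    cfg
}

.validateSimulationConfig <- function(cfg) {
    if (cfg$nComplexes < 0L || cfg$nMonomers < 0L)
        .stopf("counts must be non-negative")
    if (!is.data.frame(cfg$experiments) || nrow(cfg$experiments) == 0L)
        .stopf("'experiments' must be a non-empty data.frame")
    if (!all(c("id", "technique", "nFractions") %in% names(cfg$experiments)))
        .stopf("'experiments' needs columns id, technique, nFractions")
    if (!all(cfg$experiments$technique %in% c("SEC", "IEX", "SDGC")))
        .stopf("unrecognised technique in experiment list")
    if (any(cfg$experiments$nFractions < 10L))
        .stopf("every experiment needs >= 10 fractions")
    for (p in c("dropoutProb", "degradedFraction"))
        if (cfg[[p]] < 0 || cfg[[p]] > 1)
            .stopf("'%s' must lie in [0, 1]", p)
    if (cfg$elutionSigma <= 0) .stopf("'elutionSigma' must be positive")
    if (cfg$backgroundRate < 0) .stopf("'backgroundRate' must be >= 0")
    if (diff(cfg$massRangeKda) < 0 || any(cfg$massRangeKda <= 0))
        .stopf("invalid 'massRangeKda'")
    invisible(cfg)
}

#' @rdname simulationConfig
#' @export
defaultExperiments <- function() {
    data.frame(id = c("SEC24", "SEC45", "IEX43", "SDGC24"),
               technique = c("SEC", "SEC", "IEX", "SDGC"),
               nFractions = c(24L, 45L, 43L, 24L),
               stringsAsFactors = FALSE)
}

#' The simulator's mass calibration for a mass-ordered separation
#'
#' The generator places SEC and SDGC elution peaks with a log-linear
#' fraction-to-mass law spanning \code{massRangeKda[2]} kDa at fraction 1
#' down to \code{massRangeKda[1]} kDa at the last fraction. This is the
#' ground-truth line that \code{\link{fitCalibration}} recovers from the
#' emitted standards.
#'
#' @param nFractions number of fractions in the experiment.
#' @param massRangeKda mass range from last to first fraction.
#' @return A \linkS4class{CalibrationModel} with \code{rSquared = 1}.
#' @export
simulatorCalibration <- function(nFractions, massRangeKda = c(5, 2000)) {
    slope <- (log10(massRangeKda[1L]) - log10(massRangeKda[2L])) /
        (nFractions - 1)
    new("CalibrationModel", slope = slope,
        intercept = log10(massRangeKda[2L]) - slope,
        rSquared = 1, nStandards = 2L)
}

# SEC protein standards (kDa): the classical calibration ladder.
.calibrationStandardMasses <- c(thyroglobulin = 669, BSA = 66.4,
                                albumin_egg = 44.3, myoglobin = 17)

#' Simulated SEC calibration standards
#'
#' Peak fractions of the standard protein ladder under a calibration line,
#' optionally jittered by Gaussian peak-location noise to emulate
#' sub-fraction peak-estimation error.
#'
#' @param model a \linkS4class{CalibrationModel}.
#' @param jitterSd standard deviation of peak-fraction noise, in fractions.
#' @param seed RNG seed used when \code{jitterSd > 0}.
#' @return data.frame with columns \code{standard}, \code{massKda},
#'   \code{peakFraction}.
#' @export
simulateCalibrationStandards <- function(model, jitterSd = 0, seed = 1L) {
    m <- .calibrationStandardMasses
    pf <- peakFraction(model, m)
    if (jitterSd > 0)
        pf <- withr::with_seed(seed,
            pf + stats::rnorm(length(pf), sd = jitterSd))
    data.frame(standard = names(m), massKda = unname(m),
               peakFraction = unname(pf), stringsAsFactors = FALSE)
}

#' Generate the planted ground truth of a synthetic study
#'
#' Samples monomer masses, assembles complexes of truncated-geometric sizes
#' with assembly mass equal to the sum of member monomer masses
#' (stoichiometry 1), draws log-normal abundances (shared within a
#' complex so members co-elute with identical expected profiles), and flags
#' a degraded subpopulation. Deterministic for a fixed seed.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return A \linkS4class{GroundTruth}.
#' @examples
#' truth <- generateGroundTruth(simulationConfig(nComplexes = 3,
#'                                               nMonomers = 5, seed = 1))
#' truePairs(truth)
#' @export
generateGroundTruth <- function(config) {
    .validateSimulationConfig(config)
    withr::with_seed(config$seed, .generateGroundTruthImpl(config))
}

.generateGroundTruthImpl <- function(config) {
    if (is.null(config$complexSizes)) {
        lo <- config$complexSizeRange[1L]; hi <- config$complexSizeRange[2L]
        support <- lo:hi
        prob <- (1 - config$complexSizeGeomP)^(support - lo)
        sizes <- if (config$nComplexes > 0L)
            sample(support, config$nComplexes, replace = TRUE,
                   prob = prob / sum(prob)) else integer()
    } else {
        sizes <- rep_len(as.integer(config$complexSizes), config$nComplexes)
    }
    nProt <- sum(sizes) + config$nMonomers
    ids <- sprintf("P%04d", seq_len(nProt))
    mass <- stats::runif(nProt, config$massRangeKda[1L],
                         config$massRangeKda[2L])
    complexOf <- rep(NA_character_, nProt)
    complexes <- list()
    at <- 1L
    for (k in seq_along(sizes)) {
        nm <- sprintf("CPX%03d", k)
        mem <- ids[at:(at + sizes[k] - 1L)]
        complexes[[nm]] <- mem
        complexOf[at:(at + sizes[k] - 1L)] <- nm
        at <- at + sizes[k]
    }
    complexMass <- vapply(complexes, function(mem)
        sum(mass[match(mem, ids)]), numeric(1))
    complexAbundance <- stats::setNames(
        stats::rlnorm(length(complexes),
                      meanlog = log(config$meanTotalCounts), sdlog = 1),
        names(complexes))
    abundance <- stats::rlnorm(nProt,
                               meanlog = log(config$meanTotalCounts),
                               sdlog = 1)
    inCpx <- !is.na(complexOf)
    abundance[inCpx] <- complexAbundance[complexOf[inCpx]]
    nDeg <- round(config$degradedFraction * nProt)
    degraded <- rep(FALSE, nProt)
    if (nDeg > 0L) degraded[sample(nProt, nDeg)] <- TRUE
    new("GroundTruth",
        proteinTable = data.frame(id = ids, massKda = mass,
                                  complex = complexOf, degraded = degraded,
                                  abundance = abundance,
                                  stringsAsFactors = FALSE),
        complexes = complexes,
        complexMass = complexMass,
        complexAbundance = complexAbundance)
}

# Continuous elution-peak position of every protein in one experiment.
# Mass-ordered techniques place peaks by the calibration inverse of the
# eluting species mass (complex mass, monomer mass, or 0.4x monomer mass
# for degraded proteins); IEX draws one peak per complex (a pI proxy)
# independent of mass, shared by members, with free draws for monomers and
# degraded proteins. Call under an established RNG state.
.peakPositions <- function(truth, technique, nFractions, config) {
    pt <- truth@proteinTable
    n <- nrow(pt)
    if (technique %in% c("SEC", "SDGC")) {
        cal <- simulatorCalibration(nFractions, config$calMassRangeKda)
        elutingMass <- pt$massKda
        inCpx <- !is.na(pt$complex) & !pt$degraded
        elutingMass[inCpx] <- truth@complexMass[pt$complex[inCpx]]
        elutingMass[pt$degraded] <- 0.4 * pt$massKda[pt$degraded]
        mu <- peakFraction(cal, elutingMass)
    } else {   # IEX: mass-independent, shared within a complex
        cpxPeak <- stats::setNames(
            stats::runif(length(truth@complexes), 1, nFractions),
            names(truth@complexes))
        mu <- stats::runif(n, 1, nFractions)
        inCpx <- !is.na(pt$complex) & !pt$degraded
        mu[inCpx] <- cpxPeak[pt$complex[inCpx]]
    }
    pmin(pmax(mu, 1), nFractions)
}

#' Simulate one separation experiment
#'
#' Places a Gaussian elution peak per protein (see Details), scales the
#' kernel to the protein's abundance, draws Poisson spectral counts, thins
#' them by per-cell dropout and adds Poisson background contamination.
#'
#' Mass-ordered techniques (SEC, SDGC) put the peak at the calibration
#' inverse of the eluting species' mass: the assembly mass for complexed
#' proteins, the monomer mass for free monomers, and 0.4x the monomer mass
#' for degraded proteins (so their true Rapp is 0.4). IEX places one
#' mass-independent peak per complex, shared by its members.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param technique \code{"SEC"}, \code{"IEX"} or \code{"SDGC"}.
#' @param nFractions number of fractions (>= 10).
#' @param config the \code{\link{simulationConfig}} (noise parameters).
#' @param experimentId label for the resulting matrix.
#' @param seed RNG seed for this experiment's draws.
#' @return A \linkS4class{ProfileMatrix}.
#' @export
simulateExperiment <- function(truth, technique, nFractions, config,
                               experimentId = paste0(technique, nFractions),
                               seed = config$seed) {
    if (!technique %in% c("SEC", "IEX", "SDGC"))
        .stopf("unrecognised technique '%s'", technique)
    if (nFractions < 10L) .stopf("need >= 10 fractions")
    withr::with_seed(seed, {
        pt <- truth@proteinTable
        n <- nrow(pt)
        mu <- .peakPositions(truth, technique, nFractions, config)
        fr <- seq_len(nFractions)
        kernel <- t(vapply(mu, function(m) {
            k <- exp(-(fr - m)^2 / (2 * config$elutionSigma^2))
            k / sum(k)
        }, numeric(nFractions)))
        lambda <- kernel * pt$abundance
        m <- matrix(stats::rpois(n * nFractions, lambda), n, nFractions)
        if (config$dropoutProb > 0) {
            drop <- matrix(stats::runif(n * nFractions) < config$dropoutProb,
                           n, nFractions)
            m[drop] <- 0L
        }
        if (config$backgroundRate > 0)
            m <- m + matrix(stats::rpois(n * nFractions,
                                         config$backgroundRate),
                            n, nFractions)
        rownames(m) <- pt$id
        ProfileMatrix(m, experimentId, technique)
    })
}

#' Simulate the full experiment set of a configuration
#'
#' Runs \code{\link{simulateExperiment}} for every row of
#' \code{config$experiments}, each with a seed derived from the global seed
#' so the whole dataset is reproducible.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param config a \code{\link{simulationConfig}}.
#' @return Named list of \linkS4class{ProfileMatrix} objects.
#' @export
simulateDataset <- function(truth, config) {
    ex <- config$experiments
    out <- vector("list", nrow(ex))
    names(out) <- ex$id
    for (i in seq_len(nrow(ex)))
        out[[i]] <- simulateExperiment(truth, ex$technique[i],
                                       ex$nFractions[i], config,
                                       experimentId = ex$id[i],
                                       seed = config$seed + i)
    out
}

#' Write a synthetic study to disk as plain-text fixtures
#'
#' Emits, under \code{dir}: one fraction table per experiment
#' (\code{<id>.profiles.tsv}), the monomer-mass table
#' (\code{monomer_masses.tsv}), SEC calibration standards per SEC
#' experiment (\code{calibration_standards.tsv}), the planted complexes in
#' reference-complex format (\code{reference_complexes.tsv}) and the true
#' within-complex pair list (\code{true_pairs.tsv}). All files round-trip
#' losslessly through \code{\link{readFixture}}.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param matrices named list of \linkS4class{ProfileMatrix} objects.
#' @param dir output directory (created if absent).
#' @param calMassRangeKda calibration span used for the standards tables.
#' @return Invisibly, the vector of files written.
#' @export
writeFixture <- function(truth, matrices, dir,
                         calMassRangeKda = c(5, 2000)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    written <- character()
    for (m in matrices) {
        cts <- counts(m)
        df <- data.frame(id = rownames(cts), cts, check.names = FALSE,
                         stringsAsFactors = FALSE)
        p <- file.path(dir, paste0(experimentId(m), ".profiles.tsv"))
        .writeTsv(df, p); written <- c(written, p)
    }
    pt <- truth@proteinTable
    p <- file.path(dir, "monomer_masses.tsv")
    .writeTsv(data.frame(id = pt$id, massKda = pt$massKda), p)
    written <- c(written, p)
    std <- do.call(rbind, lapply(matrices, function(m) {
        if (technique(m) != "SEC") return(NULL)
        s <- simulateCalibrationStandards(
            simulatorCalibration(ncol(m), calMassRangeKda))
        cbind(experiment = experimentId(m), s)
    }))
    p <- file.path(dir, "calibration_standards.tsv")
    if (is.null(std))
        std <- data.frame(experiment = character(), standard = character(),
                          massKda = numeric(), peakFraction = numeric())
    .writeTsv(std, p); written <- c(written, p)
    p <- file.path(dir, "reference_complexes.tsv")
    lines <- vapply(names(truth@complexes), function(nm)
        paste(c(nm, truth@complexes[[nm]]), collapse = "\t"), character(1))
    writeLines(unname(lines), p); written <- c(written, p)
    p <- file.path(dir, "true_pairs.tsv")
    .writeTsv(truePairs(truth), p); written <- c(written, p)
    invisible(written)
}

#' Read a fixture directory written by writeFixture
#'
#' @param dir fixture directory.
#' @return list with \code{matrices} (named list of
#'   \linkS4class{ProfileMatrix}), \code{monomerMass} (named numeric),
#'   \code{standards} (data.frame), \code{referenceComplexes}
#'   (\linkS4class{ReferenceComplexSet} or \code{NULL} when empty) and
#'   \code{truePairs} (data.frame).
#' @export
readFixture <- function(dir) {
    profs <- sort(list.files(dir, pattern = "\\.profiles\\.tsv$",
                             full.names = TRUE))
    matrices <- lapply(profs, readFractionTable)
    names(matrices) <- vapply(matrices, experimentId, character(1))
    mm <- .readTsv(file.path(dir, "monomer_masses.tsv"))
    monomerMass <- stats::setNames(mm$massKda, mm$id)
    standards <- .readTsv(file.path(dir, "calibration_standards.tsv"))
    cpxPath <- file.path(dir, "reference_complexes.tsv")
    refset <- if (length(readLines(cpxPath)) > 0L)
        readComplexFile(cpxPath) else NULL
    tp <- .readTsv(file.path(dir, "true_pairs.tsv"))
    tp$idA <- as.character(tp$idA); tp$idB <- as.character(tp$idB)
    list(matrices = matrices, monomerMass = monomerMass,
         standards = standards, referenceComplexes = refset,
         truePairs = tp)
}
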