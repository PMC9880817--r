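#' Configuration for the end-to-end analysis pipeline
#'
#' Collects every stage parameter in one serialisable object. Unknown
#' arguments are rejected (there are no \code{...}).
#'
#' @param sim a \code{\link{simulationConfig}} describing the synthetic
#'   study (ignored when \code{inputDir} is supplied to
#'   \code{\link{runPipeline}}).
#' @param minPsm minimum peak spectral count (\code{\link{filterMinPsm}}).
#' @param window profile smoothing window.
#' @param prefilter strict elution-similarity cut (best cross-experiment
#'   Pearson must exceed it).
#' @param nBins mutual-information bins.
#' @param alpha Bayes-correlation pseudocount.
#' @param aggregate cross-experiment feature aggregation
#'   (\code{"mean"}/\code{"max"}).
#' @param negativeRatio negative:positive subsampling ratio for training
#'   labels.
#' @param kFolds complex-level cross-validation folds.
#' @param ntree random-forest size.
#' @param threshold classifier probability cut defining the retained
#'   network.
#' @param p cohesiveness penalty.
#' @param mergeThreshold overlap score at which candidate clusters merge.
#' @param minSize,minDensity complex filters.
#' @param seed global pipeline seed (defaults to \code{sim$seed}).
#' @return A validated list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(sim = simulationConfig(),
                           minPsm = 2L, window = 3L, prefilter = 0.5,
                           nBins = 5L, alpha = 1,
                           aggregate = c("mean", "max"),
                           negativeRatio = 5, kFolds = 5L, ntree = 500L,
                           threshold = 0.5, p = 2, mergeThreshold = 0.8,
                           minSize = 3L, minDensity = 0.3, seed = NULL) {
    cfg <- list(sim = sim, minPsm = as.integer(minPsm),
                window = as.integer(window), prefilter = prefilter,
                nBins = as.integer(nBins), alpha = alpha,
                aggregate = match.arg(aggregate),
                negativeRatio = negativeRatio, kFolds = as.integer(kFolds),
                ntree = as.integer(ntree), threshold = threshold,
                p = p, mergeThreshold = mergeThreshold,
                minSize = as.integer(minSize), minDensity = minDensity,
                seed = as.integer(if (is.null(seed)) sim$seed else seed))
    if (cfg$threshold < 0 || cfg$threshold > 1)
        .stopf("'threshold' must lie in [0, 1]")
    class(cfg) <- "PipelineConfig"
    cfg
}

.logStage <- function(verbose, fmt, ...) {
    if (verbose) message(sprintf(paste0("[cofrac] ", fmt), ...))
}

#' Run the full co-fractionation analysis pipeline
#'
#' Executes, in order: data simulation (or fixture import), the
#' minimum-PSM filter, SEC calibration and Rapp-based state calling (with
#' removal of degraded proteins), five-feature pair scoring with the
#' similarity pre-filter, gold-standard label derivation, complex-level
#' cross-validated classifier evaluation, full-data training and network
#' scoring, cohesiveness clustering into complexes, and post-inference
#' network statistics. All artifacts are written to \code{outDir} as
#' plain-text tables plus a machine-readable JSON summary and a manifest
#' recording the configuration and seed; reruns with the same
#' configuration reproduce the outputs byte for byte.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory; created if needed. \code{NULL} skips
#'   writing.
#' @param inputDir optional fixture directory from
#'   \code{\link{writeFixture}}; when given, profiles, masses, standards
#'   and the reference complex set are read from it instead of being
#'   simulated.
#' @param verbose log per-stage progress to stderr.
#' @return Invisibly, a list with all intermediate objects
#'   (\code{truth}, \code{matrices}, \code{retained}, \code{rapp},
#'   \code{featureTable}, \code{labels}, \code{cv}, \code{model},
#'   \code{network}, \code{complexes}, \code{stats}, \code{summary}).
#' @export
runPipeline <- function(config, outDir = NULL, inputDir = NULL,
                        verbose = TRUE) {
    stopifnot(inherits(config, "PipelineConfig"))
    t0 <- Sys.time()

    if (is.null(inputDir)) {
        .logStage(verbose, "simulating study (seed %d)", config$sim$seed)
        truth <- generateGroundTruth(config$sim)
        matrices <- simulateDataset(truth, config$sim)
        monomerMass <- monomerMasses(truth)
        refComplexes <- complexes(truth)
        truthPairs <- truePairs(truth)
        models <- list()
        for (m in matrices)
            if (technique(m) == "SEC")
                models[[experimentId(m)]] <- fitCalibration(
                    simulateCalibrationStandards(simulatorCalibration(
                        ncol(m), config$sim$calMassRangeKda)))
    } else {
        .logStage(verbose, "reading fixture from %s", inputDir)
        fx <- readFixture(inputDir)
        truth <- NULL
        matrices <- fx$matrices
        monomerMass <- fx$monomerMass
        refComplexes <- if (!is.null(fx$referenceComplexes))
            complexes(fx$referenceComplexes) else list()
        truthPairs <- fx$truePairs
        models <- list()
        for (eid in unique(fx$standards$experiment))
            models[[eid]] <- fitCalibration(
                fx$standards[fx$standards$experiment == eid, , drop = FALSE])
    }
    .logStage(verbose, "%d experiments, %d proteins",
              length(matrices), length(monomerMass))

    flt <- filterMinPsm(matrices, minPsm = config$minPsm)
    .logStage(verbose, "PSM filter (>= %d): %d of %d proteins retained",
              config$minPsm, length(flt$retained), nrow(flt$log))

    rapp <- rappTable(matrices, monomerMass, models, window = config$window)
    degraded <- rapp$id[!is.na(rapp$state) & rapp$state == "degraded"]
    retained <- setdiff(flt$retained, degraded)
    .logStage(verbose, "Rapp: %d degraded proteins discarded; %d remain",
              length(degraded), length(retained))

    featureTable <- buildFeatureTable(matrices, retained,
                                      prefilter = config$prefilter,
                                      nBins = config$nBins,
                                      alpha = config$alpha,
                                      window = config$window,
                                      aggregate = config$aggregate)
    .logStage(verbose, "features: %d candidate pairs pass the pre-filter",
              nrow(featureTable))

    refset <- suppressWarnings(
        referenceComplexSet(refComplexes, universe = retained))
    labels <- deriveLabels(refset, featureTable,
                           negativeRatio = config$negativeRatio,
                           seed = config$seed)
    .logStage(verbose, "labels: %d positives, %d negatives, %d unlabeled",
              nrow(labels$positives), nrow(labels$negatives),
              nrow(labels$unlabeled))

    folds <- complexLevelFolds(refset,
                               k = min(config$kFolds, length(refset)),
                               seed = config$seed)
    pairFolds <- assignPairFolds(labels, refset, folds)
    cv <- crossValidatePPIClassifier(featureTable, pairFolds,
                                     ntree = config$ntree,
                                     seed = config$seed)
    .logStage(verbose, "cross-validated AUC = %.3f", cv$auc)

    model <- trainPPIClassifier(featureTable, labels,
                                ntree = config$ntree, seed = config$seed)
    network <- scoreNetwork(model, featureTable,
                            threshold = config$threshold)
    .logStage(verbose, "network: %d nodes, %d edges at threshold %.2f",
              length(nodes(network)), nrow(edges(network)),
              config$threshold)

    complexSet <- detectComplexes(network, p = config$p,
                                  mergeThreshold = config$mergeThreshold,
                                  minSize = config$minSize,
                                  minDensity = config$minDensity)
    cpxPPIs <- complexSupportedPPIs(network, complexSet)
    .logStage(verbose, "complexes: %d predicted, %d complex-supported PPIs",
              length(complexSet), nrow(cpxPPIs))

    deg <- degreeDistribution(network)
    netOverlap <- if (nrow(edges(network)) && nrow(truthPairs))
        overlapWithReference(edges(network), truthPairs)
    else list(fraction = NA_real_, nEdges = nrow(edges(network)),
              nOverlap = 0L)
    recovery <- if (length(refComplexes))
        complexRecovery(complexSet,
                        referenceComplexSet(refComplexes),
                        jaccardMin = 0.5, minSize = 3L)
    else list(recoveryRate = NA_real_)

    summary_ <- list(
        nProteins = length(monomerMass),
        nRetained = length(flt$retained),
        nDegraded = length(degraded),
        nCandidatePairs = nrow(featureTable),
        nPositives = nrow(labels$positives),
        nNegatives = nrow(labels$negatives),
        auc = cv$auc,
        nEdges = nrow(edges(network)),
        nNetworkProteins = length(nodes(network)),
        trueEdgeFraction = netOverlap$fraction,
        nComplexes = length(complexSet),
        nComplexPPIs = nrow(cpxPPIs),
        complexRecovery = recovery$recoveryRate,
        medianDegree = stats::median(deg$table$degree))

    result <- list(truth = truth, matrices = matrices, retained = retained,
                   rapp = rapp, models = models,
                   featureTable = featureTable, labels = labels,
                   folds = folds, cv = cv, model = model,
                   network = network, complexes = complexSet,
                   complexPPIs = cpxPPIs,
                   stats = list(degrees = deg, overlap = netOverlap,
                                recovery = recovery),
                   summary = summary_)

    if (!is.null(outDir)) {
        if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
        writeFeatureTable(featureTable, file.path(outDir, "features.tsv"))
        .writeTsv(rapp, file.path(outDir, "rapp.tsv"))
        .writeTsv(cv$roc, file.path(outDir, "roc.tsv"))
        .writeTsv(edges(network), file.path(outDir, "network_edges.tsv"))
        .writeTsv(deg$table, file.path(outDir, "degrees.tsv"))
        cpx <- complexes(complexSet)
        writeLines(vapply(seq_along(cpx), function(i)
            paste(c(names(cpx)[i], cpx[[i]]), collapse = "\t"),
            character(1)), file.path(outDir, "complexes.tsv"))
        .writeTsv(cpxPPIs, file.path(outDir, "complex_ppis.tsv"))
        jsonlite::write_json(summary_, file.path(outDir, "summary.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        manifest <- list(package = "CoFracPPI",
                         seed = config$seed,
                         config = unclass(config)[setdiff(names(config),
                                                          "sim")],
                         sim = unclass(config$sim)[
                             setdiff(names(unclass(config$sim)),
                                     "experiments")],
                         experiments = config$sim$experiments)
        jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    .logStage(verbose, "done in %.1f s",
              as.numeric(difftime(Sys.time(), t0, units = "secs")))
    invisible(result)
}
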