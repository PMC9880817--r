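#' Fit the SEC mass calibration from protein standards
#'
#' Size-exclusion chromatography separates by hydrodynamic size, and over the
#' useful range of a column the peak (apex) fraction of a species is linear
#' in the logarithm of its molecular mass. Protein standards of known mass
#' (classically thyroglobulin, BSA, egg albumin and myoglobin) run with the
#' same method anchor the line
#' \deqn{\log_{10}(M_{kDa}) = a \cdot fraction + b,}
#' fitted here by ordinary least squares.
#'
#' @param standards data.frame with columns \code{massKda} and
#'   \code{peakFraction}, one row per standard. Peak fractions may be
#'   fractional (sub-fraction peak interpolation).
#' @return A \linkS4class{CalibrationModel}.
#' @examples
#' std <- data.frame(massKda = c(100, 10), peakFraction = c(10, 20))
#' fitCalibration(std)   # slope -0.1, intercept 3
#' @seealso \code{\link{apparentMass}}, \code{\link{peakFraction}}
#' @export
fitCalibration <- function(standards) {
    if (!all(c("massKda", "peakFraction") %in% names(standards)))
        .stopf("'standards' needs columns 'massKda' and 'peakFraction'")
    standards <- standards[is.finite(standards$massKda) &
                           is.finite(standards$peakFraction), , drop = FALSE]
    if (length(unique(standards$peakFraction)) < 2L)
        .stopf("calibration needs >= 2 standards with distinct peak fractions")
    if (any(standards$massKda <= 0))
        .stopf("standard masses must be positive")
    fit <- stats::lm(log10(massKda) ~ peakFraction, data = standards)
    new("CalibrationModel",
        slope = unname(stats::coef(fit)[2L]),
        intercept = unname(stats::coef(fit)[1L]),
        rSquared = suppressWarnings(summary(fit)$r.squared),
        nStandards = nrow(standards))
}

#' Predicted peak fraction for a species of given mass
#'
#' Inverts the calibration line: the fraction at which a species of mass
#' \code{massKda} is expected to elute. Used by the simulator to place
#' elution peaks on mass-ordered separations.
#'
#' @param model a \linkS4class{CalibrationModel}.
#' @param massKda molecular mass(es) in kDa.
#' @return Continuous (unrounded) fraction positions.
#' @export
peakFraction <- function(model, massKda) {
    stopifnot(is(model, "CalibrationModel"))
    (log10(massKda) - model@intercept) / model@slope
}

#' Mass at a given fraction under a calibration model
#'
#' @param model a \linkS4class{CalibrationModel}.
#' @param fraction fraction index (may be fractional).
#' @return Mass in kDa.
#' @export
massAtFraction <- function(model, fraction) {
    stopifnot(is(model, "CalibrationModel"))
    10^(model@slope * fraction + model@intercept)
}

#' Apex fraction of an elution profile
#'
#' Index of the profile maximum; ties resolve to the earliest fraction
#' (under a negative calibration slope, the largest mass).
#'
#' @param profile numeric elution profile over ordered fractions.
#' @return Integer fraction index, or \code{NA} with a warning of class
#'   \code{undefinedMassWarning} when the profile is all zero.
#' @export
apexFraction <- function(profile) {
    if (all(profile == 0) || all(!is.finite(profile))) {
        w <- simpleWarning("all-zero profile: apex (and mass) undefined")
        class(w) <- c("undefinedMassWarning", class(w))
        warning(w)
        return(NA_integer_)
    }
    which.max(profile)   # which.max takes the first (earliest) maximum
}

#' Apparent molecular mass from an elution profile
#'
#' Evaluates the calibration line at the profile's apex fraction:
#' \eqn{M_{app} = 10^{a \cdot apex + b}}. The apex of a smoothed profile is
#' used rather than a fitted peak centroid.
#'
#' @param profile numeric elution profile (normalised/smoothed counts) over
#'   the ordered SEC fractions.
#' @param model a \linkS4class{CalibrationModel}.
#' @return Apparent mass in kDa (\code{NA} for an all-zero profile, with an
#'   \code{undefinedMassWarning}).
#' @export
apparentMass <- function(profile, model) {
    apex <- apexFraction(profile)
    if (is.na(apex)) return(NA_real_)
    massAtFraction(model, apex)
}

#' Classify oligomerisation state from the Rapp ratio
#'
#' Rapp is the ratio of the apparent mass observed on SEC to the predicted
#' monomer mass. Rapp >= 2 indicates the protein ran as part of a stable
#' assembly (complexed); Rapp <= 0.5 indicates degradation during
#' extraction, and such proteins are discarded before pair scoring;
#' 0.5 < Rapp < 2 is consistent with a monomer.
#'
#' @param mappKda apparent mass(es), kDa.
#' @param mmonoKda monomer mass(es), kDa; must be positive.
#' @param id optional protein ids for the output table.
#' @return data.frame with columns \code{id}, \code{mappKda},
#'   \code{mmonoKda}, \code{rapp} and \code{state} (factor with levels
#'   complexed, monomeric, degraded); \code{NA} apparent masses yield
#'   \code{NA} state.
#' @examples
#' classifyState(c(200, 50, 100), c(100, 100, 100))
#' @export
classifyState <- function(mappKda, mmonoKda, id = NULL) {
    if (any(!is.finite(mmonoKda)) || any(mmonoKda <= 0))
        .stopf("monomer masses must be positive and finite")
    n <- max(length(mappKda), length(mmonoKda))
    mappKda <- rep_len(mappKda, n)
    mmonoKda <- rep_len(mmonoKda, n)
    if (is.null(id)) id <- paste0("protein", seq_len(n))
    rapp <- mappKda / mmonoKda
    state <- ifelse(rapp >= 2, "complexed",
             ifelse(rapp <= 0.5, "degraded", "monomeric"))
    data.frame(id = as.character(id), mappKda = mappKda,
               mmonoKda = mmonoKda, rapp = rapp,
               state = factor(state,
                              levels = c("complexed", "monomeric", "degraded")),
               stringsAsFactors = FALSE)
}

#' Per-protein Rapp table from SEC experiments
#'
#' Computes each protein's apparent mass from its smoothed SEC elution
#' profile and classifies its oligomerisation state by Rapp. With several
#' SEC experiments the profile with the largest single-fraction count is
#' used (the most confidently observed elution); ties fall to the first
#' experiment in the list.
#'
#' @param matrices list of \linkS4class{ProfileMatrix} objects; non-SEC
#'   entries are ignored (IEX and SDGC carry no mass axis here).
#' @param monomerMass named numeric vector of monomer masses (kDa).
#' @param models a single \linkS4class{CalibrationModel}, or a named list
#'   of models keyed by SEC experiment id (each SEC column has its own
#'   fraction-to-mass line).
#' @param window smoothing window passed to
#'   \code{\link{normalizeAndSmooth}}.
#' @return data.frame as \code{\link{classifyState}}, one row per protein
#'   observed in at least one SEC experiment with a known monomer mass.
#' @export
rappTable <- function(matrices, monomerMass, models, window = 3L) {
    sec <- Filter(function(m) technique(m) == "SEC", matrices)
    if (!length(sec)) .stopf("no SEC experiment supplied")
    if (is(models, "CalibrationModel")) {
        models <- stats::setNames(
            rep(list(models), length(sec)),
            vapply(sec, experimentId, character(1)))
    }
    missing <- setdiff(vapply(sec, experimentId, character(1)),
                       names(models))
    if (length(missing))
        .stopf("no calibration model for SEC experiment(s): %s",
               paste(missing, collapse = ", "))
    best <- list()   # per protein: (maxCount, profile, experiment)
    for (m in sec) {
        cts <- counts(m)
        eid <- experimentId(m)
        for (i in seq_len(nrow(cts))) {
            id <- rownames(cts)[i]
            mx <- max(cts[i, ])
            if (mx == 0) next
            if (is.null(best[[id]]) || mx > best[[id]]$max)
                best[[id]] <- list(max = mx, profile = cts[i, ],
                                   experiment = eid)
        }
    }
    ids <- intersect(names(best), names(monomerMass))
    mapp <- vapply(ids, function(id) {
        prof <- normalizeAndSmooth(best[[id]]$profile, window = window)
        apparentMass(prof, models[[best[[id]]$experiment]])
    }, numeric(1))
    classifyState(mapp, monomerMass[ids], id = ids)
}
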