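#' @import methods
NULL

#' Parameters of a simulated cohort
#'
#' Describes the generating process for one species x temperature cohort:
#' a per-interval death probability schedule (given directly or as a
#' Gompertz hazard pair), an age-indexed expected-fecundity schedule, the
#' census interval in days, and a safety cap on the number of intervals.
#'
#' @slot speciesLabel single character label.
#' @slot temperature treatment temperature in degrees Celsius.
#' @slot nIndividuals number of females in the cohort.
#' @slot censusInterval census spacing in days (0.5 = every 12 h).
#' @slot hazardType `"q"` (explicit per-interval death probabilities) or
#'   `"gompertz"` (hazard `a * exp(b * t)` in units of 1/day).
#' @slot q per-interval death probabilities; recycled by carrying the last
#'   value forward to `maxIntervals`.
#' @slot gompertz numeric `c(a, b)`, used when `hazardType == "gompertz"`.
#' @slot fecundity expected offspring per interval; padded with zeros to
#'   `maxIntervals`.
#' @slot maxIntervals cap on observed intervals; survivors at the cap are
#'   censored there.
#' @seealso [cohortParams()], [analyticSchedule()], [simulateCohort()]
#' @exportClass CohortParams
setClass("CohortParams", slots = c(
    speciesLabel = "character",
    temperature = "numeric",
    nIndividuals = "integer",
    censusInterval = "numeric",
    hazardType = "character",
    q = "numeric",
    gompertz = "numeric",
    fecundity = "numeric",
    maxIntervals = "integer"
))

setValidity("CohortParams", function(object) {
    msg <- character()
    if (length(object@speciesLabel) != 1L || is.na(object@speciesLabel) ||
        !nzchar(object@speciesLabel))
        msg <- c(msg, "'speciesLabel' must be a single non-empty string")
    if (length(object@temperature) != 1L || !is.finite(object@temperature))
        msg <- c(msg, "'temperature' must be a single finite number")
    if (length(object@nIndividuals) != 1L || is.na(object@nIndividuals) ||
        object@nIndividuals < 1L)
        msg <- c(msg, "'nIndividuals' must be >= 1")
    if (length(object@censusInterval) != 1L ||
        !is.finite(object@censusInterval) || object@censusInterval <= 0)
        msg <- c(msg, "'censusInterval' must be > 0")
    if (!object@hazardType %in% c("q", "gompertz"))
        msg <- c(msg, "'hazardType' must be \"q\" or \"gompertz\"")
    if (object@hazardType == "q") {
        if (length(object@q) < 1L || anyNA(object@q) ||
            any(object@q < 0 | object@q > 1))
            msg <- c(msg, "all per-interval death probabilities must lie in [0, 1]")
    } else {
        if (length(object@gompertz) != 2L || anyNA(object@gompertz) ||
            object@gompertz[1L] <= 0 || object@gompertz[2L] < 0)
            msg <- c(msg, "Gompertz hazard needs a > 0 and b >= 0")
    }
    if (anyNA(object@fecundity) || any(object@fecundity < 0))
        msg <- c(msg, "all fecundity values must be >= 0")
    if (length(object@maxIntervals) != 1L || is.na(object@maxIntervals) ||
        object@maxIntervals < 1L)
        msg <- c(msg, "'maxIntervals' must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Individual-level life-history records
#'
#' One row group per female: the interval in which she died (1-based,
#' interval `j` spanning ages `[(j-1), j] * censusInterval` days), a
#' censoring flag for individuals still alive at the observation cap, and
#' her per-interval offspring counts. All individuals enter at age 0.
#'
#' @slot id individual identifiers (unique).
#' @slot species species label per individual.
#' @slot temperature treatment temperature per individual, degrees C.
#' @slot deathInterval 1-based interval of death; for censored individuals,
#'   the last interval through which they were observed alive.
#' @slot censored TRUE if alive at the end of `deathInterval` (observation
#'   cap reached).
#' @slot offspring integer matrix, individuals x intervals; entries after
#'   the death interval are zero.
#' @slot censusInterval census spacing in days.
#' @seealso [simulateCohort()], [buildLifeTable()], [readLifeRecords()]
#' @exportClass LifeRecords
setClass("LifeRecords", slots = c(
    id = "character",
    species = "character",
    temperature = "numeric",
    deathInterval = "integer",
    censored = "logical",
    offspring = "matrix",
    censusInterval = "numeric"
))

setValidity("LifeRecords", function(object) {
    n <- length(object@id)
    msg <- character()
    if (anyDuplicated(object@id))
        msg <- c(msg, "individual ids must be unique")
    if (length(object@species) != n || length(object@temperature) != n ||
        length(object@deathInterval) != n || length(object@censored) != n)
        msg <- c(msg, "per-individual slots must all have the same length")
    if (n > 0L && nrow(object@offspring) != n)
        msg <- c(msg, "'offspring' must have one row per individual")
    if (length(object@censusInterval) != 1L || object@censusInterval <= 0)
        msg <- c(msg, "'censusInterval' must be a single value > 0")
    if (n > 0L) {
        if (anyNA(object@deathInterval) || any(object@deathInterval < 1L))
            msg <- c(msg, "'deathInterval' must be >= 1")
        off <- object@offspring
        if (anyNA(off) || any(off < 0) || any(off != floor(off)))
            msg <- c(msg, "offspring counts must be non-negative integers")
        if (ncol(off) > 0L) {
            ivl <- col(off)
            if (any(off[ivl > object@deathInterval[row(off)]] != 0))
                msg <- c(msg, "offspring must be zero after the death interval")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Cohort life table
#'
#' The (x, lx, mx) schedule of a single cohort: age `x` in days at interval
#' starts, survivorship `lx` (proportion of the initial cohort alive at the
#' start of each interval, so `lx[1] == 1`), and age-specific fecundity `mx`
#' (offspring in the interval per female alive at its start).
#'
#' @slot x age at interval starts, days.
#' @slot lx survivorship, non-increasing, in [0, 1], starting at 1.
#' @slot mx per-capita offspring per interval, >= 0.
#' @slot n0 initial cohort size.
#' @slot censusInterval interval width in days.
#' @slot species,temperature treatment labels (NA when unknown/mixed).
#' @seealso [buildLifeTable()], [solveLotka()], [netReproductiveRate()]
#' @exportClass CohortTable
setClass("CohortTable", slots = c(
    x = "numeric",
    lx = "numeric",
    mx = "numeric",
    n0 = "integer",
    censusInterval = "numeric",
    species = "character",
    temperature = "numeric"
))

setValidity("CohortTable", function(object) {
    msg <- character()
    k <- length(object@x)
    if (length(object@lx) != k || length(object@mx) != k)
        msg <- c(msg, "'x', 'lx' and 'mx' must have equal length")
    if (k == 0L)
        msg <- c(msg, "empty life table")
    if (k > 0L) {
        ## schedules starting at age 0 must start at full survivorship;
        ## partial schedules (x[1] > 0) may start below 1
        if (object@x[1L] == 0 && abs(object@lx[1L] - 1) > 1e-12)
            msg <- c(msg, "lx must start at 1 when x starts at age 0")
        if (object@lx[1L] > 1 + 1e-12)
            msg <- c(msg, "lx cannot exceed 1")
        if (any(diff(object@lx) > 1e-12))
            msg <- c(msg, "lx must be non-increasing")
        if (any(object@lx < -1e-12 | object@lx > 1 + 1e-12))
            msg <- c(msg, "lx must lie in [0, 1]")
        if (any(object@mx < 0))
            msg <- c(msg, "mx must be >= 0")
        if (any(diff(object@x) <= 0))
            msg <- c(msg, "x must be strictly increasing")
    }
    if (length(msg)) msg else TRUE
})

#' Demographic analysis result
#'
#' The intrinsic rate of increase solved from the Euler-Lotka renewal
#' equation for one cohort, with its net reproductive rate and a
#' percentile-bootstrap confidence interval obtained by resampling
#' individuals with replacement.
#'
#' @slot r intrinsic rate of increase, per day.
#' @slot residual absolute Euler-Lotka residual at the solution.
#' @slot R0 net reproductive rate (expected lifetime offspring per female).
#' @slot meanLifespan mean individual lifespan, days.
#' @slot ciLow,ciHigh percentile bootstrap bounds for r, per day.
#' @slot ciLevel nominal confidence level.
#' @slot nBoot bootstrap replicates requested.
#' @slot nFailed replicates where the renewal equation had no solution
#'   (e.g. a resample with zero reproduction); excluded from the CI.
#' @slot seed RNG seed used for resampling.
#' @slot replicates solved r of every successful replicate.
#' @seealso [bootstrapR()], [solveLotka()]
#' @exportClass DemographyResult
setClass("DemographyResult", slots = c(
    r = "numeric",
    residual = "numeric",
    R0 = "numeric",
    meanLifespan = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    ciLevel = "numeric",
    nBoot = "integer",
    nFailed = "integer",
    seed = "integer",
    replicates = "numeric"
))

setValidity("DemographyResult", function(object) {
    msg <- character()
    if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
        object@ciLow > object@ciHigh)
        msg <- c(msg, "ciLow must be <= ciHigh")
    if (object@ciLevel <= 0 || object@ciLevel >= 1)
        msg <- c(msg, "ciLevel must lie in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function from (duration, event)
#' data. At each distinct event time `t_i` with `d_i` deaths among `n_i` at
#' risk, survival multiplies by `(1 - d_i / n_i)`.
#'
#' @slot time distinct event (death) times, days.
#' @slot survival estimated survival just after each event time.
#' @slot nRisk number at risk at each event time.
#' @slot nEvent deaths at each event time.
#' @slot n total sample size.
#' @seealso [kmEstimate()], [logrankTest()]
#' @exportClass KMCurve
setClass("KMCurve", slots = c(
    time = "numeric",
    survival = "numeric",
    nRisk = "integer",
    nEvent = "integer",
    n = "integer"
))

setValidity("KMCurve", function(object) {
    msg <- character()
    k <- length(object@time)
    if (length(object@survival) != k || length(object@nRisk) != k ||
        length(object@nEvent) != k)
        msg <- c(msg, "curve slots must have equal length")
    if (k > 0L) {
        if (any(diff(object@time) <= 0))
            msg <- c(msg, "event times must be strictly increasing")
        if (any(diff(object@survival) > 1e-12))
            msg <- c(msg, "survival must be non-increasing")
        if (any(object@survival < -1e-12 | object@survival > 1 + 1e-12))
            msg <- c(msg, "survival must lie in [0, 1]")
        if (any(object@nEvent < 1L))
            msg <- c(msg, "each listed time must carry at least one event")
    }
    if (length(msg)) msg else TRUE
})

#' Table of sequence-similarity hits with database labels
#'
#' BLAST outfmt-6 style hits plus a subject -> database mapping. Exactly
#' one database label is the assignment target (e.g. the host genome);
#' the remaining labels are contaminant databases, optionally including a
#' dedicated rRNA database used for ribosomal-read flagging.
#'
#' @slot hits data.frame with at least `qseqid`, `sseqid`, `evalue`,
#'   `bitscore` (full outfmt-6 columns when read from disk).
#' @slot labels named character vector: `sseqid -> database label`.
#' @slot targetLabel the single target database label.
#' @slot rrnaLabel optional rRNA database label (`character(0)` if none).
#' @seealso [hitTable()], [assignContigs()], [flagRrna()]
#' @exportClass HitTable
setClass("HitTable", slots = c(
    hits = "data.frame",
    labels = "character",
    targetLabel = "character",
    rrnaLabel = "character"
))

setValidity("HitTable", function(object) {
    msg <- character()
    need <- c("qseqid", "sseqid", "evalue", "bitscore")
    if (!all(need %in% names(object@hits)))
        msg <- c(msg, paste("hits must contain columns:",
                            paste(need, collapse = ", ")))
    if (length(object@targetLabel) != 1L)
        msg <- c(msg, "exactly one target label is required")
    if (length(object@rrnaLabel) > 1L)
        msg <- c(msg, "at most one rRNA label is allowed")
    if (nrow(object@hits) > 0L) {
        if (is.null(names(object@labels)) ||
            !all(object@hits$sseqid %in% names(object@labels)))
            msg <- c(msg, "every subject id must carry a database label")
        if (any(object@hits$bitscore < 0))
            msg <- c(msg, "bit scores must be >= 0")
    }
    if (length(object@targetLabel) == 1L && length(object@labels) &&
        !object@targetLabel %in% object@labels)
        msg <- c(msg, "target label absent from the label mapping")
    if (length(msg)) msg else TRUE
})

#' Generalized linear model fit
#'
#' A GLM fitted by iteratively reweighted least squares (gaussian/identity
#' or poisson/log), carrying the log-likelihood and AIC used for model
#' selection. For the gaussian family the dispersion counts as one
#' estimated parameter, so `aic == 2 * (rank + 1) - 2 * logLik`.
#'
#' @slot family "gaussian" or "poisson".
#' @slot coefficients named coefficient vector.
#' @slot fitted fitted means.
#' @slot logLik maximized log-likelihood.
#' @slot deviance residual deviance.
#' @slot aic Akaike information criterion.
#' @slot rank number of estimated linear coefficients.
#' @slot nobs number of observations.
#' @slot converged TRUE if IRLS met the relative-change tolerance.
#' @slot iter IRLS iterations used.
#' @slot formula model formula (or NULL for matrix input).
#' @slot modelName short label used in model-selection output.
#' @seealso [glmFit()], [selectModelAIC()]
#' @exportClass GLMFit
setClass("GLMFit", slots = c(
    family = "character",
    coefficients = "numeric",
    fitted = "numeric",
    logLik = "numeric",
    deviance = "numeric",
    aic = "numeric",
    rank = "integer",
    nobs = "integer",
    converged = "logical",
    iter = "integer",
    formula = "ANY",
    modelName = "character"
))

setValidity("GLMFit", function(object) {
    msg <- character()
    if (!object@family %in% c("gaussian", "poisson"))
        msg <- c(msg, "family must be gaussian or poisson")
    k <- object@rank + as.integer(object@family == "gaussian")
    if (is.finite(object@aic) && is.finite(object@logLik) &&
        abs(object@aic - (2 * k - 2 * object@logLik)) > 1e-6)
        msg <- c(msg, "aic inconsistent with 2k - 2 logLik")
    if (length(msg)) msg else TRUE
})
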