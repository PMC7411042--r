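#' Construct cohort generating parameters
#'
#' Defines the stochastic process behind one simulated cohort. Mortality is
#' resolved at the census granularity: an individual alive at the start of
#' interval `j` dies within it with probability `q[j]`. The hazard can be
#' given directly as those per-interval probabilities, or as a Gompertz
#' pair `c(a, b)` (hazard `a * exp(b * t)` per day, the standard senescence
#' model for laboratory cohorts), which is converted exactly through the
#' cumulative hazard: `q_j = 1 - exp(-(H(t_j) - H(t_{j-1})))` with
#' `H(t) = a/b * (exp(b t) - 1)` (or `a t` when `b = 0`).
#'
#' Offspring are Poisson per interval with age-indexed mean `fecundity[j]`,
#' independent across intervals given survival; counts are attached to the
#' census at which neonates are first observed.
#'
#' @param speciesLabel cohort species label.
#' @param temperature treatment temperature, degrees C.
#' @param nIndividuals cohort size (the experimental design floor is 24
#'   females per treatment).
#' @param censusInterval census spacing in days; 0.5 means every 12 h.
#' @param q per-interval death probabilities in `[0, 1]`; the last value is
#'   carried forward to `maxIntervals`. Supply either `q` or `gompertz`.
#' @param gompertz numeric `c(a, b)`, `a > 0`, `b >= 0`, per-day hazard
#'   scale and ageing rate.
#' @param fecundity expected offspring per interval (>= 0); padded with
#'   zeros to `maxIntervals`.
#' @param maxIntervals observation cap; individuals alive at the cap are
#'   censored there (defaults chosen so this is vanishingly rare).
#' @return a validated \linkS4class{CohortParams}.
#' @examples
#' p <- cohortParams("sp", 20, 24, q = rep(0.1, 40), fecundity = c(0, 0, 1, 1))
#' analyticSchedule(p)
#' @export
cohortParams <- function(speciesLabel, temperature, nIndividuals,
                         censusInterval = 0.5, q = NULL, gompertz = NULL,
                         fecundity, maxIntervals = 60L) {
    if (is.null(q) == is.null(gompertz))
        stop("supply exactly one of 'q' or 'gompertz'")
    new("CohortParams",
        speciesLabel = as.character(speciesLabel),
        temperature = as.numeric(temperature),
        nIndividuals = as.integer(nIndividuals),
        censusInterval = as.numeric(censusInterval),
        hazardType = if (is.null(q)) "gompertz" else "q",
        q = if (is.null(q)) numeric() else as.numeric(q),
        gompertz = if (is.null(gompertz)) numeric() else as.numeric(gompertz),
        fecundity = as.numeric(fecundity),
        maxIntervals = as.integer(maxIntervals))
}

## Gompertz cumulative hazard on [0, t]
.gompertzCumHaz <- function(t, a, b) {
    if (b == 0) a * t else a / b * (expm1(b * t))
}

## Per-interval death probabilities implied by the parameters, length cap
.intervalQ <- function(params) {
    J <- params@maxIntervals
    if (params@hazardType == "q") {
        q <- params@q
        if (length(q) < J)
            q <- c(q, rep(q[length(q)], J - length(q)))
        q[seq_len(J)]
    } else {
        a <- params@gompertz[1L]; b <- params@gompertz[2L]
        t <- seq(0, J) * params@censusInterval
        H <- .gompertzCumHaz(t, a, b)
        1 - exp(-diff(H))
    }
}

.intervalF <- function(params) {
    J <- params@maxIntervals
    f <- params@fecundity
    if (length(f) < J) f <- c(f, rep(0, J - length(f)))
    f[seq_len(J)]
}

#' Expected life-table schedule of a generating process
#'
#' Returns the exact (x, lx, mx) schedule implied by `params`:
#' `lx[j] = prod_{i < j} (1 - q_i)` and `mx[j] = fecundity[j]`, over the
#' full observation window. This is the target against which empirical
#' cohorts converge, and the input for computing a design's true intrinsic
#' rate.
#'
#' @param params a \linkS4class{CohortParams}.
#' @return a \linkS4class{CohortTable} with `n0 = nIndividuals`.
#' @export
analyticSchedule <- function(params) {
    stopifnot(is(params, "CohortParams"))
    validObject(params)
    q <- .intervalQ(params)
    J <- params@maxIntervals
    new("CohortTable",
        x = (seq_len(J) - 1) * params@censusInterval,
        lx = cumprod(c(1, 1 - q[-J])),
        mx = .intervalF(params),
        n0 = params@nIndividuals,
        censusInterval = params@censusInterval,
        species = params@speciesLabel,
        temperature = params@temperature)
}

#' Preset cohort parameters for a two-species thermal design
#'
#' Ready-made generating parameters emulating a life-table experiment that
#' contrasts a heat-tolerant and a heat-sensitive planktonic rotifer across
#' temperature treatments, with 12-h censuses and 24 females per cohort.
#' Mortality is Gompertz with the baseline hazard rising exponentially in
#' temperature (faster for the sensitive species); fecundity starts after a
#' maturation delay, plateaus, then declines, and is reduced at each
#' species' highest treatment. See the package vignette for the rationale
#' behind the constants.
#'
#' @param type `"tolerant"` or `"sensitive"`.
#' @param temperature treatment temperature in degrees C (the default
#'   design uses 20/23/26/32 for the tolerant and 20/23/26 for the
#'   sensitive species).
#' @param nIndividuals cohort size, default 24.
#' @param censusInterval census spacing in days, default 0.5.
#' @return a \linkS4class{CohortParams}.
#' @examples
#' solveLotka(analyticSchedule(cohortPreset("tolerant", 20)))
#' @export
cohortPreset <- function(type = c("tolerant", "sensitive"), temperature,
                         nIndividuals = 24L, censusInterval = 0.5) {
    type <- match.arg(type)
    stopifnot(is.numeric(temperature), length(temperature) == 1L)
    if (type == "tolerant") {
        a <- 0.015 * exp(0.18 * (temperature - 20))
        topT <- 32
    } else {
        a <- 0.012 * exp(0.30 * (temperature - 20))
        topT <- 26
    }
    maxIvl <- 60L
    ageMid <- (seq_len(maxIvl) - 0.5) * censusInterval
    fmax <- if (temperature >= topT) 0.65 else 1.1
    f <- ifelse(ageMid < 1.5, 0,
         ifelse(ageMid < 6, fmax, pmax(0, fmax * (10 - ageMid) / 4)))
    cohortParams(paste0(type, "_sp"), temperature, nIndividuals,
                 censusInterval = censusInterval,
                 gompertz = c(a, 0.25), fecundity = f,
                 maxIntervals = maxIvl)
}

#' Factorial design specification
#'
#' Bundles one \linkS4class{CohortParams} per treatment with a global seed.
#' (species, temperature) pairs must be unique.
#'
#' @param params list of `CohortParams`, one per treatment.
#' @param seed global integer seed; per-treatment sub-seeds are derived by
#'   hashing `(seed, species, temperature)` so results do not depend on
#'   treatment order.
#' @return a list of class `DesignSpec`.
#' @seealso [simulateDesign()], [defaultDesign()]
#' @export
designSpec <- function(params, seed) {
    if (!length(params))
        stop("design must contain at least one treatment")
    if (!all(vapply(params, is, logical(1), "CohortParams")))
        stop("'params' must be a list of CohortParams")
    keys <- vapply(params, function(p)
        paste0(p@speciesLabel, "@", p@temperature), character(1))
    if (anyDuplicated(keys))
        stop("duplicate (species, temperature) treatment: ",
             keys[duplicated(keys)][1L])
    structure(list(params = params, seed = as.integer(seed)),
              class = "DesignSpec")
}

#' Default two-species, seven-treatment design
#'
#' The package's reference design: a tolerant species at 20/23/26/32 C and
#' a sensitive species at 20/23/26 C, 24 females each, censused every 12 h.
#'
#' @param seed global seed.
#' @param nIndividuals cohort size per treatment.
#' @return a `DesignSpec`.
#' @export
defaultDesign <- function(seed, nIndividuals = 24L) {
    params <- c(
        lapply(c(20, 23, 26, 32), function(T)
            cohortPreset("tolerant", T, nIndividuals)),
        lapply(c(20, 23, 26), function(T)
            cohortPreset("sensitive", T, nIndividuals)))
    designSpec(params, seed)
}
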