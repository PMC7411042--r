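#' @describeIn CohortTable-class survivorship at interval starts.
#' @export
setMethod("lx", "CohortTable", function(object) object@lx)

#' @describeIn CohortTable-class age-specific fecundity per interval.
#' @export
setMethod("mx", "CohortTable", function(object) object@mx)

#' @describeIn CohortTable-class ages (days) at interval starts.
#' @export
setMethod("ages", "CohortTable", function(object) object@x)

#' @describeIn CohortTable-class initial cohort size n0.
#' @export
setMethod("cohortSize", "CohortTable", function(object) object@n0)

#' @describeIn DemographyResult-class solved intrinsic rate r (per day).
#' @export
setMethod("intrinsicRate", "DemographyResult", function(object) object@r)

#' @describeIn DemographyResult-class solved r of each successful bootstrap
#'   replicate.
#' @export
setMethod("bootstrapReplicates", "DemographyResult",
          function(object) object@replicates)

#' @describeIn DemographyResult-class percentile bootstrap confidence
#'   interval for r.
#' @param parm,level,... ignored; the interval is fixed at construction.
#' @export
setMethod("confint", "DemographyResult", function(object, parm, level, ...) {
    out <- matrix(c(object@ciLow, object@ciHigh), nrow = 1L,
                  dimnames = list("r", c("lower", "upper")))
    out
})

#' @describeIn LifeRecords-class number of individuals.
#' @export
setMethod("length", "LifeRecords", function(x) length(x@id))

#' @describeIn LifeRecords-class subset individuals (with repetition
#'   allowed, as needed by bootstrap resampling); ids are made unique.
#' @param i index vector of individuals.
#' @param j,drop ignored.
#' @export
setMethod("[", "LifeRecords", function(x, i, j, ..., drop = TRUE) {
    ids <- x@id[i]
    if (anyDuplicated(ids))
        ids <- make.unique(ids, sep = ".rep")
    new("LifeRecords",
        id = ids,
        species = x@species[i],
        temperature = x@temperature[i],
        deathInterval = x@deathInterval[i],
        censored = x@censored[i],
        offspring = x@offspring[i, , drop = FALSE],
        censusInterval = x@censusInterval)
})

#' Combine life-history record sets
#'
#' Concatenates cohorts (e.g. the treatments of a factorial design) into a
#' single \linkS4class{LifeRecords} object. Census intervals must agree;
#' offspring matrices are padded with zero columns to a common width.
#'
#' @param x,y,... `LifeRecords` objects.
#' @return a `LifeRecords` holding all individuals.
#' @export
setMethod("c", "LifeRecords", function(x, ...) {
    all <- c(list(x), list(...))
    ci <- unique(vapply(all, function(r) r@censusInterval, numeric(1)))
    if (length(ci) != 1L)
        stop("cannot combine records with different census intervals")
    width <- max(vapply(all, function(r) ncol(r@offspring), integer(1)))
    off <- do.call(rbind, lapply(all, function(r) {
        m <- r@offspring
        if (ncol(m) < width)
            m <- cbind(m, matrix(0L, nrow(m), width - ncol(m)))
        m
    }))
    new("LifeRecords",
        id = make.unique(unlist(lapply(all, function(r) r@id)), sep = "_"),
        species = unlist(lapply(all, function(r) r@species)),
        temperature = unlist(lapply(all, function(r) r@temperature)),
        deathInterval = unlist(lapply(all, function(r) r@deathInterval)),
        censored = unlist(lapply(all, function(r) r@censored)),
        offspring = off,
        censusInterval = ci)
})

#' @describeIn LifeRecords-class long-format view: one row per individual
#'   per observed interval, in the on-disk CSV column layout.
#' @param row.names,optional,... passed through conventions of
#'   [base::as.data.frame()]; unused.
#' @export
setMethod("as.data.frame", "LifeRecords",
          function(x, row.names = NULL, optional = FALSE, ...) {
    n <- length(x)
    if (n == 0L)
        return(data.frame(individual_id = character(), species = character(),
                          temperature_C = numeric(), interval_index = integer(),
                          age_start_days = numeric(), alive_at_end = integer(),
                          offspring_count = integer(), censored = integer()))
    ivl <- sequence(x@deathInterval)
    idx <- rep.int(seq_len(n), x@deathInterval)
    alive <- as.integer(ivl < x@deathInterval[idx] |
                        (x@censored[idx] & ivl == x@deathInterval[idx]))
    data.frame(
        individual_id = x@id[idx],
        species = x@species[idx],
        temperature_C = x@temperature[idx],
        interval_index = ivl,
        age_start_days = (ivl - 1L) * x@censusInterval,
        alive_at_end = alive,
        offspring_count = x@offspring[cbind(idx, ivl)],
        censored = as.integer(x@censored[idx] & ivl == x@deathInterval[idx]))
})

#' @describeIn CohortTable-class data.frame with columns x, lx, mx.
#' @export
setMethod("as.data.frame", "CohortTable",
          function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(x = x@x, lx = x@lx, mx = x@mx)
})

#' @describeIn KMCurve-class data.frame with time, survival, n_risk,
#'   n_event.
#' @param x a `KMCurve`.
#' @param row.names,optional,... unused.
#' @export
setMethod("as.data.frame", "KMCurve",
          function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(time = x@time, survival = x@survival,
               n_risk = x@nRisk, n_event = x@nEvent)
})

setMethod("show", "CohortParams", function(object) {
    hz <- if (object@hazardType == "q")
        sprintf("per-interval q (%d values)", length(object@q))
    else
        sprintf("Gompertz a=%.4g, b=%.4g per day", object@gompertz[1L],
                object@gompertz[2L])
    cat("CohortParams:", object@speciesLabel, "at",
        object@temperature, "°C\n",
        sprintf(" n = %d, census every %g d, cap %d intervals\n",
                object@nIndividuals, object@censusInterval,
                object@maxIntervals),
        " hazard:", hz, "\n",
        sprintf(" fecundity schedule over %d intervals (max %.3g per interval)\n",
                length(object@fecundity),
                if (length(object@fecundity)) max(object@fecundity) else 0))
})

setMethod("show", "LifeRecords", function(object) {
    n <- length(object)
    cat(sprintf("LifeRecords: %d individuals, census every %g d\n",
                n, object@censusInterval))
    if (n > 0L) {
        grp <- unique(paste0(object@species, " @ ", object@temperature,
                             "°C"))
        cat(" groups:", paste(grp, collapse = "; "), "\n")
        cat(sprintf(" death intervals %d-%d, %d censored, %d offspring total\n",
                    min(object@deathInterval), max(object@deathInterval),
                    sum(object@censored), sum(object@offspring)))
    }
})

setMethod("show", "CohortTable", function(object) {
    cat(sprintf("CohortTable (%s @ %s°C): %d intervals of %g d, n0 = %d\n",
                object@species, format(object@temperature), length(object@x),
                object@censusInterval, object@n0))
    cat(sprintf(" R0 = %.4g; final lx = %.4g\n",
                sum(object@lx * object@mx), object@lx[length(object@lx)]))
})

setMethod("show", "DemographyResult", function(object) {
    cat(sprintf("DemographyResult: r = %.4f per day (R0 = %.3f, mean lifespan %.2f d)\n",
                object@r, object@R0, object@meanLifespan))
    cat(sprintf(" %g%% percentile bootstrap CI [%.4f, %.4f] from %d replicates (%d failed), seed %d\n",
                100 * object@ciLevel, object@ciLow, object@ciHigh,
                object@nBoot, object@nFailed, object@seed))
})

setMethod("show", "KMCurve", function(object) {
    cat(sprintf("KMCurve: n = %d, %d event times, %d events\n",
                object@n, length(object@time), sum(object@nEvent)))
    if (length(object@time))
        cat(sprintf(" median survival time: %s d\n",
                    format(medianSurvival(object))))
})

setMethod("show", "HitTable", function(object) {
    cat(sprintf("HitTable: %d hits on %d contigs across %d databases\n",
                nrow(object@hits), length(unique(object@hits$qseqid)),
                length(unique(object@labels))))
    cat(" target:", object@targetLabel,
        if (length(object@rrnaLabel)) paste("; rRNA:", object@rrnaLabel)
        else "", "\n")
})

setMethod("show", "GLMFit", function(object) {
    cat(sprintf("GLMFit (%s): %s\n", object@family,
                if (length(object@modelName)) object@modelName else
                    deparse(object@formula)))
    cat(sprintf(" %d coefficients, logLik = %.4f, AIC = %.4f, %s in %d iterations\n",
                object@rank, object@logLik, object@aic,
                if (object@converged) "converged" else "NOT converged",
                object@iter))
    print(round(object@coefficients, 6))
})
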