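## Fast life-table core on raw vectors; shared by buildLifeTable and the
## bootstrap hot loop. Returns list(x, lx, mx) over intervals 1..J where J
## is the last interval with a survivor at its start.
.lifeTableCore <- function(deathInterval, offspring, censusInterval) {
    n0 <- length(deathInterval)
    J <- max(deathInterval)
    ## alive at start of interval j = #(deathInterval >= j)
    deaths <- tabulate(deathInterval, nbins = J)
    aliveAtStart <- n0 - c(0, cumsum(deaths))[seq_len(J)]
    totalOff <- .colSums(offspring[, seq_len(J), drop = FALSE], n0, J)
    list(x = (seq_len(J) - 1) * censusInterval,
         lx = aliveAtStart / n0,
         mx = totalOff / aliveAtStart,
         n0 = n0)
}

#' Build a cohort life table from individual records
#'
#' Computes the (x, lx, mx) schedule from uncensored individual-level
#' records of one homogeneous (species x temperature) group:
#' `lx[j]` is the fraction of the initial cohort alive at the start of age
#' interval `j` (so an individual dying in interval `j` still counts as
#' alive at its start), and `mx[j]` is the total offspring produced in the
#' interval divided by the number alive at its start. The table extends to
#' the last interval with any survivor at its start; `x` is the interval
#' start age in days.
#'
#' @param records a \linkS4class{LifeRecords} of a single treatment group.
#' @param allowCensored if TRUE, censored records are tolerated and the
#'   table is truncated at the last interval every individual was fully
#'   observed through; default FALSE (censoring is an error).
#' @param mxDenominator `"start"` (default: females alive at the interval
#'   start) or `"mid"` (mid-interval exposure, alive-at-start minus half
#'   the interval's deaths). Only `"start"` satisfies the exact
#'   conservation `sum(lx mx) = total offspring / n0`.
#' @param xAt report ages at interval `"start"` (default) or `"mid"`
#'   (shifted by half a census interval), the latter for use in the
#'   renewal equation when mid-interval timing is preferred.
#' @return a \linkS4class{CohortTable}.
#' @examples
#' rec <- simulateCohort(cohortPreset("sensitive", 23), seed = 11)
#' tab <- buildLifeTable(rec)
#' netReproductiveRate(tab)
#' @export
buildLifeTable <- function(records, allowCensored = FALSE,
                           mxDenominator = c("start", "mid"),
                           xAt = c("start", "mid")) {
    mxDenominator <- match.arg(mxDenominator)
    xAt <- match.arg(xAt)
    stopifnot(is(records, "LifeRecords"))
    if (length(records) == 0L)
        stop("cannot build a life table from zero individuals")
    if (length(unique(records@species)) > 1L ||
        length(unique(records@temperature)) > 1L)
        stop("records mix treatment groups; split by treatment first")
    death <- records@deathInterval
    if (any(records@censored)) {
        if (!allowCensored)
            stop("censored individuals present; set allowCensored = TRUE ",
                 "to truncate at the last fully-observed interval")
        cut <- min(death[records@censored])
        death <- pmin(death, cut)
    }
    core <- .lifeTableCore(death, records@offspring,
                           records@censusInterval)
    mxOut <- core$mx
    if (mxDenominator == "mid") {
        J <- length(core$x)
        aliveAtStart <- core$lx * core$n0
        deaths <- tabulate(pmin(death, J), nbins = J)
        exposure <- aliveAtStart - deaths / 2
        mxOut <- (core$mx * aliveAtStart) / exposure
    }
    xOut <- core$x + if (xAt == "mid") records@censusInterval / 2 else 0
    new("CohortTable", x = xOut, lx = core$lx, mx = mxOut,
        n0 = as.integer(core$n0), censusInterval = records@censusInterval,
        species = records@species[1L],
        temperature = records@temperature[1L])
}

#' Average lifespan of a cohort
#'
#' Mean individual lifespan in days. Death is interval-censored by the
#' census design: an individual dying in interval `j` is assigned lifespan
#' `j * censusInterval` (the end of its death interval); the alternative
#' conventions (interval start or midpoint) are available via `at`.
#'
#' @param records an uncensored \linkS4class{LifeRecords}.
#' @param at where in the death interval to place the death:
#'   `"end"` (default), `"mid"` or `"start"`.
#' @return mean lifespan, days.
#' @export
averageLifespan <- function(records, at = c("end", "mid", "start")) {
    stopifnot(is(records, "LifeRecords"))
    at <- match.arg(at)
    if (length(records) == 0L)
        stop("no individuals")
    if (any(records@censored))
        stop("average lifespan is undefined with censored individuals")
    shift <- switch(at, end = 0, mid = 0.5, start = 1)
    mean((records@deathInterval - shift) * records@censusInterval)
}

#' Individual lifespans
#'
#' @inheritParams averageLifespan
#' @return numeric vector of lifespans in days, one per individual
#'   (censored individuals get their last observed age, flagged by the
#'   `censored` attribute being carried alongside in [as.data.frame()]).
#' @export
lifespans <- function(records, at = c("end", "mid", "start")) {
    stopifnot(is(records, "LifeRecords"))
    at <- match.arg(at)
    shift <- switch(at, end = 0, mid = 0.5, start = 1)
    (records@deathInterval - shift) * records@censusInterval
}

#' Total offspring per individual
#'
#' @param records a \linkS4class{LifeRecords}.
#' @return integer vector of lifetime offspring counts.
#' @export
totalOffspring <- function(records) {
    as.integer(rowSums(records@offspring))
}

#' Coarsen a life table to daily resolution
#'
#' Aggregates a sub-daily schedule to whole days: `lx` is taken at day
#' starts and the day's `mx` is the day's total per-capita offspring,
#' `sum(lx_j mx_j) / lx_daystart` over the sub-intervals `j` of the day —
#' which preserves the net reproductive rate exactly.
#'
#' @param table a \linkS4class{CohortTable} whose census interval divides
#'   one day.
#' @return a daily-resolution \linkS4class{CohortTable}.
#' @export
aggregateDaily <- function(table) {
    stopifnot(is(table, "CohortTable"))
    per <- round(1 / table@censusInterval)
    if (per < 1L || abs(per * table@censusInterval - 1) > 1e-9)
        stop("census interval must divide one day")
    if (per == 1L)
        return(table)
    day <- (seq_along(table@x) - 1L) %/% per
    starts <- which(!duplicated(day))
    lxd <- table@lx[starts]
    births <- tapply(table@lx * table@mx, day, sum)
    new("CohortTable", x = as.numeric(unique(day)), lx = as.numeric(lxd),
        mx = as.numeric(births / lxd), n0 = table@n0,
        censusInterval = 1, species = table@species,
        temperature = table@temperature)
}
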