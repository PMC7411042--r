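## p-values are never reported as exactly zero
.pFloor <- function(p) pmax(p, .Machine$double.xmin)

.checkSurvInput <- function(durations, events) {
    if (!length(durations))
        stop("no observations")
    if (length(events) != length(durations))
        stop("'durations' and 'events' lengths differ")
    if (anyNA(durations) || any(durations <= 0))
        stop("durations must be positive and non-missing")
}

#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function from durations and event indicators.
#' At each distinct death time `t_i`, with `n_i` individuals at risk
#' (duration `>= t_i`; individuals censored at `t_i` count as at risk) and
#' `d_i` deaths, survival multiplies by `(1 - d_i / n_i)`. With no
#' censoring the estimate equals the empirical proportion with duration
#' `> t`.
#'
#' @param durations positive times (days).
#' @param events logical/0-1: TRUE = death observed, FALSE = censored.
#' @return a \linkS4class{KMCurve}.
#' @examples
#' kmEstimate(c(1, 2, 2, 3), events = rep(TRUE, 4))
#' @export
kmEstimate <- function(durations, events = rep(TRUE, length(durations))) {
    events <- as.logical(events)
    .checkSurvInput(durations, events)
    tev <- sort(unique(durations[events]))
    if (!length(tev))
        return(new("KMCurve", time = numeric(), survival = numeric(),
                   nRisk = integer(), nEvent = integer(),
                   n = length(durations)))
    nRisk <- vapply(tev, function(t) sum(durations >= t), numeric(1))
    nEvent <- vapply(tev, function(t) sum(durations == t & events),
                     numeric(1))
    new("KMCurve", time = tev,
        survival = cumprod(1 - nEvent / nRisk),
        nRisk = as.integer(nRisk), nEvent = as.integer(nEvent),
        n = length(durations))
}

#' @describeIn kmEstimate survival probability of a fitted curve at
#'   arbitrary times (right-continuous step function).
#' @param curve a \linkS4class{KMCurve}.
#' @param times times at which to evaluate survival.
#' @export
kmSurvivalAt <- function(curve, times) {
    stopifnot(is(curve, "KMCurve"))
    idx <- findInterval(times, curve@time)
    c(1, curve@survival)[idx + 1L]
}

#' @describeIn kmEstimate smallest time with survival <= 0.5 (NA if the
#'   curve never reaches 0.5).
#' @export
medianSurvival <- function(curve) {
    stopifnot(is(curve, "KMCurve"))
    hit <- which(curve@survival <= 0.5 + 1e-12)
    if (length(hit)) curve@time[hit[1L]] else NA_real_
}

#' Two-sample log-rank test
#'
#' Compares two survival curves by pooling the distinct death times. At
#' each time with `d` pooled deaths among `n` at risk (`n_1` in group 1),
#' the observed deaths in group 1 are compared with the hypergeometric
#' expectation `d n_1 / n`, with variance
#' `d (n_1/n) (n_2/n) (n - d) / (n - 1)`. The statistic
#' `(sum(O - E))^2 / sum(V)` is chi-squared with 1 df under the null, and
#' is symmetric in the two groups.
#'
#' @param durationsA,durationsB positive times per group.
#' @param eventsA,eventsB event indicators (TRUE = death).
#' @return one-row data.frame: method, statistic, df, p.value,
#'   p.adjusted (NA here; filled by [pairwiseLogrank()]).
#' @export
logrankTest <- function(durationsA, eventsA = rep(TRUE, length(durationsA)),
                        durationsB, eventsB = rep(TRUE, length(durationsB))) {
    eventsA <- as.logical(eventsA); eventsB <- as.logical(eventsB)
    .checkSurvInput(durationsA, eventsA)
    .checkSurvInput(durationsB, eventsB)
    if (!any(eventsA) && !any(eventsB))
        stop("log-rank test undefined: no events in either group")
    dur <- c(durationsA, durationsB)
    evt <- c(eventsA, eventsB)
    grp <- rep(1:2, c(length(durationsA), length(durationsB)))
    tev <- sort(unique(dur[evt]))
    OmE <- 0; V <- 0
    for (t in tev) {
        atRisk <- dur >= t
        n <- sum(atRisk)
        n1 <- sum(atRisk & grp == 1L)
        d <- sum(dur == t & evt)
        d1 <- sum(dur == t & evt & grp == 1L)
        OmE <- OmE + (d1 - d * n1 / n)
        if (n > 1L)
            V <- V + d * (n1 / n) * ((n - n1) / n) * (n - d) / (n - 1)
    }
    stat <- if (V > 0) OmE^2 / V else 0
    p <- if (V > 0) stats::pchisq(stat, df = 1, lower.tail = FALSE) else 1
    data.frame(method = "logrank", statistic = stat, df = 1L,
               p.value = .pFloor(p), p.adjusted = NA_real_)
}

#' All pairwise log-rank tests
#'
#' Tests every unordered pair of groups and applies a multiplicity
#' correction over the `choose(k, 2)` comparisons (Bonferroni:
#' `p_adj = min(1, m * p)`).
#'
#' @param durations positive times.
#' @param events event indicators.
#' @param group group labels (>= 2 levels).
#' @param correction a [stats::p.adjust()] method, default "bonferroni".
#' @return data.frame, one row per pair: group_a, group_b, method,
#'   statistic, df, p.value, p.adjusted.
#' @export
pairwiseLogrank <- function(durations, events = rep(TRUE, length(durations)),
                            group, correction = "bonferroni") {
    group <- as.character(group)
    lev <- unique(group)
    if (length(lev) < 2L)
        stop("need at least 2 groups")
    pairs <- utils::combn(lev, 2L)
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
        a <- group == pairs[1L, k]; b <- group == pairs[2L, k]
        res <- logrankTest(durations[a], events[a],
                           durations[b], events[b])
        cbind(data.frame(group_a = pairs[1L, k], group_b = pairs[2L, k]),
              res)
    })
    out <- do.call(rbind, rows)
    out$p.adjusted <- .pFloor(stats::p.adjust(out$p.value,
                                              method = correction))
    out
}
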