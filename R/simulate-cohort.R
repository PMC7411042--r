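## Deterministic sub-seed from (seed, species, temperature); independent of
## treatment order. FNV-style string hash folded into 31 bits.
.subSeed <- function(seed, species, temperature) {
    key <- sprintf("%s|%.6g", species, temperature)
    h <- 2166136261
    for (code in utf8ToInt(key)) {
        h <- (h * 16777619) %% 2147483647
        h <- (h + code) %% 2147483647
    }
    as.integer((h + as.double(seed) * 48271) %% 2147483629 + 1)
}

#' Simulate one life-table cohort
#'
#' Draws `nIndividuals` females from the generating process in `params`:
#' each individual alive at the start of interval `j` dies within it with
#' probability `q_j`, and while alive produces `Poisson(fecundity[j])`
#' offspring in the interval (including her death interval — she was alive
#' at its start, matching the per-capita fecundity denominator).
#' Individuals still alive at `maxIntervals` are censored there. Identical
#' `(params, seed)` give bitwise-identical output.
#'
#' @param params a \linkS4class{CohortParams}.
#' @param seed integer RNG seed.
#' @return a \linkS4class{LifeRecords} with `nIndividuals` rows.
#' @examples
#' rec <- simulateCohort(cohortPreset("tolerant", 20), seed = 1)
#' buildLifeTable(rec)
#' @export
simulateCohort <- function(params, seed) {
    stopifnot(is(params, "CohortParams"))
    validObject(params)
    n <- params@nIndividuals
    J <- params@maxIntervals
    q <- .intervalQ(params)
    f <- .intervalF(params)

    rng <- .withSeed(seed)
    on.exit(rng(), add = TRUE)

    ## death interval: first j with U_j < q_j, individuals in rows
    u <- matrix(stats::runif(n * J), nrow = n)
    died <- sweep(u, 2L, q, "<")
    firstDeath <- apply(died, 1L, function(z) {
        w <- which(z)
        if (length(w)) w[1L] else NA_integer_
    })
    censored <- is.na(firstDeath)
    deathIvl <- ifelse(censored, J, firstDeath)

    ## offspring while alive at interval start (interval <= death interval)
    off <- matrix(0L, n, J)
    aliveAtStart <- outer(deathIvl, seq_len(J), ">=")
    idx <- which(aliveAtStart & rep(f > 0, each = n))
    if (length(idx)) {
        colIdx <- (idx - 1L) %/% n + 1L
        off[idx] <- stats::rpois(length(idx), f[colIdx])
    }

    new("LifeRecords",
        id = sprintf("%s_T%g_%03d", params@speciesLabel,
                     params@temperature, seq_len(n)),
        species = rep(params@speciesLabel, n),
        temperature = rep(params@temperature, n),
        deathInterval = as.integer(deathIvl),
        censored = censored,
        offspring = off,
        censusInterval = params@censusInterval)
}

## set.seed scoped to the caller: returns a restore function
.withSeed <- function(seed) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    function() {
        if (is.null(old))
            rm(".Random.seed", envir = globalenv())
        else
            assign(".Random.seed", old, envir = globalenv())
    }
}

#' Simulate a full factorial design
#'
#' Runs [simulateCohort()] for every treatment of a `DesignSpec`, with
#' per-treatment sub-seeds derived deterministically from the global seed
#' and the (species, temperature) labels, and concatenates the cohorts.
#'
#' @param spec a [designSpec()].
#' @return a \linkS4class{LifeRecords} holding all treatments.
#' @examples
#' rec <- simulateDesign(defaultDesign(seed = 7))
#' table(speciesOf(rec), temperatureOf(rec))
#' @export
simulateDesign <- function(spec) {
    if (!inherits(spec, "DesignSpec"))
        stop("'spec' must be a DesignSpec")
    cohorts <- lapply(spec$params, function(p)
        simulateCohort(p, .subSeed(spec$seed, p@speciesLabel,
                                   p@temperature)))
    do.call(c, cohorts)
}

#' @rdname simulateDesign
#' @param records a \linkS4class{LifeRecords}.
#' @export
speciesOf <- function(records) records@species

#' @rdname simulateDesign
#' @export
temperatureOf <- function(records) records@temperature

#' Split records by treatment
#'
#' @param records a \linkS4class{LifeRecords}.
#' @return named list of `LifeRecords`, one per (species, temperature)
#'   combination, names `"species@temperature"`.
#' @export
splitByTreatment <- function(records) {
    key <- paste0(records@species, "@", records@temperature)
    idx <- split(seq_along(key), key)
    ## preserve first-appearance order
    idx <- idx[unique(key)]
    lapply(idx, function(i) records[i])
}
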