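## Independent oracles and fixture builders shared across the suite.

## Brute-force bisection solver for the renewal equation, written against
## the raw definition (sum exp(-r x) lx mx = 1) and kept independent of
## the package's solver internals.
bisectLotka <- function(x, lx, mx, lower = -50, upper = 50,
                        iterations = 200L) {
    keep <- lx * mx > 0   # zero terms contribute nothing; dropping them
    x <- x[keep]          # avoids 0 * Inf at extreme bracket endpoints
    phi <- (lx * mx)[keep]
    f <- function(r) sum(exp(-r * x) * phi) - 1
    stopifnot(f(lower) > 0, f(upper) < 0)
    for (i in seq_len(iterations)) {
        mid <- (lower + upper) / 2
        if (f(mid) > 0) lower <- mid else upper <- mid
    }
    (lower + upper) / 2
}

## Random valid life-table schedule with reproduction at some x > 0
randomSchedule <- function(maxIntervals = 40L, censusInterval = 0.5) {
    J <- sample(5:maxIntervals, 1L)
    q <- runif(J, 0.02, 0.5)
    lx <- cumprod(c(1, 1 - q[-J]))
    mx <- numeric(J)
    repro <- sample(2:J, max(1L, J %/% 3L))
    mx[repro] <- runif(length(repro), 0.1, 4)
    new("CohortTable", x = (seq_len(J) - 1) * censusInterval, lx = lx,
        mx = mx, n0 = 24L, censusInterval = censusInterval,
        species = "sim", temperature = 20)
}

## Hand-built LifeRecords from death intervals and an offspring matrix
makeRecords <- function(deathInterval, offspring = NULL,
                        censusInterval = 0.5, censored = NULL,
                        species = "sp", temperature = 20) {
    n <- length(deathInterval)
    J <- max(deathInterval)
    if (is.null(offspring))
        offspring <- matrix(0L, n, J)
    storage.mode(offspring) <- "integer"
    if (is.null(censored))
        censored <- rep(FALSE, n)
    new("LifeRecords",
        id = sprintf("ind%02d", seq_len(n)),
        species = rep(species, n),
        temperature = rep(temperature, n),
        deathInterval = as.integer(deathInterval),
        censored = censored,
        offspring = offspring,
        censusInterval = censusInterval)
}

## Independent Newton-Raphson fit of a poisson log-link GLM, maximizing
## the log-likelihood directly (score and Hessian written out by hand).
newtonPoisson <- function(X, y, iterations = 50L) {
    beta <- rep(0, ncol(X))
    beta[1] <- log(mean(y) + 0.1)
    for (i in seq_len(iterations)) {
        mu <- exp(drop(X %*% beta))
        score <- drop(t(X) %*% (y - mu))
        hess <- t(X) %*% (X * mu)
        beta <- beta + solve(hess, score)
    }
    beta
}
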