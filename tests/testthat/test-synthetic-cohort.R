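test_that("certain death kills every individual in the first interval", {
    p <- cohortParams("sp", 20, 30, q = 1, fecundity = rep(1, 10),
                      maxIntervals = 10L)
    rec <- simulateCohort(p, seed = 1)
    expect_equal(rec@deathInterval, rep(1L, 30))
    expect_false(any(rec@censored))
    expect_true(all(rec@offspring[, -1] == 0))
})

test_that("a sterile cohort produces zero offspring", {
    p <- cohortParams("sp", 20, 25, q = 0.3, fecundity = 0,
                      maxIntervals = 20L)
    rec <- simulateCohort(p, seed = 2)
    expect_equal(sum(rec@offspring), 0)
})

test_that("simulation is bitwise deterministic in (params, seed)", {
    p <- cohortPreset("tolerant", 26)
    a <- simulateCohort(p, seed = 42)
    b <- simulateCohort(p, seed = 42)
    expect_identical(a@deathInterval, b@deathInterval)
    expect_identical(a@offspring, b@offspring)
    expect_identical(a@censored, b@censored)
    c <- simulateCohort(p, seed = 43)
    expect_false(identical(a@offspring, c@offspring))
})

test_that("invalid parameters are rejected", {
    expect_error(cohortParams("sp", 20, 10, q = 1.2, fecundity = 1),
                 "\\[0, 1\\]")
    expect_error(cohortParams("sp", 20, 0, q = 0.5, fecundity = 1),
                 ">= 1")
    expect_error(cohortParams("sp", 20, 10, q = 0.5, fecundity = -1),
                 ">= 0")
    expect_error(cohortParams("sp", 20, 10, fecundity = 1), "exactly one")
    expect_error(cohortParams("sp", 20, 10, q = 0.5, gompertz = c(1, 1),
                              fecundity = 1), "exactly one")
})

test_that("analytic schedule reproduces geometric and immortal limits", {
    p <- cohortParams("sp", 20, 10, q = 0.5, fecundity = 1,
                      maxIntervals = 8L)
    expect_equal(lx(analyticSchedule(p)), 0.5^(0:7))
    p0 <- cohortParams("sp", 20, 10, q = 0, fecundity = rep(1, 8),
                       maxIntervals = 8L)
    expect_equal(lx(analyticSchedule(p0)), rep(1, 8))
    expect_equal(mx(analyticSchedule(p0)), rep(1, 8))
    ## fecundity beyond the supplied schedule pads with zeros
    pShort <- cohortParams("sp", 20, 10, q = 0, fecundity = 1,
                           maxIntervals = 4L)
    expect_equal(mx(analyticSchedule(pShort)), c(1, 0, 0, 0))
})

test_that("Gompertz conversion matches numerical integration of the hazard", {
    a <- 0.04; b <- 0.3; ci <- 0.5
    p <- cohortParams("sp", 20, 10, gompertz = c(a, b),
                      fecundity = 1, maxIntervals = 20L)
    sched <- analyticSchedule(p)
    hazard <- function(t) a * exp(b * t)
    for (j in c(1L, 5L, 12L, 20L)) {
        Hcum <- integrate(hazard, 0, (j - 1) * ci, rel.tol = 1e-12)$value
        expect_equal(lx(sched)[j], exp(-Hcum), tolerance = 1e-9)
    }
    ## survivorship ratio between consecutive intervals = exp(-interval
    ## cumulative hazard)
    H1 <- integrate(hazard, 0, ci, rel.tol = 1e-12)$value
    expect_equal(lx(sched)[2] / lx(sched)[1], exp(-H1), tolerance = 1e-9)
})

test_that("empirical cohorts converge to the analytic schedule", {
    p <- cohortParams("sp", 20, 10000L, q = c(0.05, 0.1, 0.2, 0.3, 0.4),
                      fecundity = c(0, 1.5, 2, 1, 0.5),
                      maxIntervals = 12L)
    rec <- simulateCohort(p, seed = 7)
    tab <- buildLifeTable(rec, allowCensored = TRUE)
    sched <- analyticSchedule(p)
    J <- length(lx(tab))
    for (j in seq_len(J)) {
        l <- lx(sched)[j]
        tolBinom <- 3 * sqrt(l * (1 - l) / 10000) + 1e-12
        expect_lt(abs(lx(tab)[j] - l), tolBinom + 1e-9)
    }
    ## mean offspring among those alive at interval start, within 4 SE
    f <- c(0, 1.5, 2, 1, 0.5)
    for (j in 1:5) {
        nAlive <- round(lx(tab)[j] * 10000)
        se <- sqrt(f[j] / nAlive)
        expect_lt(abs(mx(tab)[j] - f[j]), 4 * se + 1e-12)
    }
})

test_that("design simulation derives order-independent sub-seeds", {
    p1 <- cohortPreset("tolerant", 20)
    p2 <- cohortPreset("tolerant", 26)
    d12 <- simulateDesign(designSpec(list(p1, p2), seed = 9))
    d21 <- simulateDesign(designSpec(list(p2, p1), seed = 9))
    g12 <- splitByTreatment(d12)[["tolerant_sp@20"]]
    g21 <- splitByTreatment(d21)[["tolerant_sp@20"]]
    expect_identical(g12@deathInterval, g21@deathInterval)
    expect_identical(g12@offspring, g21@offspring)
    ## same params at different treatments differ but share structure
    expect_false(identical(
        splitByTreatment(d12)[[1]]@deathInterval,
        splitByTreatment(d12)[[2]]@deathInterval))
})

test_that("design specification rejects duplicates and emptiness", {
    p <- cohortPreset("tolerant", 20)
    expect_error(designSpec(list(p, p), seed = 1), "duplicate")
    expect_error(designSpec(list(), seed = 1), "at least one")
})

test_that("tolerant preset lifespan declines with temperature in expectation", {
    meanLife <- vapply(c(20, 23, 26, 32), function(T) {
        sched <- analyticSchedule(cohortPreset("tolerant", T))
        l <- lx(sched)
        J <- length(l)
        ## P(die in j) = lx_j - lx_{j+1}; death placed at interval end
        pDie <- c(l[-J] - l[-1], l[J])
        sum(pDie * seq_len(J)) * 0.5
    }, numeric(1))
    expect_true(all(diff(meanLife) < 0))
})

test_that("hit-table generator honours its class mix and determinism", {
    pureNoHit <- simulateHitTable(
        50, c(target = 0, contaminant = 0, rrna = 0, nohit = 1,
              ambiguous = 0), seed = 3)
    expect_equal(nrow(pureNoHit$hits@hits), 0)
    expect_true(all(pureNoHit$truth$class == "unassigned"))

    pureTarget <- simulateHitTable(
        40, c(target = 1, contaminant = 0, rrna = 0, nohit = 0,
              ambiguous = 0), seed = 3, marginRange = c(150, 150.5))
    asg <- assignContigs(pureTarget$hits)
    expect_true(all(asg$class == "target"))

    again <- simulateHitTable(
        40, c(target = 1, contaminant = 0, rrna = 0, nohit = 0,
              ambiguous = 0), seed = 3, marginRange = c(150, 150.5))
    expect_identical(pureTarget$hits@hits, again$hits@hits)
    expect_error(simulateHitTable(10, c(target = 0.5, contaminant = 0.2,
                                        rrna = 0, nohit = 0,
                                        ambiguous = 0), seed = 1),
                 "summing to 1")
})

test_that("count-matrix generator plants exactly the advertised violations", {
    clean <- simulateCountMatrix(80, 6, seed = 5, lowCountFraction = 0)
    expect_true(all(clean$truth$keep))
    expect_equal(nrow(filterLowCounts(clean$counts)), 80)

    dirty <- simulateCountMatrix(80, 6, seed = 5, lowCountFraction = 1)
    expect_false(any(dirty$truth$keep))
    expect_equal(nrow(filterLowCounts(dirty$counts)), 0)

    a <- simulateCountMatrix(60, 5, seed = 11, lowCountFraction = 0.4)
    b <- simulateCountMatrix(60, 5, seed = 11, lowCountFraction = 0.4)
    expect_identical(a$counts, b$counts)
})
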