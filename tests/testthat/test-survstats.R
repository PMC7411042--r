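test_that("Kaplan-Meier reproduces hand product-limit computations", {
    ## all die at t = 2
    km <- kmEstimate(rep(2, 5))
    expect_equal(km@time, 2)
    expect_equal(km@survival, 0)
    expect_equal(kmSurvivalAt(km, c(1.9, 2, 3)), c(1, 0, 0))

    ## durations 1, 2, 2, 3 all events: S = 3/4, 1/4, 0
    km2 <- kmEstimate(c(1, 2, 2, 3))
    expect_equal(km2@time, c(1, 2, 3))
    expect_equal(km2@survival, c(3/4, 1/4, 0))
    expect_equal(km2@nRisk, c(4L, 3L, 1L))
    expect_equal(km2@nEvent, c(1L, 2L, 1L))
    expect_equal(medianSurvival(km2), 2)

    ## censored-only sample: flat at 1 with no events
    km3 <- kmEstimate(c(1, 2), events = c(FALSE, FALSE))
    expect_equal(length(km3@time), 0)
    expect_equal(kmSurvivalAt(km3, c(0.5, 5)), c(1, 1))
})

test_that("KM with censoring matches the survival package", {
    skip_if_not_installed("survival")
    set.seed(33)
    for (i in 1:10) {
        dur <- sample(1:8, 30, replace = TRUE) / 2
        evt <- runif(30) < 0.8
        if (!any(evt)) evt[1] <- TRUE
        km <- kmEstimate(dur, evt)
        ref <- survival::survfit(survival::Surv(dur, evt) ~ 1)
        refSurv <- summary(ref, times = km@time)$surv
        expect_equal(km@survival, refSurv, tolerance = 1e-12)
    }
})

test_that("log-rank test is null, symmetric and oracle-consistent", {
    a <- c(1, 2, 3, 4)
    same <- logrankTest(a, durationsB = a)
    expect_equal(same$statistic, 0)
    expect_equal(same$p.value, 1)

    b <- c(2, 3, 5, 6)
    ab <- logrankTest(a, durationsB = b)
    ba <- logrankTest(b, durationsB = a)
    expect_equal(ab$statistic, ba$statistic, tolerance = 1e-12)

    ## direct hypergeometric-moment oracle, written out longhand
    dur <- c(a, b); grp <- rep(1:2, each = 4)
    OmE <- 0; V <- 0
    for (t in sort(unique(dur))) {
        n <- sum(dur >= t); n1 <- sum(dur >= t & grp == 1)
        d <- sum(dur == t); d1 <- sum(dur == t & grp == 1)
        OmE <- OmE + d1 - d * n1 / n
        if (n > 1) V <- V + d * n1 * (n - n1) * (n - d) / (n^2 * (n - 1))
    }
    expect_equal(ab$statistic, OmE^2 / V, tolerance = 1e-12)
    expect_error(logrankTest(c(1, 2), c(FALSE, FALSE),
                             c(2, 3), c(FALSE, FALSE)), "no events")
})

test_that("log-rank agrees with survival::survdiff", {
    skip_if_not_installed("survival")
    set.seed(44)
    for (i in 1:20) {
        da <- sample(1:10, 15, replace = TRUE) / 2
        db <- sample(1:12, 18, replace = TRUE) / 2
        ours <- logrankTest(da, durationsB = db)
        ref <- survival::survdiff(
            survival::Surv(c(da, db)) ~ rep(1:2, c(15, 18)))
        expect_equal(ours$statistic, ref$chisq, tolerance = 1e-8)
        expect_equal(ours$p.value,
                     pchisq(ref$chisq, 1, lower.tail = FALSE),
                     tolerance = 1e-6)
    }
})

test_that("pairwise log-rank covers all pairs with Bonferroni", {
    dur <- c(1, 2, 3, 2, 3, 4, 5, 6, 7)
    grp <- rep(c("a", "b", "c"), each = 3)
    out <- pairwiseLogrank(dur, group = grp)
    expect_equal(nrow(out), 3)
    expect_equal(out$p.adjusted, pmin(1, 3 * out$p.value))
    same <- pairwiseLogrank(rep(dur[1:3], 3), group = grp)
    expect_true(all(same$p.adjusted == 1))
})

test_that("Kruskal-Wallis handles ties and matches the rank formula", {
    vals <- c(1, 2, 2, 3, 5, 5, 5, 8, 9)
    grp <- rep(c("a", "b", "c"), each = 3)
    out <- kruskalWallisTest(vals, grp)
    ## longhand: average ranks, tie-corrected H
    r <- rank(vals); N <- 9
    Rj <- tapply(r, grp, sum)
    H <- 12 / (N * (N + 1)) * sum(Rj^2 / 3) - 3 * (N + 1)
    ties <- table(vals)
    H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
    expect_equal(out$statistic, H, tolerance = 1e-12)
    expect_equal(out$df, 2L)

    ref <- kruskal.test(vals, factor(grp))
    expect_equal(out$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(out$p.value, ref$p.value, tolerance = 1e-10)

    ident <- kruskalWallisTest(rep(2, 8), rep(c("a", "b"), 4))
    expect_equal(ident$statistic, 0)
    expect_equal(ident$p.value, 1)
    expect_error(kruskalWallisTest(1:3, rep("a", 3)), "2 groups")
})

test_that("Wilcoxon exact path reproduces the enumerated null", {
    ## complete separation at n = 3 vs 3: U = 0, two-sided p = 2/20
    out <- wilcoxonTest(c(1, 2, 3), c(10, 11, 12))
    expect_equal(out$method, "wilcoxon-exact")
    expect_equal(out$statistic, 0)
    expect_equal(out$p.value, 0.1)

    ident <- wilcoxonTest(c(1, 3, 5, 7), c(1, 3, 5, 7))
    expect_equal(ident$p.value, 1)

    ref <- wilcox.test(c(1, 2, 6), c(3, 4, 5), exact = TRUE)
    ours <- wilcoxonTest(c(1, 2, 6), c(3, 4, 5))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic))
})

test_that("Wilcoxon normal approximation matches the reference with ties", {
    set.seed(55)
    for (i in 1:20) {
        x <- sample(1:6, 12, replace = TRUE)
        y <- sample(2:8, 15, replace = TRUE)
        ours <- wilcoxonTest(x, y)
        expect_equal(ours$method, "wilcoxon-normal")
        ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))
        expect_equal(ours$statistic, unname(ref$statistic))
        expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
    }
    expect_error(wilcoxonTest(c(1, 1, 2), c(2, 3), exact = TRUE), "ties")
    expect_error(wilcoxonTest(numeric(), 1:3), "empty")
})

test_that("pairwise Wilcoxon applies the Bonferroni cap", {
    set.seed(56)
    vals <- c(rnorm(6), rnorm(6) + 0.2, rnorm(6) + 0.4)
    grp <- rep(c("a", "b", "c"), each = 6)
    out <- pairwiseWilcoxon(vals, grp)
    expect_equal(nrow(out), 3)
    expect_equal(out$p.adjusted, pmin(1, 3 * out$p.value))
    expect_true(all(out$p.adjusted <= 1))
    expect_true(all(out$p.adjusted >= out$p.value))
})

test_that("gaussian GLM equals the least-squares closed form", {
    set.seed(60)
    y <- rnorm(25, 5, 2)
    fit <- glmFit(y ~ 1, data.frame(y = y), family = "gaussian")
    expect_equal(unname(fit@coefficients), mean(y), tolerance = 1e-12)

    x <- runif(30)
    d <- data.frame(x = x, y = 2 + 3 * x)
    noiseFree <- glmFit(y ~ x, d, family = "gaussian")
    expect_equal(noiseFree@deviance, 0, tolerance = 1e-20)
    expect_equal(unname(noiseFree@coefficients), c(2, 3),
                 tolerance = 1e-10)

    d2 <- data.frame(x = x, y = 2 + 3 * x + rnorm(30))
    ours <- glmFit(y ~ x, d2, family = "gaussian")
    ls <- lm(y ~ x, d2)
    expect_equal(unname(ours@coefficients), unname(coef(ls)),
                 tolerance = 1e-10)
    ref <- glm(y ~ x, data = d2, family = gaussian())
    expect_equal(ours@aic, AIC(ref), tolerance = 1e-8)
})

test_that("poisson GLM matches an independent Newton solver and glm()", {
    d <- data.frame(x = c(0, 0.25, 0.5, 0.75, 1), y = c(1, 2, 3, 4, 5))
    ours <- glmFit(y ~ x, d, family = "poisson")
    X <- cbind(1, d$x)
    oracle <- newtonPoisson(X, d$y)
    expect_equal(unname(ours@coefficients), oracle, tolerance = 1e-8)
    ref <- glm(y ~ x, data = d, family = poisson())
    expect_equal(unname(ours@coefficients), unname(coef(ref)),
                 tolerance = 1e-8)
    expect_equal(ours@aic, AIC(ref), tolerance = 1e-8)
    expect_equal(ours@deviance, deviance(ref), tolerance = 1e-8)
    expect_error(glmFit(y ~ x, data.frame(x = 1:3, y = c(0.5, 1, 2)),
                        family = "poisson"), "integer")
})

test_that("rank-deficient designs are rejected", {
    d <- data.frame(x = 1:6, z = 2 * (1:6), y = rnorm(6))
    expect_error(glmFit(y ~ x + z, d, family = "gaussian"),
                 "rank-deficient")
})

test_that("AIC selection prefers the truth and breaks ties to smaller models", {
    fits <- list(
        glmFit(y ~ 1, data.frame(y = rnorm(10)), family = "gaussian"))
    expect_identical(selectModelAIC(fits), fits[[1]])
    expect_error(selectModelAIC(list()), "no candidate")

    ## strong interaction, n = 200: interaction model wins
    set.seed(62)
    d <- data.frame(species = rep(c("a", "b"), each = 100),
                    temperature = rep(c(20, 26), 100))
    d$lifespan <- with(d, 10 - 0.2 * (temperature - 20) -
                           2 * (species == "b") -
                           1.5 * (species == "b") * (temperature - 20) / 6 +
                           rnorm(200, 0, 0.8))
    fits <- candidateFits(d, "lifespan", family = "gaussian")
    expect_equal(selectModelAIC(fits)@modelName, "interaction")
    tab <- aicTable(fits)
    expect_equal(tab$model[1], "interaction")
    expect_equal(tab$delta_aic[1], 0)
})

test_that("equal-AIC ties resolve toward fewer parameters", {
    f1 <- glmFit(y ~ 1, data.frame(y = c(1, 2, 3)), family = "gaussian")
    f2 <- f1
    f2@rank <- 2L   # pretend a bigger model happened to tie
    f2@aic <- f1@aic
    f2@logLik <- f1@logLik + 1  # keep validity: aic = 2k - 2 ll
    f2@logLik <- (2 * (f2@rank + 1) - f2@aic) / 2
    expect_identical(selectModelAIC(list(big = f2, small = f1))@rank, 1L)
})
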