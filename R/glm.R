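## Family internals for the two supported GLMs
.glmFamily <- function(family) {
    switch(family,
        gaussian = list(
            linkinv = identity,
            mueta = function(eta) rep(1, length(eta)),
            variance = function(mu) rep(1, length(mu)),
            dev = function(y, mu) sum((y - mu)^2),
            logLik = function(y, mu) {
                n <- length(y)
                s2 <- sum((y - mu)^2) / n   # ML dispersion
                -n / 2 * (log(2 * pi * s2) + 1)
            },
            initEta = function(y) rep(mean(y), length(y))),
        poisson = list(
            linkinv = exp,
            mueta = exp,
            variance = identity,
            dev = function(y, mu)
                2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu)),
            logLik = function(y, mu) sum(stats::dpois(y, mu, log = TRUE)),
            initEta = function(y) log(y + 0.5)),
        stop("unsupported family: ", family))
}

#' Fit a generalized linear model by IRLS
#'
#' Fits a gaussian (identity link) or poisson (log link) GLM by
#' iteratively reweighted least squares, iterated to a relative deviance
#' change below `tol` (the gaussian case converges in one step and equals
#' the least-squares closed form). The AIC is `2k - 2 logLik` with `k`
#' counting the gaussian dispersion as an estimated parameter, matching
#' the usual convention for model comparison.
#'
#' @param formula model formula, e.g. `response ~ species * temperature`
#'   (alternatively pass a design matrix as `x` and response as `y`).
#' @param data data.frame for the formula interface.
#' @param family `"gaussian"` or `"poisson"`.
#' @param x,y design matrix and response for the matrix interface.
#' @param tol relative convergence tolerance on the deviance.
#' @param maxIter iteration cap (exceeding it is an error).
#' @param modelName optional label carried into model-selection output.
#' @return a \linkS4class{GLMFit}.
#' @examples
#' d <- data.frame(g = gl(2, 5), y = c(rpois(5, 4), rpois(5, 9)))
#' glmFit(y ~ g, d, family = "poisson")
#' @export
glmFit <- function(formula = NULL, data = NULL,
                   family = c("gaussian", "poisson"),
                   x = NULL, y = NULL, tol = 1e-8, maxIter = 100L,
                   modelName = NULL) {
    family <- match.arg(family)
    if (!is.null(formula)) {
        mf <- stats::model.frame(formula, data)
        y <- stats::model.response(mf)
        x <- stats::model.matrix(formula, mf)
    } else if (is.null(x) || is.null(y)) {
        stop("supply either a formula + data or x + y")
    } else {
        x <- as.matrix(x)
    }
    y <- as.numeric(y)
    if (nrow(x) != length(y))
        stop("design matrix and response dimensions differ")
    p <- ncol(x)
    if (qr(x)$rank < p)
        stop("rank-deficient design matrix")
    if (family == "poisson" && (any(y < 0) || any(y != floor(y))))
        stop("poisson family requires non-negative integer response")

    fam <- .glmFamily(family)
    eta <- fam$initEta(y)
    mu <- fam$linkinv(eta)
    dev <- fam$dev(y, mu)
    converged <- FALSE
    it <- 0L
    while (it < maxIter) {
        it <- it + 1L
        me <- fam$mueta(eta)
        w <- me^2 / fam$variance(mu)
        z <- eta + (y - mu) / me
        fit <- stats::lm.wfit(x, z, w)
        beta <- fit$coefficients
        eta <- drop(x %*% beta)
        mu <- fam$linkinv(eta)
        devNew <- fam$dev(y, mu)
        if (abs(devNew - dev) / (0.1 + abs(devNew)) < tol) {
            dev <- devNew
            converged <- TRUE
            break
        }
        dev <- devNew
    }
    if (!converged)
        stop("IRLS failed to converge in ", maxIter, " iterations")
    ll <- fam$logLik(y, mu)
    k <- p + as.integer(family == "gaussian")
    new("GLMFit",
        family = family,
        coefficients = stats::setNames(as.numeric(beta), colnames(x)),
        fitted = mu,
        logLik = ll,
        deviance = dev,
        aic = 2 * k - 2 * ll,
        rank = as.integer(p),
        nobs = length(y),
        converged = converged,
        iter = it,
        formula = formula,
        modelName = if (is.null(modelName)) {
            if (is.null(formula)) "matrix" else deparse(formula)
        } else modelName)
}

#' Fit the species/temperature candidate-model lattice
#'
#' Fits the four nested models used to quantify treatment effects on a
#' response: `~ temperature`, `~ species`, `~ species + temperature` and
#' `~ species * temperature`.
#'
#' @param data data.frame with columns `species`, `temperature` and the
#'   response.
#' @param response response column name.
#' @param family `"gaussian"` (e.g. lifespan) or `"poisson"` (e.g. total
#'   fecundity counts).
#' @return named list of \linkS4class{GLMFit} objects.
#' @export
candidateFits <- function(data, response,
                          family = c("gaussian", "poisson")) {
    family <- match.arg(family)
    forms <- list(
        temperature = ~ temperature,
        species = ~ species,
        additive = ~ species + temperature,
        interaction = ~ species * temperature)
    out <- lapply(names(forms), function(nm) {
        f <- stats::as.formula(paste(response,
                                     paste(deparse(forms[[nm]]),
                                           collapse = "")))
        glmFit(f, data, family = family, modelName = nm)
    })
    stats::setNames(out, names(forms))
}

#' Select the best model by AIC
#'
#' Returns the minimum-AIC fit among candidates fitted to the same
#' response; AIC ties are broken toward the model with fewer parameters.
#'
#' @param fits non-empty list of \linkS4class{GLMFit} objects.
#' @return the selected \linkS4class{GLMFit}.
#' @export
selectModelAIC <- function(fits) {
    if (!length(fits))
        stop("no candidate models supplied")
    if (!all(vapply(fits, is, logical(1), "GLMFit")))
        stop("all candidates must be GLMFit objects")
    nobs <- vapply(fits, function(f) f@nobs, integer(1))
    if (length(unique(nobs)) != 1L)
        stop("candidates were not fitted to the same response")
    aic <- vapply(fits, function(f) f@aic, numeric(1))
    rank <- vapply(fits, function(f) f@rank, integer(1))
    best <- order(aic, rank)[1L]
    fits[[best]]
}

#' AIC comparison table for candidate fits
#'
#' @param fits named list of \linkS4class{GLMFit} objects.
#' @return data.frame: model, k, logLik, aic, delta_aic, sorted by AIC.
#' @export
aicTable <- function(fits) {
    out <- data.frame(
        model = vapply(fits, function(f) f@modelName, character(1)),
        k = vapply(fits, function(f)
            f@rank + as.integer(f@family == "gaussian"), integer(1)),
        logLik = vapply(fits, function(f) f@logLik, numeric(1)),
        aic = vapply(fits, function(f) f@aic, numeric(1)))
    out <- out[order(out$aic, out$k), ]
    out$delta_aic <- out$aic - out$aic[1L]
    rownames(out) <- NULL
    out
}
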