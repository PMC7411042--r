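#' Kruskal-Wallis rank test
#'
#' One-way analysis of variance on ranks. With pooled average ranks
#' `R_j` summed per group, the statistic is
#' `H = (12 / (N (N + 1)) * sum(R_j^2 / n_j) - 3 (N + 1))` divided by the
#' tie correction `1 - sum(t^3 - t) / (N^3 - N)` over tie groups of size
#' `t`; `H` is chi-squared with `k - 1` df under the null. When every
#' observation is identical the statistic is defined as 0 with p = 1.
#'
#' @param values numeric observations (e.g. lifetime fecundity counts).
#' @param group group labels (>= 2 non-empty groups).
#' @return one-row data.frame: method, statistic, df, p.value, p.adjusted
#'   (NA).
#' @export
kruskalWallisTest <- function(values, group) {
    group <- as.character(group)
    if (anyNA(values) || anyNA(group))
        stop("missing values are not supported")
    lev <- unique(group)
    if (length(lev) < 2L)
        stop("need at least 2 groups")
    if (any(tabulate(factor(group, lev)) == 0L))
        stop("empty group")
    N <- length(values)
    r <- rank(values)
    Rj <- tapply(r, group, sum)
    nj <- tapply(r, group, length)
    H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
    ties <- table(values)
    corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
    H <- if (corr > 0) H / corr else 0
    df <- length(lev) - 1L
    p <- if (corr > 0) stats::pchisq(H, df, lower.tail = FALSE) else 1
    data.frame(method = "kruskal-wallis", statistic = H, df = df,
               p.value = .pFloor(p), p.adjusted = NA_real_)
}

## Exact null distribution of the Mann-Whitney U for sizes (m, n) without
## ties: frequencies of U = 0..m*n over all choose(m+n, m) equally likely
## rank subsets, by direct enumeration (sizes are capped at 8 so the
## largest case visits 12870 subsets). Cached per size pair.
.uCountsCache <- new.env(parent = emptyenv())
.wilcoxUCounts <- function(m, n) {
    key <- paste(m, n)
    if (!is.null(got <- .uCountsCache[[key]]))
        return(got)
    subsets <- utils::combn(m + n, m)
    u <- colSums(subsets) - m * (m + 1) / 2
    out <- tabulate(u + 1L, nbins = m * n + 1L)
    .uCountsCache[[key]] <- out
    out
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test. The statistic is
#' `U = sum(rank(x in pooled)) - m (m + 1) / 2`. The exact null
#' distribution (enumerated by a counting recursion over rank subsets) is
#' used when both groups have at most 8 observations and there are no
#' ties; otherwise a normal approximation with tie correction and
#' continuity correction is applied.
#'
#' @param x,y numeric samples.
#' @param exact force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact
#'   path; forcing `TRUE` with ties is an error.
#' @return one-row data.frame: method, statistic (U), df (NA), p.value,
#'   p.adjusted (NA).
#' @export
wilcoxonTest <- function(x, y, exact = NULL) {
    if (!length(x) || !length(y))
        stop("empty group")
    if (anyNA(x) || anyNA(y))
        stop("missing values are not supported")
    m <- length(x); n <- length(y)
    pooled <- c(x, y)
    r <- rank(pooled)
    U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
    hasTies <- anyDuplicated(pooled) > 0L
    if (is.null(exact))
        exact <- m <= 8L && n <= 8L && !hasTies
    if (exact && hasTies)
        stop("exact null distribution unavailable with ties")
    if (exact) {
        counts <- .wilcoxUCounts(m, n)
        tot <- sum(counts)
        if (U > m * n / 2)
            p <- 2 * sum(counts[(U:(m * n)) + 1L]) / tot
        else
            p <- 2 * sum(counts[(0:U) + 1L]) / tot
        p <- min(1, p)
    } else {
        mu <- m * n / 2
        z <- U - mu
        nt <- table(pooled)
        N <- m + n
        sigma <- sqrt((m * n / 12) *
                      ((N + 1) - sum(nt^3 - nt) / (N * (N - 1))))
        if (sigma == 0) {
            p <- 1
        } else {
            z <- (z - sign(z) * 0.5) / sigma
            p <- min(1, 2 * min(stats::pnorm(z),
                                stats::pnorm(z, lower.tail = FALSE)))
        }
    }
    data.frame(method = if (exact) "wilcoxon-exact" else "wilcoxon-normal",
               statistic = U, df = NA_integer_,
               p.value = .pFloor(p), p.adjusted = NA_real_)
}

#' All pairwise Wilcoxon tests with multiplicity correction
#'
#' Runs [wilcoxonTest()] on every unordered pair of groups and corrects
#' the p-values over the `choose(k, 2)` comparisons (default Bonferroni,
#' capped at 1).
#'
#' @param values numeric observations.
#' @param group group labels (>= 2 non-empty groups).
#' @param correction a [stats::p.adjust()] method, default "bonferroni".
#' @param exact passed to [wilcoxonTest()].
#' @return data.frame, one row per pair: group_a, group_b, method,
#'   statistic, df, p.value, p.adjusted.
#' @export
pairwiseWilcoxon <- function(values, group, correction = "bonferroni",
                             exact = NULL) {
    group <- as.character(group)
    lev <- unique(group)
    if (length(lev) < 2L)
        stop("need at least 2 groups")
    pairs <- utils::combn(lev, 2L)
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
        res <- wilcoxonTest(values[group == pairs[1L, k]],
                            values[group == pairs[2L, k]], exact = exact)
        cbind(data.frame(group_a = pairs[1L, k], group_b = pairs[2L, k]),
              res)
    })
    out <- do.call(rbind, rows)
    out$p.adjusted <- .pFloor(stats::p.adjust(out$p.value,
                                              method = correction))
    out
}
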