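## database labels used by the hit-table generator
.SIM_TARGET <- "host_genome"
.SIM_CONTAM <- c("alga_monoraphidium", "alga_chlamydomonas",
                 "alga_cryptomonas")
.SIM_RRNA <- "rrna_18S_28S"

## plausible e-value for a bit score (rounded so it survives a TSV round
## trip); capped away from exact zero
.bitsToEvalue <- function(bits) {
    e <- 2^(-bits) * 4e9
    signif(pmax(e, 1e-180), 3)
}

#' Simulate a labelled hit table with ground truth
#'
#' Generates a BLAST-style hit table over five contig classes with known
#' truth, for testing the competitive assignment rule:
#' \describe{
#'   \item{target}{best target hit beats the best competitor by a margin
#'     drawn strictly above the 100-bit threshold;}
#'   \item{ambiguous}{top hit is the target but the margin lies in
#'     (0, 100];}
#'   \item{contaminant}{best competitor hit at or above the best target
#'     hit;}
#'   \item{rrna}{a strong hit against the rRNA database;}
#'   \item{nohit}{no rows at all (truth label `"unassigned"`).}
#' }
#'
#' @param nContigs number of contigs.
#' @param classMix named proportions over
#'   `c("target", "contaminant", "rrna", "nohit", "ambiguous")`; must sum
#'   to 1. Class counts are the rounded proportions.
#' @param seed integer seed; identical inputs reproduce the table.
#' @param marginRange bit-score margin range for true targets (must stay
#'   strictly above 100 to keep the fixture noiseless).
#' @return list with `hits` (a \linkS4class{HitTable}) and `truth`
#'   (data.frame `contig_id`, `class` with `"nohit"` reported as
#'   `"unassigned"`).
#' @export
simulateHitTable <- function(nContigs,
                             classMix = c(target = 0.55,
                                          contaminant = 0.25,
                                          rrna = 0.05, nohit = 0.05,
                                          ambiguous = 0.10),
                             seed = 1L,
                             marginRange = c(110, 400)) {
    need <- c("target", "contaminant", "rrna", "nohit", "ambiguous")
    if (!all(need %in% names(classMix)) ||
        abs(sum(classMix) - 1) > 1e-8 || any(classMix < 0))
        stop("'classMix' must be non-negative proportions over ",
             paste(need, collapse = "/"), " summing to 1")
    rng <- .withSeed(seed)
    on.exit(rng(), add = TRUE)

    nPer <- diff(round(cumsum(c(0, classMix[need])) * nContigs))
    names(nPer) <- need
    truth <- rep(need, nPer)
    ids <- sprintf("contig_%05d", seq_len(nContigs))

    subj <- function(db, n) sprintf("%s_seq%03d", db,
                                    sample.int(200L, n, replace = TRUE))
    rows <- list()
    addHit <- function(qid, db, bits) {
        n <- length(qid)
        data.frame(qseqid = qid, sseqid = subj(db, n),
                   pident = round(stats::runif(n, 75, 100), 2),
                   length = sample(80:1200, n, replace = TRUE),
                   mismatch = sample(0:40, n, replace = TRUE),
                   gapopen = sample(0:5, n, replace = TRUE),
                   qstart = 1L, qend = sample(80:1200, n, replace = TRUE),
                   sstart = 1L, send = sample(80:1200, n, replace = TRUE),
                   evalue = .bitsToEvalue(bits), bitscore = round(bits, 1))
    }
    for (cl in need[nPer > 0]) {
        qid <- ids[truth == cl]
        n <- length(qid)
        if (cl == "nohit") next
        if (cl == "rrna") {
            rows[[cl]] <- addHit(qid, .SIM_RRNA,
                                 stats::runif(n, 200, 600))
            next
        }
        bc <- stats::runif(n, 50, 500)   # best competitor
        contamDb <- sample(.SIM_CONTAM, n, replace = TRUE)
        if (cl == "target") {
            bt <- bc + stats::runif(n, marginRange[1L], marginRange[2L])
            rows[[cl]] <- rbind(addHit(qid, .SIM_TARGET, bt),
                                addHit(qid, contamDb, bc))
        } else if (cl == "ambiguous") {
            bt <- bc + stats::runif(n, 1, 100)
            rows[[cl]] <- rbind(addHit(qid, .SIM_TARGET, bt),
                                addHit(qid, contamDb, bc))
        } else {  # contaminant: target hit absent or dominated
            hasTarget <- stats::runif(n) < 0.5
            bt <- pmax(0, bc - stats::runif(n, 0, 150))
            rows[[cl]] <- rbind(
                addHit(qid, contamDb, bc),
                addHit(qid[hasTarget], .SIM_TARGET, bt[hasTarget]))
        }
    }
    hits <- if (length(rows)) do.call(rbind, rows) else
        data.frame(qseqid = character(), sseqid = character(),
                   pident = numeric(), length = integer(),
                   mismatch = integer(), gapopen = integer(),
                   qstart = integer(), qend = integer(),
                   sstart = integer(), send = integer(),
                   evalue = numeric(), bitscore = numeric())
    rownames(hits) <- NULL
    sids <- unique(hits$sseqid)
    labels <- stats::setNames(sub("_seq[0-9]+$", "", sids), sids)
    truthOut <- ifelse(truth == "nohit", "unassigned", truth)
    list(hits = hitTable(hits, labels, targetLabel = .SIM_TARGET,
                         rrnaLabel = .SIM_RRNA),
         truth = data.frame(contig_id = ids, class = truthOut))
}

#' Simulate an RNA-seq style count matrix with filter ground truth
#'
#' Draws negative-binomial counts (log-normal gene means, dispersion
#' `1/size`) and plants a known fraction of genes that violate the
#' low-count filter: half of the planted genes get a total count below
#' `minCount`, the other half are detected in a single sample only (with
#' a large count, so only the replicate criterion fails). The remaining
#' genes are adjusted, if ever necessary, to satisfy both criteria, so the
#' returned `keep` flags are exact ground truth.
#'
#' @param nGenes,nSamples matrix dimensions.
#' @param seed integer seed.
#' @param lowCountFraction fraction of genes constructed to fail the
#'   filter, in `[0, 1]`.
#' @param minCount,minReplicates the filter thresholds the truth flags
#'   refer to.
#' @param meanlog,sdlog,size negative-binomial parameters for expressed
#'   genes.
#' @return list with `counts` (integer matrix, genes x samples, sample
#'   metadata in `attr(counts, "samples")`) and `truth` (data.frame
#'   `gene_id`, `keep`, `reason`).
#' @export
simulateCountMatrix <- function(nGenes, nSamples, seed = 1L,
                                lowCountFraction = 0.2,
                                minCount = 10, minReplicates = 2,
                                meanlog = 4, sdlog = 1.2, size = 8) {
    stopifnot(nGenes >= 1, nSamples >= 1,
              lowCountFraction >= 0, lowCountFraction <= 1)
    rng <- .withSeed(seed)
    on.exit(rng(), add = TRUE)

    nBad <- round(lowCountFraction * nGenes)
    nLowTotal <- nBad %/% 2L
    nSingle <- nBad - nLowTotal
    reason <- c(rep("low_total", nLowTotal), rep("single_replicate", nSingle),
                rep("expressed", nGenes - nBad))
    reason <- sample(reason)   # shuffle gene order

    mu <- stats::rlnorm(nGenes, meanlog, sdlog)
    m <- matrix(stats::rnbinom(nGenes * nSamples, mu = rep(mu, nSamples),
                               size = size),
                nrow = nGenes)
    ## plant violations
    lowIdx <- which(reason == "low_total")
    if (length(lowIdx)) {
        m[lowIdx, ] <- 0L
        tot <- sample(0:(minCount - 1L), length(lowIdx), replace = TRUE)
        for (k in seq_along(lowIdx)) {
            if (tot[k] > 0) {
                sel <- sample.int(nSamples, min(nSamples, tot[k]),
                                  replace = FALSE)
                put <- stats::rmultinom(1L, tot[k],
                                        rep(1, length(sel)))[, 1L]
                m[lowIdx[k], sel] <- put
            }
        }
    }
    singleIdx <- which(reason == "single_replicate")
    if (length(singleIdx)) {
        m[singleIdx, ] <- 0L
        m[cbind(singleIdx, sample.int(nSamples, length(singleIdx),
                                      replace = TRUE))] <-
            sample(seq(minCount, minCount + 200L), length(singleIdx),
                   replace = TRUE)
    }
    ## ensure kept genes really satisfy both criteria
    goodIdx <- which(reason == "expressed")
    if (nSamples >= minReplicates) {
        for (g in goodIdx) {
            if (sum(m[g, ]) < minCount || sum(m[g, ] > 0) < minReplicates) {
                bump <- seq_len(min(nSamples, max(minReplicates, 2L)))
                m[g, bump] <- m[g, bump] + ceiling(minCount / length(bump))
            }
        }
    } else {
        reason[goodIdx] <- "single_replicate"   # cannot satisfy by design
        m[goodIdx, 1L] <- pmax(m[goodIdx, 1L], minCount)
    }
    storage.mode(m) <- "integer"
    rownames(m) <- sprintf("gene_%05d", seq_len(nGenes))
    colnames(m) <- sprintf("sample_%02d", seq_len(nSamples))
    attr(m, "samples") <- data.frame(
        sample_id = colnames(m),
        species = rep_len(c("tolerant_sp", "sensitive_sp"), nSamples),
        temperature_C = rep_len(c(20, 26), nSamples),
        replicate = seq_len(nSamples))
    keep <- rowSums(m) >= minCount & rowSums(m > 0) >= minReplicates
    list(counts = m,
         truth = data.frame(gene_id = rownames(m), keep = unname(keep),
                            reason = reason))
}
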