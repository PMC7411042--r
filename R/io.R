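#' Read and write individual-level life-history records
#'
#' The on-disk format is a CSV with one row per individual per observed
#' census interval: `individual_id, species, temperature_C,
#' interval_index` (1-based), `age_start_days, alive_at_end` (0/1),
#' `offspring_count, censored` (0/1, set on the last observed interval of
#' individuals alive at the observation cap).
#'
#' @param records a \linkS4class{LifeRecords}.
#' @param path file path.
#' @return `readLifeRecords` returns a \linkS4class{LifeRecords};
#'   `writeLifeRecords` returns `path` invisibly.
#' @export
writeLifeRecords <- function(records, path) {
    stopifnot(is(records, "LifeRecords"))
    utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                     quote = FALSE)
    invisible(path)
}

#' @rdname writeLifeRecords
#' @param censusInterval census spacing in days of the stored records;
#'   inferred from `age_start_days` when possible.
#' @export
readLifeRecords <- function(path, censusInterval = NULL) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("individual_id", "species", "temperature_C", "interval_index",
              "offspring_count", "censored")
    if (!all(need %in% names(d)))
        stop("missing columns: ", paste(setdiff(need, names(d)),
                                        collapse = ", "))
    if (is.null(censusInterval)) {
        censusInterval <- if ("age_start_days" %in% names(d) &&
                              any(d$interval_index > 1L)) {
            with(d[d$interval_index > 1L, ],
                 age_start_days[1L] / (interval_index[1L] - 1L))
        } else 0.5
    }
    ids <- unique(d$individual_id)
    J <- max(d$interval_index)
    n <- length(ids)
    off <- matrix(0L, n, J)
    idx <- match(d$individual_id, ids)
    off[cbind(idx, d$interval_index)] <- as.integer(d$offspring_count)
    last <- tapply(d$interval_index, idx, max)
    ## censored flag and species/temperature read off each individual's rows
    firstRow <- match(ids, d$individual_id)
    cens <- vapply(seq_len(n), function(i)
        any(d$censored[idx == i & d$interval_index == last[[i]]] == 1L),
        logical(1))
    new("LifeRecords",
        id = as.character(ids),
        species = as.character(d$species[firstRow]),
        temperature = as.numeric(d$temperature_C[firstRow]),
        deathInterval = as.integer(last),
        censored = cens,
        offspring = off,
        censusInterval = censusInterval)
}

#' Read and write cohort life tables
#'
#' TSV with columns `x` (age in days at interval starts), `lx`, `mx`.
#'
#' @param table a \linkS4class{CohortTable}.
#' @param path file path.
#' @param n0,censusInterval,species,temperature metadata to attach when
#'   reading (the TSV stores only the schedule).
#' @return `readCohortTable` returns a \linkS4class{CohortTable}.
#' @export
writeCohortTable <- function(table, path) {
    stopifnot(is(table, "CohortTable"))
    utils::write.table(as.data.frame(table), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeCohortTable
#' @export
readCohortTable <- function(path, n0 = NA_integer_, censusInterval = NULL,
                            species = NA_character_,
                            temperature = NA_real_) {
    d <- utils::read.delim(path)
    if (!all(c("x", "lx", "mx") %in% names(d)))
        stop("life-table TSV must have columns x, lx, mx")
    if (is.null(censusInterval))
        censusInterval <- if (nrow(d) > 1L) d$x[2L] - d$x[1L] else 1
    new("CohortTable", x = d$x, lx = d$lx, mx = d$mx,
        n0 = as.integer(n0), censusInterval = censusInterval,
        species = species, temperature = temperature)
}

.OUTFMT6 <- c("qseqid", "sseqid", "pident", "length", "mismatch",
              "gapopen", "qstart", "qend", "sstart", "send", "evalue",
              "bitscore")

#' Read and write BLAST-style tabular hits
#'
#' Hits are stored as headerless outfmt-6 TSV (qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore); the subject-to-database mapping travels in a sidecar TSV
#' with header `sseqid<TAB>database`.
#'
#' @param hits a \linkS4class{HitTable}.
#' @param hitsPath,labelsPath file paths.
#' @param targetLabel,rrnaLabel database roles, see [hitTable()].
#' @return `readHitTable` returns a \linkS4class{HitTable}.
#' @export
writeHitTable <- function(hits, hitsPath, labelsPath) {
    stopifnot(is(hits, "HitTable"))
    cols <- intersect(.OUTFMT6, names(hits@hits))
    utils::write.table(hits@hits[, cols], hitsPath, sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    utils::write.table(
        data.frame(sseqid = names(hits@labels),
                   database = unname(hits@labels)),
        labelsPath, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(hitsPath)
}

#' @rdname writeHitTable
#' @export
readHitTable <- function(hitsPath, labelsPath, targetLabel,
                         rrnaLabel = character()) {
    h <- utils::read.delim(hitsPath, header = FALSE,
                           col.names = .OUTFMT6,
                           stringsAsFactors = FALSE)
    lab <- utils::read.delim(labelsPath, stringsAsFactors = FALSE)
    if (!all(c("sseqid", "database") %in% names(lab)))
        stop("label TSV must have columns sseqid, database")
    hitTable(h, stats::setNames(lab$database, lab$sseqid),
             targetLabel = targetLabel, rrnaLabel = rrnaLabel)
}

#' Read and write count matrices
#'
#' Genes in rows, samples in columns, header row of sample ids, first
#' column `gene_id`.
#'
#' @param counts integer matrix with gene row names and sample column
#'   names.
#' @param path file path.
#' @return `readCountMatrix` returns an integer matrix.
#' @export
writeCountMatrix <- function(counts, path) {
    d <- data.frame(gene_id = rownames(counts), counts,
                    check.names = FALSE)
    utils::write.table(d, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' @rdname writeCountMatrix
#' @export
readCountMatrix <- function(path) {
    d <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1L]]
    storage.mode(m) <- "integer"
    m
}
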