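#' Construct a labelled hit table
#'
#' @param hits data.frame of alignment hits with at least `qseqid`,
#'   `sseqid`, `evalue`, `bitscore` (the full 12 outfmt-6 columns when read
#'   from disk).
#' @param labels named character vector mapping every subject id to its
#'   database label.
#' @param targetLabel the single label counting as the assignment target
#'   (e.g. the host genome database).
#' @param rrnaLabel optional label of a ribosomal-RNA database.
#' @return a \linkS4class{HitTable}.
#' @export
hitTable <- function(hits, labels, targetLabel, rrnaLabel = character()) {
    new("HitTable", hits = as.data.frame(hits), labels = labels,
        targetLabel = as.character(targetLabel),
        rrnaLabel = as.character(rrnaLabel))
}

#' Flag ribosomal-RNA contigs
#'
#' Returns the contigs with at least one hit against the rRNA database at
#' or below the e-value ceiling. Flagged contigs are classified as
#' `"rrna"` by [assignContigs()] and removed from the competitive
#' assignment.
#'
#' @param hits a \linkS4class{HitTable} whose `rrnaLabel` is set (an empty
#'   rRNA label yields an empty set).
#' @param eValueCeiling maximum e-value for a hit to count (default
#'   1e-10).
#' @return character vector of contig ids.
#' @export
flagRrna <- function(hits, eValueCeiling = 1e-10) {
    stopifnot(is(hits, "HitTable"))
    if (!length(hits@rrnaLabel) || !nrow(hits@hits))
        return(character())
    h <- hits@hits
    isR <- hits@labels[h$sseqid] == hits@rrnaLabel & h$evalue <= eValueCeiling
    unique(h$qseqid[isR])
}

#' Competitive contig assignment by bit-score gain
#'
#' Classifies each contig by comparing its best bit-score against the
#' target database (`B_t`) with its best bit-score against any competitor
#' database (`B_c`, 0 with no competitor hit):
#' \describe{
#'   \item{target}{top hit is the target (`B_t > B_c`) and the bit-score
#'     gain `B_t - B_c` strictly exceeds `gainThreshold`;}
#'   \item{ambiguous}{top hit is the target but the gain is at or below
#'     the threshold;}
#'   \item{contaminant}{`B_c >= B_t` — a tie means the top hit is not
#'     uniquely the target and fails the assignment rule;}
#'   \item{rrna}{flagged by [flagRrna()] (takes precedence);}
#'   \item{unassigned}{no hits at all.}
#' }
#' The partition is total and exclusive; raising the threshold can only
#' move contigs out of the target class.
#'
#' @param hits a \linkS4class{HitTable}.
#' @param gainThreshold minimum bit-score gain for a confident target
#'   assignment; strictly-greater-than comparison (default 100).
#' @param contigIds optional universe of contig ids; ids without hits are
#'   reported as `"unassigned"`.
#' @param eValueCeiling rRNA flagging ceiling, see [flagRrna()].
#' @return data.frame with columns `contig_id`, `class`, `margin`
#'   (`B_t - B_c`; NA for unassigned/rrna contigs).
#' @export
assignContigs <- function(hits, gainThreshold = 100, contigIds = NULL,
                          eValueCeiling = 1e-10) {
    stopifnot(is(hits, "HitTable"))
    validObject(hits)
    h <- hits@hits
    if (nrow(h) > 0L && anyNA(hits@labels[h$sseqid]))
        stop("hits against subjects without a database label")
    rrna <- flagRrna(hits, eValueCeiling)

    ids <- unique(as.character(h$qseqid))
    if (!is.null(contigIds)) {
        contigIds <- as.character(contigIds)
        ids <- union(ids, contigIds)
    }
    cls <- stats::setNames(rep("unassigned", length(ids)), ids)
    margin <- stats::setNames(rep(NA_real_, length(ids)), ids)

    if (nrow(h) > 0L) {
        lab <- hits@labels[h$sseqid]
        notRrnaDb <- if (length(hits@rrnaLabel))
            lab != hits@rrnaLabel else rep(TRUE, nrow(h))
        competitive <- !(h$qseqid %in% rrna) & notRrnaDb
        hc <- h[competitive, , drop = FALSE]
        labc <- lab[competitive]
        if (nrow(hc) > 0L) {
            isTarget <- labc == hits@targetLabel
            bt <- tapply(ifelse(isTarget, hc$bitscore, -Inf), hc$qseqid, max)
            bc <- tapply(ifelse(isTarget, -Inf, hc$bitscore), hc$qseqid, max)
            bt[!is.finite(bt)] <- 0
            bc[!is.finite(bc)] <- 0
            g <- bt - bc
            cid <- names(bt)
            cls[cid] <- ifelse(bc >= bt, "contaminant",
                        ifelse(g > gainThreshold, "target", "ambiguous"))
            margin[cid] <- g
        }
    }
    cls[names(cls) %in% rrna] <- "rrna"
    margin[names(cls) %in% rrna] <- NA_real_
    out <- data.frame(contig_id = names(cls), class = unname(cls),
                      margin = unname(margin))
    rownames(out) <- NULL
    out
}

#' Partition a FASTA file by contig assignment
#'
#' Splits contigs into class-exclusive FASTA files (`target.fasta`,
#' `contaminant.fasta`, ...) according to an [assignContigs()] result;
#' sequence ids absent from the assignment are written to the unassigned
#' file. Per-class counts always sum to the input count.
#'
#' @param fasta path to a FASTA file, or a [Biostrings::DNAStringSet].
#' @param assignment data.frame from [assignContigs()].
#' @param outDir output directory (created if needed); set NULL to skip
#'   writing and only return counts/membership.
#' @return invisible list with `counts` (named integer vector by class)
#'   and `files` (written paths, if any).
#' @export
partitionFasta <- function(fasta, assignment, outDir = NULL) {
    seqs <- if (is(fasta, "DNAStringSet")) fasta
            else Biostrings::readDNAStringSet(fasta)
    ids <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(ids))
        stop("duplicate sequence ids in FASTA input")
    names(seqs) <- ids
    cls <- stats::setNames(assignment$class, assignment$contig_id)[ids]
    cls[is.na(cls)] <- "unassigned"
    classes <- c("target", "contaminant", "ambiguous", "rrna", "unassigned")
    counts <- stats::setNames(integer(length(classes)), classes)
    tab <- table(factor(cls, levels = classes))
    counts[names(tab)] <- as.integer(tab)
    files <- character()
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        for (cl in classes) {
            path <- file.path(outDir, paste0(cl, ".fasta"))
            Biostrings::writeXStringSet(seqs[cls == cl], path)
            files[cl] <- path
        }
    }
    invisible(list(counts = counts, files = files,
                   class = stats::setNames(unname(cls), ids)))
}

#' Filter low-count genes from a count matrix
#'
#' Retains genes whose total count across all samples is at least
#' `minCount` and that are detected (nonzero) in at least `minReplicates`
#' samples — the standard pre-filter applied before differential
#' expression modelling. The operation subsets rows only (columns and
#' retained counts are untouched) and is idempotent.
#'
#' @param counts non-negative integer matrix (genes x samples), or a
#'   `SummarizedExperiment` (its first assay is filtered and the object
#'   row-subset is returned).
#' @param minCount minimum total count (default 10: totals below 10 are
#'   removed).
#' @param minReplicates minimum number of samples with a nonzero count
#'   (default 2).
#' @return the row-subset object of the same type as the input.
#' @examples
#' m <- rbind(keep = c(5, 6, 0), low = c(9, 0, 0), single = c(100, 0, 0))
#' colnames(m) <- paste0("s", 1:3)
#' filterLowCounts(m)
#' @export
filterLowCounts <- function(counts, minCount = 10, minReplicates = 2) {
    mat <- if (methods::is(counts, "SummarizedExperiment"))
        SummarizedExperiment::assay(counts) else counts
    if (!is.matrix(mat))
        mat <- as.matrix(mat)
    if (anyNA(mat) || any(mat < 0))
        stop("counts must be non-negative and non-missing")
    keep <- rowSums(mat) >= minCount & rowSums(mat > 0) >= minReplicates
    counts[keep, , drop = FALSE]
}
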