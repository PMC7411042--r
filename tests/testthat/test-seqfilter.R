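smallHits <- function(rows, target = "host", rrna = character()) {
    h <- do.call(rbind, lapply(rows, function(r)
        data.frame(qseqid = r[[1]], sseqid = r[[2]], evalue = r[[3]],
                   bitscore = r[[4]])))
    sids <- unique(h$sseqid)
    labels <- setNames(sub("_.*$", "", sids), sids)
    hitTable(h, labels, targetLabel = target, rrnaLabel = rrna)
}

test_that("assignment applies the strict bit-score-gain rule", {
    ht <- smallHits(list(
        list("c1", "host_1", 1e-50, 500), list("c1", "alga_1", 1e-30, 350),
        list("c2", "host_2", 1e-40, 400), list("c2", "alga_2", 1e-30, 350),
        list("c3", "host_3", 1e-40, 300), list("c3", "alga_3", 1e-30, 300),
        list("c4", "alga_4", 1e-30, 220),
        list("c5", "host_4", 1e-60, 900)))
    out <- assignContigs(ht, contigIds = paste0("c", 1:6))
    cls <- setNames(out$class, out$contig_id)
    expect_equal(unname(cls[paste0("c", 1:6)]),
                 c("target",       # gain 150 > 100
                   "ambiguous",    # gain 50
                   "contaminant",  # tie: top hit not uniquely target
                   "contaminant",  # competitor only
                   "target",       # no competitor, gain = 900
                   "unassigned"))  # no hits at all
    expect_equal(out$margin[out$contig_id == "c1"], 150)
    ## exactly at the threshold stays ambiguous (strict >)
    at <- smallHits(list(list("c1", "host_1", 1e-50, 450),
                         list("c1", "alga_1", 1e-30, 350)))
    expect_equal(assignContigs(at)$class, "ambiguous")
})

test_that("raising the gain threshold never adds target contigs", {
    set.seed(71)
    for (i in 1:10) {
        sim <- simulateHitTable(120, seed = i)
        loose <- assignContigs(sim$hits, gainThreshold = 50)
        strict <- assignContigs(sim$hits, gainThreshold = 200)
        tLoose <- loose$contig_id[loose$class == "target"]
        tStrict <- strict$contig_id[strict$class == "target"]
        expect_true(all(tStrict %in% tLoose))
    }
})

test_that("the class partition is total and exclusive", {
    sim <- simulateHitTable(250, seed = 13)
    out <- assignContigs(sim$hits, contigIds = sim$truth$contig_id)
    expect_setequal(out$contig_id, sim$truth$contig_id)
    expect_equal(anyDuplicated(out$contig_id), 0L)
    expect_true(all(out$class %in%
        c("target", "contaminant", "ambiguous", "rrna", "unassigned")))
})

test_that("rRNA flagging respects the e-value ceiling", {
    ht <- smallHits(list(
        list("c1", "rrna_18S", 1e-20, 300),
        list("c2", "rrna_18S", 1e-05, 300),
        list("c3", "host_1", 1e-40, 400)),
        rrna = "rrna")
    expect_equal(flagRrna(ht), "c1")
    expect_equal(sort(flagRrna(ht, eValueCeiling = 1e-4)), c("c1", "c2"))
    noR <- smallHits(list(list("c1", "host_1", 1e-40, 400)))
    expect_equal(flagRrna(noR), character())
    ## flagged contigs leave the competitive assignment entirely
    out <- assignContigs(ht)
    expect_equal(out$class[out$contig_id == "c1"], "rrna")
    expect_equal(out$class[out$contig_id == "c3"], "target")
})

test_that("FASTA partition is class-exclusive and conserves counts", {
    sim <- simulateHitTable(60, seed = 19)
    asg <- assignContigs(sim$hits, contigIds = sim$truth$contig_id)
    set.seed(20)
    seqs <- Biostrings::DNAStringSet(vapply(sim$truth$contig_id,
        function(id) paste(sample(c("A", "C", "G", "T"), 50,
                                  replace = TRUE), collapse = ""),
        character(1)))
    outDir <- withr::local_tempdir()
    res <- partitionFasta(seqs, asg, outDir)
    expect_equal(sum(res$counts), 60)
    expect_equal(unname(res$counts),
                 as.integer(table(factor(asg$class, names(res$counts)))))
    written <- sum(vapply(res$files, function(f)
        length(Biostrings::readDNAStringSet(f)), integer(1)))
    expect_equal(written, 60)

    allTarget <- data.frame(contig_id = names(seqs),
                            class = "target", margin = 200)
    res2 <- partitionFasta(seqs, allTarget, outDir)
    back <- Biostrings::readDNAStringSet(res2$files[["target"]])
    expect_equal(as.character(back), as.character(seqs))

    dup <- seqs[c(1, 1)]
    expect_error(partitionFasta(dup, allTarget, NULL), "duplicate")

    empty <- partitionFasta(Biostrings::DNAStringSet(), allTarget, NULL)
    expect_equal(sum(empty$counts), 0)
})

test_that("ids absent from the assignment fall back to unassigned", {
    seqs <- Biostrings::DNAStringSet(c(known = "ACGT", novel = "GGGG"))
    asg <- data.frame(contig_id = "known", class = "target", margin = 200)
    res <- partitionFasta(seqs, asg, NULL)
    expect_equal(unname(res$class["novel"]), "unassigned")
    expect_equal(unname(res$counts[c("target", "unassigned")]), c(1L, 1L))
})

test_that("low-count filter drops exactly the rule violators, idempotently", {
    m <- rbind(lowTotal = c(9L, 0L, 0L, 0L),
               oneRep = c(100L, 0L, 0L, 0L),
               edgeTotal = c(5L, 5L, 0L, 0L),
               spread = c(3L, 3L, 3L, 3L),
               zero = c(0L, 0L, 0L, 0L))
    colnames(m) <- paste0("s", 1:4)
    out <- filterLowCounts(m)
    expect_equal(rownames(out), c("edgeTotal", "spread"))
    expect_identical(colnames(out), colnames(m))
    expect_identical(filterLowCounts(out), out)
    ## retained counts untouched
    expect_identical(out["spread", ], m["spread", ])
    expect_error(filterLowCounts(m - 1L), "non-negative")
})

test_that("low-count filter works on SummarizedExperiment containers", {
    skip_if_not_installed("SummarizedExperiment")
    sim <- simulateCountMatrix(50, 6, seed = 23, lowCountFraction = 0.3)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = sim$counts))
    out <- filterLowCounts(se)
    expect_s4_class(out, "SummarizedExperiment")
    expect_equal(rownames(out), sim$truth$gene_id[sim$truth$keep])
})

test_that("hit tables and count matrices survive TSV round trips", {
    sim <- simulateHitTable(80, seed = 29)
    hitsPath <- withr::local_tempfile(fileext = ".tsv")
    labelsPath <- withr::local_tempfile(fileext = ".tsv")
    writeHitTable(sim$hits, hitsPath, labelsPath)
    back <- readHitTable(hitsPath, labelsPath, targetLabel = "host_genome",
                         rrnaLabel = "rrna_18S_28S")
    a1 <- assignContigs(sim$hits, contigIds = sim$truth$contig_id)
    a2 <- assignContigs(back, contigIds = sim$truth$contig_id)
    a1 <- a1[order(a1$contig_id), ]; rownames(a1) <- NULL
    a2 <- a2[order(a2$contig_id), ]; rownames(a2) <- NULL
    expect_identical(a1, a2)

    cm <- simulateCountMatrix(40, 5, seed = 31)
    cPath <- withr::local_tempfile(fileext = ".tsv")
    writeCountMatrix(cm$counts, cPath)
    backM <- readCountMatrix(cPath)
    cnt <- cm$counts; attr(cnt, "samples") <- NULL
    expect_identical(backM, cnt)
})

test_that("mislabelled hits are rejected", {
    h <- data.frame(qseqid = "c1", sseqid = "mystery", evalue = 1e-5,
                    bitscore = 100)
    expect_error(hitTable(h, c(other = "host"), targetLabel = "host"),
                 "database label")
})
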