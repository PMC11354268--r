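test_that("plus-strand single-exon coordinates partition the transcript", {
    set.seed(1)
    chromSeq <- randSeq(100)
    an <- makeAnnotation(list(list(
        chrom = "chr1", chromSeq = chromSeq, gene_id = "g1",
        transcript_id = "t1", strand = "+",
        exons = rbind(c(1, 100)), cds = rbind(c(21, 80)))))
    g <- geneTable(an)
    expect_equal(g$utr5_len, 20L)
    expect_equal(g$cds_len, 60L)
    expect_equal(g$utr3_len, 20L)
    expect_equal(g$spliced_length, 100L)
    expect_equal(as.character(regionSeqs(an, "utr5")[["g1"]]),
                 substr(chromSeq, 1, 20))
    expect_equal(as.character(regionSeqs(an, "cds")[["g1"]]),
                 substr(chromSeq, 21, 80))
    expect_equal(as.character(transcriptSeqs(an)[["g1"]]), chromSeq)
})

test_that("minus-strand transcripts are reverse-complemented, 5'UTR on genomic 3' side", {
    set.seed(2)
    chromSeq <- randSeq(100)
    an <- makeAnnotation(list(list(
        chrom = "chr1", chromSeq = chromSeq, gene_id = "g1",
        transcript_id = "t1", strand = "-",
        exons = rbind(c(1, 100)), cds = rbind(c(21, 80)))))
    g <- geneTable(an)
    expect_equal(g$utr5_len, 20L)
    expect_equal(g$cds_len, 60L)
    expect_equal(g$tss, 100)
    rc <- function(s) as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    ## 5'UTR comes from the genomic 3' side (81..100), reverse-complemented
    expect_equal(as.character(regionSeqs(an, "utr5")[["g1"]]),
                 rc(substr(chromSeq, 81, 100)))
    expect_equal(as.character(transcriptSeqs(an)[["g1"]]), rc(chromSeq))
})

test_that("introns are spliced out and the manual splice matches", {
    set.seed(3)
    chromSeq <- randSeq(220)
    ## exons 1-90 and 141-220; CDS 31-90 + 141-170 (60 nt total + stop in
    ## exon 2): keep it simple - CDS genomic span 31..170 clipped to exons
    an <- makeAnnotation(list(list(
        chrom = "chr1", chromSeq = chromSeq, gene_id = "g1",
        transcript_id = "t1", strand = "+",
        exons = rbind(c(1, 90), c(141, 220)),
        cds = rbind(c(31, 90), c(141, 173)))))
    g <- geneTable(an)
    expect_equal(g$spliced_length, 90L + 80L)
    expect_equal(g$utr5_len, 30L)
    expect_equal(g$cds_len, 60L + 33L)
    manual <- paste0(substr(chromSeq, 1, 90), substr(chromSeq, 141, 220))
    expect_equal(as.character(transcriptSeqs(an)[["g1"]]), manual)
})

test_that("invalid CDS lengths are skipped and missing chroms are fatal", {
    set.seed(4)
    chromSeq <- randSeq(100)
    expect_warning(
        expect_error(
            makeAnnotation(list(list(
                chrom = "chr1", chromSeq = chromSeq, gene_id = "g1",
                transcript_id = "t1", strand = "+",
                exons = rbind(c(1, 100)), cds = rbind(c(21, 81))))),
            "no usable transcript"),
        "multiple of 3")

    dir <- tempfile(); dir.create(dir)
    writeLines(c(">chr1", chromSeq), file.path(dir, "g.fa"))
    writeLines(paste("chrMISSING", "t", "exon", 1, 99, ".", "+", ".",
                     'gene_id "g"; transcript_id "t";', sep = "\t"),
               file.path(dir, "a.gtf"))
    expect_error(parseGTF(file.path(dir, "a.gtf"), file.path(dir, "g.fa")),
                 "chrMISSING")
})

test_that("representative transcript is longest CDS, ties broken by id", {
    set.seed(5)
    chromSeq <- randSeq(300)
    base <- list(chrom = "chr1", chromSeq = chromSeq, gene_id = "g1",
                 strand = "+")
    an <- makeAnnotation(list(
        c(base, list(transcript_id = "tB", exons = rbind(c(1, 200)),
                     cds = rbind(c(21, 80)))),
        c(base, list(transcript_id = "tA", exons = rbind(c(1, 200)),
                     cds = rbind(c(21, 110))))))
    expect_equal(geneTable(an)$transcript_id, "tA")   # longer CDS wins

    an2 <- makeAnnotation(list(
        c(base, list(transcript_id = "tB", exons = rbind(c(1, 200)),
                     cds = rbind(c(21, 80)))),
        c(base, list(transcript_id = "tA", exons = rbind(c(1, 200)),
                     cds = rbind(c(31, 90))))))
    expect_equal(geneTable(an2)$transcript_id, "tA")  # tie: smaller id
})

test_that("parsed models always satisfy the region partition invariant", {
    sim <- simulateAnnotation(simulationConfig(n_genes = 40L, seed = 9L))
    d <- tempfile()
    writeSimulation(c(sim, list(
        counts = simulateCounts(simulationConfig(n_genes = 40L, seed = 9L),
                                sim$truth),
        footprints = data.frame(gene_id = "g0001", five_prime_pos = 0L,
                                length = 28L))), d)
    an <- parseGTF(file.path(d, "annot.gtf"), file.path(d, "genome.fa"))
    g <- geneTable(an)
    expect_true(all(g$utr5_len >= 0 & g$utr3_len >= 0))
    expect_true(all(g$cds_len > 0 & g$cds_len %% 3 == 0))
    expect_true(all(g$utr5_len + g$cds_len + g$utr3_len ==
                    g$spliced_length))
})

test_that("region FASTA round-trips byte-identically", {
    set.seed(6)
    an <- simpleAnnotation(randSeq(25), randSeq(60), randSeq(30))
    dir <- tempfile()
    writeRegionFasta(an, dir)
    for (region in c("utr5", "cds", "utr3")) {
        back <- Biostrings::readDNAStringSet(
            file.path(dir, paste0(region, ".fa")))
        expect_identical(as.character(back),
                         as.character(regionSeqs(an, region)))
    }
})

test_that("count tables validate integers, duplicates and library sizes", {
    dir <- tempfile(); dir.create(dir)
    w <- function(lines, f) { writeLines(lines, file.path(dir, f));
                              file.path(dir, f) }

    p <- w(c("gene_id\tCG_1\tHS_1", "g1\t0\t0", "g2\t0\t0"), "zeros.tsv")
    ct <- readCounts(p, "rna")
    expect_equal(unname(libSizes(ct)), c(0, 0))

    p <- w(c("gene_id\tCG_1\tHS_1", "g1\t1\t2", "g1\t3\t4"), "dup.tsv")
    expect_error(readCounts(p, "rna"), "duplicate")

    p <- w(c("gene_id\tCG_1\tHS_1", "g1\t1\t-2"), "neg.tsv")
    expect_error(readCounts(p, "rna"), "negative or non-integer")

    p <- w(c("gene_id\tCG_1\tCG_2\tHS_1\tHS_2",
             "g1\t1\t2\t3\t4", "g2\t5\t6\t7\t8", "g3\t9\t10\t11\t12"),
           "ok.tsv")
    ct <- readCounts(p, "ribo")
    expect_equal(unname(libSizes(ct)), c(15, 18, 21, 24))
    expect_equal(as.character(sampleGroups(ct)), c("CG", "CG", "HS", "HS"))
})
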