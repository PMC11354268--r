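## 5'UTR with a single embedded uORF: ATG + 18 sense codons + TAA at
## offset 7 (60 nt total)
.embeddedUtr <- function() {
    set.seed(61)
    body <- paste(rep("GCT", 18), collapse = "")
    paste0("CCGCCGC", "ATG", body, "TAA",
           paste(rep("C", 30), collapse = ""))
}

test_that("uORF finder applies the ATG/stop scan and 60-450 nt bounds", {
    expect_equal(nrow(findUorfs(paste(rep("C", 100), collapse = ""))), 0)

    u <- findUorfs(.embeddedUtr())
    expect_equal(u$start, 7)
    expect_equal(u$length, 60)
    expect_equal(substr(u$seq, 1, 3), "ATG")
    expect_equal(substr(u$seq, 58, 60), "TAA")

    ## 57 nt (17 sense codons) falls below the 60-nt floor
    short <- paste0("CCGCCGC", "ATG", paste(rep("GCT", 17), collapse = ""),
                    "TAA", paste(rep("C", 30), collapse = ""))
    expect_equal(nrow(findUorfs(short)), 0)
    ## but is found when the floor is lowered
    expect_equal(findUorfs(short, minLen = 57)$length, 57)
})

test_that("finder equals the brute-force codon-walk oracle on random 5'UTRs", {
    set.seed(62)
    for (i in 1:300) {
        s <- randSeq(sample(100:1000, 1))
        mine <- findUorfs(s)
        oracle <- bruteUorfs(s)
        expect_equal(nrow(mine), nrow(oracle))
        if (nrow(mine)) {
            expect_equal(mine$start, oracle$start)
            expect_equal(mine$length, oracle$length)
        }
    }
})

test_that("reported uORFs decode with no internal in-frame stop", {
    set.seed(63)
    for (i in 1:50) {
        u <- findUorfs(randSeq(600))
        for (s in u$seq) {
            codons <- substring(s, seq(1, nchar(s) - 2, 3),
                                seq(3, nchar(s), 3))
            expect_equal(codons[1], "ATG")
            expect_true(utils::tail(codons, 1) %in% c("TAA", "TAG", "TGA"))
            expect_false(any(head(codons, -1)[-1] %in%
                             c("TAA", "TAG", "TGA")))
        }
    }
})

test_that("translated classification applies the FPKM >= 1 rule inclusively", {
    uorfs <- data.frame(gene_id = "g1", start = 10L, length = 60L)
    noFp <- data.frame(gene_id = character(0),
                       five_prime_pos = integer(0), length = integer(0))
    r <- classifyTranslated(uorfs, noFp, libSize = 1e6)
    expect_equal(r$fpkm_ribo, 0)
    expect_false(r$translated)

    ## 6 footprints with P-sites inside a 60-nt interval, library 1e6
    fp <- data.frame(gene_id = "g1", five_prime_pos = c(0, 5, 10, 20, 30,
                                                        40), length = 28)
    r <- classifyTranslated(uorfs, fp, libSize = 1e6)
    expect_equal(r$fpkm_ribo, 6e9 / (1e6 * 60))
    expect_true(r$translated)

    ## FPKM exactly 1 is translated (inclusive boundary)
    u100 <- data.frame(gene_id = "g1", start = 0L, length = 100L)
    one <- data.frame(gene_id = "g1", five_prime_pos = 38, length = 28)
    r <- classifyTranslated(u100, one, libSize = 1e7)
    expect_equal(r$fpkm_ribo, 1)
    expect_true(r$translated)
})

test_that("Kozak context is the -6..+4 window, N-padded at boundaries", {
    expect_equal(kozakContext("GCCACCATGGTT", 6), "GCCACCATGG")
    ctx <- kozakContext("CCATGGGGGGGG", 2)
    expect_equal(nchar(ctx), 10)
    expect_equal(substr(ctx, 1, 4), "NNNN")
    expect_equal(substr(ctx, 5, 10), "CCATGG")
    ## right boundary: ATG at the very end
    ctx2 <- kozakContext("CCCCCCATG", 6)
    expect_equal(substr(ctx2, 10, 10), "N")
})

test_that("upstream -4..-1 GC pools the group and excludes N", {
    expect_equal(startContextGC("GCCACCATGG"), 0.75)  # CACC: 3 of 4 G/C
    expect_equal(startContextGC("GTTACCATGG"), 0.5)   # TACC: 2 of 4 G/C
    expect_equal(startContextGC(rep("GCCACCATGG", 7)), 0.75)
    expect_true(is.na(suppressWarnings(startContextGC("NNNNNNATGG"))))
    expect_warning(startContextGC(character(0)), "empty")
})

test_that("position frequency matrix recovers planted base probabilities", {
    pfm1 <- positionFrequencyMatrix("GCCACCATGG")
    expect_equal(colSums(pfm1), setNames(rep(1, 10), colnames(pfm1)))
    expect_equal(unname(pfm1["G", 1]), 1)             # one-hot columns

    set.seed(64)
    p <- c(A = 0.1, C = 0.2, G = 0.4, T = 0.3)
    ctx <- vapply(1:5000, function(i) paste(
        c(sample(names(p), 6, TRUE, p), "ATG",
          sample(names(p), 1, TRUE, p)), collapse = ""), "")
    pfm <- positionFrequencyMatrix(ctx)
    expect_true(all(abs(pfm[, 1:6] - p) < 0.02))
    expect_equal(unname(pfm["A", "+1"]), 1)           # degenerate ATG cols
    expect_equal(unname(pfm["T", "+2"]), 1)
    expect_equal(unname(pfm["G", "+3"]), 1)
})

test_that("uORF distances follow the stated normalization", {
    d <- uorfDistances(0, 200)
    expect_equal(d$dist_to_tss, 0)
    expect_equal(d$dist_to_cds_norm, 1)
    d <- uorfDistances(150, 200)
    expect_equal(d$dist_to_tss, 150)
    expect_equal(d$dist_to_cds_norm, 0.25)
    set.seed(65)
    st <- sample(0:199, 50, TRUE)
    d <- uorfDistances(st, 200)
    expect_true(all(d$dist_to_cds_norm > 0 & d$dist_to_cds_norm <= 1))
})

test_that("group comparison covers exactly five metrics and detects shifts", {
    mk <- function(n, translated, lenMean) data.frame(
        translated = translated, length = rnorm(n, lenMean, 10),
        utr5_len = rnorm(n, 200, 20), nmfe = rnorm(n, -0.3, 0.05),
        dist_to_cds_norm = runif(n), dist_to_tss = runif(n, 0, 200))
    set.seed(66)
    same <- rbind(mk(50, TRUE, 100), mk(50, FALSE, 100))
    ## identical groups elementwise -> p = 1 everywhere
    dup <- mk(10, TRUE, 100); dup2 <- dup; dup2$translated <- FALSE
    r0 <- compareUorfGroups(rbind(dup, dup2))
    expect_equal(r0$pvalue, rep(1, 5))
    expect_setequal(r0$metric, c("uorf_length", "utr5_length", "nmfe",
                                 "dist_to_cds_norm", "dist_to_tss"))

    shifted <- rbind(mk(200, TRUE, 90), mk(200, FALSE, 150))
    r <- compareUorfGroups(shifted)
    lenRow <- r[r$metric == "uorf_length", ]
    expect_lt(lenRow$mean_translated, lenRow$mean_untranslated)
    expect_lt(lenRow$pvalue, 1e-6)
    expect_error(compareUorfGroups(rbind(mk(2, TRUE, 90),
                                         mk(10, FALSE, 90))),
                 "at least 3")
})

test_that("TE by uORF class partitions genes and runs pairwise KS tests", {
    uorfs <- data.frame(
        gene_id = c("g2", "g3", "g3", "g4"),
        translated = c(TRUE, TRUE, TRUE, FALSE))
    r <- teByUorfClass(c("g1", "g2", "g3", "g4"), c(0, 0.5, 1, 0), uorfs)
    expect_equal(as.character(r$classes),
                 c("none", "single", "multiple", "none"))

    ## all genes in one class: no tests, sizes reported
    r1 <- suppressWarnings(
        teByUorfClass(paste0("g", 1:10), rnorm(10),
                      uorfs[0, ]))
    expect_equal(nrow(r1$tests), 0)
    expect_equal(unname(r1$sizes["none"]), 10L)
})

test_that("KS on equal TE distributions rejects at about the nominal rate", {
    set.seed(67)
    reps <- 100
    hits <- 0
    uorfs <- data.frame(gene_id = paste0("g", 1:300),
                        translated = rep(c(TRUE, FALSE), 150))
    genes <- paste0("g", 1:600)   # 150 single-uORF, 450 none
    for (i in seq_len(reps)) {
        r <- suppressWarnings(teByUorfClass(genes, rnorm(600), uorfs))
        p <- r$tests$pvalue[r$tests$class1 == "none" &
                            r$tests$class2 == "single"]
        if (p < 0.05) hits <- hits + 1
    }
    expect_lt(hits / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("a planted TE shift in multi-uORF genes is detected by KS", {
    set.seed(68)
    ids <- paste0("g", 1:400)
    uorfs <- do.call(rbind, lapply(201:400, function(i) data.frame(
        gene_id = paste0("g", i), translated = TRUE)))
    uorfs <- rbind(uorfs, uorfs)      # two translated uORFs each
    te <- c(rnorm(200), rnorm(200, mean = 1))
    r <- suppressWarnings(teByUorfClass(ids, te, uorfs))
    p <- r$tests$pvalue[r$tests$class1 == "none" &
                        r$tests$class2 == "multiple"]
    expect_lt(p, 1e-3)
})
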