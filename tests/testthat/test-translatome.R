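test_that("the nine-quadrant truth table is exact and exhaustive", {
    expected <- c("up.down" = "A", "up.ns" = "B", "up.up" = "C",
                  "ns.down" = "D", "ns.ns" = "E", "ns.up" = "F",
                  "down.down" = "G", "down.ns" = "H", "down.up" = "I")
    for (tx in c("up", "down", "ns")) for (tl in c("up", "down", "ns"))
        expect_equal(classifyQuadrant(tx, tl),
                     unname(expected[paste(tx, tl, sep = ".")]))
    expect_equal(sort(unname(expected)), LETTERS[1:9])   # bijection
    expect_error(classifyQuadrant("up", "sideways"), "up/down/ns")
})

test_that("overlap summary reports shared DEGs under all denominators", {
    mk <- function(ids, status) data.frame(gene_id = ids, status = status)
    tx <- mk(c("g1", "g2", "g3"), c("up", "up", "ns"))
    tl <- mk(c("g1", "g2", "g3"), c("ns", "up", "up"))
    ov <- overlapSummary(tx, tl)
    expect_equal(ov$up$n_shared, 1)
    expect_equal(ov$up$frac_of_tl, 0.5)
    expect_equal(ov$up$frac_of_tx, 0.5)
    expect_equal(ov$up$frac_of_union, 1 / 3)

    disj <- overlapSummary(mk("g1", "up"), mk("g2", "up"))
    expect_equal(disj$up$n_shared, 0)
    ident <- overlapSummary(tx, tx)
    expect_equal(ident$up$frac_of_tl, 1)
})

test_that("fold-change correlation respects the FPKM filter", {
    x <- c(-2, -1, 0, 1, 2, 3)
    fpkm <- rep(10, 6)
    expect_equal(foldchangeCorrelation(x, x, fpkm, fpkm)$r, 1)
    expect_equal(foldchangeCorrelation(x, -x, fpkm, fpkm)$r, -1)
    ## low-FPKM genes are dropped from the computation
    y <- x; y[6] <- -50
    r <- foldchangeCorrelation(x, y, c(rep(10, 5), 0.1), fpkm)
    expect_equal(r$n_used, 5)
    expect_equal(r$r, 1)
    expect_error(foldchangeCorrelation(x[1:2], x[1:2], fpkm[1:2],
                                       fpkm[1:2]), "fewer than 3")
})

test_that("r2 grows with the planted shared-effect fraction", {
    r2For <- function(shared, seed) {
        set.seed(seed)
        n <- 500
        common <- rnorm(n, sd = 1.5)
        tx <- common + rnorm(n, sd = 0.3)
        tl <- ifelse(runif(n) < shared, common, rnorm(n, sd = 1.5)) +
            rnorm(n, sd = 0.3)
        foldchangeCorrelation(tx, tl, rep(10, n), rep(10, n))$r2
    }
    r2s <- vapply(c(0.2, 0.5, 0.9), r2For, 0, seed = 100)
    expect_true(all(diff(r2s) > 0))
})

test_that("TE follows the FPKM ratio with undefined cases flagged", {
    expect_equal(computeTE(8, 2)$te, 4)
    expect_equal(computeTE(8, 2)$log2te, 2)
    expect_equal(computeTE(5, 5)$log2te, 0)
    z <- computeTE(0, 3)
    expect_false(z$defined)
    expect_equal(z$te, 0)
    u <- computeTE(3, 0)
    expect_false(u$defined)
    ## pseudocount rescues the zero denominator
    expect_true(computeTE(3, 0, pseudocount = 0.01)$defined)
})

test_that("TE over FPKM is invariant to a common library-size factor", {
    cnt <- c(ribo = 120, rna = 80)
    te1 <- computeTE(computeFPKM(cnt["ribo"], 900, 1e6),
                     computeFPKM(cnt["rna"], 900, 1e6))$te
    te2 <- computeTE(computeFPKM(cnt["ribo"], 900, 5e6),
                     computeFPKM(cnt["rna"], 900, 5e6))$te
    expect_equal(te1, te2)
})

test_that("TE bins partition log2TE at -1, 0, 1 with stated boundaries", {
    expect_equal(as.character(teBin(c(2, -0.5, 0, -1, 1, 0.99, -1.01))),
                 c("high", "mid_low", "mid_low", "low", "high",
                   "mid_high", "low"))
})

test_that("TE-differential handles degenerate and planted cases", {
    cg <- rbind(g1 = c(0.2, 0.1, 0.3), g2 = c(0, 0, 0))
    hs <- rbind(g1 = c(0.2, 0.1, 0.3), g2 = c(2, 2, 2))
    r <- teDifferential(cg, hs)
    expect_equal(r$delta_log2te[1], 0)
    expect_equal(r$te_status[1], "ns")
    expect_equal(r$delta_log2te[2], 2)

    ## undefined replicate TE excludes the gene
    cg2 <- rbind(g1 = c(0.1, -Inf, 0.2))
    hs2 <- rbind(g1 = c(1, 2, 1))
    expect_equal(teDifferential(cg2, hs2)$te_status, "excluded")
})

test_that("planted two-bit TE shifts are recovered at NB depth 100", {
    set.seed(91)
    ng <- 500
    l2 <- function(mu) {
        m <- matrix(rnbinom(ng * 3, mu = mu, size = 10), ng)
        rownames(m) <- paste0("g", 1:ng)
        m
    }
    l2te <- function(ribo, rna) log2((ribo + 0.5) / (rna + 0.5))
    cg <- l2te(l2(100), l2(100))
    hs <- l2te(l2(400), l2(100))     # planted deltaTE = 2 for every gene
    r <- teDifferential(cg, hs)
    expect_gt(mean(r$te_status == "up"), 0.8)
})

test_that("transcription x TE classes cover the 4- and 5-group partitions", {
    expect_equal(classifyTxTE("up", "up"), "both")
    expect_equal(classifyTxTE("up", "ns"), "transcription_only")
    expect_equal(classifyTxTE("ns", "down"), "te_only")
    expect_equal(classifyTxTE("ns", "ns"), "neither")
    expect_equal(classifyTxTE("ns", "excluded"), "neither")
    expect_equal(classifyTxTE(c("up", "up"), c("up", "down"),
                              splitBothByDirection = TRUE),
                 c("both_concordant", "both_discordant"))
})

test_that("quadrant counts always conserve the gene universe", {
    set.seed(92)
    for (i in 1:5) {
        tx <- sample(c("up", "down", "ns"), 200, TRUE)
        tl <- sample(c("up", "down", "ns"), 200, TRUE)
        q <- classifyQuadrant(tx, tl)
        expect_equal(sum(table(factor(q, levels = LETTERS[1:9]))), 200)
    }
})
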