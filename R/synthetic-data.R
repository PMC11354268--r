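#' SimulationConfig: parameters of the synthetic translatome generator
#'
#' Defaults emulate the statistical structure of a liver ribosome-profiling
#' heat-stress experiment: footprint lengths peaked at 26-28 nt, ~94\% CDS
#' occupancy, strong frame-0 periodicity (weight 0.85), negative-binomial
#' replicate counts (3 vs 3) with planted transcription-level and TE-level
#' two-bit (4-fold) changes, and 5'UTRs carrying planted uORFs of known
#' translated status at an average rate of 1.3 per gene.
#'
#' @slot n_genes number of genes.
#' @slot utr5_meanlog,utr5_sdlog,cds_meanlog,cds_sdlog,utr3_meanlog,utr3_sdlog
#'   log-normal length parameters (nt) for the three regions.
#' @slot gc_mean background GC fraction.
#' @slot n_replicates replicates per group.
#' @slot mean_count NB mean count per gene.
#' @slot dispersion NB dispersion.
#' @slot frac_tx_up,frac_tx_down,frac_te_up,frac_te_down fractions of genes
#'   carrying planted transcription-level / TE-level effects.
#' @slot effect_log2fc planted effect size (log2).
#' @slot n_footprints footprints emitted by \link{simulateFootprints}.
#' @slot footprint_len_weights named weights over lengths 25-35.
#' @slot frame0_weight probability that a CDS P-site falls in frame 0.
#' @slot region_weights named weights over utr5/cds/utr3 occupancy.
#' @slot uorf_rate mean planted uORFs per gene (Poisson).
#' @slot uorf_translated_frac fraction of planted uORFs that are translated.
#' @slot kozak_pfm 4 x 10 frequency matrix (rows A/C/G/T) from which the
#'   start-codon contexts of translated uORFs are drawn.
#' @slot clean_background suppress chance ATGs in 5'UTR backgrounds (drawn
#'   from C/G/T only) so planted-uORF recovery can be asserted as set
#'   equality.
#' @slot multi_exon insert one intron per transcript to exercise the
#'   splicing path.
#' @slot intron_len intron length when \code{multi_exon} is TRUE.
#' @slot seed RNG seed.
#'
#' @aliases SimulationConfig
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(
        n_genes = "integer",
        utr5_meanlog = "numeric", utr5_sdlog = "numeric",
        cds_meanlog = "numeric", cds_sdlog = "numeric",
        utr3_meanlog = "numeric", utr3_sdlog = "numeric",
        gc_mean = "numeric",
        n_replicates = "integer",
        mean_count = "numeric",
        dispersion = "numeric",
        frac_tx_up = "numeric", frac_tx_down = "numeric",
        frac_te_up = "numeric", frac_te_down = "numeric",
        effect_log2fc = "numeric",
        n_footprints = "integer",
        footprint_len_weights = "numeric",
        frame0_weight = "numeric",
        region_weights = "numeric",
        uorf_rate = "numeric",
        uorf_translated_frac = "numeric",
        kozak_pfm = "matrix",
        clean_background = "logical",
        multi_exon = "logical",
        intron_len = "integer",
        seed = "integer"
    )
)

.defaultKozakPFM <- function() {
    pfm <- matrix(0, 4, 10, dimnames = list(
        c("A", "C", "G", "T"),
        c(paste0("-", 6:1), paste0("+", 1:4))))
    # GC-rich upstream (GCCACC-like), A/G at -3, fixed ATG, G-rich +4.
    for (j in 1:6) pfm[, j] <- c(0.15, 0.40, 0.45, 0)
    pfm[, 4] <- c(0.55, 0.10, 0.35, 0)          # -3: A/G dominated
    pfm[, 7] <- c(1, 0, 0, 0)                    # +1 A
    pfm[, 8] <- c(0, 0, 0, 1)                    # +2 T
    pfm[, 9] <- c(0, 0, 1, 0)                    # +3 G
    pfm[, 10] <- c(0, 0.3, 0.7, 0)               # +4 G-rich
    pfm
}

.defaultLenWeights <- function() {
    w <- c(0.04, 0.20, 0.25, 0.20, 0.10, 0.07, 0.05, 0.04, 0.03,
           0.01, 0.01)
    names(w) <- as.character(25:35)
    w
}

setValidity("SimulationConfig", function(object) {
    msgs <- character(0)
    frac <- c(object@frac_tx_up, object@frac_tx_down, object@frac_te_up,
              object@frac_te_down, object@uorf_translated_frac,
              object@frame0_weight, object@gc_mean)
    if (any(frac < 0 | frac > 1))
        msgs <- c(msgs, "fractions must lie in [0, 1]")
    if (object@frac_tx_up + object@frac_tx_down > 1)
        msgs <- c(msgs, "frac_tx_up + frac_tx_down must not exceed 1")
    if (abs(sum(object@region_weights) - 1) > 1e-9)
        msgs <- c(msgs, "region_weights must sum to 1")
    if (abs(sum(object@footprint_len_weights) - 1) > 1e-9)
        msgs <- c(msgs, "footprint_len_weights must sum to 1")
    if (!all(dim(object@kozak_pfm) == c(4, 10)))
        msgs <- c(msgs, "kozak_pfm must be 4 x 10")
    if (length(msgs)) msgs else TRUE
})

#' Construct a SimulationConfig
#'
#' All arguments default to the study-like conditions described in
#' \linkS4class{SimulationConfig}.
#'
#' @param n_genes,n_replicates,mean_count,dispersion,seed see class doc.
#' @param utr5_meanlog,utr5_sdlog,cds_meanlog,cds_sdlog,utr3_meanlog,utr3_sdlog
#'   region length distributions (log-normal, nt).
#' @param gc_mean,frac_tx_up,frac_tx_down,frac_te_up,frac_te_down,effect_log2fc
#'   background composition and planted effects.
#' @param n_footprints,footprint_len_weights,frame0_weight,region_weights
#'   footprint generator parameters.
#' @param uorf_rate,uorf_translated_frac,kozak_pfm,clean_background uORF
#'   planting parameters.
#' @param multi_exon,intron_len optional splicing structure.
#' @return a \code{SimulationConfig}
#' @export
simulationConfig <- function(n_genes = 2000L,
                             utr5_meanlog = log(150), utr5_sdlog = 0.35,
                             cds_meanlog = log(600), cds_sdlog = 0.35,
                             utr3_meanlog = log(400), utr3_sdlog = 0.40,
                             gc_mean = 0.45,
                             n_replicates = 3L,
                             mean_count = 200,
                             dispersion = 0.1,
                             frac_tx_up = 0.10, frac_tx_down = 0.10,
                             frac_te_up = 0.05, frac_te_down = 0.05,
                             effect_log2fc = 2,
                             n_footprints = 50000L,
                             footprint_len_weights = .defaultLenWeights(),
                             frame0_weight = 0.85,
                             region_weights = c(utr5 = 0.03, cds = 0.94,
                                                utr3 = 0.03),
                             uorf_rate = 1.3,
                             uorf_translated_frac = 0.5,
                             kozak_pfm = .defaultKozakPFM(),
                             clean_background = TRUE,
                             multi_exon = FALSE, intron_len = 50L,
                             seed = 42L) {
    new("SimulationConfig",
        n_genes = as.integer(n_genes),
        utr5_meanlog = utr5_meanlog, utr5_sdlog = utr5_sdlog,
        cds_meanlog = cds_meanlog, cds_sdlog = cds_sdlog,
        utr3_meanlog = utr3_meanlog, utr3_sdlog = utr3_sdlog,
        gc_mean = gc_mean,
        n_replicates = as.integer(n_replicates),
        mean_count = mean_count, dispersion = dispersion,
        frac_tx_up = frac_tx_up, frac_tx_down = frac_tx_down,
        frac_te_up = frac_te_up, frac_te_down = frac_te_down,
        effect_log2fc = effect_log2fc,
        n_footprints = as.integer(n_footprints),
        footprint_len_weights = footprint_len_weights,
        frame0_weight = frame0_weight,
        region_weights = region_weights,
        uorf_rate = uorf_rate,
        uorf_translated_frac = uorf_translated_frac,
        kozak_pfm = kozak_pfm,
        clean_background = clean_background,
        multi_exon = multi_exon, intron_len = as.integer(intron_len),
        seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@n_genes, "genes,",
        object@n_replicates, "vs", object@n_replicates, "replicates,",
        "seed", object@seed, "\n")
})

## sample background nucleotides; clean alphabets exclude A so that no
## chance ATG (or stop codon) can arise anywhere in the sequence
.bgLetters <- function(n, gc, clean) {
    if (n <= 0) return(character(0))
    if (clean)
        sample(c("C", "G", "T"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, 1 - gc))
    else
        sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

## one uORF sequence: ATG + interior codons over {C,G,T} + stop (TAG when
## clean so no A can seed a spurious ATG across the stop boundary)
.uorfSeq <- function(len, gc, clean) {
    nInterior <- len / 3 - 2
    interior <- paste(.bgLetters(3 * nInterior, gc, clean = TRUE),
                      collapse = "")
    stop_ <- if (clean) "TAG" else sample(c("TAA", "TAG", "TGA"), 1)
    paste0("ATG", interior, stop_)
}

.STOPS <- c("TAA", "TAG", "TGA")

## CDS: ATG + non-stop codons + stop; length a multiple of 3 (>= 9)
.cdsSeqSim <- function(len) {
    codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")), 1, paste,
                    collapse = "")
    codons <- codons[!codons %in% .STOPS]
    body <- paste(sample(codons, len / 3 - 2, replace = TRUE),
                  collapse = "")
    paste0("ATG", body, sample(.STOPS, 1))
}

#' Simulate an annotated genome with planted uORFs
#'
#' Generates one transcript per gene (single-exon by default; one intron
#' per transcript when \code{multi_exon}), placed head-to-tail on a single
#' synthetic chromosome with random strands. 5'UTRs carry planted,
#' non-overlapping uORFs (ATG ... stop, lengths a multiple of 3 in
#' [60, 450], interiors free of in-frame stops) at a Poisson rate of
#' \code{uorf_rate}; a 5'UTR too short for its uORFs is extended. Start
#' contexts of translated uORFs are drawn from \code{kozak_pfm}. With
#' \code{clean_background} the 5'UTR background contains no A, so the
#' planted uORFs are exactly the discoverable ones.
#'
#' @param config a \link{simulationConfig}.
#' @return list with \code{annotation} (\link{TranscriptAnnotation}),
#'   \code{genome} (\link[Biostrings]{DNAStringSet}), \code{gtf}
#'   (\link[GenomicRanges]{GRanges} ready for export), and \code{truth}
#'   (list: \code{genes} data.frame of planted effects and expected
#'   quadrants, \code{uorfs} data.frame of planted uORFs)
#' @export
simulateAnnotation <- function(config) {
    set.seed(config@seed)
    n <- config@n_genes
    gid <- sprintf("g%04d", seq_len(n))
    tid <- sprintf("t%04d", seq_len(n))

    u5len <- pmax(30L, as.integer(round(rlnorm(n, config@utr5_meanlog,
                                               config@utr5_sdlog))))
    cdslen <- pmax(120L, as.integer(round(rlnorm(n, config@cds_meanlog,
                                                 config@cds_sdlog) / 3)) * 3L)
    u3len <- pmax(30L, as.integer(round(rlnorm(n, config@utr3_meanlog,
                                               config@utr3_sdlog))))

    ## planted effects -> expected statuses and quadrants
    nTxUp <- round(n * config@frac_tx_up)
    nTxDn <- round(n * config@frac_tx_down)
    nTeUp <- round(n * config@frac_te_up)
    nTeDn <- round(n * config@frac_te_down)
    idx <- sample(n)
    txEff <- teEff <- numeric(n)
    e <- config@effect_log2fc
    txEff[idx[seq_len(nTxUp)]] <- e
    txEff[idx[nTxUp + seq_len(nTxDn)]] <- -e
    teEff[idx[nTxUp + nTxDn + seq_len(nTeUp)]] <- e
    teEff[idx[nTxUp + nTxDn + nTeUp + seq_len(nTeDn)]] <- -e
    statusOf <- function(x) ifelse(x >= 1, "up",
                                   ifelse(x <= -1, "down", "ns"))
    txStat <- statusOf(txEff)
    tlStat <- statusOf(txEff + teEff)
    quad <- classifyQuadrant(txStat, tlStat)

    ## planted uORFs
    uorfRows <- list()
    u5seq <- character(n)
    for (i in seq_len(n)) {
        k <- stats::rpois(1, config@uorf_rate)
        lens <- if (k) 3L * sample(20:150, k, replace = TRUE) else integer(0)
        need <- sum(lens)
        if (need > u5len[i]) u5len[i] <- need + 12L * k
        L <- u5len[i]
        bg <- .bgLetters(L, config@gc_mean, config@clean_background)
        if (k) {
            free <- L - need
            cuts <- sort(sample.int(free + 1L, k, replace = TRUE) - 1L)
            starts <- cuts + c(0L, cumsum(lens))[seq_len(k)]  # 0-based
            translated <- runif(k) < config@uorf_translated_frac
            for (j in seq_len(k)) {
                s <- starts[j]
                bg[(s + 1):(s + lens[j])] <-
                    strsplit(.uorfSeq(lens[j], config@gc_mean,
                                      config@clean_background), "")[[1]]
                ctxCols <- if (translated[j]) c(1:6, 10) else integer(0)
                for (cc in ctxCols) {
                    pos <- if (cc <= 6) s - 6L + cc else s + 4L  # +4 context
                    if (pos >= 1 && pos <= L) {
                        inOther <- any(pos - 1 >= starts[-j] &
                                       pos - 1 < starts[-j] + lens[-j])
                        if (!inOther)
                            bg[pos] <- sample(rownames(config@kozak_pfm), 1,
                                              prob = config@kozak_pfm[, cc])
                    }
                }
            }
            uorfRows[[length(uorfRows) + 1L]] <- data.frame(
                gene_id = gid[i], start = starts, length = lens,
                translated = translated, stringsAsFactors = FALSE)
        }
        u5seq[i] <- paste(bg, collapse = "")
    }
    uorfs <- if (length(uorfRows)) do.call(rbind, uorfRows) else
        data.frame(gene_id = character(0), start = integer(0),
                   length = integer(0), translated = logical(0))

    cdsseq <- vapply(cdslen, .cdsSeqSim, character(1))
    u3seq <- vapply(u3len, function(L)
        paste(.bgLetters(L, config@gc_mean, FALSE), collapse = ""),
        character(1))

    ## place transcripts on one chromosome; random strands
    strand <- sample(c("+", "-"), n, replace = TRUE)
    txSeq <- paste0(u5seq, cdsseq, u3seq)
    L <- nchar(txSeq)
    spacer <- 100L
    intron <- config@intron_len
    glen <- L + if (config@multi_exon) intron else 0L
    gstart <- cumsum(c(1L, head(glen + spacer, -1L)))
    gend <- gstart + glen - 1L

    gtfRows <- list()
    exonsList <- vector("list", n)
    pos <- 1L
    chromParts <- list()
    for (i in seq_len(n)) {
        gseq <- if (strand[i] == "+") txSeq[i] else
            as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(txSeq[i])))
        if (config@multi_exon) {
            half <- L[i] %/% 2L
            intr <- paste(.bgLetters(intron, config@gc_mean, FALSE),
                          collapse = "")
            gseq <- paste0(substr(gseq, 1L, half), intr,
                           substr(gseq, half + 1L, L[i]))
            ex <- rbind(c(gstart[i], gstart[i] + half - 1L),
                        c(gstart[i] + half + intron, gend[i]))
        } else {
            ex <- rbind(c(gstart[i], gend[i]))
        }
        chromParts[[2L * i - 1L]] <- gseq
        chromParts[[2L * i]] <- paste(.bgLetters(spacer, config@gc_mean,
                                                 FALSE), collapse = "")
        ## genomic CDS span (transcript coords utr5..utr5+cds)
        cdsT <- c(u5len[i], u5len[i] + cdslen[i] - 1L)   # 0-based closed
        gPosOf <- function(t) {     # transcript 0-based -> genomic 1-based
            exo <- if (strand[i] == "+") ex else ex
            offs <- cumsum(c(0L, exo[, 2] - exo[, 1] + 1L))
            k <- findInterval(t, offs)
            if (strand[i] == "+") exo[k, 1] + (t - offs[k])
            else {
                exr <- exo[rev(seq_len(nrow(exo))), , drop = FALSE]
                offs2 <- cumsum(c(0L, exr[, 2] - exr[, 1] + 1L))
                k2 <- findInterval(t, offs2)
                exr[k2, 2] - (t - offs2[k2])
            }
        }
        cg <- sort(c(gPosOf(cdsT[1]), gPosOf(cdsT[2])))
        ## CDS genomic intervals clipped to exons
        cdsEx <- ex[ex[, 2] >= cg[1] & ex[, 1] <= cg[2], , drop = FALSE]
        cdsEx[1, 1] <- max(cdsEx[1, 1], cg[1])
        cdsEx[nrow(cdsEx), 2] <- min(cdsEx[nrow(cdsEx), 2], cg[2])
        ## CDS phase per piece, in transcript (5'->3') order
        tord <- if (strand[i] == "+") order(cdsEx[, 1]) else
            order(-cdsEx[, 1])
        plens <- (cdsEx[, 2] - cdsEx[, 1] + 1L)[tord]
        ph <- integer(length(plens))
        if (length(plens) > 1)
            ph[-1] <- (3L - cumsum(plens)[-length(plens)] %% 3L) %% 3L
        phase <- integer(nrow(cdsEx)); phase[tord] <- ph
        gtfRows[[i]] <- rbind(
            data.frame(type = "exon", start = ex[, 1], end = ex[, 2],
                       phase = NA_integer_),
            data.frame(type = "CDS", start = cdsEx[, 1], end = cdsEx[, 2],
                       phase = phase))
        gtfRows[[i]]$gene_id <- gid[i]
        gtfRows[[i]]$transcript_id <- tid[i]
        gtfRows[[i]]$strand <- strand[i]
        exonsList[[i]] <- GenomicRanges::GRanges("chrS",
            IRanges::IRanges(ex[, 1], ex[, 2]), strand = strand[i])
    }
    genome <- Biostrings::DNAStringSet(paste(unlist(chromParts),
                                             collapse = ""))
    names(genome) <- "chrS"

    gtfDf <- do.call(rbind, gtfRows)
    gtf <- GenomicRanges::GRanges("chrS",
        IRanges::IRanges(gtfDf$start, gtfDf$end), strand = gtfDf$strand)
    gtf$source <- "riboTE_sim"
    gtf$type <- gtfDf$type
    gtf$phase <- gtfDf$phase
    gtf$gene_id <- gtfDf$gene_id
    gtf$transcript_id <- gtfDf$transcript_id

    genes <- data.frame(
        gene_id = gid, transcript_id = tid, chrom = "chrS",
        strand = strand,
        tss = ifelse(strand == "+", gstart, gend),
        utr5_len = u5len, cds_len = cdslen, utr3_len = u3len,
        spliced_length = u5len + cdslen + u3len,
        stringsAsFactors = FALSE)
    mk <- function(x) {
        s <- Biostrings::DNAStringSet(x); names(s) <- gid; s
    }
    exons <- GenomicRanges::GRangesList(exonsList)
    names(exons) <- gid
    annot <- new("TranscriptAnnotation", genes = genes, exons = exons,
                 utr5Seq = mk(u5seq), cdsSeq = mk(cdsseq),
                 utr3Seq = mk(u3seq))
    truthGenes <- data.frame(
        gene_id = gid, tx_effect = txEff, te_effect = teEff,
        tx_status = txStat, tl_status = tlStat, quadrant = quad,
        stringsAsFactors = FALSE)
    list(annotation = annot, genome = genome, gtf = gtf,
         truth = list(genes = truthGenes, uorfs = uorfs))
}

#' Simulate RNA-seq and Ribo-seq count tables
#'
#' RNA counts are NB(mean_count * 2^(tx_effect * group), dispersion); Ribo
#' counts are NB(mean_count * 2^((tx_effect + te_effect) * group),
#' dispersion), group 0 = CG, 1 = HS. Library sizes are the column sums.
#'
#' @param config a \link{simulationConfig}.
#' @param truth the \code{truth} element of \link{simulateAnnotation}.
#' @return list of two \link{CountTable}s: \code{rna}, \code{ribo}
#' @export
simulateCounts <- function(config, truth) {
    set.seed(config@seed + 1L)
    g <- truth$genes
    n <- nrow(g)
    reps <- config@n_replicates
    groups <- rep(c("CG", "HS"), each = reps)
    sampleIds <- paste(groups, rep(seq_len(reps), 2), sep = "_")
    draw <- function(mu) {
        if (config@dispersion > 0)
            rnbinom(length(mu), mu = mu, size = 1 / config@dispersion)
        else stats::rpois(length(mu), mu)
    }
    mk <- function(effect) {
        mu <- outer(config@mean_count * 2^(effect * 0),
                    rep(1, reps))            # CG block
        muH <- outer(config@mean_count * 2^effect, rep(1, reps))
        m <- cbind(matrix(draw(mu), n, reps), matrix(draw(muH), n, reps))
        dimnames(m) <- list(g$gene_id, sampleIds)
        m
    }
    rna <- mk(g$tx_effect)
    ribo <- mk(g$tx_effect + g$te_effect)
    list(rna = CountTable(rna, "rna", groups = groups),
         ribo = CountTable(ribo, "ribo", groups = groups))
}

#' Simulate ribosome footprints
#'
#' Footprint lengths are drawn from \code{footprint_len_weights}; the
#' region of each P-site follows \code{region_weights}; within the CDS the
#' P-site frame is 0 with probability \code{frame0_weight} (frames 1 and 2
#' split the remainder). Within the 5'UTR budget, each planted translated
#' uORF first receives enough footprints for an FPKM safely at or above 1
#' at the emitted library size, the remainder falling uniformly outside
#' uORF intervals, so untranslated uORFs stay below the translated
#' threshold. The footprint library size is the number of emitted records
#' (returned as attribute \code{libSize}).
#'
#' @param config a \link{simulationConfig}.
#' @param truth the \code{truth} element of \link{simulateAnnotation}.
#' @param annot the matching \link{TranscriptAnnotation}.
#' @return data.frame with \code{gene_id}, \code{five_prime_pos},
#'   \code{length} and attribute \code{libSize}
#' @export
simulateFootprints <- function(config, truth, annot) {
    set.seed(config@seed + 2L)
    g <- geneTable(annot)
    n <- config@n_footprints
    pOff <- 12L
    lens <- as.integer(names(config@footprint_len_weights))

    nRegion <- as.vector(stats::rmultinom(1, n, config@region_weights))
    names(nRegion) <- names(config@region_weights)

    drawLen <- function(k) sample(lens, k, replace = TRUE,
                                  prob = config@footprint_len_weights)

    out <- list()
    ## --- CDS reads with 3-nt periodicity
    k <- nRegion["cds"]
    gi <- sample.int(nrow(g), k, replace = TRUE, prob = g$cds_len)
    nCodon <- g$cds_len[gi] %/% 3L
    codon <- floor(runif(k) * nCodon)
    fr <- sample(0:2, k, replace = TRUE,
                 prob = c(config@frame0_weight,
                          (1 - config@frame0_weight) / 2,
                          (1 - config@frame0_weight) / 2))
    psite <- g$utr5_len[gi] + 3L * codon + fr
    out$cds <- data.frame(gene_id = g$gene_id[gi],
                          five_prime_pos = psite - pOff,
                          length = drawLen(k))

    ## --- 5'UTR reads: translated uORFs first, then free 5'UTR space
    uorfs <- truth$uorfs
    trU <- uorfs[uorfs$translated, , drop = FALSE]
    kNeeded <- if (nrow(trU))
        pmax(1L, ceiling(1.5 * trU$length * (1.1 * n) / 1e9)) else integer(0)
    uRows <- list()
    if (nrow(trU)) {
        for (j in seq_len(nrow(trU))) {
            lo <- max(trU$start[j], pOff)
            hi <- trU$start[j] + trU$length[j] - 1L
            ps <- lo + floor(runif(kNeeded[j]) * (hi - lo + 1L))
            uRows[[j]] <- data.frame(gene_id = trU$gene_id[j],
                                     five_prime_pos = ps - pOff,
                                     length = drawLen(kNeeded[j]))
        }
    }
    kFree <- max(0L, nRegion["utr5"] - sum(kNeeded))
    if (kFree > 0) {
        gi <- sample.int(nrow(g), kFree, replace = TRUE, prob = g$utr5_len)
        byGene <- split(uorfs, uorfs$gene_id)
        ps <- integer(kFree); keep <- logical(kFree)
        for (r in seq_len(kFree)) {
            gU <- byGene[[g$gene_id[gi[r]]]]
            for (tries in 1:50) {
                p <- pOff + floor(runif(1) * (g$utr5_len[gi[r]] - pOff))
                inU <- !is.null(gU) && any(p >= gU$start &
                                           p < gU$start + gU$length)
                if (!inU) { ps[r] <- p; keep[r] <- TRUE; break }
            }
        }
        out$utr5free <- data.frame(gene_id = g$gene_id[gi[keep]],
                                   five_prime_pos = ps[keep] - pOff,
                                   length = drawLen(sum(keep)))
    }

    ## --- 3'UTR reads
    k <- nRegion["utr3"]
    gi <- sample.int(nrow(g), k, replace = TRUE, prob = g$utr3_len)
    len3 <- drawLen(k)
    lo <- g$utr5_len[gi] + g$cds_len[gi]
    hi <- pmin(g$spliced_length[gi] - 1L,
               g$spliced_length[gi] - len3 + pOff)
    ok <- hi >= lo
    psite <- lo + floor(runif(k) * (hi - lo + 1L))
    out$utr3 <- data.frame(gene_id = g$gene_id[gi[ok]],
                           five_prime_pos = psite[ok] - pOff,
                           length = len3[ok])

    fp <- do.call(rbind, c(out, uRows))
    rownames(fp) <- NULL
    attr(fp, "libSize") <- nrow(fp)
    fp
}

#' Run the full generator and optionally write a dataset to disk
#'
#' \code{simulateAll} chains \link{simulateAnnotation},
#' \link{simulateCounts} and \link{simulateFootprints};
#' \code{writeSimulation} emits \code{genome.fa}, \code{annot.gtf},
#' \code{rna_counts.tsv}, \code{ribo_counts.tsv}, \code{footprints.tsv}
#' and \code{truth.json} under \code{dir}. Identical configurations
#' (including seed) produce byte-identical files.
#'
#' @param config a \link{simulationConfig}.
#' @return \code{simulateAll}: list with \code{annotation}, \code{genome},
#'   \code{gtf}, \code{truth}, \code{counts} (rna/ribo), \code{footprints}
#' @export
simulateAll <- function(config) {
    sim <- simulateAnnotation(config)
    sim$counts <- simulateCounts(config, sim$truth)
    sim$footprints <- simulateFootprints(config, sim$truth,
                                         sim$annotation)
    sim
}

#' @rdname simulateAll
#' @param sim result of \link{simulateAll}.
#' @param dir output directory (created if needed).
#' @return \code{writeSimulation}: invisibly, the paths written
#' @export
writeSimulation <- function(sim, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
    rtracklayer::export(sim$gtf, p("annot.gtf"), format = "gtf")
    writeCountsTSV <- function(ct, path) {
        df <- data.frame(gene_id = rownames(counts(ct)), counts(ct),
                         check.names = FALSE)
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeCountsTSV(sim$counts$rna, p("rna_counts.tsv"))
    writeCountsTSV(sim$counts$ribo, p("ribo_counts.tsv"))
    write.table(sim$footprints, p("footprints.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
        list(genes = sim$truth$genes, uorfs = sim$truth$uorfs,
             footprint_lib_size = attr(sim$footprints, "libSize")),
        p("truth.json"), dataframe = "columns", auto_unbox = TRUE,
        digits = NA)
    invisible(vapply(c("genome.fa", "annot.gtf", "rna_counts.tsv",
                       "ribo_counts.tsv", "footprints.tsv", "truth.json"),
                     p, character(1)))
}
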