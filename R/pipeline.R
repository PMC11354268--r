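#' Pipeline configuration
#'
#' Collects file paths, thresholds and the seed for a full run. Thresholds
#' default to the decision rules used throughout the package: |log2FC| >= 1
#' with BH FDR < 0.05 at every level, 25-35 nt footprints, P-site offset
#' 12, uORFs of 60-450 nt, translated at FPKM >= 1.
#'
#' @param gtf,fasta annotation inputs.
#' @param rnaCounts,riboCounts count TSVs (see \link{readCounts}).
#' @param footprints footprint TSV (see \link{readFootprints}).
#' @param outDir output directory.
#' @param fcThresh,fdrThresh,minFootprintLen,maxFootprintLen,pOffset,
#'   uorfMinLen,uorfMaxLen,translatedMinFpkm,minFpkm,tePseudocount,seed
#'   analysis parameters.
#' @param footprintLibSize Ribo-seq library size for uORF FPKM; defaults to
#'   the number of footprint records.
#' @param groups optional CG/HS labels when sample names are not
#'   self-describing.
#' @return a named list of class \code{ribote_config}
#' @export
pipelineConfig <- function(gtf, fasta, rnaCounts, riboCounts, footprints,
                           outDir, fcThresh = 1, fdrThresh = 0.05,
                           minFootprintLen = 25, maxFootprintLen = 35,
                           pOffset = 12, uorfMinLen = 60, uorfMaxLen = 450,
                           translatedMinFpkm = 1, minFpkm = 1,
                           tePseudocount = 0, footprintLibSize = NULL,
                           groups = NULL, seed = 1L) {
    stopifnot(fcThresh > 0, fdrThresh > 0, minFootprintLen > 0,
              uorfMinLen > 0)
    structure(list(
        gtf = gtf, fasta = fasta, rnaCounts = rnaCounts,
        riboCounts = riboCounts, footprints = footprints, outDir = outDir,
        fcThresh = fcThresh, fdrThresh = fdrThresh,
        minFootprintLen = minFootprintLen,
        maxFootprintLen = maxFootprintLen, pOffset = pOffset,
        uorfMinLen = uorfMinLen, uorfMaxLen = uorfMaxLen,
        translatedMinFpkm = translatedMinFpkm, minFpkm = minFpkm,
        tePseudocount = tePseudocount,
        footprintLibSize = footprintLibSize, groups = groups,
        seed = as.integer(seed)), class = "ribote_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match \link{pipelineConfig} arguments;
#'   relative paths are resolved against the YAML file's directory.
#' @return a \code{ribote_config}
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    base <- dirname(normalizePath(path))
    for (k in c("gtf", "fasta", "rnaCounts", "riboCounts", "footprints",
                "outDir"))
        if (!is.null(y[[k]]) && !grepl("^/", y[[k]]))
            y[[k]] <- file.path(base, y[[k]])
    do.call(pipelineConfig, y)
}

.logmsg <- function(log, ...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(line)
    if (!is.null(log)) cat(line, "\n", file = log, append = TRUE)
}

.wtsv <- function(df, path)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Run the full translatome-integration pipeline
#'
#' Executes the stages in dependency order - annotation preparation,
#' footprint QC, differential calling at both levels, translatome
#' integration (quadrants, TE, TE-differential), sequence features by TE
#' bin, and uORF analysis - writing per-stage TSVs, a \code{summary.json}
#' and a \code{run.log} under \code{config$outDir}. A failing stage aborts
#' with the stage name; outputs of completed stages are retained.
#' Re-running with the same inputs and configuration reproduces all
#' outputs exactly.
#'
#' @param config a \link{pipelineConfig}.
#' @return invisibly, the summary list
#' @export
runAll <- function(config) {
    for (f in c("gtf", "fasta", "rnaCounts", "riboCounts", "footprints"))
        if (!file.exists(config[[f]]))
            stop("input file not found: ", config[[f]], " (", f, ")")
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    log <- file.path(config$outDir, "run.log")
    cat("riboTE ", as.character(utils::packageVersion("riboTE")),
        " seed=", config$seed, " fc>=", config$fcThresh, " fdr<",
        config$fdrThresh, "\n", sep = "", file = log)
    set.seed(config$seed)
    stage <- function(name, expr) {
        .logmsg(log, "stage ", name)
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }

    ## prepare
    annot <- stage("prepare", parseGTF(config$gtf, config$fasta))
    g <- geneTable(annot)
    writeRegionFasta(annot, file.path(config$outDir, "regions"))

    ## riboqc
    qc <- stage("riboqc", {
        fp <- readFootprints(config$footprints)
        fp <- filterFootprints(fp, config$minFootprintLen,
                               config$maxFootprintLen)
        hist <- lengthHistogram(fp, config$minFootprintLen:
                                        config$maxFootprintLen)
        occ <- regionDistribution(fp, annot, config$pOffset)
        frames <- frameDistribution(fp, annot, config$pOffset)
        meta <- metageneFrames(fp, annot, 30, config$pOffset)
        .wtsv(data.frame(length = names(hist), count = hist),
              file.path(config$outDir, "length_histogram.tsv"))
        .wtsv(data.frame(region = names(occ), fraction = occ),
              file.path(config$outDir, "region_occupancy.tsv"))
        .wtsv(meta, file.path(config$outDir, "metagene.tsv"))
        list(fp = fp, occ = occ, frames = frames)
    })

    ## de (both levels)
    lens <- stats::setNames(g$spliced_length, g$gene_id)
    de <- stage("de", {
        rna <- readCounts(config$rnaCounts, "rna", groups = config$groups)
        ribo <- readCounts(config$riboCounts, "ribo",
                           groups = config$groups)
        txDE <- deTable(rna, lens, config$fcThresh, config$fdrThresh)
        tlDE <- deTable(ribo, lens, config$fcThresh, config$fdrThresh)
        .wtsv(txDE, file.path(config$outDir, "de_transcription.tsv"))
        .wtsv(tlDE, file.path(config$outDir, "de_translation.tsv"))
        list(rna = rna, ribo = ribo, tx = txDE, tl = tlDE)
    })

    ## integrate
    integ <- stage("integrate", {
        txDE <- de$tx; tlDE <- de$tl
        shared <- intersect(txDE$gene_id, tlDE$gene_id)
        txDE <- txDE[match(shared, txDE$gene_id), ]
        tlDE <- tlDE[match(shared, tlDE$gene_id), ]
        tested <- txDE$status != "untested" & tlDE$status != "untested"
        quad <- rep(NA_character_, length(shared))
        quad[tested] <- classifyQuadrant(txDE$status[tested],
                                         tlDE$status[tested])
        ov <- overlapSummary(txDE, tlDE)
        fc <- foldchangeCorrelation(txDE$log2fc, tlDE$log2fc,
                                    pmin(txDE$mean_fpkm_cg,
                                         txDE$mean_fpkm_hs),
                                    pmin(tlDE$mean_fpkm_cg,
                                         tlDE$mean_fpkm_hs),
                                    config$minFpkm)
        ## per-group TE from mean FPKM; per-replicate TE for the test
        te <- list()
        for (grp in c("cg", "hs")) {
            fr <- txDE[[paste0("mean_fpkm_", grp)]]
            fb <- tlDE[[paste0("mean_fpkm_", grp)]]
            te[[grp]] <- computeTE(fb, fr, config$tePseudocount)
        }
        replTE <- function(assayRna, assayRibo, grp) {
            sel <- sampleGroups(assayRna) == grp
            fr <- computeFPKM(counts(assayRna)[shared, sel, drop = FALSE],
                              matrix(lens[shared], length(shared),
                                     sum(sel)),
                              matrix(libSizes(assayRna)[sel],
                                     length(shared), sum(sel),
                                     byrow = TRUE))
            fb <- computeFPKM(counts(assayRibo)[shared, sel, drop = FALSE],
                              matrix(lens[shared], length(shared),
                                     sum(sel)),
                              matrix(libSizes(assayRibo)[sel],
                                     length(shared), sum(sel),
                                     byrow = TRUE))
            m <- log2((fb + config$tePseudocount) /
                      (fr + config$tePseudocount))
            rownames(m) <- shared
            m
        }
        teCG <- replTE(de$rna, de$ribo, "CG")
        teHS <- replTE(de$rna, de$ribo, "HS")
        teDE <- teDifferential(teCG, teHS, config$fcThresh,
                               config$fdrThresh)
        txte <- classifyTxTE(txDE$status, teDE$te_status)
        binHS <- rep(NA_character_, length(shared))
        okTE <- te$hs$defined
        binHS[okTE] <- as.character(teBin(te$hs$log2te[okTE]))
        teTab <- data.frame(
            gene_id = shared,
            fpkm_rna_cg = txDE$mean_fpkm_cg, fpkm_rna_hs = txDE$mean_fpkm_hs,
            fpkm_ribo_cg = tlDE$mean_fpkm_cg,
            fpkm_ribo_hs = tlDE$mean_fpkm_hs,
            te_cg = te$cg$te, te_hs = te$hs$te,
            log2te_cg = te$cg$log2te, log2te_hs = te$hs$log2te,
            te_bin_hs = binHS, delta_log2te = teDE$delta_log2te,
            te_pvalue = teDE$pvalue, te_fdr = teDE$fdr,
            te_status = teDE$te_status, tx_te_class = txte,
            stringsAsFactors = FALSE)
        quadTab <- data.frame(gene_id = shared,
                              tx_status = txDE$status,
                              tl_status = tlDE$status,
                              quadrant = quad, stringsAsFactors = FALSE)
        .wtsv(quadTab, file.path(config$outDir, "quadrants.tsv"))
        .wtsv(teTab, file.path(config$outDir, "te.tsv"))
        list(quad = quadTab, te = teTab, overlap = ov, fc = fc)
    })

    ## seqfeat
    seqfeat <- stage("seqfeat", {
        feats <- regionFeatures(annot)
        bins <- stats::setNames(integ$te$te_bin_hs, integ$te$gene_id)
        feats$te_bin <- bins[feats$gene_id]
        .wtsv(feats, file.path(config$outDir, "sequence_features.tsv"))
        summ <- list()
        for (region in unique(feats$region)) {
            for (metric in c("length", "gc", "nmfe")) {
                sub <- feats[feats$region == region & !is.na(feats$te_bin), ]
                if (length(unique(sub$te_bin)) < 2) next
                r <- suppressWarnings(
                    featuresByTeBin(sub[[metric]], sub$te_bin))
                r$summary$region <- region
                r$summary$metric <- metric
                summ[[paste(region, metric)]] <- r$summary
            }
        }
        summTab <- do.call(rbind, summ)
        if (!is.null(summTab))
            .wtsv(summTab, file.path(config$outDir,
                                     "features_by_te_bin.tsv"))
        feats
    })

    ## uorf
    uorf <- stage("uorf", {
        uorfs <- findUorfsByGene(annot, config$uorfMinLen,
                                 config$uorfMaxLen)
        lib <- config$footprintLibSize
        if (is.null(lib)) lib <- nrow(qc$fp)
        uorfs <- classifyTranslated(uorfs, qc$fp, lib, config$pOffset,
                                    config$translatedMinFpkm)
        if (nrow(uorfs)) {
            u5len <- stats::setNames(g$utr5_len, g$gene_id)
            tseq <- transcriptSeqs(annot)
            uorfs$utr5_len <- u5len[uorfs$gene_id]
            uorfs <- cbind(uorfs, uorfDistances(uorfs$start,
                                                uorfs$utr5_len))
            uorfs$kozak <- vapply(seq_len(nrow(uorfs)), function(i)
                kozakContext(as.character(tseq[[uorfs$gene_id[i]]]),
                             uorfs$start[i]), character(1))
            uorfs$nmfe <- nmfe(uorfs$seq)
        }
        .wtsv(uorfs[, setdiff(names(uorfs), "seq")],
              file.path(config$outDir, "uorfs.tsv"))
        if (nrow(uorfs)) {
            pfm <- positionFrequencyMatrix(uorfs$kozak)
            .wtsv(data.frame(base = rownames(pfm), pfm,
                             check.names = FALSE),
                  file.path(config$outDir, "kozak_pfm.tsv"))
            if (sum(uorfs$translated) >= 3 && sum(!uorfs$translated) >= 3)
                .wtsv(compareUorfGroups(uorfs),
                      file.path(config$outDir, "uorf_group_comparison.tsv"))
        }
        teByClass <- teByUorfClass(integ$te$gene_id, integ$te$log2te_hs,
                                   uorfs)
        if (nrow(teByClass$tests))
            .wtsv(teByClass$tests,
                  file.path(config$outDir, "te_by_uorf_class.tsv"))
        list(uorfs = uorfs, teByClass = teByClass)
    })

    ## summary
    quadCounts <- table(factor(integ$quad$quadrant, levels = LETTERS[1:9]))
    nUorfGenes <- length(unique(uorf$uorfs$gene_id))
    summary <- list(
        n_genes = nrow(g),
        frame0_fraction = unname(qc$frames["0"]),
        region_occupancy = as.list(qc$occ),
        deg_transcription = sum(de$tx$status %in% c("up", "down")),
        deg_translation = sum(de$tl$status %in% c("up", "down")),
        te_differential = sum(integ$te$te_status %in% c("up", "down")),
        quadrant_counts = as.list(quadCounts),
        shared_up_fraction_of_tl = integ$overlap$up$frac_of_tl,
        shared_down_fraction_of_tl = integ$overlap$down$frac_of_tl,
        r2 = integ$fc$r2,
        n_uorfs = nrow(uorf$uorfs),
        n_uorf_genes = nUorfGenes,
        mean_uorfs_per_gene = if (nUorfGenes)
            nrow(uorf$uorfs) / nUorfGenes else 0,
        n_translated_uorfs = sum(uorf$uorfs$translated))
    jsonlite::write_json(summary, file.path(config$outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    .logmsg(log, "done")
    invisible(summary)
}
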