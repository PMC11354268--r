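## Nine-quadrant map: transcription status x translation status.
.QUADRANT_MAP <- c(
    "up.down" = "A", "up.ns" = "B", "up.up" = "C",
    "ns.down" = "D", "ns.ns" = "E", "ns.up" = "F",
    "down.down" = "G", "down.ns" = "H", "down.up" = "I")

#' Nine-quadrant transcription x translation classification
#'
#' Maps the pair (transcriptional status, translational status), each in
#' up/down/ns, onto the nine quadrants A-I: A (transcription up,
#' translation down), B (transcription up, translation unchanged), C (up at
#' both levels), D (translation down only), E (no change at either level),
#' F (translation up only), G (down at both levels), H (transcription down
#' only), I (transcription down, translation up). Quadrants C and G contain
#' the coordinately regulated genes.
#'
#' @param txStatus,tlStatus character vectors in \code{up}/\code{down}/
#'   \code{ns}.
#' @return character vector of quadrant letters A-I
#' @examples
#' classifyQuadrant("up", "up")    # "C"
#' classifyQuadrant("down", "up")  # "I"
#' @export
classifyQuadrant <- function(txStatus, tlStatus) {
    ok <- c("up", "down", "ns")
    if (!all(txStatus %in% ok) || !all(tlStatus %in% ok))
        stop("status must be one of up/down/ns")
    unname(.QUADRANT_MAP[paste(txStatus, tlStatus, sep = ".")])
}

#' Overlap between transcriptional and translational DEG sets
#'
#' Intersects the up-regulated (and down-regulated) gene sets called at the
#' two levels and reports the shared counts together with the shared
#' fraction relative to each level's DEG set and to their union (the
#' denominator conventions differ across published reports, so all three
#' are returned).
#'
#' @param txDE,tlDE data.frames as returned by \link{deTable} over the same
#'   gene universe.
#' @return list with per-direction counts and shared fractions
#' @export
overlapSummary <- function(txDE, tlDE) {
    out <- list()
    for (dir in c("up", "down")) {
        a <- txDE$gene_id[txDE$status == dir]
        b <- tlDE$gene_id[tlDE$status == dir]
        sh <- intersect(a, b)
        out[[dir]] <- list(
            n_tx = length(a), n_tl = length(b), n_shared = length(sh),
            frac_of_tx = if (length(a)) length(sh) / length(a) else NA_real_,
            frac_of_tl = if (length(b)) length(sh) / length(b) else NA_real_,
            frac_of_union = if (length(union(a, b)))
                length(sh) / length(union(a, b)) else NA_real_)
    }
    out
}

#' Correlation of fold changes between expression levels
#'
#' Pearson correlation of transcriptional and translational log2 fold
#' changes over genes expressed at FPKM >= \code{minFpkm} in both assays.
#'
#' @param txLfc,tlLfc named (or parallel) log2 fold-change vectors.
#' @param fpkmRna,fpkmRibo per-gene FPKM used for the expression filter.
#' @param minFpkm expression floor applied to both assays.
#' @return list with \code{r}, \code{r2}, \code{n_used}
#' @export
foldchangeCorrelation <- function(txLfc, tlLfc, fpkmRna, fpkmRibo,
                                  minFpkm = 1) {
    use <- is.finite(txLfc) & is.finite(tlLfc) &
        fpkmRna >= minFpkm & fpkmRibo >= minFpkm
    if (sum(use) < 3) stop("fewer than 3 genes pass the FPKM filter")
    r <- pearsonCor(txLfc[use], tlLfc[use])
    list(r = r$statistic, r2 = r$r2, n_used = sum(use))
}

#' Translational efficiency
#'
#' TE = FPKM_ribo / FPKM_rna (optionally pseudocounted). Genes with a zero
#' denominator (or zero TE) are flagged undefined and excluded from binning
#' downstream.
#'
#' @param fpkmRibo,fpkmRna FPKM vectors.
#' @param pseudocount added to both FPKM values (default 0: the bare ratio).
#' @return data.frame with \code{te}, \code{log2te}, \code{defined}
#' @examples
#' computeTE(8, 2)  # te 4, log2te 2
#' @export
computeTE <- function(fpkmRibo, fpkmRna, pseudocount = 0) {
    num <- fpkmRibo + pseudocount
    den <- fpkmRna + pseudocount
    te <- ifelse(den > 0, num / den, NA_real_)
    log2te <- ifelse(!is.na(te) & te > 0, log2(te), -Inf)
    log2te[is.na(te)] <- NA_real_
    data.frame(te = te, log2te = log2te,
               defined = !is.na(te) & is.finite(log2te))
}

#' Assign TE bins
#'
#' Four bins on log2(TE): low (<= -1), mid_low (-1, 0], mid_high (0, 1),
#' high (>= 1). log2(TE) > 0 means ribosome loading exceeds mRNA abundance;
#' beyond |1| the imbalance is at least two-fold.
#'
#' @param log2te finite numeric vector.
#' @return factor with levels \code{low}, \code{mid_low}, \code{mid_high},
#'   \code{high}
#' @export
teBin <- function(log2te) {
    stopifnot(all(is.finite(log2te)))
    lab <- ifelse(log2te <= -1, "low",
           ifelse(log2te <= 0, "mid_low",
           ifelse(log2te < 1, "mid_high", "high")))
    factor(lab, levels = c("low", "mid_low", "mid_high", "high"))
}

#' Differential translational efficiency
#'
#' Tests the difference of group mean replicate log2(TE) between CG and
#' HS; the TE fold change is that difference. By default the replicate
#' variance is moderated: per-gene group variances are pooled across the
#' whole gene set (the per-gene estimate at 2-3 replicates is far too
#' noisy to detect even strong TE shifts), and the statistic is referred
#' to the normal distribution; \code{moderate = FALSE} gives the plain
#' per-gene Welch t-test. Zero-variance cases use a variance floor of
#' 1e-12 (degenerate but defined). Genes with undefined TE in any
#' replicate are excluded and reported with status \code{excluded}.
#' Status follows the same decision rule as expression-level calls:
#' |delta log2TE| >= \code{fcThresh} and BH FDR < \code{fdrThresh}.
#'
#' @param log2teCG,log2teHS matrices (genes x replicates) of replicate
#'   log2(TE); rownames are gene ids.
#' @param fcThresh,fdrThresh decision thresholds.
#' @param moderate pool replicate variances across genes (default TRUE).
#' @return data.frame with \code{gene_id}, \code{delta_log2te},
#'   \code{pvalue}, \code{fdr}, \code{te_status}
#' @export
teDifferential <- function(log2teCG, log2teHS, fcThresh = 1,
                           fdrThresh = 0.05, moderate = TRUE) {
    stopifnot(nrow(log2teCG) == nrow(log2teHS))
    n1 <- ncol(log2teCG); n2 <- ncol(log2teHS)
    if (n1 < 2 || n2 < 2)
        stop("insufficient replication")
    n <- nrow(log2teCG)
    ok <- rowSums(!is.finite(log2teCG)) == 0 &
          rowSums(!is.finite(log2teHS)) == 0
    delta <- pv <- rep(NA_real_, n)
    if (moderate && any(ok)) {
        v1 <- mean(apply(log2teCG[ok, , drop = FALSE], 1, var))
        v2 <- mean(apply(log2teHS[ok, , drop = FALSE], 1, var))
        se <- sqrt(max(v1 / n1 + v2 / n2, 1e-12))
        for (i in which(ok)) {
            delta[i] <- mean(log2teHS[i, ]) - mean(log2teCG[i, ])
            pv[i] <- 2 * pnorm(-abs(delta[i]) / se)
        }
    } else for (i in which(ok)) {
        x <- log2teCG[i, ]; y <- log2teHS[i, ]
        delta[i] <- mean(y) - mean(x)
        pv[i] <- tTest(y, x, variant = "welch")$pvalue
    }
    fdr <- rep(NA_real_, n)
    fdr[ok] <- bhFDR(pv[ok])
    status <- rep("excluded", n)
    status[ok] <- callStatus(delta[ok], fdr[ok], fcThresh, fdrThresh)
    data.frame(gene_id = rownames(log2teCG), delta_log2te = delta,
               pvalue = pv, fdr = fdr, te_status = status,
               stringsAsFactors = FALSE)
}

#' Cross-classify transcriptional and TE regulation
#'
#' Partitions genes by whether they are differential at the transcriptional
#' level, at the TE level, both, or neither. With
#' \code{splitBothByDirection = TRUE} the \code{both} class is split by
#' direction concordance (\code{both_concordant} / \code{both_discordant}),
#' yielding a five-group classification.
#'
#' @param txStatus,teStatus character vectors in \code{up}/\code{down}/
#'   \code{ns} (TE \code{excluded} treated as \code{ns}).
#' @param splitBothByDirection split \code{both} by sign concordance.
#' @return character vector of class labels
#' @export
classifyTxTE <- function(txStatus, teStatus, splitBothByDirection = FALSE) {
    teStatus[teStatus == "excluded"] <- "ns"
    txDE <- txStatus != "ns"; teDE <- teStatus != "ns"
    out <- rep("neither", length(txStatus))
    out[txDE & !teDE] <- "transcription_only"
    out[!txDE & teDE] <- "te_only"
    out[txDE & teDE] <- "both"
    if (splitBothByDirection) {
        conc <- txStatus == teStatus
        out[txDE & teDE & conc] <- "both_concordant"
        out[txDE & teDE & !conc] <- "both_discordant"
    }
    out
}
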