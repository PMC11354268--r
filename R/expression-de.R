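#' Fragments per kilobase per million mapped reads
#'
#' FPKM = count * 1e9 / (libSize * geneLength). Vectorized over genes.
#'
#' @param count read counts (non-negative).
#' @param geneLengthNt gene (spliced transcript or interval) length in nt,
#'   > 0.
#' @param libSize total mapped reads in the library, > 0.
#' @return numeric FPKM values
#' @examples
#' computeFPKM(100, 2000, 1e7)  # 5
#' @export
computeFPKM <- function(count, geneLengthNt, libSize) {
    if (any(libSize <= 0, na.rm = TRUE)) stop("libSize must be positive")
    if (any(geneLengthNt <= 0, na.rm = TRUE))
        stop("geneLengthNt must be positive")
    count * 1e9 / (libSize * geneLengthNt)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Validates the inputs and applies the standard step-up adjustment
#' (delegating to \code{stats::p.adjust}).
#'
#' @param pvalues numeric vector in [0, 1] (NAs preserved).
#' @return adjusted values in [0, 1]
#' @export
bhFDR <- function(pvalues) {
    finite <- pvalues[!is.na(pvalues)]
    if (any(finite < 0 | finite > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(pvalues, method = "BH")
}

#' Simplified negative-binomial Wald test for one gene
#'
#' Counts are scaled to a common depth (total-count normalization to the
#' mean library size), group means and a method-of-moments dispersion
#' (floored at 1e-8) are estimated, and a Wald statistic on the difference
#' of log means is referred to a t distribution with n1 + n2 - 2 degrees of
#' freedom; the finite-df reference keeps the type-I error near nominal at
#' the replicate numbers typical of ribosome profiling designs. The fold
#' change uses a pseudocount of 0.5 (in normalized units) in both
#' numerator and denominator.
#'
#' @param countsCG,countsHS per-replicate counts (length >= 2 each).
#' @param libSizesCG,libSizesHS per-replicate library sizes.
#' @param pseudocount added to normalized group means for the fold change.
#' @return list with \code{log2fc} (HS over CG) and \code{pvalue}
#' @export
deTest <- function(countsCG, countsHS, libSizesCG, libSizesHS,
                   pseudocount = 0.5, dispersion = NULL) {
    n1 <- length(countsCG); n2 <- length(countsHS)
    if (n1 < 2 || n2 < 2) stop("insufficient replication")
    scale <- mean(c(libSizesCG, libSizesHS))
    y1 <- countsCG * scale / libSizesCG
    y2 <- countsHS * scale / libSizesHS
    m1 <- mean(y1); m2 <- mean(y2)
    log2fc <- log2((m2 + pseudocount) / (m1 + pseudocount))

    if (is.null(dispersion)) {
        alpha <- max(.momDispersion(y1, y2), 1e-8)
        ## dispersion estimated from the gene's own 6-or-so observations:
        ## a finite-df reference keeps the type-I error near nominal
        df <- n1 + n2 - 2
    } else {
        alpha <- max(dispersion, 1e-8)
        df <- Inf
    }
    se2 <- (1 / (m1 + pseudocount) + alpha) / n1 +
           (1 / (m2 + pseudocount) + alpha) / n2
    z <- (log(m2 + pseudocount) - log(m1 + pseudocount)) / sqrt(se2)
    p <- 2 * pt(-abs(z), df = df)
    list(log2fc = log2fc, pvalue = min(1, p))
}

## DESeq-style median-of-ratios size factors (normalized to mean 1)
.medianRatioFactors <- function(cts) {
    lg <- rowMeans(log(cts))
    use <- is.finite(lg)
    if (!any(use)) return(rep(1, ncol(cts)))
    sf <- apply(cts[use, , drop = FALSE], 2, function(col)
        exp(stats::median(log(col[col > 0]) - lg[use][col > 0])))
    sf / mean(sf)
}

## method-of-moments NB dispersion pooled across the two groups of one gene
.momDispersion <- function(y1, y2) {
    mom <- function(y, m) if (m > 0) (var(y) - m) / m^2 else NA_real_
    a <- c(mom(y1, mean(y1)), mom(y2, mean(y2)))
    a <- a[!is.na(a)]
    if (!length(a)) return(1e-8)
    mean(a)
}

#' Call differential status from fold change and FDR
#'
#' up: log2FC >= \code{fcThresh} and FDR < \code{fdrThresh}; down: log2FC
#' <= -\code{fcThresh} and FDR < \code{fdrThresh}; otherwise ns. The fold
#' change gate is inclusive, the FDR gate strict.
#'
#' @param log2fc,fdr numeric vectors.
#' @param fcThresh,fdrThresh decision thresholds (defaults 1 and 0.05, i.e.
#'   a two-fold change at 5\% FDR).
#' @return character vector in \code{up}/\code{down}/\code{ns}
#' @export
callStatus <- function(log2fc, fdr, fcThresh = 1, fdrThresh = 0.05) {
    stopifnot(all(is.finite(log2fc)), all(is.finite(fdr)))
    out <- rep("ns", length(log2fc))
    out[log2fc >= fcThresh & fdr < fdrThresh] <- "up"
    out[log2fc <= -fcThresh & fdr < fdrThresh] <- "down"
    out
}

#' Genome-wide differential expression at one level
#'
#' Runs \link{deTest} per gene on a \link{CountTable}, adjusts p-values by
#' Benjamini-Hochberg across the tested genes, and applies the decision
#' rule of \link{callStatus}. Genes with all-zero counts in both groups are
#' excluded from testing and from the FDR adjustment and reported with
#' status \code{untested}.
#'
#' @param countTable a \link{CountTable}.
#' @param geneLengths named vector of gene lengths (nt) for FPKM reporting;
#'   genes missing from it get NA FPKM.
#' @param fcThresh,fdrThresh decision thresholds (see \link{callStatus}).
#' @param pseudocount see \link{deTest}.
#' @param norm library-size normalization for testing: \code{"total"}
#'   (counts per mapped million, default) or \code{"median_ratios"}
#'   (DESeq-style median-of-ratios size factors, robust to composition
#'   bias when many genes change in one direction). FPKM reporting always
#'   uses the raw library sizes.
#' @param dispersion \code{"common"} (default) shares one method-of-moments
#'   dispersion across all tested genes - the estimate is then precise
#'   enough for the normal Wald reference, which is where the test's power
#'   comes from at 3 replicates; \code{"genewise"} estimates dispersion per
#'   gene with a finite-df reference.
#' @return data.frame with \code{gene_id}, \code{mean_fpkm_cg},
#'   \code{mean_fpkm_hs}, \code{log2fc}, \code{pvalue}, \code{fdr},
#'   \code{status}
#' @export
deTable <- function(countTable, geneLengths = NULL, fcThresh = 1,
                    fdrThresh = 0.05, pseudocount = 0.5,
                    norm = c("total", "median_ratios"),
                    dispersion = c("common", "genewise")) {
    dispersion <- match.arg(dispersion)
    norm <- match.arg(norm)
    cts <- counts(countTable)
    grp <- sampleGroups(countTable)
    rawLib <- libSizes(countTable)
    lib <- if (norm == "median_ratios")
        .medianRatioFactors(cts) * mean(rawLib) else rawLib
    cg <- grp == "CG"; hs <- grp == "HS"
    if (sum(cg) < 2 || sum(hs) < 2) stop("insufficient replication")

    n <- nrow(cts)
    log2fc <- pvalue <- rep(NA_real_, n)
    tested <- rowSums(cts) > 0
    alphaCommon <- NULL
    if (dispersion == "common" && any(tested)) {
        scale <- mean(lib)
        y <- sweep(cts[tested, , drop = FALSE], 2, scale / lib, "*")
        a <- vapply(seq_len(nrow(y)), function(i)
            .momDispersion(y[i, cg], y[i, hs]), 0)
        alphaCommon <- max(mean(a, na.rm = TRUE), 1e-8)
    }
    for (i in which(tested)) {
        r <- deTest(cts[i, cg], cts[i, hs], lib[cg], lib[hs], pseudocount,
                    dispersion = alphaCommon)
        log2fc[i] <- r$log2fc
        pvalue[i] <- r$pvalue
    }
    fdr <- rep(NA_real_, n)
    fdr[tested] <- bhFDR(pvalue[tested])
    status <- rep("untested", n)
    status[tested] <- callStatus(log2fc[tested], fdr[tested],
                                 fcThresh, fdrThresh)

    fpkmCG <- fpkmHS <- rep(NA_real_, n)
    if (!is.null(geneLengths)) {
        len <- geneLengths[rownames(cts)]
        fpkm <- computeFPKM(cts, matrix(len, n, ncol(cts)),
                            matrix(rawLib, n, ncol(cts), byrow = TRUE))
        fpkmCG <- rowMeans(fpkm[, cg, drop = FALSE])
        fpkmHS <- rowMeans(fpkm[, hs, drop = FALSE])
    }
    data.frame(gene_id = rownames(cts), mean_fpkm_cg = fpkmCG,
               mean_fpkm_hs = fpkmHS, log2fc = log2fc, pvalue = pvalue,
               fdr = fdr, status = status, stringsAsFactors = FALSE)
}
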