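#' GC content of a nucleotide sequence
#'
#' (#G + #C) / (#A + #C + #G + #T); N (and any other ambiguity code) is
#' excluded from both numerator and denominator. Vectorized over a
#' character vector or \link[Biostrings]{DNAStringSet}.
#'
#' @param seq character vector or DNAStringSet.
#' @return numeric fraction in [0, 1]; NA (with a warning) for sequences
#'   with no unambiguous base
#' @examples
#' gcContent("ATGNNC")  # 0.5: two G/C among the four unambiguous bases
#' @export
gcContent <- function(seq) {
    if (!methods::is(seq, "XStringSet"))
        seq <- Biostrings::DNAStringSet(toupper(as.character(seq)))
    f <- Biostrings::letterFrequency(seq, c("A", "C", "G", "T"))
    tot <- rowSums(f)
    out <- ifelse(tot > 0, (f[, "C"] + f[, "G"]) / tot, NA_real_)
    if (anyNA(out)) warning("sequence(s) with no unambiguous base: GC NA")
    unname(out)
}

#' Normalized minimum free energy of RNA secondary structure
#'
#' MFE divided by sequence length (kcal/mol/nt, <= 0). The default backend
#' is a deterministic simplified folding model: Nussinov base-pair
#' maximization over canonical pairs (AU, GC, GU; T read as U) with a
#' minimum hairpin loop of 3 nt, scoring -1 kcal/mol per pair. Pairing is
#' local: base pairs may span at most \code{maxSpan} nt, so genome-scale
#' feature tables stay tractable; for sequences up to \code{maxSpan} the
#' result is the exact unrestricted optimum. An external thermodynamic
#' backend (\code{"rnafold"}, the ViennaRNA \code{RNAfold} executable) is
#' available behind the same contract for users who want nearest-neighbor
#' energies.
#'
#' @param seq character vector or DNAStringSet; each sequence must be at
#'   least 4 nt (shorter ones yield NA with a warning).
#' @param backend \code{"nussinov"} (default) or \code{"rnafold"}.
#' @param maxSpan maximum base-pair span (nt) for the default backend;
#'   0 disables the restriction.
#' @return numeric NMFE per sequence (kcal/mol/nt)
#' @examples
#' nmfe("GGGGAAAACCCC")  # -4/12
#' @export
nmfe <- function(seq, backend = c("nussinov", "rnafold"), maxSpan = 120L) {
    backend <- match.arg(backend)
    seq <- toupper(as.character(seq))
    n <- nchar(seq)
    out <- rep(NA_real_, length(seq))
    short <- n < 4
    if (any(short)) warning("sequence(s) shorter than 4 nt: NMFE NA")
    ok <- which(!short)
    if (backend == "nussinov") {
        for (i in ok)
            out[i] <- -.nussinovPairs(seq[i], 3L, as.integer(maxSpan)) / n[i]
    } else {
        out[ok] <- .rnafoldMFE(seq[ok]) / n[ok]
        out[ok] <- pmin(out[ok], 0)
    }
    out
}

## ViennaRNA backend: parse "( -12.30)" MFE lines from RNAfold --noPS.
.rnafoldMFE <- function(seqs) {
    exe <- Sys.which("RNAfold")
    if (exe == "") stop("RNAfold executable not found on PATH")
    outLines <- system2(exe, c("--noPS"), input = seqs, stdout = TRUE)
    mfeLines <- grep("\\(\\s*-?[0-9.]+\\)$", outLines, value = TRUE)
    as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)$", "\\1", mfeLines))
}

#' Per-region sequence feature table
#'
#' Length, GC content and NMFE for the 5'UTR, CDS and 3'UTR of every gene
#' in an annotation (zero-length regions are skipped).
#'
#' @param annot a \link{TranscriptAnnotation}.
#' @param backend folding backend passed to \link{nmfe}.
#' @return data.frame with \code{gene_id}, \code{region}, \code{length},
#'   \code{gc}, \code{nmfe}
#' @export
regionFeatures <- function(annot, backend = "nussinov") {
    out <- list()
    for (region in c("utr5", "cds", "utr3")) {
        s <- regionSeqs(annot, region)
        s <- s[Biostrings::width(s) > 0]
        if (!length(s)) next
        out[[region]] <- data.frame(
            gene_id = names(s), region = region,
            length = Biostrings::width(s),
            gc = gcContent(s),
            nmfe = nmfe(as.character(s), backend = backend),
            stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

## Compact letter display: letters are the maximal cliques of the
## "not significantly different" graph (brute-force enumeration; the number
## of bins here is at most a handful), ordered by group mean. Two bins
## share a letter if and only if their pairwise p exceeds alpha, so the
## display is exactly consistent with the reported p-values.
.letterDisplay <- function(binNames, means, pmat, alpha = 0.05) {
    k <- length(binNames)
    subsets <- lapply(seq_len(2^k - 1), function(m)
        binNames[bitwAnd(m, 2^(seq_len(k) - 1)) > 0])
    isClique <- vapply(subsets, function(s) {
        if (length(s) < 2) return(TRUE)
        prs <- utils::combn(s, 2)
        all(pmat[cbind(prs[1, ], prs[2, ])] > alpha)
    }, logical(1))
    cliques <- subsets[isClique]
    maximal <- vapply(seq_along(cliques), function(i)
        !any(vapply(seq_along(cliques), function(j)
            i != j && all(cliques[[i]] %in% cliques[[j]]) &&
                length(cliques[[j]]) > length(cliques[[i]]),
            logical(1))), logical(1))
    groups <- cliques[maximal]
    groups <- groups[order(vapply(groups, function(g)
        min(means[match(g, binNames)]), 0))]
    letters_ <- letters[seq_along(groups)]
    vapply(binNames, function(b)
        paste(letters_[vapply(groups, function(g) b %in% g, logical(1))],
              collapse = ""), character(1))
}

#' Compare a feature across TE bins
#'
#' Summarizes one feature per TE bin (n, mean, sd), performs all pairwise
#' two-tailed t-tests, and assigns a compact letter display in which bins
#' sharing a letter are not significantly different at \code{alpha}. Bins
#' with fewer than 3 genes are dropped with a warning.
#'
#' @param values numeric feature values.
#' @param bins TE bin labels parallel to \code{values}.
#' @param variant t-test variant (\code{"welch"} default; \code{"student"}
#'   for the classical pooled-variance test).
#' @param alpha significance level for the letter display.
#' @return list with \code{summary} (per-bin n/mean/sd/letters) and
#'   \code{pairwise} (bin pair, t, p); \code{pairwise} is NULL with a
#'   single qualifying bin
#' @export
featuresByTeBin <- function(values, bins, variant = c("welch", "student"),
                            alpha = 0.05) {
    variant <- match.arg(variant)
    bins <- as.character(bins)
    ok <- is.finite(values) & !is.na(bins)
    values <- values[ok]; bins <- bins[ok]
    tab <- table(bins)
    small <- names(tab)[tab < 3]
    if (length(small)) {
        warning("dropping bin(s) with fewer than 3 genes: ",
                paste(small, collapse = ", "))
        keep <- !(bins %in% small)
        values <- values[keep]; bins <- bins[keep]
    }
    binNames <- names(table(bins))
    if (!length(binNames)) stop("no qualifying bins")
    summ <- data.frame(
        bin = binNames,
        n = as.integer(table(bins)[binNames]),
        mean = vapply(binNames, function(b) mean(values[bins == b]), 0),
        sd = vapply(binNames, function(b) sd(values[bins == b]), 0),
        stringsAsFactors = FALSE)
    if (length(binNames) < 2) {
        summ$letters <- "a"
        return(list(summary = summ, pairwise = NULL))
    }
    prs <- utils::combn(binNames, 2)
    pmat <- matrix(NA_real_, length(binNames), length(binNames),
                   dimnames = list(binNames, binNames))
    pw <- data.frame(bin1 = prs[1, ], bin2 = prs[2, ],
                     statistic = NA_real_, pvalue = NA_real_)
    for (k in seq_len(ncol(prs))) {
        r <- tTest(values[bins == prs[1, k]], values[bins == prs[2, k]],
                   variant = variant)
        pw$statistic[k] <- r$statistic
        pw$pvalue[k] <- r$pvalue
        pmat[prs[1, k], prs[2, k]] <- pmat[prs[2, k], prs[1, k]] <- r$pvalue
    }
    summ$letters <- .letterDisplay(binNames, summ$mean, pmat, alpha)
    list(summary = summ, pairwise = pw)
}
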