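## All match positions (1-based) of a fixed trinucleotide in a string.
.triPositions <- function(seq, pattern) {
    m <- gregexpr(pattern, seq, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Find upstream open reading frames in a 5'UTR
#'
#' Scans every ATG in the 5'UTR sequence (not only the 5'-most); a uORF is
#' reported when the first in-frame stop codon (TAA/TAG/TGA) lies fully
#' within the 5'UTR and the resulting length (ATG through stop codon,
#' inclusive) falls within \code{[minLen, maxLen]}. Overlapping and nested
#' uORFs are all reported; uORFs whose stop would fall beyond the 5'UTR
#' (i.e. overlapping the main ORF) are not.
#'
#' @param utr5Seq character scalar (or DNAString) 5'UTR sequence, 5'->3'.
#' @param minLen,maxLen inclusive uORF length bounds in nt (defaults 60 and
#'   450).
#' @return data.frame with \code{start} (0-based offset of the A of ATG
#'   within the 5'UTR), \code{length} (nt), \code{seq}; sorted by start
#' @export
findUorfs <- function(utr5Seq, minLen = 60, maxLen = 450) {
    seq <- toupper(as.character(utr5Seq))
    empty <- data.frame(start = integer(0), length = integer(0),
                        seq = character(0), stringsAsFactors = FALSE)
    L <- nchar(seq)
    if (L < 3) return(empty)
    atg <- .triPositions(seq, "ATG")
    if (!length(atg)) return(empty)
    stops <- sort(c(.triPositions(seq, "TAA"), .triPositions(seq, "TAG"),
                    .triPositions(seq, "TGA")))
    res <- list()
    for (p in atg) {
        fr <- stops[(stops - p) %% 3 == 0 & stops >= p + 3]
        if (!length(fr)) next
        s <- fr[1]
        len <- s + 2L - p + 1L
        if (len < minLen || len > maxLen) next
        res[[length(res) + 1L]] <- data.frame(
            start = p - 1L, length = len,
            seq = substr(seq, p, s + 2L), stringsAsFactors = FALSE)
    }
    if (!length(res)) return(empty)
    out <- do.call(rbind, res)
    out[order(out$start), , drop = FALSE]
}

#' Find uORFs across an annotation
#'
#' Applies \link{findUorfs} to every gene with a non-empty 5'UTR.
#'
#' @param annot a \link{TranscriptAnnotation}.
#' @param minLen,maxLen see \link{findUorfs}.
#' @return data.frame with \code{gene_id}, \code{start}, \code{length},
#'   \code{seq}
#' @export
findUorfsByGene <- function(annot, minLen = 60, maxLen = 450) {
    u5 <- regionSeqs(annot, "utr5")
    u5 <- u5[Biostrings::width(u5) > 0]
    res <- lapply(names(u5), function(g) {
        u <- findUorfs(as.character(u5[[g]]), minLen, maxLen)
        if (nrow(u)) cbind(gene_id = g, u, stringsAsFactors = FALSE)
    })
    res <- res[!vapply(res, is.null, logical(1))]
    if (!length(res))
        return(data.frame(gene_id = character(0), start = integer(0),
                          length = integer(0), seq = character(0),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Classify uORFs as translated from footprint coverage
#'
#' A uORF is considered translated when the footprint FPKM over its
#' interval is at least \code{minFpkm} (default 1). Footprint P-sites
#' (5' end + \code{pOffset}) falling inside the uORF interval (which lies
#' within the 5'UTR, i.e. directly in transcript coordinates) are counted;
#' FPKM uses the uORF length and the same library size as gene-level Ribo
#' FPKM.
#'
#' @param uorfs data.frame from \link{findUorfsByGene} (needs
#'   \code{gene_id}, \code{start}, \code{length}).
#' @param footprints footprint data.frame (transcript coordinates).
#' @param libSize Ribo-seq library size (total footprints).
#' @param pOffset P-site offset (nt).
#' @param minFpkm translated threshold (inclusive).
#' @return the input with added \code{fpkm_ribo} and \code{translated}
#' @export
classifyTranslated <- function(uorfs, footprints, libSize, pOffset = 12,
                               minFpkm = 1) {
    psite <- footprints$five_prime_pos + pOffset
    k <- integer(nrow(uorfs))
    fpGene <- split(psite, footprints$gene_id)
    for (i in seq_len(nrow(uorfs))) {
        p <- fpGene[[uorfs$gene_id[i]]]
        if (is.null(p)) next
        k[i] <- sum(p >= uorfs$start[i] &
                    p < uorfs$start[i] + uorfs$length[i])
    }
    uorfs$fpkm_ribo <- computeFPKM(k, uorfs$length, libSize)
    uorfs$translated <- uorfs$fpkm_ribo >= minFpkm
    uorfs
}

#' Kozak context of a start codon
#'
#' Returns the 10-nt window covering positions -6..-1 and +1..+4 around the
#' A of ATG (A = +1); positions outside the transcript are padded with N.
#'
#' @param transcriptSeq character scalar full transcript sequence (5'->3').
#' @param startInTranscript 0-based transcript coordinate of the A of ATG.
#' @return 10-character string
#' @examples
#' kozakContext("GCCACCATGGTT", 6)  # "GCCACCATGG"
#' @export
kozakContext <- function(transcriptSeq, startInTranscript) {
    seq <- toupper(as.character(transcriptSeq))
    L <- nchar(seq)
    pos <- startInTranscript + 1L          # 1-based A of ATG
    idx <- c((pos - 6L):(pos - 1L), pos:(pos + 3L))
    chars <- ifelse(idx >= 1L & idx <= L,
                    substring(seq, idx, idx), "N")
    paste(chars, collapse = "")
}

#' GC content of the -4..-1 start-codon context
#'
#' Pools the four nucleotides immediately upstream of the ATG across a
#' group of 10-nt Kozak contexts (characters 3-6 of each context) and
#' returns their GC fraction, excluding N.
#'
#' @param contexts character vector of 10-nt contexts.
#' @return GC fraction (NA with a warning if the group has no unambiguous
#'   upstream base)
#' @export
startContextGC <- function(contexts) {
    if (!length(contexts)) { warning("empty context group"); return(NA_real_) }
    stopifnot(all(nchar(contexts) == 10L))
    up <- unlist(strsplit(substr(contexts, 3L, 6L), ""))
    up <- up[up %in% c("A", "C", "G", "T")]
    if (!length(up)) { warning("no unambiguous upstream base"); return(NA_real_) }
    sum(up %in% c("G", "C")) / length(up)
}

#' Position frequency matrix of Kozak contexts
#'
#' Per-position A/C/G/T frequencies over a set of 10-nt contexts
#' (positions -6..-1, +1..+4); N is excluded per position, and columns sum
#' to 1 wherever any unambiguous base is present.
#'
#' @param contexts character vector of 10-nt contexts (>= 1).
#' @return 4 x 10 numeric matrix, rows A/C/G/T, columns labelled by
#'   position
#' @export
positionFrequencyMatrix <- function(contexts) {
    if (!length(contexts)) stop("at least one context required")
    stopifnot(all(nchar(contexts) == 10L))
    m <- do.call(rbind, strsplit(toupper(contexts), ""))
    pfm <- matrix(0, 4, 10, dimnames = list(
        c("A", "C", "G", "T"),
        c(paste0("-", 6:1), paste0("+", 1:4))))
    for (j in 1:10) {
        col <- m[, j]
        col <- col[col %in% rownames(pfm)]
        if (length(col))
            pfm[, j] <- table(factor(col, levels = rownames(pfm))) /
                length(col)
    }
    pfm
}

#' uORF positional metrics
#'
#' \code{dist_to_tss} is the uORF start in nt from the transcript 5' end
#' (the 5'UTR begins at the TSS in transcript coordinates);
#' \code{dist_to_cds_norm} is the distance from the uORF start codon to the
#' main-ORF start, normalized by the 5'UTR length: (L - start) / L, in
#' (0, 1].
#'
#' @param start 0-based uORF start(s) within the 5'UTR.
#' @param utr5Len 5'UTR length(s), > 0.
#' @return data.frame with \code{dist_to_tss}, \code{dist_to_cds_norm}
#' @export
uorfDistances <- function(start, utr5Len) {
    stopifnot(all(utr5Len > 0), all(start >= 0), all(start < utr5Len))
    data.frame(dist_to_tss = start,
               dist_to_cds_norm = (utr5Len - start) / utr5Len)
}

#' Compare translated vs untranslated uORFs
#'
#' Welch t-tests (two-sided) on five metrics: uORF length, 5'UTR length,
#' NMFE, normalized distance to the CDS start, and distance to the TSS.
#'
#' @param uorfs data.frame with columns \code{translated}, \code{length},
#'   \code{utr5_len}, \code{nmfe}, \code{dist_to_cds_norm},
#'   \code{dist_to_tss}; at least 3 records per group.
#' @return data.frame with \code{metric}, \code{mean_translated},
#'   \code{mean_untranslated}, \code{pvalue}
#' @export
compareUorfGroups <- function(uorfs) {
    metrics <- c(uorf_length = "length", utr5_length = "utr5_len",
                 nmfe = "nmfe", dist_to_cds_norm = "dist_to_cds_norm",
                 dist_to_tss = "dist_to_tss")
    tr <- uorfs[uorfs$translated, , drop = FALSE]
    un <- uorfs[!uorfs$translated, , drop = FALSE]
    if (nrow(tr) < 3 || nrow(un) < 3)
        stop("need at least 3 uORFs per group")
    out <- data.frame(metric = names(metrics),
                      mean_translated = NA_real_,
                      mean_untranslated = NA_real_,
                      pvalue = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_along(metrics)) {
        x <- tr[[metrics[i]]]; y <- un[[metrics[i]]]
        out$mean_translated[i] <- mean(x)
        out$mean_untranslated[i] <- mean(y)
        out$pvalue[i] <- tTest(x, y, variant = "welch")$pvalue
    }
    out
}

#' TE by number of translated uORFs
#'
#' Partitions genes by their count of translated uORFs (none / single /
#' multiple, i.e. 0 / 1 / >= 2) and compares the log2(TE) distributions of
#' each pair of classes with two-sample Kolmogorov-Smirnov tests. Pairs
#' involving an empty class are skipped with a warning.
#'
#' @param geneIds,log2te parallel vectors of genes and their log2(TE).
#' @param uorfs data.frame with \code{gene_id} and \code{translated}.
#' @return list with \code{classes} (factor per gene), \code{sizes}, and
#'   \code{tests} (data.frame: pair, D, pvalue; possibly 0 rows)
#' @export
teByUorfClass <- function(geneIds, log2te, uorfs) {
    nTrans <- table(uorfs$gene_id[uorfs$translated])
    k <- as.integer(nTrans[geneIds]); k[is.na(k)] <- 0L
    cls <- factor(ifelse(k == 0, "none", ifelse(k == 1, "single",
                                                "multiple")),
                  levels = c("none", "single", "multiple"))
    ok <- is.finite(log2te)
    sizes <- table(cls[ok])
    prs <- utils::combn(levels(cls), 2)
    tests <- data.frame(class1 = character(0), class2 = character(0),
                        D = numeric(0), pvalue = numeric(0),
                        stringsAsFactors = FALSE)
    for (j in seq_len(ncol(prs))) {
        x <- log2te[ok & cls == prs[1, j]]
        y <- log2te[ok & cls == prs[2, j]]
        if (!length(x) || !length(y)) {
            warning("empty class; skipping pair ", prs[1, j], " vs ",
                    prs[2, j])
            next
        }
        r <- ksTwoSample(x, y)
        tests <- rbind(tests, data.frame(
            class1 = prs[1, j], class2 = prs[2, j],
            D = r$statistic, pvalue = r$pvalue, stringsAsFactors = FALSE))
    }
    list(classes = cls, sizes = sizes, tests = tests)
}
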