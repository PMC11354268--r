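#' Read a footprint table
#'
#' Footprints live in transcript coordinates: the 5' end position of the
#' protected fragment (0-based) plus its length.
#'
#' @param path TSV with columns \code{gene_id}, \code{five_prime_pos},
#'   \code{length}.
#' @return data.frame of footprints
#' @export
readFootprints <- function(path) {
    fp <- read.delim(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("gene_id", "five_prime_pos", "length")
    if (!all(need %in% names(fp)))
        stop("footprint table must have columns: ",
             paste(need, collapse = ", "))
    fp
}

#' Filter footprints by length
#'
#' Retains footprints with lengths in \code{[minLen, maxLen]} (default the
#' conventional 25-35 nt window for ribosome-protected fragments),
#' preserving input order.
#'
#' @param footprints data.frame with a \code{length} column.
#' @param minLen,maxLen inclusive length bounds (nt).
#' @return the filtered data.frame
#' @export
filterFootprints <- function(footprints, minLen = 25, maxLen = 35) {
    footprints[footprints$length >= minLen & footprints$length <= maxLen, ,
               drop = FALSE]
}

#' Footprint length histogram
#'
#' @param footprints data.frame with a \code{length} column.
#' @param range lengths to report (absent lengths are reported as 0).
#' @return named integer vector of counts per length
#' @export
lengthHistogram <- function(footprints, range = 25:35) {
    counts <- table(factor(footprints$length, levels = range))
    out <- as.integer(counts)
    names(out) <- as.character(range)
    out
}

## P-site transcript positions for a footprint table (vectorized)
.psites <- function(footprints, pOffset) footprints$five_prime_pos + pOffset

#' Assign footprints to transcript regions
#'
#' Each footprint's P-site (5' end + \code{pOffset}) is located within its
#' gene's 5'UTR / CDS / 3'UTR partition; positions beyond the transcript,
#' or footprints on genes absent from the annotation, are labelled
#' \code{other}. The default 12-nt offset is the standard P-site offset for
#' ~28-nt footprints; set \code{pOffset = 0} to reproduce raw 5'-end
#' assignment.
#'
#' @param footprints data.frame with \code{gene_id}, \code{five_prime_pos}.
#' @param annot a \link{TranscriptAnnotation}.
#' @param pOffset P-site offset in nt from the footprint 5' end.
#' @return factor with levels \code{utr5}, \code{cds}, \code{utr3},
#'   \code{other}, one per footprint
#' @export
assignRegion <- function(footprints, annot, pOffset = 12) {
    g <- geneTable(annot)
    idx <- match(footprints$gene_id, g$gene_id)
    p <- .psites(footprints, pOffset)
    u5 <- g$utr5_len[idx]
    cdsEnd <- u5 + g$cds_len[idx]
    L <- g$spliced_length[idx]
    out <- rep("other", nrow(footprints))
    inb <- !is.na(idx) & p >= 0 & p < L
    out[inb & p < u5] <- "utr5"
    out[inb & p >= u5 & p < cdsEnd] <- "cds"
    out[inb & p >= cdsEnd] <- "utr3"
    factor(out, levels = c("utr5", "cds", "utr3", "other"))
}

#' Region occupancy of a footprint set
#'
#' @inheritParams assignRegion
#' @return named numeric vector of fractions over
#'   \code{utr5}/\code{cds}/\code{utr3}/\code{other}, summing to 1
#' @export
regionDistribution <- function(footprints, annot, pOffset = 12) {
    if (!nrow(footprints)) stop("empty footprint set")
    r <- assignRegion(footprints, annot, pOffset)
    tab <- table(r)
    as.numeric(tab) / nrow(footprints) -> prop
    names(prop) <- names(tab)
    prop
}

#' P-site reading-frame distribution within the CDS
#'
#' Fraction of CDS-assigned P-sites in each reading frame relative to the
#' annotated start codon (frame 0 = first codon position). Translating
#' ribosomes step one codon at a time, so real libraries concentrate on
#' frame 0.
#'
#' @inheritParams assignRegion
#' @return numeric vector of length 3 (frames 0, 1, 2) summing to 1
#' @export
frameDistribution <- function(footprints, annot, pOffset = 12) {
    g <- geneTable(annot)
    idx <- match(footprints$gene_id, g$gene_id)
    p <- .psites(footprints, pOffset)
    u5 <- g$utr5_len[idx]
    incds <- !is.na(idx) & p >= u5 & p < u5 + g$cds_len[idx]
    if (!any(incds)) stop("no CDS-assigned P-sites")
    fr <- (p[incds] - u5[incds]) %% 3
    tab <- table(factor(fr, levels = 0:2))
    out <- as.numeric(tab) / sum(tab)
    names(out) <- c("0", "1", "2")
    out
}

#' Metagene P-site profiles around the start and stop codons
#'
#' Counts P-sites at each position relative to the first nucleotide of the
#' start codon and of the stop codon (position 0 = first nt of the codon),
#' annotated with the reading frame relative to the CDS start. Only genes
#' whose CDS is at least \code{window} nt long contribute.
#'
#' @inheritParams assignRegion
#' @param window half-width of the profile in nt around each anchor.
#' @return data.frame with columns \code{anchor} (\code{start}/\code{stop}),
#'   \code{rel_pos} (-window..window), \code{frame} (0/1/2), \code{count}
#' @export
metageneFrames <- function(footprints, annot, window = 30, pOffset = 12) {
    g <- geneTable(annot)
    keep <- g$cds_len >= window
    idx <- match(footprints$gene_id, g$gene_id)
    p <- .psites(footprints, pOffset)
    ok <- !is.na(idx) & keep[idx] & p >= 0 & p < g$spliced_length[idx]
    idx <- idx[ok]; p <- p[ok]
    u5 <- g$utr5_len[idx]
    cdsEnd <- u5 + g$cds_len[idx]
    frame <- (p - u5) %% 3

    out <- list()
    for (anchor in c("start", "stop")) {
        anchorPos <- if (anchor == "start") u5 else cdsEnd - 3L
        rel <- p - anchorPos
        sel <- rel >= -window & rel <= window
        grid <- expand.grid(rel_pos = -window:window, frame = 0:2)
        key <- paste(rel[sel], frame[sel])
        cnt <- table(factor(key, levels = paste(grid$rel_pos, grid$frame)))
        out[[anchor]] <- data.frame(anchor = anchor, grid,
                                    count = as.integer(cnt))
    }
    rbind(out$start, out$stop)
}
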