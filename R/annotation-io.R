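#' Parse a GTF + genome FASTA into a TranscriptAnnotation
#'
#' Builds one transcript model per gene (the representative transcript is the
#' one with the longest CDS; ties are broken by the lexicographically
#' smallest \code{transcript_id}), splices exons, extracts region sequences,
#' and converts everything to 0-based half-open transcript coordinates
#' running 5'->3'. Minus-strand sequences are reverse-complemented. The stop
#' codon is counted as part of the CDS: when the GTF carries separate
#' \code{stop_codon} features (Ensembl dialect) they are merged into the CDS
#' span. Transcripts whose resulting CDS length is not a positive multiple
#' of 3 are skipped with a warning.
#'
#' @param gtfPath path to a GTF with \code{exon} and \code{CDS} features
#'   carrying \code{gene_id}/\code{transcript_id} attributes.
#' @param genomeFastaPath path to the genome FASTA; every chromosome
#'   referenced by the GTF must be present (missing ones are a hard error).
#' @return a \link{TranscriptAnnotation}
#' @export
parseGTF <- function(gtfPath, genomeFastaPath) {
    gr <- rtracklayer::import(gtfPath, format = "gtf")
    genome <- Biostrings::readDNAStringSet(genomeFastaPath)
    names(genome) <- sub("\\s.*$", "", names(genome))

    gr <- gr[gr$type %in% c("exon", "CDS", "stop_codon")]
    if (!length(gr)) stop("GTF contains no exon/CDS features")
    missing <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                       names(genome))
    if (length(missing))
        stop("chromosome(s) absent from genome FASTA: ",
             paste(missing, collapse = ", "))

    df <- data.frame(
        chrom  = as.character(GenomicRanges::seqnames(gr)),
        start  = GenomicRanges::start(gr),
        end    = GenomicRanges::end(gr),
        strand = as.character(GenomicRanges::strand(gr)),
        type   = as.character(gr$type),
        gene_id = gr$gene_id,
        transcript_id = gr$transcript_id,
        stringsAsFactors = FALSE)

    rows <- list(); u5 <- list(); cds <- list(); u3 <- list(); exl <- list()
    for (tx in split(df, df$transcript_id)) {
        m <- .buildTranscriptModel(tx, genome)
        if (is.null(m)) next
        gid <- m$row$gene_id
        rows[[length(rows) + 1L]] <- m$row
        u5[[length(u5) + 1L]] <- m$utr5
        cds[[length(cds) + 1L]] <- m$cds
        u3[[length(u3) + 1L]] <- m$utr3
        exl[[length(exl) + 1L]] <- m$exons
    }
    if (!length(rows)) stop("no usable transcript models in GTF")
    genes <- do.call(rbind, rows)

    ## representative transcript per gene: longest CDS, then smallest id
    ord <- order(genes$gene_id, -genes$cds_len, genes$transcript_id)
    genes <- genes[ord, , drop = FALSE]
    keep <- !duplicated(genes$gene_id)
    idx <- ord[keep]
    genes <- genes[keep, , drop = FALSE]
    rownames(genes) <- NULL

    mk <- function(lst) {
        s <- Biostrings::DNAStringSet(unlist(lst, use.names = FALSE)[idx])
        names(s) <- genes$gene_id
        s
    }
    exons <- GenomicRanges::GRangesList(exl[idx])
    names(exons) <- genes$gene_id
    new("TranscriptAnnotation", genes = genes, exons = exons,
        utr5Seq = mk(u5), cdsSeq = mk(cds), utr3Seq = mk(u3))
}

## One transcript: splice exons, locate CDS in transcript coordinates,
## return NULL (with warning) when the CDS is not a positive multiple of 3.
.buildTranscriptModel <- function(tx, genome) {
    ex <- tx[tx$type == "exon", , drop = FALSE]
    cd <- tx[tx$type %in% c("CDS", "stop_codon"), , drop = FALSE]
    if (!nrow(ex) || !nrow(cd)) return(NULL)
    strand <- ex$strand[1]
    chrom <- ex$chrom[1]
    minus <- identical(strand, "-")
    ex <- ex[order(ex$start, decreasing = minus), , drop = FALSE]

    chromSeq <- genome[[chrom]]
    ## concatenate exon pieces in ascending genomic order; the reverse
    ## complement of that concatenation is the minus-strand transcript
    asc <- ex[order(ex$start), , drop = FALSE]
    pieces <- mapply(function(s, e) {
        as.character(Biostrings::subseq(chromSeq, s, e))
    }, asc$start, asc$end)
    spliced <- Biostrings::DNAString(paste(pieces, collapse = ""))
    if (minus) spliced <- Biostrings::reverseComplement(spliced)
    L <- length(spliced)

    ## genomic -> transcript coordinate (0-based) of a genomic position
    exStarts <- ex$start; exEnds <- ex$end
    cumLen <- cumsum(c(0L, abs(exEnds - exStarts) + 1L))
    g2t <- function(pos) {
        for (i in seq_len(nrow(ex))) {
            if (pos >= exStarts[i] && pos <= exEnds[i]) {
                off <- if (minus) exEnds[i] - pos else pos - exStarts[i]
                return(cumLen[i] + off)
            }
        }
        NA_integer_
    }
    cdsG <- c(min(cd$start), max(cd$end))
    tpos <- if (minus) c(g2t(cdsG[2]), g2t(cdsG[1])) else
        c(g2t(cdsG[1]), g2t(cdsG[2]))
    if (anyNA(tpos)) {
        warning("CDS of transcript ", tx$transcript_id[1],
                " falls outside its exons; skipped")
        return(NULL)
    }
    cdsStart <- tpos[1]; cdsEnd <- tpos[2] + 1L   # half-open
    cdsLen <- cdsEnd - cdsStart
    if (cdsLen <= 0L || cdsLen %% 3L != 0L) {
        warning("CDS length of transcript ", tx$transcript_id[1],
                " is not a positive multiple of 3; skipped")
        return(NULL)
    }
    tss <- if (minus) max(exEnds) else min(exStarts)
    sc <- as.character(spliced)
    list(
        row = data.frame(
            gene_id = tx$gene_id[1], transcript_id = tx$transcript_id[1],
            chrom = chrom, strand = strand, tss = tss,
            utr5_len = cdsStart, cds_len = cdsLen,
            utr3_len = L - cdsEnd, spliced_length = L,
            stringsAsFactors = FALSE),
        utr5 = substr(sc, 1L, cdsStart),
        cds  = substr(sc, cdsStart + 1L, cdsEnd),
        utr3 = substr(sc, cdsEnd + 1L, L),
        exons = GenomicRanges::GRanges(chrom,
            IRanges::IRanges(ex$start, ex$end), strand = strand))
}

#' Read a gene x sample count TSV into a CountTable
#'
#' Expects a header row of sample ids and gene ids in the first column.
#' Negative or non-integer cells and duplicated gene ids are hard errors.
#'
#' @param tsvPath path to a tab-separated count table.
#' @param assay \code{"rna"} or \code{"ribo"}.
#' @param groups,libSizes see \link{CountTable}; \code{libSizes} defaults to
#'   column sums.
#' @return a \link{CountTable}
#' @export
readCounts <- function(tsvPath, assay = c("rna", "ribo"), groups = NULL,
                       libSizes = NULL) {
    assay <- match.arg(assay)
    tab <- read.delim(tsvPath, header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE)
    geneIds <- as.character(tab[[1]])
    dup <- geneIds[duplicated(geneIds)]
    if (length(dup))
        stop("duplicate gene id(s) in ", tsvPath, ": ",
             paste(unique(dup), collapse = ", "))
    m <- as.matrix(tab[, -1, drop = FALSE])
    bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad))
        stop("negative or non-integer count at row ", bad[1, 1],
             " (gene ", geneIds[bad[1, 1]], "), column ",
             colnames(m)[bad[1, 2]])
    rownames(m) <- geneIds
    CountTable(m, assay = assay, groups = groups, libSizes = libSizes)
}

#' Write and re-read region sequences as FASTA
#'
#' \code{writeRegionFasta} writes the 5'UTR, CDS and 3'UTR sequences of an
#' annotation to one FASTA per region (\code{utr5.fa}, \code{cds.fa},
#' \code{utr3.fa}) under \code{dir}; records are named by gene id.
#' Zero-length regions are written as empty records so that a round trip
#' reproduces the sequences byte-identically.
#'
#' @param annot a \link{TranscriptAnnotation}
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeRegionFasta <- function(annot, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- character(0)
    for (region in c("utr5", "cds", "utr3")) {
        p <- file.path(dir, paste0(region, ".fa"))
        Biostrings::writeXStringSet(regionSeqs(annot, region), p)
        paths <- c(paths, p)
    }
    invisible(paths)
}
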