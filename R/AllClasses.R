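#' TranscriptAnnotation: one representative transcript model per gene
#'
#' Holds the transcript-coordinate backbone used by every downstream stage:
#' per-gene region lengths (5'UTR / CDS / 3'UTR partitioning the spliced
#' transcript), genomic exon structure, and the region sequences. Transcript
#' coordinates are 0-based, half-open, and always run 5'->3' regardless of
#' genomic strand. The stop codon is counted as part of the CDS, so the CDS
#' length is a positive multiple of 3.
#'
#' @slot genes data.frame with one row per gene: \code{gene_id},
#'   \code{transcript_id}, \code{chrom}, \code{strand}, \code{tss},
#'   \code{utr5_len}, \code{cds_len}, \code{utr3_len},
#'   \code{spliced_length}.
#' @slot exons \link[GenomicRanges]{GRangesList} of exons per gene (genomic
#'   coordinates).
#' @slot utr5Seq,cdsSeq,utr3Seq \link[Biostrings]{DNAStringSet} of region
#'   sequences named by \code{gene_id}; their concatenation is the spliced
#'   transcript sequence.
#'
#' @aliases TranscriptAnnotation
#' @exportClass TranscriptAnnotation
setClass("TranscriptAnnotation",
    representation(
        genes   = "data.frame",
        exons   = "GRangesList",
        utr5Seq = "DNAStringSet",
        cdsSeq  = "DNAStringSet",
        utr3Seq = "DNAStringSet"
    )
)

setValidity("TranscriptAnnotation", function(object) {
    g <- object@genes
    msgs <- character(0)
    need <- c("gene_id", "transcript_id", "chrom", "strand", "tss",
              "utr5_len", "cds_len", "utr3_len", "spliced_length")
    if (!all(need %in% names(g)))
        return(paste("genes is missing columns:",
                     paste(setdiff(need, names(g)), collapse = ", ")))
    if (anyDuplicated(g$gene_id))
        msgs <- c(msgs, "duplicate gene_id in annotation")
    if (nrow(g)) {
        if (any(g$cds_len <= 0L) || any(g$cds_len %% 3L != 0L))
            msgs <- c(msgs, "cds_len must be a positive multiple of 3")
        if (any(g$utr5_len < 0L) || any(g$utr3_len < 0L))
            msgs <- c(msgs, "negative UTR length")
        if (any(g$utr5_len + g$cds_len + g$utr3_len != g$spliced_length))
            msgs <- c(msgs, "region lengths do not partition spliced_length")
        for (slot in c("utr5Seq", "cdsSeq", "utr3Seq")) {
            s <- slot(object, slot)
            if (length(s) && !all(names(s) %in% g$gene_id))
                msgs <- c(msgs, paste(slot, "has names absent from genes"))
        }
        if (length(object@cdsSeq) &&
            !all(Biostrings::width(object@cdsSeq) ==
                 g$cds_len[match(names(object@cdsSeq), g$gene_id)]))
            msgs <- c(msgs, "cdsSeq widths disagree with cds_len")
    }
    if (length(msgs)) msgs else TRUE
})

#' @describeIn TranscriptAnnotation number of genes
#' @param x,object a \code{TranscriptAnnotation}
#' @export
setMethod("length", "TranscriptAnnotation", function(x) nrow(x@genes))

#' @describeIn TranscriptAnnotation gene ids
#' @export
geneIds <- function(x) x@genes$gene_id

#' Accessors for TranscriptAnnotation
#'
#' \code{geneTable} returns the per-gene coordinate table; \code{regionSeqs}
#' returns one of the three region sequence sets; \code{transcriptSeqs}
#' returns the full spliced transcript sequences (5'UTR + CDS + 3'UTR).
#'
#' @param x a \code{TranscriptAnnotation}
#' @param region one of \code{"utr5"}, \code{"cds"}, \code{"utr3"}
#' @return \code{geneTable}: data.frame; \code{regionSeqs},
#'   \code{transcriptSeqs}: \link[Biostrings]{DNAStringSet}
#' @export
geneTable <- function(x) x@genes

#' @rdname geneTable
#' @export
regionSeqs <- function(x, region = c("utr5", "cds", "utr3")) {
    region <- match.arg(region)
    switch(region, utr5 = x@utr5Seq, cds = x@cdsSeq, utr3 = x@utr3Seq)
}

#' @rdname geneTable
#' @export
transcriptSeqs <- function(x) {
    ids <- geneIds(x)
    out <- Biostrings::DNAStringSet(paste0(
        as.character(x@utr5Seq[ids]),
        as.character(x@cdsSeq[ids]),
        as.character(x@utr3Seq[ids])))
    names(out) <- ids
    out
}

setMethod("show", "TranscriptAnnotation", function(object) {
    g <- object@genes
    cat("TranscriptAnnotation with", nrow(g), "genes\n")
    if (nrow(g)) {
        cat("  spliced length: ", min(g$spliced_length), "-",
            max(g$spliced_length), " nt\n", sep = "")
        cat("  genes with 5'UTR: ", sum(g$utr5_len > 0L), "\n", sep = "")
    }
})

#' CountTable: gene x sample counts for one assay
#'
#' A minimal count container for a two-group (CG vs HS) design: an integer
#' matrix of gene-level counts, per-sample group labels, and per-sample
#' library sizes (total mapped reads; at least the column sums).
#'
#' @slot assay \code{"rna"} or \code{"ribo"}.
#' @slot counts integer matrix, rows = genes, columns = samples.
#' @slot groups factor of \code{"CG"}/\code{"HS"} per sample.
#' @slot libSizes numeric vector of per-sample library sizes.
#'
#' @aliases CountTable
#' @exportClass CountTable
setClass("CountTable",
    representation(
        assay    = "character",
        counts   = "matrix",
        groups   = "factor",
        libSizes = "numeric"
    )
)

setValidity("CountTable", function(object) {
    msgs <- character(0)
    if (!object@assay %in% c("rna", "ribo"))
        msgs <- c(msgs, "assay must be 'rna' or 'ribo'")
    cts <- object@counts
    if (is.null(rownames(cts)))
        msgs <- c(msgs, "counts must have gene ids as rownames")
    else if (anyDuplicated(rownames(cts)))
        msgs <- c(msgs, "duplicate gene ids in counts")
    if (any(cts < 0) || any(cts != round(cts)))
        msgs <- c(msgs, "counts must be non-negative integers")
    if (length(object@groups) != ncol(cts))
        msgs <- c(msgs, "one group label per sample required")
    if (!all(levels(object@groups) %in% c("CG", "HS")))
        msgs <- c(msgs, "groups must be CG/HS")
    if (length(object@libSizes) != ncol(cts))
        msgs <- c(msgs, "one library size per sample required")
    else if (ncol(cts) && any(object@libSizes < colSums(cts)))
        msgs <- c(msgs, "library size smaller than column sum")
    if (length(msgs)) msgs else TRUE
})

#' Construct a CountTable
#'
#' @param counts integer matrix with gene-id rownames and sample colnames.
#' @param assay \code{"rna"} or \code{"ribo"}.
#' @param groups character/factor of \code{"CG"}/\code{"HS"} per sample; if
#'   \code{NULL}, inferred from sample names of the form \code{CG_1}.
#' @param libSizes per-sample library sizes; defaults to column sums.
#' @return a \code{CountTable}
#' @export
CountTable <- function(counts, assay = c("rna", "ribo"), groups = NULL,
                       libSizes = NULL) {
    assay <- match.arg(assay)
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (is.null(groups)) {
        groups <- sub("[_.].*$", "", colnames(counts))
        if (!all(groups %in% c("CG", "HS")))
            stop("cannot infer CG/HS groups from sample names; ",
                 "pass `groups` explicitly")
    }
    groups <- factor(as.character(groups), levels = c("CG", "HS"))
    if (is.null(libSizes)) libSizes <- colSums(counts)
    new("CountTable", assay = assay, counts = counts, groups = groups,
        libSizes = as.numeric(libSizes))
}

#' @describeIn CountTable count matrix
#' @param object a \code{CountTable}
#' @export
counts <- function(object) object@counts

#' @describeIn CountTable sample group labels
#' @export
sampleGroups <- function(object) object@groups

#' @describeIn CountTable per-sample library sizes
#' @export
libSizes <- function(object) object@libSizes

#' @describeIn CountTable assay label
#' @export
assayType <- function(object) object@assay

setMethod("show", "CountTable", function(object) {
    cat("CountTable [", object@assay, "]: ", nrow(object@counts), " genes x ",
        ncol(object@counts), " samples (",
        paste(table(object@groups), collapse = " CG / "), " HS)\n", sep = "")
})
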