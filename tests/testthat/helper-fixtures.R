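# Fixture builders and independent oracles shared across the test files.

## Write a GTF + FASTA for explicitly given transcripts and parse them back.
## Each element of `tx` is a list with: chrom sequence is assembled from the
## given spliced sequence (one gene per chromosome), exons given as a matrix
## of 1-based [start, end] genomic intervals, cds as genomic [start, end].
makeAnnotation <- function(tx, dir = tempfile()) {
    dir.create(dir, showWarnings = FALSE)
    gtfLines <- character(0)
    fa <- character(0)
    for (t in tx) {
        fa <- c(fa, paste0(">", t$chrom), t$chromSeq)
        attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                         t$gene_id, t$transcript_id)
        for (i in seq_len(nrow(t$exons)))
            gtfLines <- c(gtfLines, paste(t$chrom, "test", "exon",
                t$exons[i, 1], t$exons[i, 2], ".", t$strand, ".", attrs,
                sep = "\t"))
        for (i in seq_len(nrow(t$cds)))
            gtfLines <- c(gtfLines, paste(t$chrom, "test", "CDS",
                t$cds[i, 1], t$cds[i, 2], ".", t$strand, ".", attrs,
                sep = "\t"))
    }
    gtfPath <- file.path(dir, "test.gtf")
    faPath <- file.path(dir, "test.fa")
    writeLines(gtfLines, gtfPath)
    writeLines(fa, faPath)
    parseGTF(gtfPath, faPath)
}

randSeq <- function(n, letters_ = c("A", "C", "G", "T"))
    paste(sample(letters_, n, replace = TRUE), collapse = "")

## Single-gene annotation with given region sequences on one chromosome.
simpleAnnotation <- function(utr5, cds, utr3, strand = "+",
                             gene_id = "g1", transcript_id = "t1") {
    txSeq <- paste0(utr5, cds, utr3)
    L <- nchar(txSeq)
    chromSeq <- if (strand == "+") txSeq else
        as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(txSeq)))
    u5 <- nchar(utr5); cl <- nchar(cds)
    cdsG <- if (strand == "+") c(u5 + 1, u5 + cl) else
        c(L - u5 - cl + 1, L - u5)
    makeAnnotation(list(list(
        chrom = paste0("chr_", gene_id), chromSeq = chromSeq,
        gene_id = gene_id, transcript_id = transcript_id,
        strand = strand, exons = rbind(c(1, L)), cds = rbind(cdsG))))
}

## Independent uORF oracle: walk codons from every ATG until the first
## in-frame stop, no precomputed stop tables.
bruteUorfs <- function(seq, minLen = 60, maxLen = 450) {
    seq <- toupper(seq)
    L <- nchar(seq)
    out <- list()
    for (p in seq_len(max(0, L - 2))) {
        if (substr(seq, p, p + 2) != "ATG") next
        q <- p + 3
        while (q + 2 <= L) {
            codon <- substr(seq, q, q + 2)
            if (codon %in% c("TAA", "TAG", "TGA")) {
                len <- q + 2 - p + 1
                if (len >= minLen && len <= maxLen)
                    out[[length(out) + 1]] <- c(start = p - 1, length = len)
                break
            }
            q <- q + 3
        }
    }
    if (!length(out))
        return(data.frame(start = integer(0), length = integer(0)))
    as.data.frame(do.call(rbind, out))
}

## Independent folding oracle: exhaustive recursion over all nested
## pairings (leftmost base unpaired or paired to each admissible partner).
brutePairsMax <- function(seq, minLoop = 3) {
    s <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
    canPair <- function(a, b)
        paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
    rec <- function(i, j) {
        if (j - i < minLoop + 1) return(0)
        best <- rec(i + 1, j)                    # i unpaired
        for (k in (i + minLoop + 1):j) {
            if (!canPair(s[i], s[k])) next
            v <- 1 + rec(i + 1, k - 1) + (if (k < j) rec(k + 1, j) else 0)
            if (v > best) best <- v
        }
        best
    }
    rec(1, length(s))
}

uorfKey <- function(d) paste(d$gene_id, d$start, d$length)
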