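---
title: "Methods: translatome-transcriptome integration with riboTE"
author: "riboTE authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translatome-transcriptome integration with riboTE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

riboTE analyses matched Ribo-seq and RNA-seq experiments with a two-group
design (control, `CG`, versus treatment, `HS`) in *transcript coordinates*:
every gene is represented by a single transcript model partitioned into
5'UTR, CDS and 3'UTR (0-based, half-open intervals; the stop codon belongs
to the CDS so that the CDS length is a multiple of 3). Genomic alignment,
contaminant depletion and isoform quantification are out of scope; the
package consumes gene-level counts and transcript-coordinate footprint
records, or simulates them.

Where a gene has several annotated transcripts, the representative is the
one with the longest CDS, ties broken by the lexicographically smallest
transcript id. This is a convention, not biology: gene-level TE and uORF
analyses need one coordinate backbone per gene, and the longest CDS is the
most conservative choice for CDS-anchored statistics. Genes with an empty
5'UTR stay in the expression and TE analyses but are excluded from uORF
and 5'UTR feature work.

# Footprint QC

Ribosome-protected fragments are filtered to 25-35 nt. Footprints are
located by their P-site, taken as the 5' end plus a fixed 12-nt offset —
the standard value for ~28-nt metazoan footprints. The offset is a
parameter (`pOffset`); setting it to 0 reproduces raw 5'-end assignment,
which matters when comparing against reports that do not state their
convention. Region occupancy is the fraction of P-sites in each of
5'UTR/CDS/3'UTR; positions outside the transcript model fall into an
`other` class. Because the pipeline works in transcript space, intronic
occupancy is not measurable here — reads that would be intronic in genomic
space simply do not map to the model.

Periodicity is summarized two ways: `frameDistribution()` gives the
fraction of CDS P-sites per reading frame, and `metageneFrames()` gives
per-position counts in ±30-nt windows anchored at the first nucleotide of
the start and stop codons (position 0 = first nt of the codon, frames
relative to the CDS start).

# Differential expression

FPKM is count × 10^9 / (library size × transcript length). The
differential test at each level is a deliberately simple negative-binomial
Wald test rather than a DESeq2/edgeR reimplementation: counts are scaled
to a common depth (total-count by default; DESeq-style median-of-ratios
is available as `norm = "median_ratios"` and is the better choice when
regulation is strongly one-sided), group means and a method-of-moments
dispersion are estimated, and the difference of log means is tested.

Two estimator variants exist, and the distinction matters at 3 replicates:

* `deTest()` (one gene) estimates dispersion from that gene's own
  observations and uses a t reference with n1+n2−2 degrees of freedom.
  This is calibrated (null rejection ≈ 0.056 at nominal 0.05) but has
  limited power because the variance is noisy.
* `deTable()` (genome-wide, the pipeline's route) pools the
  method-of-moments dispersion across all tested genes and uses the
  normal reference. With thousands of genes the pooled dispersion is
  essentially known, which restores calibration for the normal reference
  and yields >90% detection of 4-fold changes at mean count 100-200,
  3 vs 3. Pooling information across genes is what every mainstream
  RNA-seq tool does; `dispersion = "genewise"` switches it off.

The decision rule everywhere is |log2FC| ≥ 1 (inclusive) with
Benjamini–Hochberg FDR < 0.05 (strict). Fold changes are pseudocounted
(0.5 in normalized units) so all-zero groups stay finite; genes with zero
counts in both groups are excluded from testing and from the BH family and
reported as `untested`.

# Integration: quadrants, TE, TE-differential

The nine-quadrant classification is the Cartesian product of the
transcriptional and translational status (up/down/ns), labelled A–I with
C and G the coordinately up- and down-regulated classes. Overlap
fractions between the DEG sets are reported against three denominators
(each level's set and their union) because published percentages are
ambiguous in this respect.

TE is FPKM_ribo / FPKM_rna, by default without pseudocount (the bare
ratio); genes with a zero denominator are flagged undefined and excluded
from binning. Bins on log2(TE) cut at −1, 0, 1: low (≤ −1), mid_low
(−1, 0], mid_high (0, 1), high (≥ 1).

TE-differential calling works on per-replicate log2 TE (replicate *i* of
one assay paired with replicate *i* of the other). The fold change is the
difference of group means. For the p-value the default pools the
replicate variance across genes and uses a normal reference; the plain
per-gene Welch t-test (`moderate = FALSE`) is available but at 3 vs 3 it
cannot reliably detect even a 4-fold TE shift (its recovery in our
calibration simulations is ~28% versus >90% moderated) — a per-gene
variance from three ratios is simply too noisy. Zero-variance cases use a
variance floor (1e-12). Status uses the same |Δlog2TE| ≥ 1, FDR < 0.05
rule. The transcription × TE cross-classification is reported 4-way
(both / transcription_only / te_only / neither), with an optional split of
`both` by direction concordance giving the 5-way view.

# Sequence features

GC content excludes ambiguity codes from numerator and denominator. The
folding score is a normalized minimum free energy: MFE / length in
kcal/mol/nt, with the default backend a simplified deterministic model —
Nussinov base-pair maximization over canonical pairs (AU, GC, GU; T read
as U), minimum hairpin loop 3 nt, −1 kcal/mol per pair. Two numerical
choices deserve note:

* Pairing is local, restricted to a maximum span of 120 nt. For
  sequences up to the span the result is the exact unrestricted optimum
  (this covers the exhaustive-oracle tests and all uORF-sized inputs);
  for long CDS/3'UTR sequences it is the standard local-folding view and
  keeps the computation O(n · span²) instead of O(n³). `maxSpan = 0`
  restores the unrestricted model.
* An external thermodynamic backend (`backend = "rnafold"`, ViennaRNA)
  is supported behind the same contract for users who want
  nearest-neighbor energies; all defaults and tests use the built-in
  model so results are reproducible without external binaries.

Per-bin feature comparisons report n/mean/sd, all pairwise two-tailed
t-tests (Welch by default; Student selectable where the classical pooled
test is wanted) and a compact letter display. Letters are assigned from
the maximal cliques of the "not significantly different at α" graph,
ordered by group mean. We chose the exact clique construction over the
common insert-and-absorb heuristic because the heuristic can leave a
non-significant pair without a shared letter; with at most four TE bins
the exact construction is trivial and guarantees that two bins share a
letter *iff* their pairwise p exceeds α.

# uORF analysis

The finder scans every ATG in the 5'UTR (not only the 5'-most one) and
reports a uORF when the first in-frame stop lies fully within the 5'UTR
and the length (ATG through stop, inclusive) is 60–450 nt. Nested and
overlapping uORFs are all reported; ORFs whose stop would fall beyond the
5'UTR (overlapping the main ORF) are not. The inclusive-stop length
convention is a stated choice; the 60-nt floor is applied to that
inclusive length.

A uORF is called translated when the footprint FPKM over its interval
(P-sites inside [start, start+length), the same library size as
gene-level Ribo FPKM) is ≥ 1, inclusive. Kozak contexts are the 10-nt
window −6..−1/+1..+4 around the A of ATG (N-padded at transcript edges),
wide enough to cover the GCCACCATGG consensus; position frequency
matrices exclude N per position. Upstream GC is computed over −4..−1,
pooled within each group. Distances: `dist_to_tss` is the uORF start
(the 5'UTR begins at the transcript 5' end), and `dist_to_cds_norm` is
(L − start)/L, measured from the start codon — the anchor is a
convention, and measuring from the stop codon instead is a one-line
config change.

Group comparisons (translated vs untranslated) use Welch t-tests on uORF
length, 5'UTR length, NMFE and the two distances. TE by translated-uORF
count (none / single / multiple) uses pairwise two-sample KS tests with
asymptotic p-values — adequate at the group sizes (tens to hundreds)
arising anywhere in this pipeline; exact small-sample KS is a non-goal.

# Statistical primitives

t (Student/Welch), two-sample KS and Pearson correlation are implemented
in the package with explicitly stated conventions (variance floor 1e-12
with a degeneracy flag; asymptotic KS with the theta-function form below
t = 1 and the series truncation of the conventional tol = 1e-6
evaluation, matching `stats::psmirnov`'s asymptotic path to ~1e-10). The
base-R implementations serve as independent references in the test suite,
which checks agreement to 1e-8 relative error on committed fixtures.

# The synthetic-data generator

The generator is first-class, tested code that defines the study
conditions every calibration test runs under:

* 2000 genes, one transcript each (an optional one-intron mode exists
  solely to exercise the splicing path), region lengths log-normal
  (5'UTR ~150 nt, CDS ~600 nt, 3'UTR ~400 nt medians — desk-scale but
  realistically proportioned), random strands on one synthetic
  chromosome.
* NB counts, 3 vs 3, mean 200, dispersion 0.1; 10% of genes carry +2 or
  −2 log2 transcription effects and 5% carry ±2 log2 TE effects (the
  Ribo mean is mean × 2^(tx+te)), so planted quadrant memberships are
  known exactly.
* 50,000 footprints with length weights peaked at 26–28 nt (65% of
  mass), region weights 3/94/3% (5'UTR/CDS/3'UTR), and frame-0
  probability 0.85 within the CDS.
* uORFs planted at Poisson rate 1.3 per gene, lengths uniform multiples
  of 3 in [60, 450], non-overlapping within a 5'UTR; half are flagged
  translated. Translated uORFs receive at least one footprint from the
  5'UTR budget (at these library sizes one read already exceeds FPKM 1);
  the remaining 5'UTR reads avoid all uORF intervals so untranslated
  uORFs stay below threshold. Start contexts of translated uORFs are
  drawn from a Kozak-like PFM (GC-rich upstream, A/G at −3, G-rich +4).

Two deliberate artificialities make ground-truth assertions exact rather
than approximate, and they bound what passing tests show about real
data. First, with `clean_background` (default) 5'UTR backgrounds are
drawn from {C,G,T} and planted stops are TAG, so no chance ATG or stop
can arise and the planted uORF set is *exactly* the discoverable set —
real 5'UTRs contain chance uORFs, and real recovery is necessarily
fuzzier. Second, footprint placement knows the truth (translated uORFs
are guaranteed coverage), so translated-flag recovery measures the
classifier's bookkeeping, not biological signal detection. The generator
also omits rRNA contamination, UMI/duplication artifacts, GC bias and
expression-level variation between genes; calibration results transfer
to real data only to the extent that the NB replicate model does.

Determinism: a configuration plus seed reproduces every output file
byte-identically.

# Problem sizes and numerical conventions

Default problem sizes were chosen once as the package's desk-scale study
conditions: 2000 genes, 3 vs 3 replicates, 50,000 footprints, 2000-gene
calibration simulations. The full pipeline on these defaults runs in a
few minutes on one CPU. Tolerances asserted in tests are derived from
the binomial/sampling error of the corresponding quantity at these sizes
(typically three standard errors), not tuned to outcomes.

Known limitations: no multi-isoform support; no genomic-space intron
accounting; asymptotic (not exact) KS p-values; the simplified folding
model ranks folding potential but its absolute energies are not
thermodynamic; DESeq2/edgeR concordance is explicitly not a goal — the
differential machinery is calibrated against its own generative model
instead.
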