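# riboTE

Integration of ribosome profiling (Ribo-seq) with matched RNA-seq for
two-condition experiments. Heat stress, like many acute perturbations,
reshapes gene expression at two levels at once: transcript abundance and
how efficiently each transcript is translated. Comparing the two requires
a pipeline that treats both assays symmetrically — footprint quality
control, normalized expression at both levels, differential calling,
and the statistics that connect them. riboTE provides that pipeline for
anyone analysing bulk Ribo-seq + RNA-seq count data in transcript
coordinates, together with a fully deterministic synthetic-data generator
so every stage can be calibrated against known ground truth.

## What it computes

* **Footprint QC** — read-length histograms (ribosome-protected fragments
  are filtered to 25–35 nt and typically peak at 26–28 nt), region
  occupancy of P-sites (5′UTR / CDS / 3′UTR; healthy libraries are ~94%
  CDS), and 3-nt periodicity metagene profiles around start and stop
  codons. P-site = 5′ end + 12 nt by default.
* **Expression and TE** — FPKM = count·10⁹/(library size · length);
  translational efficiency TE = FPKM_Ribo / FPKM_RNA, binned on log₂TE at
  −1, 0, 1.
* **Differential calling** — a simplified negative-binomial Wald test at
  each level (method-of-moments dispersion pooled across genes), decision
  rule |log₂FC| ≥ 1 with Benjamini–Hochberg FDR < 0.05; the same rule on
  replicate log₂TE gives TE-differential genes.
* **Nine-quadrant classification** — each gene's (transcriptional,
  translational) status pair, both in {up, down, ns}, maps to quadrants
  A–I; C and G are the coordinately up-/down-regulated classes. Overlap
  fractions and the Pearson r² between fold changes at the two levels
  quantify coordination.
* **Sequence features by TE bin** — length, GC content and normalized
  minimum free energy (MFE/length from a deterministic Nussinov folding
  backend) per region, with pairwise t-tests and a compact letter
  display.
* **uORF analysis** — every ATG-initiated upstream ORF of 60–450 nt
  contained in the 5′UTR; translated if footprint FPKM over the uORF
  interval ≥ 1; Kozak context (−6..+4) frequency matrices, upstream
  (−4..−1) GC, lengths, folding and positional metrics for translated vs
  untranslated uORFs; TE compared across genes with 0 / 1 / ≥2 translated
  uORFs by Kolmogorov–Smirnov tests.

## Worked example

Simulate a small experiment with known ground truth, run the full
pipeline, and inspect the summary:

```r
library(riboTE)

cfg <- simulationConfig(n_genes = 300L, n_footprints = 30000L, seed = 7L)
sim <- simulateAll(cfg)
dir <- tempfile(); writeSimulation(sim, dir)

summary <- runAll(pipelineConfig(
  gtf        = file.path(dir, "annot.gtf"),
  fasta      = file.path(dir, "genome.fa"),
  rnaCounts  = file.path(dir, "rna_counts.tsv"),
  riboCounts = file.path(dir, "ribo_counts.tsv"),
  footprints = file.path(dir, "footprints.tsv"),
  outDir     = file.path(dir, "out"), seed = 1))

str(summary[c("frame0_fraction", "deg_transcription", "deg_translation",
              "te_differential", "quadrant_counts", "r2",
              "n_uorfs", "n_translated_uorfs")])
#> $ frame0_fraction   : num 0.849
#> $ deg_transcription : int 70
#> $ deg_translation   : int 99
#> $ te_differential   : int 27
#> $ quadrant_counts   : List of 9 (A 0, B 1, C 29, D 24, E 192,
#>                       F 14, G 31, H 8, I 1)
#> $ r2                : num 0.459
#> $ n_uorfs           : int 414
#> $ n_translated_uorfs: int 216
```

Reading the output: the generator planted frame-0 periodicity 0.85, and
the QC recovers 0.849. It planted 4-fold transcription effects in 20% of
the 300 genes (30 up and 30 down, which translation follows, so they
belong in quadrants C and G) and 4-fold TE-only effects in 10% (15
translation-down, 15 translation-up: quadrants D and F). The counts above
recover 29 of the 30 planted C genes and all 30 G genes (plus one false
positive); D (24) and F (14) sit around
their planted 15s, the excess D reflecting total-count normalization bias
at the translation level when regulation is asymmetric (see the vignette;
`norm = "median_ratios"` removes it). The
`out/` directory holds the per-stage TSVs (DE tables at both levels, TE
records, quadrant assignments, uORF catalogue, Kozak PFM, feature
summaries with letter displays) plus `summary.json` and `run.log`.

A thin command-line wrapper over the same functions ships in
`inst/scripts/ribotrans` (subcommands `simulate`, `prepare`, `riboqc`,
`de`, `run-all`).

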