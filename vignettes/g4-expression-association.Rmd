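---
title: "Quantifying the association between observed G-quadruplexes and differential gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the association between observed G-quadruplexes and differential gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4assoc)
```

## The question and the model

G-quadruplexes (G4s) are four-stranded nucleic-acid structures that form in
G-rich sequence, concentrate in regulatory regions, and are resolved by
helicases such as DHX36. When a G4 helicase is lost, genes whose promoters
or bodies carry many G4s are candidates for expression change. `g4assoc`
asks the corresponding statistical question: *given a catalog of
experimentally observed quadruplexes (OQs, e.g. G4-Seq calls) and a table
of differential-expression (DE) results, are DE genes more likely to carry
OQs, and do they carry more of them, than the genomic background?*

The analysis is deliberately simple and fully specified:

1. **Promoters.** For each gene, the promoter is the fixed window of
   `window` bp (default 1000) directly upstream of its transcription start
   site, strand-aware. The TSS is taken as the 5' end of the annotated gene
   span — the only transcript-free reading when one promoter per gene is
   required. Transcript-level promoters are out of scope.
2. **Consensus OQ catalog.** G4-Seq detects OQs under two stabilizing
   conditions (K+ and pyridostatin, PDS). The catalog used downstream is
   the set supported by both: the coordinate intersection of every
   overlapping K+/PDS pair, merged and sorted. An alternative mode keeps
   the whole K+ interval whenever any PDS overlap exists
   (`consensus_mode = "kplus-anchored"`); it is exposed because it changes
   OQ counts.
3. **Strict containment.** An OQ is assigned to a promoter or gene body
   only if its coordinates lie entirely within the region; boundary
   straddlers are not counted. An OQ inside several overlapping regions
   increments each of them, which keeps every region's count independent of
   what other regions exist. OQ strand is ignored by default
   (`strand_policy = "match"` restricts to same-strand calls).
4. **Stratification.** A gene is DE when its adjusted p-value is present
   and below `alpha` (default 0.05). Fold-change tiers are inclusive:
   tier *k* requires |log2 fold-change| >= log2(*k*), with tiers 2, 5, 10 by
   default. The non-DE background is the *annotation complement*: every
   annotated gene not called DE, including genes the DE tool never tested
   (missing `padj` rows are kept as non-DE rather than dropped).
5. **Tests.** Presence enrichment is an upper-tail hypergeometric test:
   from *N* regions of which *K* contain an OQ, a group of *n* regions
   showing *k* OQ-containing members has
   \[p = \sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i}\Big/\binom{N}{n},\]
   accumulated in log space so that genome-scale universes (N ~ 50,000)
   with p-values far below double-precision underflow remain exact on the
   log scale. Count comparisons use the Wilcoxon rank-sum statistic
   \(W = \sum \mathrm{rank}(x) - n_1(n_1+1)/2\) with midranks for ties; the
   per-region OQ counts are heavily skewed, which is why a rank test is
   used rather than a t-test. By default the count comparison is restricted
   to OQ-containing regions (so the group means reported alongside are
   means per OQ-containing region); `positive_only = FALSE` includes the
   zeros. Because DE genes can simply be longer, `length_comparison()`
   runs the same rank test on annotated gene lengths as a confound check.
6. **Over-representation.** `ora_with_bh()` provides generic term
   over-representation (hypergeometric upper tail per term,
   Benjamini–Hochberg step-up across terms) for user-supplied term-to-gene
   mappings; no ontology content ships with the package.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `window` | 1000 | bp | conventional proximal-promoter width; exposed because results scale with it |
| `alpha` | 0.05 | adjusted p | standard FDR threshold for calling DE |
| `tiers` | 2, 5, 10 | fold change | inclusive thresholds on \(2^{|log2fc|}\) |
| `strand_policy` | ignore | — | G4-Seq reports per-strand calls but promoter G4 effects are not strand-restricted a priori |
| `consensus_mode` | intersect | — | conservative; count-stable under either input's fragmentation |
| `positive_only` | TRUE | — | group means are per OQ-containing region |

## Statistical conventions

* **W convention.** `rank_sum_test()` returns the Mann–Whitney form of W
  (first-sample rank sum minus \(n_1(n_1+1)/2\)), bounded by
  \([0, n_1 n_2]\), with the DE group first in the pipeline's comparisons.
* **Sidedness.** Two-sided p-values are reported by default — the
  conservative choice when direction is not pre-registered; one-sided
  alternatives are available.
* **Exact vs approximate.** The rank-sum p is exact (full enumeration of
  \(\binom{n_1+n_2}{n_1}\) rank assignments) for tie-free samples with
  \(n_1+n_2 \le 20\); otherwise a normal approximation with tie-corrected
  variance \(\tfrac{n_1 n_2}{12}\big[(N+1)-\sum(t^3-t)/(N(N-1))\big]\) and
  a 0.5 continuity correction is used. For tie-free samples of sizes 8–10
  the approximation tracks the exact one-sided tail within 0.01 (a
  two-sided p is twice the smaller tail, so its error bound is doubled).
* **Rounding.** Report tables print the percentage of regions with an OQ
  to 1 decimal and the mean OQs per OQ-containing region to 2 decimals;
  unrounded values are retained in `pct_raw`/`mean_raw` and in the JSON
  report.
* **Degenerate inputs.** Empty OQ sets yield all-zero counts rather than
  errors; a group with no OQ-containing region makes the count comparison
  impossible and is recorded in the report as a skipped test; a
  hypergeometric call outside its support is an error, not a clamped value.

## Coordinate conventions

Internally every interval is a `GenomicRanges::GRanges` (1-based, closed),
the Bioconductor convention. GTF/GFF (1-based closed) pass through
unchanged; BED (0-based half-open) and the TSV annotation dialect
(`start0` column) are shifted at the I/O boundary. All containment logic
therefore lives in one convention and the off-by-one surface is confined
to readers and writers, which round-trip in the tests. Promoters that run
past a chromosome edge are clipped (and flagged); promoters clipped to
zero length are dropped and reported. Promoters overlapping neighboring
genes are *not* masked — the analysis counts them as-is, and
the per-region independence of strict containment makes this harmless.

## What the synthetic generator emulates

`synthetic_config()` / `generate_g4_dataset()` produce a complete input
set with known ground truth: a few chromosomes carrying non-overlapping
genes with log-normal lengths truncated to 1–100 kb on both strands; OQ
intervals of 15–50 bp placed by a Poisson process at `lambda0` expected
OQs per kb, multiplied by `rho` in the promoters and bodies of the DE
subset; and a DESeq2-shaped DE table in which `de_fraction` of genes get
`padj < alpha` with fold-changes spread across the 2-/5-/10-fold tiers
(most DE genes below 2-fold, matching the subtle-effect regime the method
targets). Defaults: 2000 genes on 4 x 25 Mb chromosomes, `lambda0 = 0.5`,
`rho = 3`, `de_fraction = 0.15`, 54.3% of DE genes upregulated.

Constructional guarantees worth knowing:

* inter-gene gaps are at least `2*window + 2` bp, so promoters and gene
  bodies are pairwise disjoint and every planted per-region count is
  exactly recoverable by strict containment;
* planted OQs keep a 1 bp margin from region edges and >= 1 bp from each
  other, so no two planted intervals merge during the consensus
  intersection;
* each condition BED is the planted (consensus) set plus condition-private
  decoys placed only in intergenic space and alternately assigned to
  K+/PDS, so decoys exercise `intersect_conditions()` but never survive
  it;
* a single RNG stream keyed by `seed` makes files byte-identical across
  reruns.

What it does **not** emulate: sequence composition (no FASTA is
generated), OQ clustering or hotspots, overlapping genes and shared
bidirectional promoters, correlated OQ counts between a gene's promoter
and body beyond the shared DE multiplier, and any realistic null
correlation between expression change and G4 content. Passing tests on
synthetic data therefore demonstrate the *pipeline's correctness and
calibration*, not biological conclusions about any real genome.

Problem sizes used by the test suite were chosen to exercise the
asymptotic behavior while keeping runs quick: null calibration uses 200
generated datasets of 400 genes at `rho = 1` (rejection rate at
alpha = 0.05 must fall in the central 95% binomial band), and
power/recovery uses 100 datasets of 5000 genes at `rho = 3`,
`lambda0 = 0.5` (presence enrichment p < 0.01 and the DE/non-DE mean
promoter count ratio within 15% of `rho`, each in at least 95% of seeds).

## Design choices where the design was open

* **Hypergeometric universe.** The background for presence enrichment is
  all annotated regions of the class, with successes being regions that
  contain at least one consensus OQ. The additive structure of the group
  counts (DE plus non-DE equals all OQ-containing regions) requires the
  non-DE group to be the annotation complement, which is why missing-padj
  genes stay in the universe.
* **Consensus geometry.** "Supported by both conditions" is implemented
  as intersect-then-merge, which equals the intersection of the two
  condition coverages; it is symmetric, deterministic, and the most
  conservative of the available readings.
* **Multi-region OQs** are counted once per containing region; any
  de-duplication rule would make one region's count depend on the rest of
  the annotation.
* **Interval lookup** uses the indexed overlap engine of
  `GenomicRanges::findOverlaps(type = "within")`; a quadratic all-pairs
  scan is kept in the test suite as an independent oracle.

## Known limitations

* One promoter per gene; alternative transcripts with distinct promoters
  are invisible to the analysis.
* OQ catalogs are taken at face value; no re-calling, scoring, or motif
  prediction of putative quadruplexes is performed.
* The DE model itself (normalization, dispersion, shrinkage) is upstream;
  `log2fc` is used exactly as supplied.
* The gene-length confound is *reported*, not adjusted for; a
  length-matched resampling would be the natural extension.

## A minimal run

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 7, n_genes = 1000)
paths <- generate_g4_dataset(cfg, "g4demo")$paths
report <- run_g4_analysis(paths$genes, paths$oq_kplus, paths$oq_pds,
                          paths$de_table, chrom_sizes = paths$chrom_sizes,
                          outdir = "g4demo/out")
report$summaries
report$tests$promoter_presence_DE
recover_truth(report, file.path("g4demo", "truth.json"))
```
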