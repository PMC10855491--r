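# g4assoc

Association analysis between observed G-quadruplexes (OQs) and
differential gene expression, in R.

G-quadruplexes are four-stranded DNA/RNA structures that accumulate in
regulatory regions and are resolved by dedicated helicases (e.g. DHX36).
When such a helicase is perturbed, genes with G4-rich promoters or bodies
are prime candidates for expression change. Given (i) a gene annotation,
(ii) two G4-Seq-style interval sets from different stabilizer conditions
(K+ and pyridostatin), and (iii) a DESeq2-shaped differential-expression
(DE) table, `g4assoc` answers two questions for promoters and gene bodies:

* **Presence** — are DE genes more likely than the genomic background to
  carry at least one OQ in the region? Tested with the upper-tail
  hypergeometric probability
  *p* = Σ<sub>i≥k</sub> C(K,i)·C(N−K,n−i)/C(N,n), computed in log space
  (N = all regions, K = regions with an OQ, n = group size, k = group
  regions with an OQ), so genome-scale p-values below double underflow
  remain exact on the log scale.
* **Load** — do DE genes carry *more* OQs per region? Tested with the
  Wilcoxon rank-sum statistic W = Σ rank(x) − n₁(n₁+1)/2 (midranks for
  ties; exact enumeration for small tie-free samples, otherwise a
  tie-corrected normal approximation with continuity correction), because
  per-region OQ counts are strongly skewed. A gene-length comparison flags
  the classic confound that DE genes may simply be longer.

Around this core: strand-aware promoter derivation (fixed window upstream
of each gene's TSS), a consensus OQ catalog built by intersecting the two
stabilizer conditions, strict-containment assignment of OQs to regions
(boundary straddlers never count), DE stratification into inclusive 2-/5-/
10-fold tiers, gene-list tallies (transcription factors, oncogenes,
helicases), generic over-representation with Benjamini–Hochberg
correction, and a synthetic-data generator with planted enrichment that
makes every stage testable end to end.

## Worked example

Everything below is computed; no external data needed.

```r
library(g4assoc)

cfg   <- synthetic_config(seed = 7, n_genes = 1000)   # rho = 3 planted enrichment
paths <- generate_g4_dataset(cfg, "g4demo")$paths
report <- run_g4_analysis(paths$genes, paths$oq_kplus, paths$oq_pds,
                          paths$de_table, chrom_sizes = paths$chrom_sizes)
```

```
[g4assoc] genes read: 1000
[g4assoc] promoters derived: 1000 (0 dropped by edge clipping)
[g4assoc] OQs: K+=19792, PDS=19791, consensus=8973
[g4assoc] DE genes: 150 of 1000 in universe (0 table ids unmatched)
```

```r
report$summaries[report$summaries$group %in% c("all", "DE", "nonDE"), c(1:4, 6:7)]
```

```
 region_class group n_regions n_with_oq pct_with_oq mean_oq_per_oq_region
     promoter   all      1000       472        47.2                  1.43
     promoter    DE       150       119        79.3                  1.96
     promoter nonDE       850       353        41.5                  1.26
         gene   all      1000       930        93.0                  8.92
         gene    DE       150       147        98.0                 18.99
         gene nonDE       850       783        92.1                  7.03
```

79.3% of DE-gene promoters contain an OQ versus 47.2% genome-wide, and
OQ-containing DE promoters average 1.96 OQs versus 1.26 for non-DE — the
planted 3-fold density enrichment, recovered. The tests quantify it:

```r
report$tests$promoter_presence_DE      # N=1000 K=472 n=150 k=119  p=2.67e-18
report$tests$promoter_counts_DE_vs_nonDE  # W=29,994  p=1.31e-17
recover_truth(report, file.path("g4demo", "truth.json"))
# recovery OK: pipeline output matches planted truth
```

With real data, point `annotation` at a GTF/GFF3 (`dialect = "gtf"`), the
two OQ arguments at G4-Seq BED files, and `de_table` at your DESeq2
results export; `run_g4_analysis(..., outdir = ...)` writes `report.json`
plus TSV/BED artifacts. A thin command-line wrapper with `run`,
`simulate`, and `validate` subcommands is installed at
`inst/cli/g4assoc.R`.

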