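Package: g4assoc
Title: G-Quadruplex Content and Differential Gene Expression Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the association between observed G-quadruplex
    (G4) structures and differential gene expression. Derives strand-aware
    promoter windows from a gene annotation, builds a consensus observed
    quadruplex (OQ) catalog from two G4-Seq stabilizer-condition interval
    sets, assigns OQs to promoters and gene bodies by strict containment,
    stratifies genes by differential-expression status and fold-change tier,
    and tests OQ enrichment with hypergeometric and Wilcoxon rank-sum
    statistics. Includes a synthetic-data generator with planted enrichment
    so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
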