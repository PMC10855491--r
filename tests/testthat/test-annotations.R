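test_that("GTF gene lines convert 1-based closed coordinates correctly", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tgene_id "g1"; gene_biotype "protein_coding";',
    'chr1\tsrc\texon\t1001\t1500\t.\t+\t.\tgene_id "g1"; gene_biotype "protein_coding";',
    'chr2\tsrc\tgene\t501\t900\t.\t-\t.\tgene_id "g2"; gene_biotype "lincRNA";',
    'GL000192.1\tsrc\tgene\t10\t200\t.\t+\t.\tgene_id "g3"; gene_biotype "misc";'
  ), gtf)
  genes <- read_gene_annotation(gtf, dialect = "gtf",
                                chrom_filter = c("chr1", "chr2"))
  expect_equal(length(genes), 2L)  # exon row and filtered scaffold excluded
  expect_equal(GenomicRanges::start(genes)[1], 1001)
  expect_equal(GenomicRanges::end(genes)[1], 2000)
  expect_equal(GenomicRanges::width(genes)[1], 1000)
  expect_equal(genes$biotype, c("protein_coding", "non_coding"))
})

test_that("TSV dialect reads 0-based half-open coordinates and rejects bad input", {
  tsv <- tempfile(fileext = ".tsv")
  write_genes_tsv(data.frame(gene_id = c("a", "b"), chrom = "c1",
                             start0 = c(1000, 5000), end = c(2000, 8000),
                             strand = c("+", "-"),
                             biotype = c("protein_coding", "antisense")), tsv)
  genes <- read_gene_annotation(tsv, dialect = "tsv")
  expect_equal(GenomicRanges::start(genes), c(1001, 5001))
  expect_equal(GenomicRanges::width(genes), c(1000, 3000))
  expect_equal(genes$biotype, c("protein_coding", "non_coding"))

  dup <- tempfile()
  write_genes_tsv(data.frame(gene_id = c("a", "a"), chrom = "c1",
                             start0 = c(0, 100), end = c(50, 200),
                             strand = "+", biotype = "non_coding"), dup)
  expect_error(read_gene_annotation(dup, dialect = "tsv"), "duplicate gene_id.*a")
  expect_error(read_gene_annotation(tsv, dialect = "tsv",
                                    chrom_filter = "absent"),
               "no gene records")
})

test_that("promoters are strand-aware upstream windows with edge clipping", {
  genes <- gr0(c("c1", "c1", "c1"), c(5000, 5000, 300), c(8000, 8000, 900),
               strand = c("+", "-", "+"), id = c("gp", "gm", "gclip"))
  prom <- derive_promoters(genes, window = 1000, chrom_sizes = c(c1 = 20000))
  # + strand gene [5000,8000) -> promoter [4000,5000)
  expect_equal(GenomicRanges::start(prom)[1] - 1, 4000)
  expect_equal(GenomicRanges::end(prom)[1], 5000)
  # - strand gene -> promoter [8000,9000)
  expect_equal(GenomicRanges::start(prom)[2] - 1, 8000)
  expect_equal(GenomicRanges::end(prom)[2], 9000)
  # edge clip: gene [300,900) + strand -> promoter [0,300), flagged
  expect_equal(GenomicRanges::start(prom)[3] - 1, 0)
  expect_equal(GenomicRanges::end(prom)[3], 300)
  expect_equal(prom$clipped, c(FALSE, FALSE, TRUE))
  expect_equal(GenomicRanges::width(prom)[1:2], c(1000, 1000))
  # promoters are disjoint from every unclipped gene body
  expect_equal(length(GenomicRanges::findOverlaps(prom, genes[1:2],
                                                  ignore.strand = TRUE)), 0L)

  expect_error(derive_promoters(genes, 1000, c(other = 100)),
               "missing from chrom_sizes")
})

test_that("promoters clipping to zero length are dropped and reported", {
  # gclip keeps a shortened promoter; gdrop's promoter falls entirely past
  # the chromosome end (minus-strand gene ending at the last base)
  genes <- gr0("c1", c(300, 5000), c(900, 6000), strand = c("+", "-"),
               id = c("gclip", "gdrop"))
  prom <- derive_promoters(genes, window = 1000, chrom_sizes = c(c1 = 6000))
  expect_equal(prom$gene_id, "gclip")
  expect_true(prom$clipped)
  expect_equal(attr(prom, "dropped"), "gdrop")
  # a gene starting at base 0 on + strand likewise yields no promoter
  g0 <- gr0("c1", 0, 400, strand = "+", id = "gzero")
  p0 <- derive_promoters(g0, 1000, c(c1 = 6000))
  expect_equal(length(p0), 0L)
  expect_equal(attr(p0, "dropped"), "gzero")
})

test_that("strand reflection maps plus promoters onto minus promoters", {
  set.seed(11)
  L <- 100000
  for (i in 1:20) {
    s <- sample(2000:80000, 1); e <- s + sample(500:10000, 1)
    g_plus <- gr0("c1", s, e, strand = "+", id = "g")
    g_ref <- gr0("c1", L - e, L - s, strand = "-", id = "g")
    p_plus <- derive_promoters(g_plus, 1000, c(c1 = L))
    p_ref <- derive_promoters(g_ref, 1000, c(c1 = L))
    # reflection of [a, b) is [L - b, L - a)
    expect_equal(L - GenomicRanges::end(p_plus),
                 GenomicRanges::start(p_ref) - 1)
    expect_equal(L - (GenomicRanges::start(p_plus) - 1),
                 GenomicRanges::end(p_ref))
  }
})

test_that("promoter BED round-trips through write and re-read", {
  genes <- gr0("c7", c(5000, 9000), c(8000, 12000), strand = c("+", "-"),
               id = c("a", "b"))
  prom <- derive_promoters(genes, 1000, c(c7 = 50000))
  bed <- tempfile(fileext = ".bed")
  write_regions_bed(prom, bed)
  back <- utils::read.delim(bed, header = FALSE)
  expect_equal(back$V2, GenomicRanges::start(prom) - 1)
  expect_equal(back$V3, GenomicRanges::end(prom))
  expect_equal(back$V4, prom$gene_id)
})

test_that("gene_body_intervals is an order-stable identity extraction", {
  genes <- gr0("c1", c(1000, 300), c(2000, 600), strand = c("+", "-"),
               id = c("x", "y"))
  gb <- gene_body_intervals(genes)
  expect_equal(length(gb), 2L)
  expect_equal(gb$gene_id, c("x", "y"))
  expect_equal(GenomicRanges::start(gb), GenomicRanges::start(genes))
  expect_equal(length(gene_body_intervals(genes[0])), 0L)
})
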