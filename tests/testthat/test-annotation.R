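test_that("GTF reading collapses transcripts to outermost TSS/TES", {
  gtf <- tempfile(fileext = ".gtf")
  lines <- c(
    # single-transcript gene: [1000,6000) zero-based <- 1-based 1001..6000
    'chr1\tsrc\ttranscript\t1001\t6000\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t1001\t6000\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    # two transcripts [1000,6000) and [1500,7000) -> collapsed [1000,7000)
    'chr1\tsrc\ttranscript\t10001\t15000\t.\t+\t.\tgene_id "g2"; transcript_id "t2a";',
    'chr1\tsrc\texon\t10001\t15000\t.\t+\t.\tgene_id "g2"; transcript_id "t2a";',
    'chr1\tsrc\ttranscript\t10501\t16000\t.\t+\t.\tgene_id "g2"; transcript_id "t2b";',
    'chr1\tsrc\texon\t10501\t16000\t.\t+\t.\tgene_id "g2"; transcript_id "t2b";')
  writeLines(lines, gtf)
  idx <- read_annotation(gtf, chrom_sizes = c(chr1 = 50000))
  g1 <- idx$genes[idx$genes$gene_id == "g1", ]
  expect_equal(g1$tss, 1000)
  expect_equal(g1$tes, 6000)
  g2 <- idx$genes[idx$genes$gene_id == "g2", ]
  expect_equal(c(g2$start, g2$end), c(10000, 16000))
  expect_equal(c(g2$tss, g2$tes), c(10000, 16000))
  # overlapping exons of the two transcripts merged into one
  expect_equal(nrow(idx$exons[idx$exons$gene_id == "g2", ]), 1)
})

test_that("GTF errors name the offending line and empty annotation fails", {
  bad <- tempfile(fileext = ".gtf")
  writeLines(c('chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1";',
               'chr1\tsrc\texon\tNOPE\t300\t.\t+\t.\tgene_id "g1";'), bad)
  expect_error(read_annotation(bad), "line 2")
  noid <- tempfile(fileext = ".gtf")
  writeLines('chr1\tsrc\texon\t100\t200\t.\t+\t.\tfoo "bar";', noid)
  expect_error(read_annotation(noid), "gene_id")
  empty <- tempfile(fileext = ".gtf")
  writeLines("# header only", empty)
  expect_error(read_annotation(empty), "no genes|parseable|malformed")
})

test_that("BED12 blocks become exons and thick region becomes CDS", {
  bed <- tempfile(fileext = ".bed")
  writeLines(paste(c("chr1", 1000, 9000, "gX", 0, "+", 2000, 8000,
                     "0,0,0", 3, "500,1000,1500", "0,3000,6500"),
                   collapse = "\t"), bed)
  idx <- read_annotation(bed, chrom_sizes = c(chr1 = 20000))
  ex <- idx$exons
  expect_equal(ex$start, c(1000, 4000, 7500))
  expect_equal(ex$end, c(1500, 5000, 9000))
  # thick [2000,8000) intersected with blocks: first block misses it
  expect_equal(idx$cds$start, c(4000, 7500))
  expect_equal(idx$cds$end, c(5000, 8000))
})

test_that("promoters sit strictly upstream of the TSS, clipped at bounds", {
  genes <- tibble::tibble(
    gene_id = c("p", "m", "edge"), chrom = "chr1",
    start = c(10000, 5000, 0), end = c(12000, 10000, 1000),
    strand = c("+", "-", "+"))
  idx <- annotation_index(genes, chrom_sizes = c(chr1 = 50000))
  pr <- promoter_regions(idx, 3000)
  expect_equal(unlist(pr[pr$gene_id == "p", c("start", "end")],
                      use.names = FALSE), c(7000, 10000))
  expect_equal(unlist(pr[pr$gene_id == "m", c("start", "end")],
                      use.names = FALSE), c(10000, 13000))
  expect_equal(unlist(pr[pr$gene_id == "edge", c("start", "end")],
                      use.names = FALSE), c(0, 0))  # fully clipped
})

test_that("reversing a gene's strand mirrors the promoter about its span", {
  mk <- function(strand) {
    annotation_index(tibble::tibble(gene_id = "g", chrom = "chr1",
                                    start = 20000, end = 30000,
                                    strand = strand),
                     chrom_sizes = c(chr1 = 100000))
  }
  fwd <- promoter_regions(mk("+"))
  rev <- promoter_regions(mk("-"))
  expect_equal(c(fwd$start, fwd$end), c(17000, 20000))
  expect_equal(c(rev$start, rev$end), c(30000, 33000))
  # mirror: distances to the gene span are symmetric
  expect_equal(20000 - fwd$start, rev$end - 30000)
})

test_that("gene body equals the gene span regardless of strand", {
  idx <- toy_index()
  gb <- gene_body_regions(idx)
  expect_equal(gb$start, idx$genes$start)
  expect_equal(gb$end, idx$genes$end)
})

test_that("metagene bins tile the flanked span with near-equal widths", {
  g <- tibble::tibble(gene_id = "g", chrom = "chr1", start = 10000,
                      end = 15000, strand = "+")
  b <- metagene_bins(g, flank_bp = 5000, n_bins = 100)
  expect_equal(nrow(b), 100)
  expect_true(all(b$end - b$start == 150))  # 15000 bp / 100 bins
  expect_equal(min(b$start), 5000)
  expect_equal(max(b$end), 20000)
  expect_true(all(b$start[-1] == b$end[-100]))  # contiguous

  # remainder spread: 15007 bp over 100 bins -> first 7 bins get 151
  g2 <- tibble::tibble(gene_id = "g2", chrom = "chr1", start = 10000,
                       end = 15007, strand = "+")
  b2 <- metagene_bins(g2, 5000, 100)
  w <- b2$end - b2$start
  expect_equal(w, c(rep(151, 7), rep(150, 93)))
  expect_equal(sum(w), 15007)
})

test_that("minus-strand bins run 3'-to-5' in genomic coordinates", {
  g <- tibble::tibble(gene_id = "g", chrom = "chr1", start = 10000,
                      end = 15000, strand = "-")
  b <- metagene_bins(g, 5000, 100)
  # bin 1 is the 5'-most in transcription direction = genomic right end
  expect_equal(b$end[1], 20000)
  expect_equal(b$start[1], 20000 - 150)
  expect_equal(b$start[100], 5000)
  # single bin degenerate case covers the whole span
  b1 <- metagene_bins(g, 5000, 1)
  expect_equal(c(b1$start, b1$end), c(5000, 20000))
})

test_that("bins beyond the chromosome end are clipped and flagged", {
  g <- tibble::tibble(gene_id = "g", chrom = "chr1", start = 1000,
                      end = 3000, strand = "+")
  b <- metagene_bins(g, flank_bp = 5000, n_bins = 10,
                     chrom_sizes = c(chr1 = 6000))
  expect_true(any(b$clipped))
  expect_true(all(b$start >= 0 & b$end <= 6000))
})

test_that("position classification follows CDS > UTR > intron > promoter", {
  idx <- toy_index()
  pts <- tibble::tibble(
    chrom = "chr1",
    pos = c(11500,  # inside gA CDS
            10500,  # gA exon outside CDS -> UTR
            15000,  # gA intronic gap
            8000,   # gA promoter ('+', [7000,10000))
            41000,  # gB promoter ('-', [40000,43000))
            1000))  # intergenic
  got <- classify_positions(idx, pts)$category
  expect_equal(got, c("CDS", "UTR", "intron", "promoter", "promoter",
                      "intergenic"))
  expect_error(classify_positions(idx, tibble::tibble(chrom = "chrZ", pos = 1)),
               "unknown chromosome")
})

test_that("gene-body categories outrank an overlapping neighbour promoter", {
  # gene n2 starts inside the intron-free body of n1's downstream region:
  # n2's promoter [12000,15000) overlaps n1's body [10000,20000)
  genes <- tibble::tibble(gene_id = c("n1", "n2"), chrom = "chr1",
                          start = c(10000, 15000), end = c(20000, 25000),
                          strand = "+")
  exons <- tibble::tibble(gene_id = c("n1", "n2"), chrom = "chr1",
                          start = c(10000, 15000), end = c(10100, 25000))
  idx <- annotation_index(genes, exons, chrom_sizes = c(chr1 = 50000))
  got <- classify_positions(idx, tibble::tibble(chrom = "chr1", pos = 13000))
  expect_equal(got$category, "intron")
})

test_that("classification partitions the toy genome (per-base oracle)", {
  idx <- toy_index()
  pos <- seq(0, 49999, by = 7)  # systematic sample of every 7th base
  got <- classify_positions(idx, tibble::tibble(chrom = "chr1", pos = pos))
  want <- classify_oracle(idx, "chr1", pos)
  expect_equal(got$category, want)
  expect_true(all(table(got$category) > 0))
})
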