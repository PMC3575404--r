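# Readers, writers and container invariants for the external formats.

test_that("BED6 reading maps fields directly and sorts in genome order", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr2\t500\t900\tgeneC\t0\t-",
               "chr1\t100\t200\tgeneA\t0\t+",
               "chr1\t300\t450\tgeneB\t0\t-"), p)
  g <- read_gene_locations(p, "bed")
  expect_s3_class(g, "gene_table")
  expect_equal(g$gene_id, c("geneA", "geneB", "geneC"))
  expect_equal(g$start, c(100, 300, 500))
  expect_equal(g$end, c(200, 450, 900))
  expect_equal(g$strand, c("+", "-", "-"))
  expect_equal(g$length, c(100, 150, 400))
})

test_that("malformed or empty BED input raises a parse error naming the line", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tgeneA\t0\t+",
               "chr1\t300"), p)
  expect_error(read_gene_locations(p, "bed"), "line 2")
  writeLines(character(0), p)
  expect_error(read_gene_locations(p, "bed"), "no records")
})

test_that("GFF3 coordinates are converted from 1-based inclusive to 0-based half-open", {
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=geneA",
               "chr1\tsrc\tgene\t501\t800\t.\t-\t.\tID=geneB"), p)
  g <- read_gene_locations(p, "gff3")
  expect_equal(g$start, c(100, 500))
  expect_equal(g$end, c(200, 800))
  expect_equal(g$gene_id, c("geneA", "geneB"))
})

test_that("duplicate gene ids are rejected", {
  expect_error(
    gene_table(c("geneA", "geneA"), "chr1", c(0, 500), c(100, 700),
               c("+", "+")),
    "duplicate gene_id")
})

test_that("gene tables round-trip through BED and GFF3 shifts only the start", {
  g <- gene_table(c("a", "b", "c"), c("chr1", "chr1", "chr2"),
                  c(0, 5000, 100), c(2000, 7000, 900),
                  c("+", "-", "+"))
  p <- withr::local_tempfile(fileext = ".bed")
  write_gene_locations(g, p)
  expect_equal(read_gene_locations(p, "bed"), g)

  # same gene expressed in both conventions: GFF3 start is BED start + 1
  pg <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t2000\t.\t+\t.\tID=a"), pg)
  gg <- read_gene_locations(pg, "gff3")
  expect_equal(gg$start, 0)
  expect_equal(gg$end, 2000)
})

test_that("expression tables parse with sample count and reject NA / mismatches", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2",
               "gA\t1.5\t2.0", "gB\t0.1\t0.2", "gC\t3\t4"), p)
  e <- read_expression_table(p)
  expect_equal(n_samples(e), 2)
  expect_equal(rownames(e$values), c("gA", "gB", "gC"))

  writeLines(c("gene_id\ts1\ts2", "gA\tNA\t2.0", "gB\t1\t2"), p)
  expect_error(read_expression_table(p), "missing")

  writeLines(c("gene_id\ts1\ts2", "gA\tx\t2.0", "gB\t1\t2"), p)
  expect_error(read_expression_table(p), "non-numeric")

  # detection with a mismatched sample header
  writeLines(c("gene_id\ts1\ts2", "gA\t1\t2", "gB\t1\t2"), p)
  pd <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\tsX", "gA\tP\tP", "gB\tA\tA"), pd)
  expect_error(read_expression_table(p, pd), "sample header")

  # detection naming a gene absent from the values
  writeLines(c("gene_id\ts1\ts2", "gA\tP\tP", "gB\tA\tA", "gZ\tP\tP"), pd)
  expect_error(read_expression_table(p, pd), "absent")

  writeLines(c("gene_id\ts1\ts2", "gA\tP\tP", "gB\tA\tM"), pd)
  e2 <- read_expression_table(p, pd)
  expect_equal(e2$detection["gB", ], c(s1 = "A", s2 = "M"))
})

test_that("synteny block tables read, validate and round-trip", {
  p <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(ref_chrom = "chr1", ref_start = 0, ref_end = 1e6,
                   tgt_chrom = "chrX", tgt_start = 5e6, tgt_end = 6e6,
                   orientation = "+", stringsAsFactors = FALSE)
  bs <- synteny_blocks("cow", df)
  write_synteny_blocks(bs, p)
  back <- read_synteny_blocks(p, species = "cow")
  expect_equal(back$blocks, bs$blocks)
  expect_equal(nrow(back$blocks), 1)

  # overlapping reference intervals are invalid
  bad <- rbind(df, within(df, { ref_start <- 5e5; ref_end <- 2e6 }))
  expect_error(synteny_blocks("cow", bad), "overlapping")

  # inverted interval is invalid
  expect_error(
    synteny_blocks("cow", within(df, { ref_start <- 2e6; ref_end <- 1e6 })),
    "ref_start >= ref_end")

  # an empty file is a valid empty set
  writeLines(character(0), p)
  empty <- read_synteny_blocks(p, species = "empty")
  expect_equal(nrow(empty$blocks), 0)
})
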