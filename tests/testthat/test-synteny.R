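# Span conservation, the synteny score, and the anchor-chaining builder.

test_that("conservation means containment in a single block", {
  bs <- simple_blocks(list("chr1", 0, 1e6))
  expect_true(is_conserved("chr1", 1e5, 2e5, bs))
  expect_false(is_conserved("chr2", 1e5, 2e5, bs))

  # a span crossing a block boundary is not unbroken
  two <- simple_blocks(list("chr1", 0, 1e6), list("chr1", 1.05e6, 2e6))
  expect_false(is_conserved("chr1", 9e5, 1.1e6, two))

  # empty block set conserves nothing
  empty <- synteny_blocks("none", data.frame(
    ref_chrom = character(), ref_start = numeric(), ref_end = numeric(),
    tgt_chrom = character(), tgt_start = numeric(), tgt_end = numeric(),
    orientation = character()))
  expect_false(is_conserved("chr1", 10, 20, empty))
})

test_that("shrinking a span never flips conserved to not conserved", {
  set.seed(17)
  bs <- simple_blocks(list("chr1", 0, 5e5), list("chr1", 6e5, 9e5))
  for (i in 1:50) {
    s <- sort(sample.int(1e6, 2))
    if (s[1] == s[2]) next
    outer <- is_conserved("chr1", s[1], s[2], bs)
    mid <- floor(mean(s))
    inner <- c(s[1], max(s[1] + 1, mid))
    if (outer) expect_true(is_conserved("chr1", inner[1], inner[2], bs))
  }
})

test_that("the synteny score is the conserved fraction of species", {
  conserved <- simple_blocks(list("chr1", 0, 1e6))
  broken <- simple_blocks(list("chr1", 0, 4e5), list("chr1", 4.5e5, 1e6))
  sets <- c(rep(list(conserved), 7), rep(list(broken), 2))
  expect_equal(synteny_score("chr1", 1e5, 3.9e5 + 2e4, sets), 7 / 9)
  expect_equal(round(synteny_score("chr1", 1.2e5, 4.2e5, sets), 2), 0.78)
  expect_equal(synteny_score("chr1", 1e5, 2e5, rep(list(conserved), 3)), 1)
  expect_equal(synteny_score("chr1", 1e5, 4.4e5, rep(list(broken), 3)), 0)
  expect_error(synteny_score("chr1", 1e5, 2e5, list()), "at least one")
})

test_that("duplicating every species file leaves SS unchanged (k/m structure)", {
  conserved <- simple_blocks(list("chr1", 0, 1e6))
  broken <- simple_blocks(list("chr1", 0, 4e5), list("chr1", 4.5e5, 1e6))
  sets <- c(rep(list(conserved), 2), list(broken))
  ss1 <- synteny_score("chr1", 1e5, 4.4e5, sets)
  ss2 <- synteny_score("chr1", 1e5, 4.4e5, c(sets, sets))
  expect_equal(ss1, ss2)
  expect_equal(ss1, 2 / 3)
})

anchor_df <- function(ref_pos, tgt_pos, ref_chrom = "chr1",
                      tgt_chrom = "t1", orientation = "+") {
  data.frame(ref_chrom = ref_chrom, ref_pos = ref_pos,
             tgt_chrom = tgt_chrom, tgt_pos = tgt_pos,
             orientation = orientation, stringsAsFactors = FALSE)
}

test_that("two close anchors chain into one block under the default parameters", {
  # defaults: max_gap 1 Mb, min_blk 100 kb, num_mark 2; a 120 kb chain
  # passes every filter
  a <- anchor_df(c(2e6, 2.12e6), c(5e6, 5.06e6))
  bs <- build_blocks(a, synteny_params())
  expect_equal(nrow(bs$blocks), 1)
  expect_equal(bs$blocks$ref_start, 2e6)
  expect_equal(bs$blocks$ref_end, 2.12e6)
  expect_equal(bs$blocks$tgt_start, 5e6)
  expect_equal(bs$blocks$tgt_end, 5.06e6)
  expect_equal(bs$blocks$orientation, "+")
})

test_that("anchors separated beyond max_gap form discarded singleton chains", {
  a <- anchor_df(c(2e6, 4e6), c(5e6, 5.06e6))  # ref gap 2 Mb > 1 Mb
  bs <- build_blocks(a, synteny_params())
  expect_equal(nrow(bs$blocks), 0)
})

test_that("a target-chromosome switch breaks the chain", {
  a <- anchor_df(c(1e6, 1.2e6, 1.4e6), c(5e6, 9e6, 5.4e6),
                 tgt_chrom = c("t1", "t2", "t1"))
  bs <- build_blocks(a, synteny_params())
  # the middle anchor isolates all three into chains of < 2 markers
  expect_equal(nrow(bs$blocks), 0)

  # without the intruder the flanks chain fine
  b2 <- build_blocks(a[c(1, 3), ], synteny_params())
  expect_equal(nrow(b2$blocks), 1)
})

test_that("num_mark and min_blk filters apply, and orientation never breaks chains", {
  a <- anchor_df(c(1e6, 1.2e6, 1.4e6), c(5e6, 5.2e6, 5.4e6),
                 orientation = c("+", "-", "+"))
  expect_equal(nrow(build_blocks(a, synteny_params())$blocks), 1)
  expect_equal(nrow(build_blocks(a, synteny_params(num_mark = 4))$blocks), 0)
  expect_equal(nrow(build_blocks(a, synteny_params(min_blk = 5e5))$blocks), 0)
  # majority orientation wins
  am <- anchor_df(c(1e6, 1.2e6, 1.4e6), c(5e6, 5.2e6, 5.4e6),
                  orientation = c("-", "-", "+"))
  expect_equal(build_blocks(am, synteny_params())$blocks$orientation, "-")
})

test_that("built blocks satisfy the reader's non-overlap invariant and round-trip", {
  set.seed(23)
  a <- anchor_df(sort(sample.int(5e6, 40)),
                 sort(sample.int(5e6, 40)) + 1e6,
                 orientation = sample(c("+", "-"), 40, replace = TRUE))
  bs <- build_blocks(a, synteny_params(min_blk = 1e4))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_synteny_blocks(bs, p)
  back <- read_synteny_blocks(p, species = bs$species)
  expect_equal(back$blocks, bs$blocks)
})
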