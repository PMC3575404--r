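# Window enumeration and the Average Neighborhood Correlation.

test_that("four genes with sizes 2-4 give exactly AB, ABC, ABCD, BC, BCD, CD", {
  g <- simple_genes(4, prefix = "")
  # rename for readability
  g$gene_id <- c("A", "B", "C", "D")
  w <- enumerate_gene_windows(g, 2, 4)
  expect_setequal(w$members,
                  c("A,B", "A,B,C", "A,B,C,D", "B,C", "B,C,D", "C,D"))
})

test_that("window counts follow sum over W of max(0, n - W + 1), clipped at n", {
  g5 <- simple_genes(5)
  expect_equal(nrow(enumerate_gene_windows(g5, 2, 2)), 4)

  g3 <- simple_genes(3)
  w <- enumerate_gene_windows(g3, 2, 5)  # sizes beyond n are skipped
  expect_setequal(w$members, c("g001,g002", "g002,g003", "g001,g002,g003"))

  # multi-chromosome: windows never span chromosomes
  g <- rbind(simple_genes(4, chrom = "chr1"),
             simple_genes(3, chrom = "chr2", prefix = "h"))
  class(g) <- c("gene_table", "data.frame")
  w2 <- enumerate_gene_windows(g, 2, 3)
  expect_equal(nrow(w2), (3 + 2) + (2 + 1))
  expect_false(any(grepl("g.*,h|h.*,g", w2$members)))
})

test_that("window membership matches the brute-force run enumeration", {
  set.seed(13)
  for (rep in 1:25) {
    n <- sample(2:30, 1)
    n2 <- sample(1:10, 1)
    g <- rbind(simple_genes(n, chrom = "chr1"),
               simple_genes(n2, chrom = "chr2", prefix = "h"))
    class(g) <- c("gene_table", "data.frame")
    min_s <- sample(2:4, 1)
    max_s <- min_s + sample(0:6, 1)
    w <- enumerate_gene_windows(g, min_s, max_s)
    expect_setequal(w$members, oracle_gene_windows(g, min_s, max_s))
  }
})

test_that("bp windows take the maximal run fitting the budget", {
  g <- gene_table(c("A", "B", "C"), "chr1",
                  c(0, 20000, 1e6), c(10000, 30000, 1.01e6), rep("+", 3))
  w <- enumerate_bp_windows(g, 100000)
  expect_equal(w$members, "A,B")  # C is isolated at 100 kb
  expect_equal(w$span_end - w$span_start, 30000)

  # budget below any 2-gene span -> nothing
  expect_equal(nrow(enumerate_bp_windows(g, 5000)), 0)

  # single-gene chromosome contributes nothing in any mode
  g1 <- simple_genes(1, chrom = "chrY")
  expect_equal(nrow(enumerate_bp_windows(g1, 1e6)), 0)
  expect_equal(nrow(enumerate_gene_windows(simple_genes(2), 2, 2)), 1)
})

test_that("compute_anc averages the distinct pairwise correlations", {
  g <- simple_genes(3, prefix = "")
  g$gene_id <- c("A", "B", "C")
  # build a correlation matrix object by hand via an expression matrix with
  # known pairwise structure is fiddly; instead check against the definition
  e <- simple_expr(list(c(1, 2, 3, 4), c(1, 2, 4, 3), c(4, 3, 2, 1)),
                   ids = c("A", "B", "C"))
  cm <- pairwise_spearman(e, genes = g)
  m <- cm$rho$chr1
  expected <- (m["A", "B"] + m["B", "C"] + m["A", "C"]) / 3
  expect_equal(compute_anc(c("A", "B", "C"), cm, "chr1"), expected)
  # 2-gene window is exactly the pair's rho
  expect_equal(compute_anc(c("A", "B"), cm, "chr1"), m["A", "B"])
  # silent member in a 2-gene window forces ANC = 0
  cm_sil <- pairwise_spearman(e, silent = "B", genes = g)
  expect_equal(compute_anc(c("A", "B"), cm_sil, "chr1"), 0)
  expect_error(compute_anc(c("A", "Z"), cm, "chr1"), "absent")
})

test_that("incremental ANC equals the brute-force mean over all pairs", {
  set.seed(77)
  for (rep in 1:30) {
    n <- sample(4:30, 1)
    g <- simple_genes(n)
    vals <- matrix(rnorm(n * 6), nrow = n,
                   dimnames = list(g$gene_id, sprintf("s%02d", 1:6)))
    e <- expression_matrix(vals)
    cm <- pairwise_spearman(e, genes = g)
    w <- enumerate_gene_windows(g, 2, min(10, n))
    w <- compute_all_ancs(w, cm)
    oracle_m <- oracle_spearman_matrix(vals)
    mem <- strsplit(w$members, ",", fixed = TRUE)
    brute <- vapply(mem, oracle_anc, numeric(1), m = oracle_m)
    expect_equal(w$anc, brute, tolerance = 1e-12)
    # ANC is bounded by the extreme pairwise rho among members
    for (r in seq_len(nrow(w))) {
      idx <- match(mem[[r]], rownames(oracle_m))
      pr <- oracle_m[idx, idx][upper.tri(diag(length(idx)))]
      expect_gte(w$anc[r], min(pr) - 1e-12)
      expect_lte(w$anc[r], max(pr) + 1e-12)
    }
  }
})

test_that("degenerate chromosomes: identical profiles give ANC 1, silent give 0", {
  g <- simple_genes(4)
  same <- matrix(rep(c(1, 3, 2, 5), each = 4), nrow = 4,
                 dimnames = list(g$gene_id, sprintf("s%02d", 1:4)))
  e <- expression_matrix(same)
  w <- compute_all_ancs(enumerate_gene_windows(g, 2, 4),
                        pairwise_spearman(e, genes = g))
  expect_equal(w$anc, rep(1, nrow(w)))

  w0 <- compute_all_ancs(enumerate_gene_windows(g, 2, 4),
                         pairwise_spearman(e, silent = g$gene_id, genes = g))
  expect_equal(w0$anc, rep(0, nrow(w0)))
})
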