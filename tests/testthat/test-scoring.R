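# The TNS gate, per-gene bests, non-redundant selection and the writers.

test_that("the TNS gate is inclusive at alpha and exact zero above it", {
  expect_equal(total_neighborhood_score(0.5, 0.78, 0.01), 0.39)
  expect_identical(total_neighborhood_score(0.9, 1.0, 0.06), 0)
  # p exactly at alpha passes
  expect_equal(total_neighborhood_score(0.8, 0.5, 0.05), 0.4)
  # out-of-range inputs are rejected
  expect_error(total_neighborhood_score(1.5, 0.5, 0.01), "anc")
  expect_error(total_neighborhood_score(0.5, 1.5, 0.01), "ss")
  expect_error(total_neighborhood_score(0.5, 0.5, 1.5), "p")
})

test_that("|TNS| <= SS <= 1 and the gate zeroes everything above alpha", {
  set.seed(19)
  anc <- runif(200, -1, 1)
  ss <- runif(200)
  p <- runif(200)
  tns <- total_neighborhood_score(anc, ss, p)
  expect_true(all(abs(tns) <= ss + 1e-12))
  expect_true(all(tns[p > 0.05] == 0))
  expect_equal(tns[p <= 0.05], (ss * anc)[p <= 0.05])
})

test_that("2-gene windows with a silent member end with TNS = 0", {
  set.seed(29)
  g <- simple_genes(12)
  e <- simple_expr(lapply(1:12, function(i) rnorm(8)), ids = g$gene_id)
  silent <- g$gene_id[c(3, 7)]
  cm <- pairwise_spearman(e, silent = silent, genes = g)
  w <- compute_all_ancs(enumerate_gene_windows(g, 2, 2), cm)
  w <- empirical_pvalues(w, e, g, silent = silent, n_shuffles = 10, seed = 2)
  w$ss <- 1
  sc <- finalize_scores(w, g)
  has_silent <- vapply(strsplit(w$members, ","), function(m) {
    any(m %in% silent)
  }, logical(1))
  expect_true(all(sc$neighborhoods$tns[has_silent] == 0))
})

test_that("best TNS per gene is the max over containing windows, 0 otherwise", {
  g <- simple_genes(4)
  w <- enumerate_gene_windows(g, 2, 3)
  w$anc <- 0.5; w$p_value <- 0.01; w$ss <- 1
  w$tns <- c(0, 0.3, 0.41, 0.2, 0.1)[seq_len(nrow(w))]
  # g002 appears in windows 1 (g1,g2), 2 (g2,g3), 4 (g1,g2,g3): max of
  # those tns values
  best <- best_tns_per_gene(w, g)
  in_w <- vapply(strsplit(w$members, ","), function(m) "g002" %in% m,
                 logical(1))
  expect_equal(unname(best["g002"]), max(w$tns[in_w]))
  # every best value is attained by some window (or is the 0 default)
  expect_true(all(best %in% c(0, w$tns)))

  # a gene on a single-gene chromosome is in no window
  g2 <- rbind(g, simple_genes(1, chrom = "chrZ", prefix = "z"))
  class(g2) <- c("gene_table", "data.frame")
  expect_equal(unname(best_tns_per_gene(w, g2)["z001"]), 0)
})

test_that("non-redundant selection is greedy by score and gene-disjoint", {
  g <- simple_genes(6)
  w <- enumerate_gene_windows(g, 2, 3)
  w$anc <- 0.5; w$p_value <- 0.01; w$ss <- 1
  w$tns <- 0
  i_ab <- which(w$members == "g001,g002")
  i_bc <- which(w$members == "g002,g003")
  i_de <- which(w$members == "g004,g005")
  w$tns[i_ab] <- 0.5
  w$tns[i_bc] <- 0.4   # overlaps the 0.5 window -> dropped
  w$tns[i_de] <- 0.4   # disjoint -> kept
  sel <- select_nonredundant(w, min_tns = 0.2)
  expect_setequal(sel$members, c("g001,g002", "g004,g005"))
  # all below the threshold -> empty
  expect_equal(nrow(select_nonredundant(w, min_tns = 0.9)), 0)
  # result is pairwise gene-disjoint on a random instance
  set.seed(4)
  w$tns <- runif(nrow(w))
  sel2 <- select_nonredundant(w, min_tns = 0.1)
  ids <- unlist(strsplit(sel2$members, ","))
  expect_equal(anyDuplicated(ids), 0)
})

test_that("report, custom track and TNS matrix writers emit deterministic files", {
  set.seed(37)
  g <- simple_genes(8)
  e <- simple_expr(lapply(1:8, function(i) rnorm(6)), ids = g$gene_id)
  cm <- pairwise_spearman(e, genes = g)
  w <- compute_all_ancs(enumerate_gene_windows(g, 2, 3), cm)
  w <- empirical_pvalues(w, e, g, n_shuffles = 5, seed = 11)
  w$ss <- 1
  sc <- finalize_scores(w, g)

  rp <- withr::local_tempfile(fileext = ".tsv")
  write_report(sc, rp)
  lines <- readLines(rp)
  expect_equal(length(lines), nrow(w) + 1)  # header + one row per window
  expect_match(lines[1], "^chrom\tspan_start")
  write_report(sc, rp2 <- withr::local_tempfile(fileext = ".tsv"))
  expect_identical(readLines(rp2), lines)

  tr <- withr::local_tempfile(fileext = ".bedGraph")
  write_custom_track(sc, tr)
  tl <- readLines(tr)
  expect_match(tl[1], "^track type=bedGraph")
  expect_equal(length(tl), nrow(g) + 1)
  vals <- as.numeric(vapply(strsplit(tl[-1], "\t"), `[[`, "", 4))
  expect_equal(vals, unname(sc$best_tns[g$gene_id]))

  mx <- withr::local_tempfile(fileext = ".tsv")
  write_tns_matrix(sc, mx)
  m <- read.delim(mx, check.names = FALSE)
  expect_equal(dim(m), c(nrow(g), 1 + 2))  # gene_id + sizes g2, g3
  expect_setequal(colnames(m)[-1], c("g2", "g3"))
})

test_that("an empty genome yields a header-only report", {
  g <- simple_genes(1)  # no possible window
  e <- simple_expr(list(c(1, 2, 3)), ids = g$gene_id)
  w <- enumerate_gene_windows(g, 2, 4)
  sc <- finalize_scores(w, g)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_report(sc, p)
  expect_equal(length(readLines(p)), 1)
})
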