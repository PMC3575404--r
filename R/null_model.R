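# Position-preserving permutation null. Gene positions (and hence the whole
# window structure) are fixed; expression profiles are shuffled across genes,
# preserving the gene-density and regional characteristics of the genome.
# Silent status travels with each profile, and silent-gene zeroing is applied
# after the shuffle, exactly as for the observed data.

#' Shuffle expression profiles across gene positions
#'
#' Returns a matrix with the same gene ids in the same order, each now mapped
#' to a uniform-random permutation of the original profile rows (detection
#' calls, if present, travel with their profile). The multiset of row vectors
#' is preserved exactly, and the same seed always yields the same
#' permutation. The permutation used is attached as attribute
#' `"permutation"` so silent flags can follow their profiles.
#'
#' @param expr an [expression_matrix()].
#' @param rng_seed integer seed for the shuffle.
#' @return An [expression_matrix()] with shuffled rows.
#' @export
shuffle_profiles <- function(expr, rng_seed) {
  set.seed(rng_seed)
  n <- nrow(expr$values)
  perm <- sample.int(n)
  v <- expr$values[perm, , drop = FALSE]
  rownames(v) <- rownames(expr$values)
  d <- expr$detection
  if (!is.null(d)) {
    d <- d[perm, , drop = FALSE]
    rownames(d) <- rownames(expr$values)
  }
  out <- expression_matrix(v, d)
  attr(out, "permutation") <- perm
  out
}

#' Empirical p-values from randomized transcriptomes
#'
#' For each of `n_shuffles` shuffles, the pairwise correlations and the ANC
#' of every window are recomputed on the shuffled matrix (positions and
#' window structure fixed) and the null ANCs are pooled per window-size
#' stratum (`size_key`: gene count, or requested bp budget). The p-value of
#' an observed window is the proportion of pooled null ANCs at its size that
#' are strictly greater than the observed ANC. p-values are reported
#' unadjusted; [stats::p.adjust()] can be applied downstream if desired, but
#' no adjustment ever feeds the TNS gate.
#'
#' @param windows window data frame with `anc` set (see
#'   [compute_all_ancs()]).
#' @param expr the observed [expression_matrix()].
#' @param genes the non-redundant [gene_table()] the windows came from.
#' @param silent character vector of silent gene ids of the observed matrix.
#' @param n_shuffles number of randomized transcriptomes to pool (>= 1);
#'   pooling across all same-size windows genome-wide yields thousands of
#'   null draws per stratum even with few shuffles.
#' @param seed integer; drives one reproducible stream for all shuffles.
#' @param pseudo_count if `TRUE`, report (k+1)/(n+1) instead of k/n, so no
#'   p-value is exactly 0.
#' @param scope correlation scope, as in [pairwise_spearman()].
#' @return `windows` with the `p_value` column set (each in \[0, 1\]).
#' @export
empirical_pvalues <- function(windows, expr, genes, silent = character(),
                              n_shuffles = 10L, seed = 1L,
                              pseudo_count = FALSE,
                              scope = "per_chromosome") {
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1")
  if (!nrow(windows)) {
    windows$p_value <- numeric(0)
    return(windows)
  }
  if (anyNA(windows$anc)) stop("windows must have anc set before p-values")

  set.seed(seed)
  shuffle_seeds <- sample.int(2^31 - 1, n_shuffles)
  is_silent <- rownames(expr$values) %in% silent

  null_anc <- vector("list", n_shuffles)
  for (k in seq_len(n_shuffles)) {
    sh <- shuffle_profiles(expr, shuffle_seeds[k])
    perm <- attr(sh, "permutation")
    silent_k <- rownames(expr$values)[is_silent[perm]]
    corr_k <- pairwise_spearman(sh, silent_k, scope, genes)
    null_anc[[k]] <- compute_all_ancs(windows, corr_k)$anc
  }
  pool_anc <- unlist(null_anc, use.names = FALSE)
  pool_key <- rep(windows$size_key, times = n_shuffles)

  p <- rep(NA_real_, nrow(windows))
  for (skey in unique(windows$size_key)) {
    null_sorted <- sort(pool_anc[pool_key == skey])
    n_tot <- length(null_sorted)
    if (n_tot == 0L) stop("internal: empty null stratum for size ", skey)
    rows <- which(windows$size_key == skey)
    n_greater <- n_tot - findInterval(windows$anc[rows], null_sorted)
    p[rows] <- if (pseudo_count) {
      (n_greater + 1) / (n_tot + 1)
    } else {
      n_greater / n_tot
    }
  }
  windows$p_value <- p
  windows
}
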