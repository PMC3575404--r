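# Candidate-neighborhood enumeration and the Average Neighborhood
# Correlation (ANC): the mean of all distinct pairwise Spearman correlations
# among a window's member genes. Windows are runs of consecutive genes on one
# chromosome; a window of size W starting at gene i reuses the pair-sum of
# the size W-1 window at the same start, so all sizes are scored in one pass.

empty_windows <- function() {
  data.frame(chrom = character(), start_index = integer(), size = integer(),
             size_mode = character(), size_key = character(),
             span_start = numeric(), span_end = numeric(),
             members = character(),
             anc = numeric(), p_value = numeric(), ss = numeric(),
             tns = numeric(), stringsAsFactors = FALSE)
}

#' Enumerate all gene-count windows
#'
#' For every chromosome with n genes and every window size W in
#' `min_size:max_size`, emits the `max(0, n - W + 1)` windows of W consecutive
#' genes. Sizes larger than a chromosome's gene count are silently skipped.
#' The window span runs from the smallest member start to the largest member
#' end (nested genes make the end non-monotone, hence the max).
#'
#' @param genes a non-redundant [gene_table()] in genome order (see
#'   [remove_overlapping_transcripts()]).
#' @param min_size,max_size window size range in genes; `2 <= min <= max`.
#' @return Data frame of windows with columns `chrom`, `start_index` (1-based
#'   position of the first member within its chromosome), `size` (gene
#'   count), `size_mode`, `size_key` (stratification key for the permutation
#'   null), `span_start`, `span_end`, `members` (comma-separated gene ids),
#'   and unset score columns `anc`, `p_value`, `ss`, `tns`.
#' @examples
#' g <- gene_table(letters[1:4], "chr1", c(0, 10, 20, 30) * 1000,
#'                 c(5, 15, 25, 35) * 1000, rep("+", 4))
#' enumerate_gene_windows(g, 2, 4)$members
#' @export
enumerate_gene_windows <- function(genes, min_size = 2L, max_size = min_size) {
  min_size <- as.integer(min_size)
  max_size <- as.integer(max_size)
  if (min_size < 2L || min_size > max_size) {
    stop("need 2 <= min_size <= max_size")
  }
  out <- list()
  for (ch in unique(genes$chrom)) {
    sub <- genes[genes$chrom == ch, , drop = FALSE]
    n <- nrow(sub)
    if (n < min_size) next
    for (W in min_size:min(max_size, n)) {
      starts <- seq_len(n - W + 1L)
      members <- vapply(starts, function(i) {
        paste(sub$gene_id[i:(i + W - 1L)], collapse = ",")
      }, character(1))
      span_end <- vapply(starts, function(i) {
        max(sub$end[i:(i + W - 1L)])
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_index = starts, size = W,
        size_mode = "gene_count", size_key = sprintf("g%d", W),
        span_start = sub$start[starts], span_end = span_end,
        members = members,
        anc = NA_real_, p_value = NA_real_, ss = NA_real_, tns = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_windows())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Enumerate base-pair windows
#'
#' For each base-pair budget S and each start gene i, the window is the
#' maximal run of consecutive genes i..j whose span (min start to max end)
#' fits within S, provided it holds at least 2 genes. The same member run can
#' satisfy several budgets; each such row is tagged with its own `size_key`
#' (`bp<S>`) so the permutation null stratifies by the requested size, and
#' the scores of duplicate runs are identical by construction.
#'
#' @param genes a non-redundant [gene_table()] in genome order.
#' @param sizes integer vector of base-pair budgets, sorted ascending.
#' @return Data frame of windows in the same shape as
#'   [enumerate_gene_windows()]; `size` is the gene count of the run.
#' @export
enumerate_bp_windows <- function(genes, sizes) {
  sizes <- as.numeric(sizes)
  if (!length(sizes) || any(sizes < 1)) stop("bp sizes must be >= 1")
  if (is.unsorted(sizes)) stop("bp sizes must be sorted ascending")
  out <- list()
  for (ch in unique(genes$chrom)) {
    sub <- genes[genes$chrom == ch, , drop = FALSE]
    n <- nrow(sub)
    if (n < 2L) next
    for (S in sizes) {
      for (i in seq_len(n - 1L)) {
        run_end <- sub$end[i]
        j_ok <- NA_integer_
        for (j in (i + 1L):n) {
          run_end <- max(run_end, sub$end[j])
          if (run_end - sub$start[i] <= S) j_ok <- j else break
        }
        if (is.na(j_ok)) next
        W <- j_ok - i + 1L
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start_index = i, size = W,
          size_mode = "bp", size_key = sprintf("bp%s",
            format(S, scientific = FALSE, trim = TRUE)),
          span_start = sub$start[i],
          span_end = max(sub$end[i:j_ok]),
          members = paste(sub$gene_id[i:j_ok], collapse = ","),
          anc = NA_real_, p_value = NA_real_, ss = NA_real_, tns = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_windows())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Average Neighborhood Correlation of one window
#'
#' Mean of the W(W-1)/2 distinct pairwise rho values among the members; for a
#' 2-gene window this is exactly the pair's rho. Entries touching silent
#' genes are already 0 in the correlation matrix, so silent members pull the
#' ANC toward 0.
#'
#' @param members character vector of member gene ids, or a single
#'   comma-separated string.
#' @param corr a `corr_matrix` from [pairwise_spearman()].
#' @param chrom chromosome holding the window; optional for genome-wide
#'   matrices, otherwise inferred from the first member if omitted.
#' @return The ANC, a real in \[-1, 1\].
#' @export
compute_anc <- function(members, corr, chrom = NULL) {
  if (length(members) == 1L && grepl(",", members, fixed = TRUE)) {
    members <- strsplit(members, ",", fixed = TRUE)[[1L]]
  }
  if (length(members) < 2L) stop("a window needs at least 2 members")
  if (corr$scope == "genome_wide") {
    m <- corr$rho[[".all"]]
  } else {
    if (is.null(chrom)) {
      hit <- vapply(corr$gene_ids, function(ids) members[1L] %in% ids,
                    logical(1))
      if (!any(hit)) stop("window member absent from correlation matrix: ",
                          members[1L])
      chrom <- names(corr$gene_ids)[which(hit)[1L]]
    }
    m <- corr_rho(corr, chrom)
  }
  idx <- match(members, rownames(m))
  if (anyNA(idx)) {
    stop("window member absent from correlation matrix: ",
         members[which(is.na(idx))[1L]])
  }
  sub <- m[idx, idx, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' ANC for every window, sharing work across sizes
#'
#' Produces values identical to calling [compute_anc()] window by window, but
#' grows each start position's pair-sum incrementally: the window (i, W)
#' reuses the sum of (i, W-1) and adds only the W-1 pairs introduced by the
#' new member. Requires that the windows were enumerated from the same gene
#' table that `corr` was built from, so that `start_index` indexes the
#' chromosome's rho matrix directly.
#'
#' @param windows window data frame from [enumerate_gene_windows()] or
#'   [enumerate_bp_windows()].
#' @param corr a `corr_matrix` over the same genes.
#' @return `windows` with the `anc` column set.
#' @export
compute_all_ancs <- function(windows, corr) {
  if (!nrow(windows)) {
    windows$anc <- numeric(0)
    return(windows)
  }
  anc <- rep(NA_real_, nrow(windows))
  for (ch in unique(windows$chrom)) {
    m <- corr_rho(corr, ch)
    wi <- which(windows$chrom == ch)
    for (rows in split(wi, windows$start_index[wi])) {
      i <- windows$start_index[rows[1L]]
      Ws <- windows$size[rows]
      want <- split(rows, Ws)
      pair_sum <- 0
      for (W in 2:max(Ws)) {
        j <- i + W - 1L
        if (j > nrow(m)) break
        pair_sum <- pair_sum + sum(m[i:(j - 1L), j])
        hit <- want[[as.character(W)]]
        if (!is.null(hit)) anc[hit] <- pair_sum / (W * (W - 1L) / 2)
      }
    }
  }
  windows$anc <- anc
  windows
}
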