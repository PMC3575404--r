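# Per-gene and per-pair annotations used downstream of neighborhood scoring:
# Tau tissue specificity, adjacent-pair orientation classes, and tandem
# duplicate flags from precomputed BLAST tabular output.

#' Tau tissue-specificity index (unnormalized)
#'
#' `Tau = sum_i (1 - x_i / max_j x_j)` over the N samples of a non-negative
#' expression profile. A gene expressed equally in all samples has Tau = 0; a
#' gene expressed in exactly one sample has Tau = N - 1. Note this is the
#' unnormalized form with range \[0, N-1\] — many tools divide by N - 1 to
#' map it onto \[0, 1\]; divide yourself if you need that scale. Tau is
#' scale-invariant, so any positive rescaling of the profile leaves it
#' unchanged, but it expects linear-scale, non-negative expression (RPKM or
#' de-logged intensities): de-log log2 data before calling.
#'
#' @param x non-negative numeric vector (length N >= 1) with `max(x) > 0`.
#' @return Tau in \[0, N-1\].
#' @examples
#' tau(rep(5, 6))          # 0
#' tau(c(7, 0, 0, 0, 0))   # 4 = N - 1
#' tau(c(2, 1, 1))         # 1
#' @export
tau <- function(x) {
  if (!length(x)) stop("empty expression profile")
  if (any(x < 0)) stop("Tau requires non-negative expression values")
  m <- max(x)
  if (m <= 0) stop("Tau is undefined for an all-zero profile")
  sum(1 - x / m)
}

#' Tau for every gene of an expression matrix
#'
#' @param expr an [expression_matrix()] on a linear non-negative scale.
#' @return Named numeric vector of Tau values.
#' @export
tau_per_gene <- function(expr) {
  apply(expr$values, 1L, tau)
}

#' Orientation class of an adjacent gene pair
#'
#' Non-overlapping adjacent gene pairs fall in one of three strand
#' configurations: both genes on the same strand (`co_oriented`), head-to-head
#' on opposite strands (`divergent`: upstream gene on `-`, downstream on `+`,
#' i.e. transcription start sites face each other), or tail-to-tail
#' (`convergent`: upstream on `+`, downstream on `-`).
#'
#' @param a,b single-row [gene_table()] slices (or lists with `chrom`,
#'   `start`, `end`, `strand`); `a` must precede `b` on the same chromosome
#'   without overlap.
#' @return `"co_oriented"`, `"divergent"` or `"convergent"`.
#' @export
classify_orientation <- function(a, b) {
  if (a$chrom != b$chrom) stop("genes lie on different chromosomes")
  if (a$start >= b$start) stop("first gene must precede the second")
  if (b$start < a$end) stop("overlapping genes have no pair orientation")
  if (a$strand == b$strand) {
    "co_oriented"
  } else if (a$strand == "-") {
    "divergent"
  } else {
    "convergent"
  }
}

#' Orientation classes of all adjacent pairs
#'
#' @param genes a non-redundant [gene_table()] in genome order.
#' @return Data frame with one row per adjacent same-chromosome pair:
#'   `gene_a`, `gene_b`, `class`. Classes partition the pairs, so per
#'   chromosome with n genes there are exactly n - 1 rows.
#' @export
adjacent_orientations <- function(genes) {
  out <- list()
  for (ch in unique(genes$chrom)) {
    sub <- genes[genes$chrom == ch, , drop = FALSE]
    n <- nrow(sub)
    if (n < 2L) next
    cls <- vapply(seq_len(n - 1L), function(i) {
      classify_orientation(sub[i, ], sub[i + 1L, ])
    }, character(1))
    out[[length(out) + 1L]] <- data.frame(
      gene_a = sub$gene_id[-n], gene_b = sub$gene_id[-1L],
      class = cls, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      class = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read BLAST tabular hits (outfmt-6 dialect)
#'
#' Only columns 1 (query), 2 (subject) and 11 (e-value) are consumed.
#'
#' @param path path to a 12-column tab-separated BLAST report (no header).
#' @return Data frame with columns `query`, `subject`, `evalue`.
#' @export
read_blast_hits <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 11L) {
    stop("BLAST tabular input needs at least 11 columns (outfmt 6)")
  }
  data.frame(query = as.character(df[[1L]]),
             subject = as.character(df[[2L]]),
             evalue = as.numeric(df[[11L]]),
             stringsAsFactors = FALSE)
}

#' Flag duplicate gene pairs from BLAST hits
#'
#' A pair is flagged as duplicates iff any hit in either direction has
#' e-value strictly below `threshold`. Self-hits are ignored; hits naming
#' unknown genes are skipped with a warning.
#'
#' @param hits data frame from [read_blast_hits()] (columns `query`,
#'   `subject`, `evalue`).
#' @param known_ids character vector of valid gene ids.
#' @param threshold e-value cutoff, default `1e-07`.
#' @return Data frame of unordered flagged pairs, columns `gene_a` <
#'   `gene_b` lexicographically, one row per pair.
#' @export
flag_duplicates <- function(hits, known_ids, threshold = 1e-07) {
  if (threshold <= 0) stop("threshold must be > 0")
  unknown <- !(hits$query %in% known_ids) | !(hits$subject %in% known_ids)
  if (any(unknown)) {
    bad <- unique(c(hits$query[!(hits$query %in% known_ids)],
                    hits$subject[!(hits$subject %in% known_ids)]))
    warning("skipping hit(s) naming unknown gene id(s): ",
            paste(head(bad, 5L), collapse = ", "))
    hits <- hits[!unknown, , drop = FALSE]
  }
  hits <- hits[hits$query != hits$subject & hits$evalue < threshold, ,
               drop = FALSE]
  if (!nrow(hits)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  }
  pairs <- data.frame(gene_a = pmin(hits$query, hits$subject),
                      gene_b = pmax(hits$query, hits$subject),
                      stringsAsFactors = FALSE)
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Remove one member of each duplicate pair
#'
#' Produces a duplicate-free gene set: for each flagged pair with both
#' members still present, the member with the lower maximum expression is
#' removed (ties: the shorter gene, then the lexicographically later id).
#' Pairs are revisited until no flagged pair survives intact, so a chain
#' {A,B}, {B,C} can be resolved by the single removal of B.
#'
#' @param genes a [gene_table()].
#' @param dup_pairs data frame of flagged pairs (see [flag_duplicates()]).
#' @param expr an [expression_matrix()] covering the genes.
#' @return The reduced [gene_table()].
#' @export
drop_duplicate_partners <- function(genes, dup_pairs, expr) {
  if (!nrow(dup_pairs)) return(genes)
  max_expr <- apply(expr$values, 1L, max)
  glen <- stats::setNames(genes$length, genes$gene_id)
  present <- genes$gene_id
  loser <- function(a, b) {
    if (max_expr[a] != max_expr[b]) {
      return(if (max_expr[a] < max_expr[b]) a else b)
    }
    if (glen[a] != glen[b]) return(if (glen[a] < glen[b]) a else b)
    max(a, b)
  }
  repeat {
    intact <- dup_pairs$gene_a %in% present & dup_pairs$gene_b %in% present
    if (!any(intact)) break
    pr <- which(intact)[1L]
    drop <- loser(dup_pairs$gene_a[pr], dup_pairs$gene_b[pr])
    present <- setdiff(present, drop)
  }
  out <- genes[genes$gene_id %in% present, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_table", "data.frame")
  out
}
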