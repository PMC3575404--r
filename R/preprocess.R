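# Non-redundant gene set + silent-gene flags.
#
# Overlapping transcripts are reduced to one representative per overlap group
# before any window is formed; silent genes are kept in the gene set but have
# their correlations zeroed later, because "not expressed" is informative and
# dropping such genes would splice unrelated neighbors together.

#' Define a silent-gene policy
#'
#' Two policies mirror the two kinds of input the pipeline accepts:
#' \describe{
#'   \item{`detection_calls`}{a gene is silent iff it has fewer than
#'     `min_present_calls` `"P"` (Present) detection calls across all samples
#'     (microarray-style input; default 12).}
#'   \item{`expression_threshold`}{a gene is silent iff its maximum expression
#'     over samples is strictly below `min_max_expression` (RNA-seq-style
#'     input; default 0.2, i.e. 0.2 RPKM on a linear scale).}
#' }
#'
#' @param mode which criterion to apply.
#' @param min_present_calls minimum number of `"P"` calls (detection mode).
#' @param min_max_expression minimum of the per-gene maximum expression
#'   (threshold mode); genes at exactly the threshold are not silent.
#' @return An object of class `silent_policy`.
#' @export
silent_policy <- function(mode = c("detection_calls", "expression_threshold"),
                          min_present_calls = 12,
                          min_max_expression = 0.2) {
  mode <- match.arg(mode)
  if (min_present_calls < 0 || min_max_expression < 0) {
    stop("silent-policy thresholds must be non-negative")
  }
  structure(list(mode = mode,
                 min_present_calls = as.integer(min_present_calls),
                 min_max_expression = min_max_expression),
            class = "silent_policy")
}

#' Flag silent genes
#'
#' @param expr an [expression_matrix()].
#' @param policy a [silent_policy()]; detection mode requires the expression
#'   matrix to carry detection calls.
#' @return Character vector of silent gene ids (possibly empty).
#' @export
flag_silent_genes <- function(expr, policy) {
  stopifnot(inherits(policy, "silent_policy"))
  if (policy$mode == "detection_calls") {
    if (is.null(expr$detection)) {
      stop("detection-call policy requires a detection matrix")
    }
    n_present <- rowSums(expr$detection == "P")
    rownames(expr$values)[n_present < policy$min_present_calls]
  } else {
    row_max <- apply(expr$values, 1L, max)
    rownames(expr$values)[row_max < policy$min_max_expression]
  }
}

#' Remove overlapping transcripts, keeping the strongest representative
#'
#' Transcripts whose coordinate intervals overlap on the same chromosome
#' (strand ignored) are grouped into connected components; within each group
#' the survivor is chosen greedily: highest maximum expression across samples
#' wins, ties broken by greater length, remaining ties by lexicographic
#' gene id. Everything overlapping a chosen survivor is dropped and the rule
#' recurses on the remainder, so a group may contribute several mutually
#' non-overlapping survivors. The operation is idempotent.
#'
#' @param genes a [gene_table()]; every gene must have an expression row.
#' @param expr an [expression_matrix()].
#' @return A [gene_table()] with no two overlapping records, in genome order.
#' @export
remove_overlapping_transcripts <- function(genes, expr) {
  missing <- setdiff(genes$gene_id, rownames(expr$values))
  if (length(missing)) {
    stop("gene(s) without an expression row: ",
         paste(head(missing, 5L), collapse = ", "))
  }
  max_expr <- apply(expr$values[genes$gene_id, , drop = FALSE], 1L, max)

  keep <- integer(0)
  for (ch in unique(genes$chrom)) {
    idx <- which(genes$chrom == ch)  # genome order: sorted by start
    if (length(idx) == 1L) {
      keep <- c(keep, idx)
      next
    }
    # connected components of the interval-overlap graph: a new component
    # starts where a gene begins at/after the running max end of its
    # predecessors
    run_end <- cummax(genes$end[idx])
    comp <- cumsum(c(TRUE, genes$start[idx][-1L] >= run_end[-length(idx)]))
    for (grp in split(idx, comp)) {
      keep <- c(keep, resolve_overlap_group(genes, grp, max_expr))
    }
  }
  out <- genes[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_table", "data.frame")
  out
}

resolve_overlap_group <- function(genes, idx, max_expr) {
  kept <- integer(0)
  remaining <- idx
  while (length(remaining)) {
    o <- order(-max_expr[genes$gene_id[remaining]],
               -genes$length[remaining],
               genes$gene_id[remaining])
    best <- remaining[o[1L]]
    kept <- c(kept, best)
    overlaps_best <- genes$start[remaining] < genes$end[best] &
      genes$end[remaining] > genes$start[best]
    remaining <- remaining[!overlaps_best]
  }
  kept
}
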