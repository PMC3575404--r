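# Cross-species conservation of neighborhood spans, plus a simplified
# marker-anchor chaining builder for users who do not have precomputed block
# tables. Conservation demands containment of the span in a single block's
# reference interval: a span crossing a block boundary is not an unbroken
# segment in the comparison genome. Block orientation never matters here —
# local inversions are inconsequential at neighborhood resolution.

#' Is a span conserved in one comparison species?
#'
#' @param chrom,start,end the reference-genome span (0-based half-open,
#'   `start < end`).
#' @param blocks a [synteny_blocks()] set for one species.
#' @return `TRUE` iff the span is entirely contained within a single block's
#'   reference interval. Shrinking a span can therefore never flip the answer
#'   from `TRUE` to `FALSE`.
#' @export
is_conserved <- function(chrom, start, end, blocks) {
  if (start >= end) stop("span must have start < end")
  b <- blocks$blocks
  if (!nrow(b)) return(FALSE)
  any(b$ref_chrom == chrom & b$ref_start <= start & b$ref_end >= end)
}

#' Synteny Score of a span across comparison species
#'
#' SS = (number of species whose block set conserves the span) / (number of
#' species): a proportion k/m in \[0, 1\]. With 9 comparison species and the
#' span conserved in 7 of them, SS = 7/9 (about 0.78).
#'
#' @inheritParams is_conserved
#' @param block_sets list of [synteny_blocks()], one per comparison species;
#'   must be non-empty.
#' @return SS in \[0, 1\].
#' @export
synteny_score <- function(chrom, start, end, block_sets) {
  if (!length(block_sets)) {
    stop("at least one comparison species is required for a synteny score")
  }
  conserved <- vapply(block_sets, function(bs) {
    is_conserved(chrom, start, end, bs)
  }, logical(1))
  mean(conserved)
}

#' Synteny scores for every window
#'
#' @param windows window data frame (see [enumerate_gene_windows()]).
#' @param block_sets list of [synteny_blocks()], one per comparison species.
#' @return `windows` with the `ss` column set.
#' @export
add_synteny_scores <- function(windows, block_sets) {
  if (!nrow(windows)) {
    windows$ss <- numeric(0)
    return(windows)
  }
  windows$ss <- vapply(seq_len(nrow(windows)), function(r) {
    synteny_score(windows$chrom[r], windows$span_start[r],
                  windows$span_end[r], block_sets)
  }, numeric(1))
  windows
}

#' Block-builder parameters
#'
#' @param min_blk minimum reference span (bp) of the smallest retained block;
#'   default 100 kb.
#' @param max_gap maximum gap (bp) between consecutive anchors that may be
#'   aggregated into one block, applied on both the reference and the target
#'   genome; default 1 Mb.
#' @param num_mark minimum number of anchors per block; default 2.
#' @return An object of class `synteny_params`.
#' @export
synteny_params <- function(min_blk = 100000, max_gap = 1000000,
                           num_mark = 2L) {
  if (min_blk <= 0 || max_gap <= 0 || num_mark < 1L) {
    stop("synteny parameters must be strictly positive (num_mark >= 1)")
  }
  structure(list(min_blk = min_blk, max_gap = max_gap,
                 num_mark = as.integer(num_mark)),
            class = "synteny_params")
}

#' Build syntenic blocks from marker anchors
#'
#' A simplified stand-in for a full synteny pipeline: anchors (point matches
#' between the reference and one comparison genome) sorted by
#' (`ref_chrom`, `ref_pos`) are chained greedily. Consecutive anchors join
#' one chain iff they share the reference chromosome and the target
#' chromosome and both the reference gap and the target gap are at most
#' `max_gap`. Anchor orientation never breaks a chain (local inversions are
#' tolerated). Chains with fewer than `num_mark` anchors or a reference span
#' below `min_blk` are discarded; each survivor becomes one block spanning
#' its extreme reference and target coordinates, oriented by majority anchor
#' orientation. Ref-overlapping chains (possible when chains on different
#' target chromosomes interleave) are merged at the end so the result always
#' satisfies the [synteny_blocks()] non-overlap invariant.
#'
#' @param anchors data frame with columns `ref_chrom`, `ref_pos`,
#'   `tgt_chrom`, `tgt_pos`, `orientation` (`"+"`/`"-"`), for one species
#'   pair.
#' @param params a [synteny_params()].
#' @param species label for the resulting block set.
#' @return A [synteny_blocks()] object.
#' @export
build_blocks <- function(anchors, params = synteny_params(),
                         species = "anchors") {
  stopifnot(inherits(params, "synteny_params"))
  req <- c("ref_chrom", "ref_pos", "tgt_chrom", "tgt_pos", "orientation")
  miss <- setdiff(req, names(anchors))
  if (length(miss)) {
    stop("anchor table missing column(s): ", paste(miss, collapse = ", "))
  }
  empty <- data.frame(ref_chrom = character(), ref_start = numeric(),
                      ref_end = numeric(), tgt_chrom = character(),
                      tgt_start = numeric(), tgt_end = numeric(),
                      orientation = character(), stringsAsFactors = FALSE)
  if (!nrow(anchors)) return(synteny_blocks(species, empty))
  if (any(anchors$ref_pos < 0) || any(anchors$tgt_pos < 0)) {
    stop("anchor positions must be non-negative")
  }

  a <- anchors[order(anchors$ref_chrom, anchors$ref_pos), , drop = FALSE]
  n <- nrow(a)
  breaks <- if (n == 1L) logical(0) else {
    a$ref_chrom[-1L] != a$ref_chrom[-n] |
      a$tgt_chrom[-1L] != a$tgt_chrom[-n] |
      (a$ref_pos[-1L] - a$ref_pos[-n]) > params$max_gap |
      abs(a$tgt_pos[-1L] - a$tgt_pos[-n]) > params$max_gap
  }
  chain_id <- cumsum(c(TRUE, breaks))

  chains <- lapply(split(seq_len(n), chain_id), function(idx) {
    ref_span <- max(a$ref_pos[idx]) - min(a$ref_pos[idx])
    if (length(idx) < params$num_mark || ref_span < params$min_blk) {
      return(NULL)
    }
    plus <- sum(a$orientation[idx] == "+")
    data.frame(
      ref_chrom = a$ref_chrom[idx[1L]],
      ref_start = min(a$ref_pos[idx]),
      ref_end = max(a$ref_pos[idx]),
      tgt_chrom = a$tgt_chrom[idx[1L]],
      tgt_start = min(a$tgt_pos[idx]),
      tgt_end = max(a$tgt_pos[idx]),
      orientation = if (plus >= length(idx) - plus) "+" else "-",
      n_markers = length(idx),
      stringsAsFactors = FALSE)
  })
  chains <- do.call(rbind, chains)
  if (is.null(chains) || !nrow(chains)) return(synteny_blocks(species, empty))

  chains <- chains[order(chains$ref_chrom, chains$ref_start), , drop = FALSE]
  merged <- chains[1L, , drop = FALSE]
  if (nrow(chains) > 1L) {
    for (r in 2:nrow(chains)) {
      last <- nrow(merged)
      if (chains$ref_chrom[r] == merged$ref_chrom[last] &&
          chains$ref_start[r] < merged$ref_end[last]) {
        # ref-overlapping chains: take the union of the reference interval;
        # target side and orientation follow the chain with more markers
        merged$ref_end[last] <- max(merged$ref_end[last], chains$ref_end[r])
        if (chains$n_markers[r] > merged$n_markers[last]) {
          merged[last, c("tgt_chrom", "tgt_start", "tgt_end", "orientation")] <-
            chains[r, c("tgt_chrom", "tgt_start", "tgt_end", "orientation")]
        }
        merged$n_markers[last] <- merged$n_markers[last] + chains$n_markers[r]
      } else {
        merged <- rbind(merged, chains[r, , drop = FALSE])
      }
    }
  }
  merged$n_markers <- NULL
  synteny_blocks(species, merged)
}
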