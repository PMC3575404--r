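# The Total Neighborhood Score and its outputs. TNS = SS x ANC when the
# window's empirical p-value passes the (inclusive) significance gate,
# otherwise exactly 0. The TNS is a ranking score for prioritizing candidate
# neighborhoods, not a calibrated probability.

#' Total Neighborhood Score
#'
#' `TNS = ss * anc` when `p <= alpha` (inclusive gate), else exactly 0.
#' Since `ss` is in \[0, 1\] and `anc` in \[-1, 1\], `|TNS| <= ss` always.
#' The gate demotes neighborhoods of non-expressed genes automatically: a
#' silent member zeroes the pairwise correlations, pulling the ANC (and so
#' the upper-tail significance) down.
#'
#' @param anc Average Neighborhood Correlation(s) in \[-1, 1\].
#' @param ss Synteny Score(s) in \[0, 1\].
#' @param p empirical p-value(s) in \[0, 1\].
#' @param alpha significance gate, default 0.05.
#' @return Numeric vector of TNS values.
#' @examples
#' total_neighborhood_score(0.5, 0.78, 0.01)  # 0.39
#' total_neighborhood_score(0.9, 1.0, 0.06)   # 0
#' @export
total_neighborhood_score <- function(anc, ss, p, alpha = 0.05) {
  k <- max(length(anc), length(ss), length(p))
  anc <- rep_len(anc, k); ss <- rep_len(ss, k); p <- rep_len(p, k)
  tol <- 1e-9  # tolerate floating jitter at the range boundaries
  if (any(ss < -tol | ss > 1 + tol)) stop("ss out of [0, 1]")
  if (any(p < -tol | p > 1 + tol)) stop("p out of [0, 1]")
  if (any(anc < -1 - tol | anc > 1 + tol)) stop("anc out of [-1, 1]")
  if (length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]")
  }
  ifelse(p <= alpha, ss * anc, 0)
}

#' Attach TNS values and per-gene bests to a scored window set
#'
#' @param windows window data frame with `anc`, `p_value` and `ss` set.
#' @param genes the non-redundant [gene_table()] the windows came from.
#' @param alpha significance gate (inclusive), default 0.05.
#' @return An object of class `scored_genome`: list with `neighborhoods`
#'   (the windows, `tns` set), `best_tns` (named vector over all genes),
#'   `genes` and `alpha`.
#' @export
finalize_scores <- function(windows, genes, alpha = 0.05) {
  if (nrow(windows) &&
      (anyNA(windows$anc) || anyNA(windows$p_value) || anyNA(windows$ss))) {
    stop("windows must have anc, p_value and ss set before scoring")
  }
  windows$tns <- if (nrow(windows)) {
    total_neighborhood_score(windows$anc, windows$ss, windows$p_value, alpha)
  } else numeric(0)
  structure(list(neighborhoods = windows,
                 best_tns = best_tns_per_gene(windows, genes),
                 genes = genes, alpha = alpha),
            class = "scored_genome")
}

#' @export
print.scored_genome <- function(x, ...) {
  nb <- x$neighborhoods
  cat(sprintf(
    "scored_genome: %d window(s) over %d gene(s); %d with TNS > 0 (alpha = %g)\n",
    nrow(nb), nrow(x$genes), sum(nb$tns > 0), x$alpha))
  invisible(x)
}

#' Best associated TNS per gene
#'
#' For each gene, the maximum TNS over all scored windows that contain it;
#' 0 for genes in no window (e.g. on a single-gene chromosome) or whose
#' windows all failed the gate.
#'
#' @param windows window data frame with `tns` set.
#' @param genes a [gene_table()].
#' @return Named numeric vector, one entry per gene in genome order.
#' @export
best_tns_per_gene <- function(windows, genes) {
  best <- stats::setNames(numeric(nrow(genes)), genes$gene_id)
  if (nrow(windows) && !all(is.na(windows$tns))) {
    mem <- strsplit(windows$members, ",", fixed = TRUE)
    ids <- unlist(mem, use.names = FALSE)
    tns <- rep(windows$tns, times = lengths(mem))
    agg <- tapply(tns, ids, max)
    hit <- intersect(names(agg), names(best))
    best[hit] <- pmax(best[hit], agg[hit])
  }
  best
}

#' Greedy non-redundant window selection
#'
#' Repeatedly takes the highest-TNS remaining window above `min_tns` (ties
#' broken toward the larger window, then the leftmost) and discards every
#' window sharing any member gene with it. The result is pairwise
#' gene-disjoint.
#'
#' @param windows window data frame with `tns` set (or a `scored_genome`).
#' @param min_tns strict lower bound on TNS for a window to be considered.
#' @return The selected subset of `windows`, in selection order.
#' @export
select_nonredundant <- function(windows, min_tns = 0.2) {
  if (inherits(windows, "scored_genome")) windows <- windows$neighborhoods
  cand <- windows[!is.na(windows$tns) & windows$tns > min_tns, , drop = FALSE]
  if (!nrow(cand)) return(cand[0L, , drop = FALSE])
  cand <- cand[order(-cand$tns, -cand$size, cand$chrom, cand$span_start,
                     cand$start_index), , drop = FALSE]
  mem <- strsplit(cand$members, ",", fixed = TRUE)
  picked <- integer(0)
  used <- character(0)
  for (r in seq_len(nrow(cand))) {
    if (!any(mem[[r]] %in% used)) {
      picked <- c(picked, r)
      used <- c(used, mem[[r]])
    }
  }
  out <- cand[picked, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the full neighborhood report
#'
#' One TSV row per scored window with its location, members and all scores,
#' sorted by chromosome, span start, then size. Byte output is deterministic
#' for fixed inputs and seed.
#'
#' @param scored a `scored_genome` from [finalize_scores()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(scored, path) {
  nb <- scored$neighborhoods
  nb <- nb[order(nb$chrom, nb$span_start, nb$size, nb$size_key), , drop = FALSE]
  out <- data.frame(
    chrom = nb$chrom,
    span_start = format(nb$span_start, scientific = FALSE, trim = TRUE),
    span_end = format(nb$span_end, scientific = FALSE, trim = TRUE),
    size_mode = nb$size_mode,
    size = nb$size,
    member_gene_ids = nb$members,
    anc = nb$anc, p_value = nb$p_value, ss = nb$ss, tns = nb$tns,
    stringsAsFactors = FALSE)
  if (!nrow(out)) {
    writeLines(paste(names(out), collapse = "\t"), path)
    return(invisible(path))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a UCSC bedGraph custom track of best TNS per gene
#'
#' One bedGraph line per gene (coordinates from the gene table, value = the
#' gene's best associated TNS) under a track header, ready to upload to the
#' UCSC Genome Browser.
#'
#' @param scored a `scored_genome`.
#' @param path output path.
#' @param name,description track header attributes.
#' @return `path`, invisibly.
#' @export
write_custom_track <- function(scored, path, name = "best_TNS",
                               description = "best total neighborhood score per gene") {
  g <- scored$genes
  header <- sprintf('track type=bedGraph name="%s" description="%s"',
                    name, description)
  body <- sprintf("%s\t%s\t%s\t%s",
                  g$chrom,
                  format(g$start, scientific = FALSE, trim = TRUE),
                  format(g$end, scientific = FALSE, trim = TRUE),
                  format(scored$best_tns[g$gene_id], trim = TRUE,
                         digits = 15, scientific = FALSE))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the TNS-by-window-size matrix
#'
#' Genes x window-size matrix of the best TNS per (gene, size) stratum, for
#' external heatmap rendering of how scores persist across window sizes.
#' Cells default to 0 for (gene, size) combinations with no passing window.
#'
#' @param scored a `scored_genome`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tns_matrix <- function(scored, path) {
  g <- scored$genes
  nb <- scored$neighborhoods
  keys <- unique(nb$size_key[order(nb$size_mode, nb$size)])
  if (!length(keys)) keys <- character(0)
  m <- matrix(0, nrow = nrow(g), ncol = length(keys),
              dimnames = list(g$gene_id, keys))
  if (nrow(nb)) {
    mem <- strsplit(nb$members, ",", fixed = TRUE)
    for (r in seq_len(nrow(nb))) {
      ids <- mem[[r]]
      m[ids, nb$size_key[r]] <- pmax(m[ids, nb$size_key[r]], nb$tns[r])
    }
  }
  out <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
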