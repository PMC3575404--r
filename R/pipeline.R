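# End-to-end wiring: preprocess -> correlation -> windows -> permutation
# null -> synteny -> TNS, plus a file-in/file-out runner that also writes a
# run manifest (all parameters, input digests, seed, version) sufficient to
# reproduce a run.

#' Score every candidate gene neighborhood of a genome
#'
#' Runs the full in-memory pipeline: overlap filtering, silent-gene
#' flagging, per-chromosome Spearman correlations, window enumeration over
#' the requested size range(s), incremental ANC, empirical p-values from the
#' position-preserving permutation null, synteny scores, and the TNS gate.
#'
#' @param genes a [gene_table()] of gene locations.
#' @param expr an [expression_matrix()] covering the genes.
#' @param block_sets list of [synteny_blocks()], one per comparison species;
#'   required unless `no_synteny = TRUE`.
#' @param min_genes,max_genes gene-count window size range.
#' @param bp_sizes optional ascending vector of base-pair window budgets to
#'   score in addition to the gene-count windows.
#' @param policy optional [silent_policy()]; `NULL` flags nothing silent.
#' @param n_shuffles randomized transcriptomes for the null (default 10).
#' @param seed integer seed driving all randomization.
#' @param alpha TNS significance gate (inclusive), default 0.05.
#' @param pseudo_count see [empirical_pvalues()].
#' @param no_synteny expression-only mode: sets SS = 1 for every window
#'   instead of requiring block sets. An extension for users without
#'   conservation data; the TNS then reduces to the gated ANC.
#' @return A `scored_genome` (see [finalize_scores()]).
#' @export
score_genome <- function(genes, expr, block_sets = NULL,
                         min_genes = 2L, max_genes = 5L, bp_sizes = NULL,
                         policy = NULL, n_shuffles = 10L, seed = 1L,
                         alpha = 0.05, pseudo_count = FALSE,
                         no_synteny = FALSE) {
  if (!no_synteny && !length(block_sets)) {
    stop("no synteny block sets given; supply block_sets or set no_synteny = TRUE")
  }
  genes <- remove_overlapping_transcripts(genes, expr)
  silent <- if (is.null(policy)) character() else flag_silent_genes(expr, policy)
  corr <- pairwise_spearman(expr, silent, "per_chromosome", genes)
  w <- enumerate_gene_windows(genes, min_genes, max_genes)
  if (!is.null(bp_sizes)) {
    w <- rbind(w, enumerate_bp_windows(genes, bp_sizes))
  }
  w <- compute_all_ancs(w, corr)
  w <- empirical_pvalues(w, expr, genes, silent,
                         n_shuffles = n_shuffles, seed = seed,
                         pseudo_count = pseudo_count)
  w <- if (no_synteny) {
    w$ss <- rep(1, nrow(w))
    w
  } else {
    add_synteny_scores(w, block_sets)
  }
  finalize_scores(w, genes, alpha)
}

#' File-level pipeline run
#'
#' Reads the inputs, calls [score_genome()], and writes the neighborhood
#' report (`report.tsv`), the best-TNS bedGraph custom track
#' (`best_tns.bedGraph`), the TNS-by-window-size matrix (`tns_matrix.tsv`)
#' and a run manifest (`manifest.json`) into `out_dir`. Repeating a run with
#' the same inputs and seed reproduces the outputs byte for byte.
#'
#' @param genes_path gene-location file (BED6 or GFF3).
#' @param expr_path expression TSV (gene ids + one column per sample).
#' @param out_dir output directory (created if needed).
#' @param detection_path optional detection-call TSV.
#' @param blocks_dir optional directory of per-species block TSVs (every
#'   `*.tsv` file is one species).
#' @param format gene-location format, `"bed"` or `"gff3"`.
#' @param silent_min_present,silent_max_expr silent-gene thresholds: if a
#'   detection file is given the detection-call policy applies with
#'   `silent_min_present`; otherwise the expression-threshold policy applies
#'   with `silent_max_expr`. Set both to `NULL` to flag nothing.
#' @inheritParams score_genome
#' @return The `scored_genome`, invisibly.
#' @export
run_score <- function(genes_path, expr_path, out_dir,
                      detection_path = NULL, blocks_dir = NULL,
                      format = c("bed", "gff3"),
                      min_genes = 2L, max_genes = 5L, bp_sizes = NULL,
                      silent_min_present = 12L, silent_max_expr = 0.2,
                      n_shuffles = 10L, seed = 1L, alpha = 0.05,
                      pseudo_count = FALSE, no_synteny = FALSE) {
  format <- match.arg(format)
  genes <- read_gene_locations(genes_path, format)
  expr <- read_expression_table(expr_path, detection_path)

  policy <- if (!is.null(detection_path) && !is.null(silent_min_present)) {
    silent_policy("detection_calls", min_present_calls = silent_min_present)
  } else if (!is.null(silent_max_expr)) {
    silent_policy("expression_threshold", min_max_expression = silent_max_expr)
  } else {
    NULL
  }

  block_sets <- NULL
  block_paths <- character(0)
  if (!no_synteny) {
    if (is.null(blocks_dir)) {
      stop("blocks_dir is required unless no_synteny = TRUE (expression-only mode)")
    }
    block_paths <- sort(list.files(blocks_dir, pattern = "\\.tsv$",
                                   full.names = TRUE))
    if (!length(block_paths)) stop("no *.tsv block files found in ", blocks_dir)
    block_sets <- lapply(block_paths, read_synteny_blocks)
  }

  scored <- score_genome(genes, expr, block_sets,
                         min_genes = min_genes, max_genes = max_genes,
                         bp_sizes = bp_sizes, policy = policy,
                         n_shuffles = n_shuffles, seed = seed,
                         alpha = alpha, pseudo_count = pseudo_count,
                         no_synteny = no_synteny)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_report(scored, file.path(out_dir, "report.tsv"))
  write_custom_track(scored, file.path(out_dir, "best_tns.bedGraph"))
  write_tns_matrix(scored, file.path(out_dir, "tns_matrix.tsv"))

  manifest <- list(
    tool = "genehoods",
    version = as.character(utils::packageVersion("genehoods")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    parameters = list(
      format = format, min_genes = min_genes, max_genes = max_genes,
      bp_sizes = bp_sizes, silent_min_present = silent_min_present,
      silent_max_expr = silent_max_expr, n_shuffles = n_shuffles,
      alpha = alpha, pseudo_count = pseudo_count, no_synteny = no_synteny),
    input_md5 = as.list(tools::md5sum(c(
      genes_path, expr_path,
      if (!is.null(detection_path)) detection_path, block_paths)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(scored)
}
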