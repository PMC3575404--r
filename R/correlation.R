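# Pairwise Spearman correlation of expression profiles, with silent genes
# zeroed. Ties get average (fractional) ranks; a constant profile carries no
# rank information and is given correlation 0 with every partner, matching
# the silent-gene convention.

#' Spearman rank correlation of two profiles
#'
#' Average ranks are used for ties. If either vector is constant the rank
#' correlation is undefined and 0 is returned: a flat profile carries no
#' co-expression evidence.
#'
#' @param x,y numeric vectors of equal length (N >= 2).
#' @return Spearman's rho in \[-1, 1\].
#' @examples
#' spearman_rho(c(1, 2, 3), c(10, 20, 30))  # 1
#' spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3))  # 0.6
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y, method = "spearman")
}

# Spearman matrix of the rows of `values`: rank each row (average ranks),
# then Pearson across rank vectors. Constant rows come back NA from cor()
# and are zeroed, including their diagonal.
spearman_matrix <- function(values) {
  if (nrow(values) == 1L) {
    constant <- stats::sd(values[1L, ]) == 0
    m <- matrix(if (constant) 0 else 1, 1L, 1L)
    dimnames(m) <- list(rownames(values), rownames(values))
    return(m)
  }
  ranked <- t(apply(values, 1L, rank))
  m <- suppressWarnings(stats::cor(t(ranked)))
  m[!is.finite(m)] <- 0
  constant <- apply(values, 1L, stats::sd) == 0
  m[constant, ] <- 0    # incl. the diagonal, which cor() reports as 1
  m[, constant] <- 0
  dimnames(m) <- list(rownames(values), rownames(values))
  m
}

#' Pairwise Spearman correlation matrix with silent genes zeroed
#'
#' Computes rho for every gene pair within the requested scope and sets every
#' entry touching a silent gene (rows, columns and diagonal) to exactly 0.
#' The default per-chromosome scope stores one matrix per chromosome: windows
#' never span chromosomes, so between-chromosome correlations are never
#' consumed and skipping them cuts the work roughly by the square of the
#' chromosome count. A genome-wide scope is available for diagnostics.
#'
#' @param expr an [expression_matrix()].
#' @param silent character vector of silent gene ids (see
#'   [flag_silent_genes()]).
#' @param scope `"per_chromosome"` (default) or `"genome_wide"`.
#' @param genes a [gene_table()]; required for per-chromosome scope, where it
#'   defines both the chromosome grouping and the genome order of genes.
#' @return An object of class `corr_matrix`: per chromosome, the ordered gene
#'   ids and the symmetric rho matrix.
#' @export
pairwise_spearman <- function(expr, silent = character(),
                              scope = c("per_chromosome", "genome_wide"),
                              genes = NULL) {
  scope <- match.arg(scope)
  v <- expr$values
  if (scope == "genome_wide") {
    groups <- list(.all = rownames(v))
  } else {
    if (is.null(genes)) {
      stop("per-chromosome scope requires the gene table")
    }
    missing <- setdiff(genes$gene_id, rownames(v))
    if (length(missing)) {
      stop("gene(s) without an expression row: ",
           paste(head(missing, 5L), collapse = ", "))
    }
    groups <- split(genes$gene_id, genes$chrom)
  }
  mats <- lapply(groups, function(ids) {
    m <- spearman_matrix(v[ids, , drop = FALSE])
    sil <- ids %in% silent
    if (any(sil)) {
      m[sil, ] <- 0
      m[, sil] <- 0
    }
    m
  })
  structure(list(scope = scope, gene_ids = groups, rho = mats,
                 silent = intersect(rownames(v), silent)),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("corr_matrix (%s): %d gene(s) over %d group(s), %d silent\n",
              x$scope, sum(lengths(x$gene_ids)), length(x$gene_ids),
              length(x$silent)))
  invisible(x)
}

# rho matrix for one chromosome (or the single genome-wide matrix)
corr_rho <- function(corr, chrom) {
  if (corr$scope == "genome_wide") return(corr$rho[[".all"]])
  m <- corr$rho[[chrom]]
  if (is.null(m)) stop("chromosome absent from correlation matrix: ", chrom)
  m
}

#' Export a correlation matrix as TSV (for inspection)
#'
#' @param corr a `corr_matrix`.
#' @param path output path; one block per chromosome group, genes as both
#'   header and first column.
#' @return `path`, invisibly.
#' @export
write_correlation_matrix <- function(corr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (grp in names(corr$rho)) {
    m <- corr$rho[[grp]]
    cat(sprintf("# group\t%s\n", grp), file = con)
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
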