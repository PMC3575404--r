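# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately avoid the package's own code paths: Spearman via
# explicit ranks + the Pearson sum formula, windows via direct enumeration
# of all consecutive runs, ANC via plain means over an oracle matrix.

oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) return(0)
  sum(dx * dy) / den
}

oracle_spearman_matrix <- function(values) {
  n <- nrow(values)
  m <- diag(n)
  for (i in seq_len(n)) {
    if (sd(values[i, ]) == 0) m[i, i] <- 0
    for (j in seq_len(n)) {
      if (j > i) m[i, j] <- m[j, i] <- oracle_spearman(values[i, ], values[j, ])
    }
  }
  dimnames(m) <- list(rownames(values), rownames(values))
  m
}

# all consecutive runs of W genes, W in sizes, per chromosome
oracle_gene_windows <- function(genes, min_size, max_size) {
  out <- character(0)
  for (ch in unique(genes$chrom)) {
    ids <- genes$gene_id[genes$chrom == ch]
    n <- length(ids)
    for (W in min_size:max_size) {
      if (W > n) next
      for (i in seq_len(n - W + 1)) {
        out <- c(out, paste(ids[i:(i + W - 1)], collapse = ","))
      }
    }
  }
  out
}

# mean pairwise value over an (oracle) correlation matrix
oracle_anc <- function(members, m) {
  idx <- match(members, rownames(m))
  sub <- m[idx, idx, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

# a gene table of n evenly spaced genes on one chromosome
simple_genes <- function(n, chrom = "chr1", pitch = 10000, width = 2000,
                         strand = rep("+", n), prefix = "g") {
  starts <- (seq_len(n) - 1) * pitch
  gene_table(sprintf("%s%03d", prefix, seq_len(n)), chrom,
             starts, starts + width, strand)
}

# an expression matrix with given rows (list of numeric vectors) and ids
simple_expr <- function(rows, ids = sprintf("g%03d", seq_along(rows)),
                        detection = NULL) {
  v <- do.call(rbind, rows)
  rownames(v) <- ids
  colnames(v) <- sprintf("s%02d", seq_len(ncol(v)))
  if (!is.null(detection)) {
    detection <- matrix(detection, nrow = nrow(v), ncol = ncol(v),
                        dimnames = dimnames(v))
  }
  expression_matrix(v, detection)
}

# a one-species block set from (chrom, start, end) triplets
simple_blocks <- function(..., species = "sp") {
  iv <- list(...)
  df <- data.frame(
    ref_chrom = vapply(iv, function(b) as.character(b[[1]]), ""),
    ref_start = vapply(iv, function(b) as.numeric(b[[2]]), 0),
    ref_end = vapply(iv, function(b) as.numeric(b[[3]]), 0),
    stringsAsFactors = FALSE)
  df$tgt_chrom <- "t1"
  df$tgt_start <- df$ref_start + 1e6
  df$tgt_end <- df$ref_end + 1e6
  df$orientation <- "+"
  synteny_blocks(species, df)
}
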