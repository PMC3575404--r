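# Truth-labelled synthetic data: complete input bundles (locations,
# expression, detection calls, per-species block tables, BLAST hits) with a
# machine-readable truth table, so the whole pipeline is testable without
# any download. Co-expression uses a latent-factor model: members of a
# planted cluster share a latent profile plus independent noise, with the
# factor loading calibrated so the expected pairwise Spearman correlation
# hits the requested target. Expression is emitted on a linear non-negative
# scale so Tau and silence thresholds apply directly.

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate a small tissue-atlas-shaped study: a few chromosomes of
#' evenly spaced genes, 20 samples, one planted 3-gene co-expression cluster
#' with target pairwise Spearman 0.9 that is conserved in every comparison
#' species, 9 comparison species, and a 10% silent fraction.
#'
#' @param n_chromosomes number of chromosomes.
#' @param genes_per_chrom genes per chromosome (evenly spaced, 2 kb genes on
#'   a 5 kb pitch, alternating-free random strands).
#' @param n_samples number of expression samples (N).
#' @param planted_clusters list of clusters, each a list with `chrom`
#'   (integer index), `start_index`, `size` (genes), `rho` (target pairwise
#'   Spearman in \[0, 1)), and optional `conserved_species` (how many of the
#'   comparison species conserve the cluster span; defaults to all).
#' @param silent_fraction fraction of background genes rendered silent
#'   (sub-threshold values, all-"A" detection calls).
#' @param n_species number of comparison species block sets to emit.
#' @param background_conserved_fraction probability that a background
#'   (non-cluster) chromosome segment is covered by a block, per species.
#' @param noise_sd within-cluster noise multiplier; 1 leaves the Spearman
#'   target calibrated, larger values degrade it.
#' @param n_duplicate_pairs number of adjacent background gene pairs planted
#'   as BLAST duplicates.
#' @param seed integer seed; the full bundle is deterministic given the seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 3L, genes_per_chrom = 30L,
                       n_samples = 20L,
                       planted_clusters = list(
                         list(chrom = 1L, start_index = 5L, size = 3L,
                              rho = 0.9)),
                       silent_fraction = 0.1, n_species = 9L,
                       background_conserved_fraction = 0.7,
                       noise_sd = 1, n_duplicate_pairs = 1L, seed = 1L) {
  if (n_chromosomes < 1L || genes_per_chrom < 2L) {
    stop("need at least 1 chromosome with at least 2 genes")
  }
  if (n_samples < 2L) stop("need at least 2 samples")
  if (silent_fraction < 0 || silent_fraction > 1 ||
      background_conserved_fraction < 0 || background_conserved_fraction > 1) {
    stop("fractions must lie in [0, 1]")
  }
  if (n_species < 1L) stop("need at least 1 comparison species")
  planted_clusters <- lapply(planted_clusters, function(cl) {
    if (is.null(cl$conserved_species)) cl$conserved_species <- n_species
    if (cl$conserved_species < 0L || cl$conserved_species > n_species) {
      stop("conserved_species must lie in [0, n_species]")
    }
    if (cl$rho < 0 || cl$rho >= 1) stop("cluster rho must lie in [0, 1)")
    if (cl$size < 2L) stop("a planted cluster needs at least 2 genes")
    if (cl$chrom < 1L || cl$chrom > n_chromosomes ||
        cl$start_index < 1L ||
        cl$start_index + cl$size - 1L > genes_per_chrom) {
      stop("planted cluster does not fit within its chromosome")
    }
    cl
  })
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 genes_per_chrom = as.integer(genes_per_chrom),
                 n_samples = as.integer(n_samples),
                 planted_clusters = planted_clusters,
                 silent_fraction = silent_fraction,
                 n_species = as.integer(n_species),
                 background_conserved_fraction = background_conserved_fraction,
                 noise_sd = noise_sd,
                 n_duplicate_pairs = as.integer(n_duplicate_pairs),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Spearman target -> Pearson factor loading for bivariate-normal latents
# (the classical rho_S = (6/pi) asin(r/2) relation, inverted)
spearman_to_pearson <- function(s) 2 * sin(pi * s / 6)

GENE_WIDTH <- 2000
GENE_PITCH <- 5000

#' Generate a complete synthetic input bundle
#'
#' Places genes at non-overlapping intervals in genome order, simulates
#' expression (background genes: independent noise; planted cluster members:
#' shared latent profile plus noise calibrated to the target Spearman
#' correlation; silent genes: sub-threshold values with "A" calls), and
#' builds per-species block tables that contain each planted cluster's span
#' in exactly its `conserved_species` species (the others split the region at
#' the cluster midpoint so the span crosses a block boundary). Background
#' segments are covered with probability `background_conserved_fraction`.
#' Adjacent background gene pairs are planted as BLAST duplicates. The same
#' seed always reproduces the same bundle byte for byte.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory for the bundle files (block tables land
#'   in a `blocks/` subdirectory, one TSV per species, ready for
#'   [run_score()]'s `blocks_dir`); `NULL` keeps everything in memory and
#'   writes nothing.
#' @return Invisibly, a list with `genes` ([gene_table()]), `expr`
#'   ([expression_matrix()]), `block_sets` (list of [synteny_blocks()]),
#'   `blast_hits`, `truth` (cluster memberships, per-species conservation
#'   flags, silent ids, duplicate pairs) and, when `out_dir` is given,
#'   `paths` to the emitted files.
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_chr <- config$n_chromosomes
  npc <- config$genes_per_chrom
  N <- config$n_samples

  chroms <- sprintf("chr%d", seq_len(n_chr))
  gene_df <- do.call(rbind, lapply(seq_len(n_chr), function(c_i) {
    starts <- (seq_len(npc) - 1L) * GENE_PITCH
    data.frame(gene_id = sprintf("%s_g%03d", chroms[c_i], seq_len(npc)),
               chrom = chroms[c_i],
               start = starts, end = starts + GENE_WIDTH,
               strand = sample(c("+", "-"), npc, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  genes <- gene_table(gene_df$gene_id, gene_df$chrom, gene_df$start,
                      gene_df$end, gene_df$strand)

  # cluster bookkeeping (member ids + reference spans, padded for blocks)
  clusters <- lapply(config$planted_clusters, function(cl) {
    ch <- chroms[cl$chrom]
    idx <- cl$start_index:(cl$start_index + cl$size - 1L)
    ids <- sprintf("%s_g%03d", ch, idx)
    span_start <- (min(idx) - 1L) * GENE_PITCH
    span_end <- (max(idx) - 1L) * GENE_PITCH + GENE_WIDTH
    list(chrom = ch, member_ids = ids, start_index = cl$start_index,
         size = cl$size, rho = cl$rho,
         conserved_species = cl$conserved_species,
         span_start = span_start, span_end = span_end)
  })
  cluster_ids <- unlist(lapply(clusters, `[[`, "member_ids"))
  if (anyDuplicated(cluster_ids)) stop("planted clusters overlap")

  # expression: latent-factor clusters over iid normal background, then an
  # increasing map onto a positive linear scale (Spearman-invariant)
  raw <- matrix(stats::rnorm(nrow(genes) * N), nrow = nrow(genes),
                dimnames = list(genes$gene_id,
                                sprintf("s%02d", seq_len(N))))
  for (cl in clusters) {
    a <- spearman_to_pearson(cl$rho)
    z <- stats::rnorm(N)
    noise <- matrix(stats::rnorm(cl$size * N, sd = config$noise_sd),
                    nrow = cl$size)
    raw[cl$member_ids, ] <- sqrt(a) * rep(z, each = cl$size) +
      sqrt(1 - a) * noise
  }
  values <- 2^(3 + 1.5 * raw)

  background_ids <- setdiff(genes$gene_id, cluster_ids)
  n_silent <- round(config$silent_fraction * length(background_ids))
  silent_ids <- sort(sample(background_ids, n_silent))
  if (n_silent > 0L) {
    values[silent_ids, ] <- matrix(stats::runif(n_silent * N, 0.001, 0.15),
                                   nrow = n_silent)
  }
  detection <- matrix("P", nrow = nrow(values), ncol = N,
                      dimnames = dimnames(values))
  detection[silent_ids, ] <- "A"
  expr <- expression_matrix(values, detection)

  # per-species blocks: padded cluster blocks (whole or split), then
  # background complement segments with the configured coverage probability
  chrom_len <- npc * GENE_PITCH
  pad <- 1500  # < inter-gene gap, so padding never reaches a neighbor gene
  block_sets <- lapply(seq_len(config$n_species), function(sp) {
    dfs <- list()
    for (ch_i in seq_len(n_chr)) {
      ch <- chroms[ch_i]
      ivs <- list()     # block intervals on this chromosome
      cluster_iv <- NULL  # padded cluster footprints (for the complement)
      for (cl in Filter(function(cl) cl$chrom == ch, clusters)) {
        s <- max(0, cl$span_start - pad)
        e <- min(chrom_len, cl$span_end + pad)
        if (sp <= cl$conserved_species) {
          ivs[[length(ivs) + 1L]] <- c(s, e)
        } else {
          # breakpoint strictly inside the span: neither half contains it
          mid <- floor((cl$span_start + cl$span_end) / 2)
          ivs[[length(ivs) + 1L]] <- c(s, mid)
          ivs[[length(ivs) + 1L]] <- c(mid + 100, e)
        }
        cluster_iv <- rbind(cluster_iv, c(s, e))
      }
      # background: complement of the padded cluster footprints
      pos <- 0
      segs <- list()
      if (!is.null(cluster_iv)) {
        cluster_iv <- cluster_iv[order(cluster_iv[, 1L]), , drop = FALSE]
        for (r in seq_len(nrow(cluster_iv))) {
          if (cluster_iv[r, 1L] - pos >= 1000) {
            segs[[length(segs) + 1L]] <- c(pos, cluster_iv[r, 1L] - 100)
          }
          pos <- cluster_iv[r, 2L] + 100
        }
      }
      if (chrom_len - pos >= 1000) {
        segs[[length(segs) + 1L]] <- c(pos, chrom_len)
      }
      for (seg in segs) {
        if (stats::runif(1) < config$background_conserved_fraction) {
          ivs[[length(ivs) + 1L]] <- seg
        }
      }
      if (length(ivs)) {
        m <- do.call(rbind, ivs)
        dfs[[length(dfs) + 1L]] <- data.frame(
          ref_chrom = ch, ref_start = m[, 1L], ref_end = m[, 2L],
          stringsAsFactors = FALSE)
      }
    }
    df <- if (length(dfs)) do.call(rbind, dfs) else {
      data.frame(ref_chrom = character(), ref_start = numeric(),
                 ref_end = numeric(), stringsAsFactors = FALSE)
    }
    df$tgt_chrom <- paste0("syn_", df$ref_chrom)
    df$tgt_start <- df$ref_start + 5e6
    df$tgt_end <- df$ref_end + 5e6
    df$orientation <- rep("+", nrow(df))
    synteny_blocks(sprintf("species%02d", sp), df)
  })

  # planted duplicate pairs: adjacent, non-silent, non-cluster genes
  eligible <- setdiff(background_ids, silent_ids)
  dup_pairs <- list()
  used <- character(0)
  for (ch in chroms) {
    sub <- genes$gene_id[genes$chrom == ch]
    for (i in seq_len(length(sub) - 1L)) {
      if (length(dup_pairs) >= config$n_duplicate_pairs) break
      a <- sub[i]; b <- sub[i + 1L]
      if (a %in% eligible && b %in% eligible &&
          !(a %in% used) && !(b %in% used)) {
        dup_pairs[[length(dup_pairs) + 1L]] <- c(a, b)
        used <- c(used, a, b)
      }
    }
  }
  blast_hits <- do.call(rbind, c(
    lapply(dup_pairs, function(pr) {
      data.frame(query = pr[1L], subject = pr[2L], evalue = 1e-30,
                 stringsAsFactors = FALSE)
    }),
    list(data.frame(query = genes$gene_id[1L], subject = genes$gene_id[1L],
                    evalue = 0, stringsAsFactors = FALSE))  # self-hit decoy
  ))

  truth <- list(
    clusters = lapply(clusters, function(cl) {
      cl[c("chrom", "member_ids", "size", "rho", "conserved_species",
           "span_start", "span_end")]
    }),
    silent_ids = silent_ids,
    duplicate_pairs = dup_pairs,
    seed = config$seed
  )

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "blocks"), showWarnings = FALSE,
               recursive = TRUE)
    paths <- list(
      genes = file.path(out_dir, "genes.bed"),
      expression = file.path(out_dir, "expression.tsv"),
      detection = file.path(out_dir, "detection.tsv"),
      blocks = vapply(block_sets, function(bs) {
        file.path(out_dir, "blocks", sprintf("%s.tsv", bs$species))
      }, character(1)),
      blocks_dir = file.path(out_dir, "blocks"),
      blast = file.path(out_dir, "blast.tsv"),
      truth = file.path(out_dir, "truth.json"))
    write_gene_locations(genes, paths$genes)
    write_matrix_tsv(values, paths$expression)
    write_matrix_tsv(detection, paths$detection)
    for (k in seq_along(block_sets)) {
      write_synteny_blocks(block_sets[[k]], paths$blocks[k])
    }
    write_blast_tab(blast_hits, paths$blast)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }

  invisible(list(genes = genes, expr = expr, block_sets = block_sets,
                 blast_hits = blast_hits, truth = truth, paths = paths,
                 config = config))
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_blast_tab <- function(hits, path) {
  out <- data.frame(hits$query, hits$subject, 97.5, 450, 10, 2,
                    1, 450, 1, 450,
                    format(hits$evalue, scientific = TRUE, trim = TRUE), 800)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Recovery metrics of planted structure
#'
#' For each planted cluster, reports whether some window above `min_tns` on
#' the cluster's chromosome shares at least half of the cluster's members;
#' also counts windows above `min_tns` with no planted-cluster overlap at all
#' (false positives on background).
#'
#' @param truth the `truth` element of a [generate_dataset()] result.
#' @param scored a `scored_genome` from [finalize_scores()] /
#'   [score_genome()].
#' @param min_tns strict TNS threshold for a window to count.
#' @return List with `clusters` (data frame: `chrom`, `size`, `recovered`),
#'   `n_false_positive` and `n_windows_above`.
#' @export
recovery_report <- function(truth, scored, min_tns = 0.2) {
  nb <- scored$neighborhoods
  hits <- nb[!is.na(nb$tns) & nb$tns > min_tns, , drop = FALSE]
  mem <- strsplit(hits$members, ",", fixed = TRUE)
  cluster_overlap <- rep(FALSE, nrow(hits))
  cl_rows <- lapply(truth$clusters, function(cl) {
    ids <- unlist(cl$member_ids)
    frac <- vapply(seq_along(mem), function(r) {
      if (hits$chrom[r] != cl$chrom) return(0)
      length(intersect(mem[[r]], ids)) / length(ids)
    }, numeric(1))
    cluster_overlap <<- cluster_overlap | frac > 0
    data.frame(chrom = cl$chrom, size = length(ids),
               recovered = any(frac >= 0.5), stringsAsFactors = FALSE)
  })
  list(clusters = do.call(rbind, cl_rows),
       n_false_positive = sum(!cluster_overlap),
       n_windows_above = nrow(hits))
}
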