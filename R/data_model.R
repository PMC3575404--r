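#' @importFrom utils read.delim write.table head tail
#' @importFrom stats setNames
NULL

# ---- gene tables -----------------------------------------------------------

validate_gene_table <- function(df) {
  req <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("gene table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("gene table has no records")
  if (anyNA(df$start) || anyNA(df$end)) {
    stop("gene coordinates must be numeric and complete")
  }
  if (any(df$start >= df$end)) {
    bad <- df$gene_id[df$start >= df$end][1L]
    stop("gene '", bad, "' has start >= end (coordinates are 0-based half-open)")
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup)) {
    stop("duplicate gene_id(s): ", paste(unique(dup), collapse = ", "))
  }
  invisible(df)
}

new_gene_table <- function(df) {
  df <- df[order(df$chrom, df$start, df$end, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Construct a table of gene locations
#'
#' The central location container: one row per gene/transcript with 0-based
#' half-open coordinates (BED convention). Rows are kept sorted in genome
#' order (chromosome, then start), which the window enumeration relies on.
#' Chromosome names are compared verbatim throughout the package; no "chr"
#' aliasing is applied, so location and synteny-block files must agree.
#'
#' @param gene_id character vector of unique gene/transcript identifiers.
#' @param chrom chromosome name per gene.
#' @param start,end 0-based half-open coordinates (`start < end`).
#' @param strand `"+"` or `"-"` per gene.
#' @return A `gene_table` (data frame with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `length`), sorted in genome order.
#' @examples
#' gene_table(c("a", "b"), "chr1", c(0, 5000), c(2000, 7000), c("+", "-"))
#' @export
gene_table <- function(gene_id, chrom, start, end, strand) {
  df <- data.frame(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  df$length <- df$end - df$start
  validate_gene_table(df)
  new_gene_table(df)
}

#' Read gene locations from BED6 or GFF3
#'
#' BED6 input is used as-is (already 0-based half-open); GFF3 coordinates are
#' 1-based inclusive and converted on read by shifting starts down by one.
#' For GFF3, records of type `gene` are used when present (otherwise all
#' records), and the identifier is taken from the `ID`, `Name` or `gene_id`
#' attribute, in that order.
#'
#' @param path input file path.
#' @param format `"bed"` or `"gff3"`.
#' @return A [gene_table()] sorted in genome order.
#' @export
read_gene_locations <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "bed") {
    read_bed6(path)
  } else {
    read_gff3_genes(path)
  }
}

read_bed6 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  if (!any(keep)) stop("no records in ", path)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop(sprintf("malformed BED line %d in %s: expected at least 6 tab-separated fields, got %d",
                 lineno[nf < 6L][1L], path, nf[nf < 6L][1L]))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  start <- suppressWarnings(as.numeric(col(2)))
  end <- suppressWarnings(as.numeric(col(3)))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("malformed BED line %d in %s: non-numeric coordinate",
                 lineno[is.na(start) | is.na(end)][1L], path))
  }
  gene_table(col(4), col(1), start, end, col(6))
}

read_gff3_genes <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("failed to parse GFF3 file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(gr) == 0L) stop("no records in ", path)
  md <- GenomicRanges::mcols(gr)
  if ("type" %in% names(md) && any(md$type == "gene")) {
    gr <- gr[md$type == "gene"]
    md <- GenomicRanges::mcols(gr)
  }
  ids <- NULL
  for (field in c("ID", "Name", "gene_id")) {
    if (field %in% names(md) && !anyNA(md[[field]])) {
      ids <- as.character(md[[field]])
      break
    }
  }
  if (is.null(ids)) stop("GFF3 records carry no usable ID/Name/gene_id attribute")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop("GFF3 gene records must be stranded (+ or -)")
  gene_table(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,  # 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = strand
  )
}

#' Write gene locations as BED6
#'
#' Coordinates are written unchanged (the internal convention is already the
#' BED one). Reading the file back with [read_gene_locations()] reproduces
#' the table exactly.
#'
#' @param genes a [gene_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_locations <- function(genes, path) {
  out <- data.frame(
    genes$chrom,
    format(genes$start, scientific = FALSE, trim = TRUE),
    format(genes$end, scientific = FALSE, trim = TRUE),
    genes$gene_id,
    0L,
    genes$strand
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- expression matrices ---------------------------------------------------

#' Construct an expression matrix object
#'
#' Genes x samples quantitative expression values with an optional matching
#' matrix of detection calls ("P"/"A"/"M"). Values must be complete: missing
#' entries are an error, not imputed, because every downstream statistic
#' (ranks, permutation null) assumes a full matrix.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids); at least 2 samples.
#' @param detection optional character matrix of `"P"`, `"A"`, `"M"` calls
#'   with identical dimnames.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, detection = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (ncol(values) < 2L) stop("need at least 2 samples")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("values must have unique gene ids as rownames")
  }
  if (is.null(colnames(values))) stop("values must have sample ids as colnames")
  if (!is.null(detection)) {
    if (!identical(dim(detection), dim(values)) ||
        !identical(rownames(detection), rownames(values)) ||
        !identical(colnames(detection), colnames(values))) {
      stop("detection matrix must align with the expression matrix by gene and sample id")
    }
    if (!all(detection %in% c("P", "A", "M"))) {
      stop("detection calls must be 'P', 'A' or 'M'")
    }
  }
  structure(list(values = values, detection = detection), class = "expr_matrix")
}

#' Number of samples in an expression matrix
#' @param expr an [expression_matrix()].
#' @return integer sample count N.
#' @export
n_samples <- function(expr) ncol(expr$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$detection)) "" else " (with detection calls)"))
  invisible(x)
}

#' Read an expression table (and optional detection calls)
#'
#' Tab-separated, header row of sample ids, first column gene ids. The
#' detection file, if supplied, must cover exactly the same genes and samples;
#' extra or missing genes, mismatched sample headers, non-numeric cells and
#' `NA` values are all errors.
#'
#' @param path expression TSV path.
#' @param detection_path optional detection-call TSV path (cells P/A/M).
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, detection_path = NULL) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3L) {
    stop("expression table needs a gene id column plus at least 2 sample columns")
  }
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in expression table")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression value in ", path)
  if (anyNA(vals)) stop("missing (NA) expression value in ", path,
                        "; the pipeline requires a complete matrix")
  rownames(vals) <- gene_ids

  det <- NULL
  if (!is.null(detection_path)) {
    dd <- read.delim(detection_path, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE, colClasses = "character")
    det_ids <- as.character(dd[[1L]])
    dmat <- as.matrix(dd[, -1L, drop = FALSE])
    rownames(dmat) <- det_ids
    if (!setequal(colnames(dmat), colnames(vals))) {
      stop("detection sample header does not match expression samples")
    }
    extra <- setdiff(det_ids, gene_ids)
    if (length(extra)) {
      stop("gene(s) present in detection but absent from expression: ",
           paste(head(extra, 5L), collapse = ", "))
    }
    missing <- setdiff(gene_ids, det_ids)
    if (length(missing)) {
      stop("gene(s) missing from the detection table: ",
           paste(head(missing, 5L), collapse = ", "))
    }
    det <- dmat[gene_ids, colnames(vals), drop = FALSE]
  }
  expression_matrix(vals, det)
}

# ---- syntenic block sets ---------------------------------------------------

block_columns <- c("ref_chrom", "ref_start", "ref_end",
                   "tgt_chrom", "tgt_start", "tgt_end", "orientation")

#' Construct a per-species set of syntenic blocks
#'
#' Each block records an interval of the reference genome that maps to an
#' unbroken segment of the comparison species' genome. Reference intervals on
#' the same chromosome must not overlap; a span is "conserved" in the species
#' when it is entirely contained in a single block's reference interval.
#'
#' @param species comparison species label.
#' @param blocks data frame with columns `ref_chrom`, `ref_start`, `ref_end`,
#'   `tgt_chrom`, `tgt_start`, `tgt_end`, `orientation` (`"+"`/`"-"`).
#'   May have zero rows (the species then conserves nothing).
#' @return An object of class `synteny_blocks`.
#' @export
synteny_blocks <- function(species, blocks) {
  miss <- setdiff(block_columns, names(blocks))
  if (length(miss)) {
    stop("block table missing column(s): ", paste(miss, collapse = ", "))
  }
  blocks <- blocks[, block_columns, drop = FALSE]
  if (nrow(blocks)) {
    if (any(blocks$ref_start >= blocks$ref_end)) {
      stop("block with ref_start >= ref_end in species '", species, "'")
    }
    if (!all(blocks$orientation %in% c("+", "-"))) {
      stop("block orientation must be '+' or '-'")
    }
    blocks <- blocks[order(blocks$ref_chrom, blocks$ref_start), , drop = FALSE]
    rownames(blocks) <- NULL
    for (ch in unique(blocks$ref_chrom)) {
      b <- blocks[blocks$ref_chrom == ch, , drop = FALSE]
      if (nrow(b) > 1L && any(b$ref_start[-1L] < b$ref_end[-nrow(b)])) {
        stop("overlapping reference intervals on ", ch,
             " in species '", species, "'")
      }
    }
  }
  structure(list(species = species, blocks = blocks), class = "synteny_blocks")
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat(sprintf("synteny_blocks: species '%s', %d block(s)\n",
              x$species, nrow(x$blocks)))
  invisible(x)
}

#' Read a per-species syntenic block table
#'
#' TSV with a header naming the seven block columns (see [synteny_blocks()]).
#' An empty file yields a valid empty block set: that species simply conserves
#' no neighborhood and contributes 0 to every synteny-score numerator.
#'
#' @param path block TSV path (one file per comparison species).
#' @param species species label; defaults to the file name without extension.
#' @return A [synteny_blocks()] object with blocks sorted by
#'   (`ref_chrom`, `ref_start`).
#' @export
read_synteny_blocks <- function(path,
                                species = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  empty <- as.data.frame(setNames(
    c(list(character()), list(numeric()), list(numeric()),
      list(character()), list(numeric()), list(numeric()), list(character())),
    block_columns))
  if (length(lines) <= 1L) {           # empty, or header only
    return(synteny_blocks(species, empty))
  }
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  miss <- setdiff(block_columns, names(df))
  if (length(miss)) {
    stop("block file ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  num <- c("ref_start", "ref_end", "tgt_start", "tgt_end")
  for (cc in num) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(df[[cc]])) stop("non-numeric ", cc, " in ", path)
  }
  synteny_blocks(species, df)
}

#' Write a syntenic block table
#'
#' Emits the same seven-column TSV format that [read_synteny_blocks()]
#' consumes, so built or filtered block sets round-trip exactly.
#'
#' @param blocks a [synteny_blocks()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_synteny_blocks <- function(blocks, path) {
  df <- blocks$blocks
  for (cc in c("ref_start", "ref_end", "tgt_start", "tgt_end")) {
    df[[cc]] <- format(df[[cc]], scientific = FALSE, trim = TRUE)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
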