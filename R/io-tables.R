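#' Read a gene annotation table with differential-expression statistics
#'
#' The gene table is the canonical annotation input: one row per gene with
#' its TSS coordinate and strand, optionally carrying differential-expression
#' statistics. `de_status` is (re)derived from `padj` and `log2fc`:
#' a gene is `up` when `padj < alpha` and `log2fc > 0`, `down` when
#' `padj < alpha` and `log2fc < 0` (strict inequalities, default
#' `alpha = 0.05`), `not_de` when tested but not significant, and
#' `untested` when `padj` or `log2fc` is missing.
#'
#' @param path TSV file with header; required columns `gene_id`, `chrom`,
#'   `strand`, `tss`; optional `symbol`, `log2fc`, `padj`.
#' @param alpha Adjusted-p significance threshold (strict `<`).
#' @return A tibble of gene records with a `de_status` factor-like column.
#' @export
read_gene_table <- function(path, alpha = 0.05) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("gene_id", "chrom", "strand", "tss")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(sprintf("gene table lacks required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "gretarget_schema_error")
  }
  for (nm in c("symbol", "log2fc", "padj")) {
    if (!nm %in% names(x)) x[[nm]] <- if (nm == "symbol") NA_character_ else NA_real_
  }
  x <- as_tibble(x)
  x$tss <- as.integer(x$tss)
  validate_gene_table(x)
  x$de_status <- de_status(x$log2fc, x$padj, alpha = alpha)
  select(x, "gene_id", "symbol", "chrom", "strand", "tss",
         "log2fc", "padj", "de_status")
}

validate_gene_table <- function(x) {
  if (anyDuplicated(x$gene_id)) {
    abort(sprintf("duplicate gene_id in gene table: %s",
                  x$gene_id[duplicated(x$gene_id)][1]),
          class = "gretarget_validation_error")
  }
  if (any(!x$strand %in% c("+", "-"))) {
    abort("gene strand must be '+' or '-'", class = "gretarget_validation_error")
  }
  if (any(is.na(x$tss)) || any(x$tss < 0)) {
    abort("gene tss must be a non-negative integer",
          class = "gretarget_validation_error")
  }
  if (any(!is.na(x$padj) & (x$padj < 0 | x$padj > 1))) {
    abort("padj must lie in [0, 1]", class = "gretarget_validation_error")
  }
  invisible(x)
}

#' Classify differential-expression status
#'
#' @param log2fc,padj Numeric vectors (may contain `NA`).
#' @param alpha Significance threshold on the adjusted p-value (strict `<`).
#' @return Character vector over `up`, `down`, `not_de`, `untested`.
#' @export
de_status <- function(log2fc, padj, alpha = 0.05) {
  out <- rep("untested", length(log2fc))
  tested <- !is.na(padj) & !is.na(log2fc)
  out[tested] <- "not_de"
  out[tested & padj < alpha & log2fc > 0] <- "up"
  out[tested & padj < alpha & log2fc < 0] <- "down"
  out
}

#' Write a gene table
#' @param x Gene tibble as returned by [read_gene_table()].
#' @param path Output TSV path.
#' @return `x`, invisibly.
#' @export
write_gene_table <- function(x, path) {
  readr::write_tsv(select(x, -dplyr::any_of("de_status")), path, progress = FALSE)
  invisible(x)
}

#' Read an enhancer-target association table
#'
#' Expected dialect: TSV with header columns `chrom`, `start`, `end`,
#' `target_gene`, `association_score` (a GeneHancer-style dump must be
#' converted to this schema upstream).
#'
#' @param path TSV path.
#' @return Tibble of enhancer links.
#' @export
read_enhancer_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("chrom", "start", "end", "target_gene", "association_score")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(sprintf("enhancer table lacks column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "gretarget_schema_error")
  }
  x <- as_tibble(x)
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  validate_intervals(x, what = "enhancer")
  if (any(x$association_score < 0)) {
    abort("association_score must be non-negative",
          class = "gretarget_validation_error")
  }
  select(x, "chrom", "start", "end", "target_gene", "association_score")
}

#' Read a chromatin class-weight table
#'
#' Maps open-chromatin class labels to non-negative scores (e.g. the binding
#' frequency of islet-specific factors per chromatin class).
#'
#' @param path TSV with header columns `chromatin_class`, `weight`.
#' @return Named numeric vector of weights.
#' @export
read_class_weights <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("chromatin_class", "weight") %in% names(x))) {
    abort("class-weight table needs columns chromatin_class, weight",
          class = "gretarget_schema_error")
  }
  w <- setNames(as.double(x$weight), x$chromatin_class)
  if (length(w) == 0 || any(w < 0) || any(is.na(w))) {
    abort("class weights must be non-negative and non-empty",
          class = "gretarget_validation_error")
  }
  w
}

#' Read/write an expression matrix stored as TSV
#'
#' First column holds gene identifiers; remaining columns are samples or
#' cells.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_matrix
#' @param m Numeric matrix with gene rownames.
#' @param id_col Name for the identifier column.
#' @export
write_expression_matrix <- function(m, path, id_col = "gene_id") {
  df <- as_tibble(m, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble(!!id_col := rownames(m)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(m)
}

#' Read and write FASTA sequence sets
#'
#' Thin tidy wrappers over Biostrings: sequences travel as a two-column
#' tibble (`seq_id`, `seq`).
#'
#' @param path FASTA path.
#' @return Tibble with columns `seq_id`, `seq`.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  tibble(seq_id = names(s), seq = as.character(s))
}

#' @rdname read_fasta
#' @param x Tibble with columns `seq_id`, `seq`.
#' @export
write_fasta <- function(x, path) {
  s <- Biostrings::DNAStringSet(setNames(x$seq, x$seq_id))
  Biostrings::writeXStringSet(s, path, width = 70L)
  invisible(x)
}
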