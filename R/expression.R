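#' Overlap and direction concordance of two DE gene sets
#'
#' Intersects two differential-expression calls by gene id and tallies how
#' many shared genes move in the same direction in both sets (concordant up
#' / concordant down) versus opposite directions (discordant).
#'
#' @param set_a,set_b Gene tibbles with `gene_id` and `de_status`; rows with
#'   `de_status` other than `up`/`down` are dropped before comparison.
#' @return A one-row tibble: `n_shared`, `n_concordant_up`,
#'   `n_concordant_down`, `n_discordant`, plus a list-column
#'   `shared_genes` with the shared ids.
#' @export
de_overlap <- function(set_a, set_b) {
  a <- filter(set_a, .data$de_status %in% c("up", "down"))
  b <- filter(set_b, .data$de_status %in% c("up", "down"))
  if (anyDuplicated(a$gene_id) || anyDuplicated(b$gene_id)) {
    abort("duplicate gene_id within a DE set", class = "gretarget_validation_error")
  }
  j <- inner_join(select(a, "gene_id", a_status = "de_status"),
                  select(b, "gene_id", b_status = "de_status"),
                  by = "gene_id")
  tibble(n_shared = nrow(j),
         n_concordant_up = sum(j$a_status == "up" & j$b_status == "up"),
         n_concordant_down = sum(j$a_status == "down" & j$b_status == "down"),
         n_discordant = sum(j$a_status != j$b_status),
         shared_genes = list(sort(j$gene_id)))
}

#' Expressed-gene filter for bulk count matrices
#'
#' Keeps genes whose normalized count exceeds `min_count` (strict `>`) in at
#' least `min_frac` of the samples (inclusive) of *every* group. The
#' fraction comparison is guarded against binary-float artifacts at exact
#' boundaries such as 4/5 vs 0.8.
#'
#' @param counts Numeric matrix, genes x samples, with rownames; or a tibble
#'   whose first column holds gene ids.
#' @param groups Named character vector mapping sample (column) name to
#'   group label; every sample must be assigned.
#' @param min_count Count threshold (default 3, strict `>`).
#' @param min_frac Per-group fraction threshold (default 0.8, inclusive).
#' @return Character vector of retained gene ids.
#' @export
expressed_gene_filter <- function(counts, groups, min_count = 3, min_frac = 0.8) {
  m <- as_gene_matrix(counts)
  missing <- setdiff(colnames(m), names(groups))
  if (length(missing) > 0) {
    abort(sprintf("sample(s) without group assignment: %s",
                  paste(missing, collapse = ", ")),
          class = "gretarget_validation_error")
  }
  groups <- groups[colnames(m)]
  pass <- rep(TRUE, nrow(m))
  for (g in unique(groups)) {
    cols <- which(groups == g)
    if (length(cols) == 0) {
      abort(sprintf("group '%s' has no samples", g),
            class = "gretarget_validation_error")
    }
    k <- rowSums(m[, cols, drop = FALSE] > min_count)
    pass <- pass & (k >= min_frac * length(cols) - 1e-9)
  }
  rownames(m)[pass]
}

#' Expressed-gene filter for single-cell RPKM matrices
#'
#' Keeps genes exceeding `min_rpkm` (strict `>`) in at least `min_cells`
#' cells.
#'
#' @param rpkm Numeric matrix, genes x cells, with rownames; or a tibble
#'   whose first column holds gene ids.
#' @param min_rpkm Expression threshold (default 1, strict `>`).
#' @param min_cells Minimum number of cells (default 1, inclusive).
#' @return Character vector of retained gene ids.
#' @export
sc_expressed_filter <- function(rpkm, min_rpkm = 1, min_cells = 1) {
  m <- as_gene_matrix(rpkm)
  rownames(m)[rowSums(m > min_rpkm) >= min_cells]
}

as_gene_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) {
      abort("expression matrix needs gene rownames",
            class = "gretarget_validation_error")
    }
    return(x)
  }
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  storage.mode(m) <- "double"
  m
}
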