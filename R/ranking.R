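#' Per-gene Open Chromatin Score
#'
#' Sums, over a gene's associated binding sites, the chromatin-class weight
#' contributed by overlap with accessible-chromatin regions. A site
#' overlapping several annotated regions contributes the maximum overlapped
#' class weight by default (`rule = "max"`, avoiding double counting of
#' stacked annotations); `rule = "sum"` adds every overlapped region's
#' weight. Sites with no overlap contribute 0.
#'
#' @param gres GRE tibble (one gene's sites or many genes'; scores are
#'   computed per gene).
#' @param oc_regions Open-chromatin tibble with `chromatin_class`.
#' @param weights Named weight vector from [read_class_weights()].
#' @param rule `"max"` (default) or `"sum"` per-site aggregation.
#' @return Tibble `gene_id`, `open_chromatin_score`.
#' @export
open_chromatin_score <- function(gres, oc_regions, weights, rule = c("max", "sum")) {
  rule <- match.arg(rule)
  validate_intervals(oc_regions, what = "open-chromatin")
  unknown <- setdiff(unique(oc_regions$chromatin_class), names(weights))
  if (length(unknown) > 0) {
    abort(sprintf("no weight configured for chromatin class(es): %s",
                  paste(unknown, collapse = ", ")),
          class = "gretarget_config_error")
  }
  if (nrow(gres) == 0) {
    return(tibble(gene_id = character(), open_chromatin_score = double()))
  }
  pairs <- overlap_pairs(gres, oc_regions)
  pairs$w <- unname(weights[oc_regions$chromatin_class[pairs$idx_b]])
  per_site <- pairs |>
    group_by(.data$idx_a) |>
    summarise(w = if (rule == "max") max(.data$w) else sum(.data$w),
              .groups = "drop")
  contrib <- rep(0, nrow(gres))
  contrib[per_site$idx_a] <- per_site$w
  tibble(gene_id = gres$gene_id, w = contrib) |>
    group_by(.data$gene_id) |>
    summarise(open_chromatin_score = sum(.data$w), .groups = "drop")
}

#' Per-gene Enhancer-Target Score
#'
#' Sums the enhancer-gene association score over every (site, enhancer)
#' overlap pair in which the enhancer is annotated to target that same
#' gene. Enhancers targeting other genes contribute nothing.
#'
#' @param gres GRE tibble.
#' @param links Enhancer-link tibble from [read_enhancer_table()].
#' @return Tibble `gene_id`, `enhancer_target_score`.
#' @export
enhancer_target_score <- function(gres, links) {
  if (nrow(gres) == 0) {
    return(tibble(gene_id = character(), enhancer_target_score = double()))
  }
  pairs <- overlap_pairs(gres, links)
  matched <- pairs[gres$gene_id[pairs$idx_a] == links$target_gene[pairs$idx_b], , drop = FALSE]
  score <- tibble(gene_id = gres$gene_id[matched$idx_a],
                  s = links$association_score[matched$idx_b]) |>
    group_by(.data$gene_id) |>
    summarise(enhancer_target_score = sum(.data$s), .groups = "drop")
  tibble(gene_id = unique(gres$gene_id)) |>
    left_join(score, by = "gene_id") |>
    mutate(enhancer_target_score = tidyr::replace_na(.data$enhancer_target_score, 0))
}

#' Per-gene motif number
#'
#' Counts retained primary-motif occurrences (p below the stringent
#' threshold) across a gene's associated sites. Hits are matched to sites
#' by peak name (`seq_id`), so a peak shared by two genes counts for both.
#'
#' @param gres GRE tibble (`name`, `gene_id`).
#' @param hits Motif-hit tibble from [scan_sequence()] already filtered to
#'   the retention threshold.
#' @return Tibble `gene_id`, `motif_count`.
#' @export
motif_number <- function(gres, hits) {
  per_peak <- hits |> group_by(.data$seq_id) |> summarise(k = n(), .groups = "drop")
  gres |>
    left_join(per_peak, by = c(name = "seq_id")) |>
    mutate(k = tidyr::replace_na(.data$k, 0L)) |>
    group_by(.data$gene_id) |>
    summarise(motif_count = as.integer(sum(.data$k)), .groups = "drop")
}

#' Min-max feature scaling
#'
#' `(value - min) / (max - min)`, elementwise; a constant vector scales to
#' all zeros.
#'
#' @param values Numeric vector (length >= 1).
#' @return Numeric vector in `[0, 1]`.
#' @export
feature_scale <- function(values) {
  if (length(values) == 0) {
    abort("feature_scale needs at least one value",
          class = "gretarget_validation_error")
  }
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(0, length(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Normalized Annotation Score
#'
#' Sum of the three min-max-scaled annotation features (open chromatin,
#' enhancer-target, motif number), in `[0, 3]`.
#'
#' @param norm_oc,norm_enh,norm_motif Scaled features in `[0, 1]`.
#' @return Numeric vector in `[0, 3]`.
#' @export
normalized_annotation_score <- function(norm_oc, norm_enh, norm_motif) {
  vals <- c(norm_oc, norm_enh, norm_motif)
  if (any(vals < 0 | vals > 1)) {
    abort("normalized features must lie in [0, 1]",
          class = "gretarget_validation_error")
  }
  norm_oc + norm_enh + norm_motif
}

#' Rank product of expression change and annotation score
#'
#' Ranks genes separately by Differential Expression Change (DEC) and by
#' Normalized Annotation Score, rank 1 for the largest value in each, ties
#' sharing the mean of their ranks, and returns
#' `(rank_DEC / n) * (rank_NAS / n)` with `n` the number of genes. Low rank
#' products indicate probable direct targets; the value can be read as a
#' p-value-like probability of the gene being directly targeted.
#'
#' @param dec,nas Aligned numeric vectors over the same genes.
#' @return Tibble `rank_dec`, `rank_nas`, `rank_product` (row order
#'   preserved).
#' @export
rank_product <- function(dec, nas) {
  if (length(dec) != length(nas)) {
    abort("dec and nas must have the same length",
          class = "gretarget_validation_error")
  }
  if (length(dec) == 0) {
    abort("rank_product needs at least one gene",
          class = "gretarget_validation_error")
  }
  n <- length(dec)
  rank_dec <- rank(-dec, ties.method = "average")
  rank_nas <- rank(-nas, ties.method = "average")
  tibble(rank_dec = rank_dec, rank_nas = rank_nas,
         rank_product = (rank_dec / n) * (rank_nas / n))
}

#' Rank differentially expressed genes as direct factor targets
#'
#' End-to-end composition of the scoring pipeline: associate peaks to DE
#' genes within the TSS window, compute the Open Chromatin Score,
#' Enhancer-Target Score and motif number per gene, min-max scale the three
#' features, sum them into the Normalized Annotation Score, and combine
#' with the Differential Expression Change through the rank product. Genes
#' with no associated peak stay in the ranking with all-zero annotation
#' scores, so `n` in the rank-product denominator equals the DE gene count.
#'
#' @param genes Gene tibble (with `log2fc`, `padj`, `de_status`); only DE
#'   genes (`up`/`down`) enter the ranking.
#' @param peaks Peak interval tibble.
#' @param oc_regions Open-chromatin tibble with `chromatin_class`.
#' @param class_weights Named weight vector.
#' @param enhancers Enhancer-link tibble.
#' @param pwm Primary-factor [pwm()].
#' @param sequences Tibble `seq_id`, `seq` of peak sequences (ids matching
#'   peak names).
#' @param cfg [window_config()]; default 150 kb window.
#' @param dec `"abs_log2fc"` (default), `"log2fc"` or `"neg_log10_padj"`:
#'   definition of the Differential Expression Change.
#' @param motif_p Retention threshold for motif hits (strict `<`).
#' @param oc_rule Per-site open-chromatin aggregation rule, see
#'   [open_chromatin_score()].
#' @return A tibble of class `target_ranking`, sorted ascending by
#'   `rank_product`, retaining every intermediate column (`n_gres`, raw and
#'   scaled features, `nas`, `dec`, ranks). Attribute `config` records the
#'   options used.
#' @export
rank_direct_targets <- function(genes, peaks, oc_regions, class_weights,
                                enhancers, pwm, sequences,
                                cfg = window_config(),
                                dec = c("abs_log2fc", "log2fc", "neg_log10_padj"),
                                motif_p = 1e-4, oc_rule = "max") {
  dec <- match.arg(dec)
  de_genes <- filter(genes, .data$de_status %in% c("up", "down"))
  if (nrow(de_genes) == 0) {
    abort("no differentially expressed genes to rank",
          class = "gretarget_validation_error")
  }
  gres <- assign_peaks_to_genes(peaks, de_genes, cfg)
  hits <- scan_gre_sequences(gres, pwm, sequences, motif_p)
  tab <- annotation_score_table(de_genes, gres, oc_regions, class_weights,
                                enhancers, hits, oc_rule)
  dec_values <- switch(dec,
                       abs_log2fc = abs(tab$log2fc),
                       log2fc = tab$log2fc,
                       neg_log10_padj = -log10(tab$padj))
  rp <- rank_product(dec_values, tab$nas)
  out <- dplyr::bind_cols(tab, tibble(dec = dec_values), rp) |>
    arrange(.data$rank_product, .data$gene_id)
  attr(out, "config") <- list(window_bp = cfg$window_bp, dec = dec,
                              motif_p = motif_p, oc_rule = oc_rule,
                              mode = "rank_product")
  class(out) <- c("target_ranking", class(out))
  out
}

# scan only the peak sequences that occur in the association table
scan_gre_sequences <- function(gres, pwm, sequences, motif_p) {
  used <- sequences[sequences$seq_id %in% unique(gres$name), , drop = FALSE]
  if (is.null(pwm) || nrow(used) == 0) {
    return(tibble(seq_id = character(), offset = integer(), strand = character(),
                  score = double(), p_value = double()))
  }
  tab <- exact_pvalue_table(pwm)
  bind_rows(purrr::map2(used$seq_id, used$seq, function(id, s) {
    scan_sequence(pwm, s, p_threshold = motif_p, seq_id = id, table = tab)
  }))
}

annotation_score_table <- function(genes, gres, oc_regions, class_weights,
                                   enhancers, hits, oc_rule = "max") {
  base <- select(genes, dplyr::any_of(c("gene_id", "symbol", "log2fc",
                                        "padj", "de_status")))
  ngre <- gres |> group_by(.data$gene_id) |> summarise(n_gres = n(), .groups = "drop")
  oc <- open_chromatin_score(gres, oc_regions, class_weights, rule = oc_rule)
  enh <- enhancer_target_score(gres, enhancers)
  mot <- motif_number(gres, hits)
  tab <- base |>
    left_join(ngre, by = "gene_id") |>
    left_join(oc, by = "gene_id") |>
    left_join(enh, by = "gene_id") |>
    left_join(mot, by = "gene_id") |>
    mutate(n_gres = tidyr::replace_na(.data$n_gres, 0L),
           open_chromatin_score = tidyr::replace_na(.data$open_chromatin_score, 0),
           enhancer_target_score = tidyr::replace_na(.data$enhancer_target_score, 0),
           motif_count = tidyr::replace_na(.data$motif_count, 0L))
  tab |>
    mutate(norm_oc = feature_scale(.data$open_chromatin_score),
           norm_enh = feature_scale(.data$enhancer_target_score),
           norm_motif = feature_scale(as.double(.data$motif_count)),
           nas = normalized_annotation_score(.data$norm_oc, .data$norm_enh,
                                             .data$norm_motif))
}

#' Rank genes by Normalized Annotation Score only
#'
#' Factor-target mode for a factor without perturbation expression data:
#' peaks are associated to every gene at a (default) 100 kb window, the
#' associations are hard-filtered to those overlapping open chromatin, and
#' genes with at least one surviving association are scored and sorted by
#' NAS descending. Genes with no surviving association are excluded from
#' the candidate list.
#'
#' @inheritParams rank_direct_targets
#' @param pwm,sequences,enhancers Optional; features whose inputs are
#'   omitted contribute zero to every gene's NAS.
#' @param oc_mode Open-chromatin filter mode, see
#'   [filter_by_open_chromatin()].
#' @return A tibble of class `target_ranking` sorted by `nas` descending.
#' @export
rank_tf_targets_nas_only <- function(genes, peaks, oc_regions, class_weights,
                                     enhancers = NULL, pwm = NULL, sequences = NULL,
                                     cfg = window_config(window_bp = 100000L),
                                     motif_p = 1e-4, oc_rule = "max",
                                     oc_mode = "any") {
  gres <- assign_peaks_to_genes(peaks, genes, cfg)
  gres <- filter_by_open_chromatin(gres, oc_regions, mode = oc_mode)
  if (nrow(gres) == 0) {
    abort("no peak-gene association survives the open-chromatin filter",
          class = "gretarget_validation_error")
  }
  candidates <- filter(genes, .data$gene_id %in% unique(gres$gene_id))
  if (is.null(enhancers)) {
    enhancers <- tibble(chrom = character(), start = integer(), end = integer(),
                        target_gene = character(), association_score = double())
  }
  if (is.null(sequences)) sequences <- tibble(seq_id = character(), seq = character())
  hits <- scan_gre_sequences(gres, pwm, sequences, motif_p)
  tab <- annotation_score_table(candidates, gres, oc_regions, class_weights,
                                enhancers, hits, oc_rule)
  out <- arrange(tab, dplyr::desc(.data$nas), .data$gene_id)
  attr(out, "config") <- list(window_bp = cfg$window_bp, motif_p = motif_p,
                              oc_rule = oc_rule, oc_mode = oc_mode,
                              mode = "nas_only")
  class(out) <- c("target_ranking", class(out))
  out
}

#' @export
print.target_ranking <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<target_ranking> %s mode, %d genes, window %d bp\n",
              cfg$mode, nrow(x), cfg$window_bp))
  NextMethod()
}

#' @rdname rank_direct_targets
#' @param x,object A `target_ranking` tibble.
#' @param ... Unused.
#' @method glance target_ranking
#' @export
glance.target_ranking <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(mode = cfg$mode, n_genes = nrow(x), window_bp = cfg$window_bp,
         n_with_gres = sum(x$n_gres > 0),
         median_nas = stats::median(x$nas))
}

#' @rdname rank_direct_targets
#' @param top Number of top-ranked genes to label in the plot.
#' @method autoplot target_ranking
#' @export
autoplot.target_ranking <- function(object, top = 10, ...) {
  cfg <- attr(object, "config")
  df <- as_tibble(object)
  df$row <- seq_len(nrow(df))
  yvar <- if (cfg$mode == "rank_product") "rank_product" else "nas"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$row, y = .data[[yvar]])) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "gene rank", y = yvar) +
    ggplot2::theme_minimal()
  if (top > 0) {
    lab <- df[seq_len(min(top, nrow(df))), , drop = FALSE]
    p <- p + ggplot2::geom_text(data = lab,
                                ggplot2::aes(label = .data$gene_id),
                                hjust = -0.1, size = 2.8, check_overlap = TRUE)
  }
  p
}
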