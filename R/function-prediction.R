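#' Distance-decayed regulatory potential
#'
#' Estimates, per gene, the likelihood of regulation by the factor as a sum
#' over its associated binding sites of an exponential decay in TSS
#' distance: `score = sum_i exp(-(offset + k * d_i / decay_scale))`. Closer
#' sites contribute more; a gene with no sites scores 0.
#'
#' @param gres GRE tibble from [assign_peaks_to_genes()] (`gene_id`,
#'   `abs_distance`).
#' @param genes Optional gene tibble (or character vector of gene ids)
#'   defining the universe; genes without associations are completed with
#'   score 0.
#' @param decay_scale Distance scale in bp (default 100000).
#' @param offset Additive constant in the exponent (default 0.5).
#' @param k Decay rate multiplier (default 4).
#' @return Tibble `gene_id`, `score`, `n_gres`.
#' @examples
#' g <- tibble::tibble(gene_id = "g1", abs_distance = 0L)
#' regulatory_potential(g)  # exp(-0.5)
#' @export
regulatory_potential <- function(gres, genes = NULL, decay_scale = 1e5,
                                 offset = 0.5, k = 4) {
  out <- gres |>
    mutate(term = exp(-(offset + k * .data$abs_distance / decay_scale))) |>
    group_by(.data$gene_id) |>
    summarise(score = sum(.data$term), n_gres = n(), .groups = "drop")
  if (!is.null(genes)) {
    ids <- if (is.data.frame(genes)) genes$gene_id else genes
    out <- tibble(gene_id = ids) |>
      left_join(out, by = "gene_id") |>
      mutate(score = tidyr::replace_na(.data$score, 0),
             n_gres = tidyr::replace_na(.data$n_gres, 0L))
  }
  arrange(out, .data$gene_id)
}

#' Activator/repressor function prediction by cumulative curves and KS test
#'
#' Ranks genes by regulatory potential from high to low and accumulates,
#' along that ranking, the fraction of up-regulated, down-regulated and
#' background genes seen so far. If the factor activates its targets, the
#' up-gene curve rises above the background curve (up-genes concentrate at
#' high regulatory potential); a repressive effect shows in the down-gene
#' curve. Significance of each deviation is a two-sample Kolmogorov-Smirnov
#' test on the rank distributions (one-sided "higher regulatory potential
#' than background" by default; two-sided available).
#'
#' @param scores Tibble `gene_id`, `score` (from [regulatory_potential()]).
#' @param de Tibble `gene_id`, `de_status`; genes in `scores` and `de` are
#'   matched by id.
#' @param background `"not_de"` (default) uses non-DE genes as background;
#'   `"all"` uses every gene.
#' @param alternative `"greater"` (one-sided, default) or `"two.sided"`.
#' @return An object of class `function_prediction`: list with `curves`
#'   (tibble `rank`, `gene_id`, `de_status`, `cum_up`, `cum_down`,
#'   `cum_background`), `ks` (tibble with statistic and p per direction),
#'   and the options used. Supports [tidy()], [glance()] and [autoplot()].
#' @export
function_prediction <- function(scores, de, background = c("not_de", "all"),
                                alternative = c("greater", "two.sided")) {
  background <- match.arg(background)
  alternative <- match.arg(alternative)
  x <- inner_join(scores, select(de, "gene_id", "de_status"), by = "gene_id")
  for (grp in c("up", "down", "not_de")) {
    if (sum(x$de_status == grp) < 2) {
      abort(sprintf("need at least 2 genes with de_status '%s'", grp),
            class = "gretarget_validation_error")
    }
  }
  x <- arrange(x, dplyr::desc(.data$score), .data$gene_id)
  x$rank <- seq_len(nrow(x))
  bg_mask <- if (background == "not_de") x$de_status == "not_de" else rep(TRUE, nrow(x))
  curves <- x |>
    mutate(cum_up = cumsum(.data$de_status == "up") / sum(.data$de_status == "up"),
           cum_down = cumsum(.data$de_status == "down") / sum(.data$de_status == "down"),
           cum_background = cumsum(bg_mask) / sum(bg_mask)) |>
    select("rank", "gene_id", "de_status", "score",
           "cum_up", "cum_down", "cum_background")
  ks <- bind_rows(lapply(c("up", "down"), function(grp) {
    grp_ranks <- x$rank[x$de_status == grp]
    bg_ranks <- x$rank[bg_mask]
    # stochastically smaller ranks = greater regulatory potential; in
    # ks.test terms the group ECDF lies above the background ECDF
    alt <- if (alternative == "greater") "greater" else "two.sided"
    kt <- suppressWarnings(stats::ks.test(grp_ranks, bg_ranks,
                                          alternative = alt, exact = FALSE))
    tibble(direction = grp, statistic = unname(kt$statistic),
           p_value = unname(kt$p.value))
  }))
  structure(list(curves = curves, ks = ks, background = background,
                 alternative = alternative,
                 n = c(up = sum(x$de_status == "up"),
                       down = sum(x$de_status == "down"),
                       background = sum(bg_mask))),
            class = "function_prediction")
}

#' @export
print.function_prediction <- function(x, ...) {
  cat(sprintf("<function_prediction> %d up / %d down vs %d background genes\n",
              x$n["up"], x$n["down"], x$n["background"]))
  cat(sprintf("  KS (%s): up D=%.3f p=%.3g; down D=%.3f p=%.3g\n",
              x$alternative,
              x$ks$statistic[x$ks$direction == "up"],
              x$ks$p_value[x$ks$direction == "up"],
              x$ks$statistic[x$ks$direction == "down"],
              x$ks$p_value[x$ks$direction == "down"]))
  invisible(x)
}

#' @rdname function_prediction
#' @param x A `function_prediction` object.
#' @param ... Unused.
#' @method tidy function_prediction
#' @export
tidy.function_prediction <- function(x, ...) x$ks

#' @rdname function_prediction
#' @method glance function_prediction
#' @export
glance.function_prediction <- function(x, ...) {
  tibble(n_up = unname(x$n["up"]), n_down = unname(x$n["down"]),
         n_background = unname(x$n["background"]),
         ks_stat_up = x$ks$statistic[x$ks$direction == "up"],
         ks_p_up = x$ks$p_value[x$ks$direction == "up"],
         ks_stat_down = x$ks$statistic[x$ks$direction == "down"],
         ks_p_down = x$ks$p_value[x$ks$direction == "down"],
         alternative = x$alternative, background = x$background)
}

#' @rdname function_prediction
#' @param object A `function_prediction` object.
#' @method autoplot function_prediction
#' @export
autoplot.function_prediction <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curves,
                              cols = c("cum_up", "cum_down", "cum_background"),
                              names_to = "group", values_to = "cum_frac")
  long$group <- factor(long$group, levels = c("cum_up", "cum_down", "cum_background"),
                       labels = c("up-regulated", "down-regulated", "background"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$cum_frac,
                                     colour = .data$group, linetype = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::scale_colour_manual(values = c("up-regulated" = "#c0392b",
                                            "down-regulated" = "#6c3483",
                                            "background" = "grey40")) +
    ggplot2::scale_linetype_manual(values = c("up-regulated" = "solid",
                                              "down-regulated" = "solid",
                                              "background" = "dashed")) +
    ggplot2::labs(x = "genes ranked by regulatory potential (high to low)",
                  y = "cumulative fraction", colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}
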