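#' Window configuration for peak-to-gene association
#'
#' @param window_bp Maximum absolute peak-to-TSS distance in bp
#'   (inclusive). Default 150000; the NAS-only factor mode uses 100000.
#' @param proximal_cutoff_bp Distance at or below which an association is
#'   `proximal` (inclusive, default 3000; distal therefore spans
#'   3001..window).
#' @param anchor Peak anchor for the distance: `peak_center` (floor of the
#'   midpoint, default) or `nearest_edge`.
#' @return A list of class `window_config`.
#' @export
window_config <- function(window_bp = 150000L, proximal_cutoff_bp = 3000L,
                          anchor = c("peak_center", "nearest_edge")) {
  anchor <- match.arg(anchor)
  window_bp <- as.integer(window_bp)
  proximal_cutoff_bp <- as.integer(proximal_cutoff_bp)
  if (window_bp <= 0 || proximal_cutoff_bp <= 0 || proximal_cutoff_bp >= window_bp) {
    abort("need 0 < proximal_cutoff_bp < window_bp",
          class = "gretarget_validation_error")
  }
  structure(list(window_bp = window_bp, proximal_cutoff_bp = proximal_cutoff_bp,
                 anchor = anchor), class = "window_config")
}

#' Associate peaks with genes within a TSS window
#'
#' Produces one record per (peak, gene) pair whose peak anchor lies within
#' `cfg$window_bp` of the gene's TSS — the responsive elements of the
#' factor (GREs in the glucocorticoid setting). A peak may associate with
#' several genes and a gene with several peaks. Distances are signed by
#' genome coordinate (anchor minus TSS), and each association is labelled
#' `proximal` or `distal` at the configured cutoff.
#'
#' @param peaks Interval tibble (see [read_bed()]); peaks without a `name`
#'   get a positional identifier.
#' @param genes Gene tibble with `gene_id`, `chrom`, `tss`.
#' @param cfg A [window_config()].
#' @return A tibble with the peak columns plus `gene_id`,
#'   `signed_distance`, `abs_distance`, `locality`, sorted by
#'   (`gene_id`, `signed_distance`).
#' @export
assign_peaks_to_genes <- function(peaks, genes, cfg = window_config()) {
  validate_intervals(peaks, what = "peak")
  if (nrow(genes) == 0) {
    warn("empty gene list: no peak-gene associations possible")
    return(empty_gre())
  }
  if (nrow(peaks) == 0) return(empty_gre())
  peaks <- as_tibble(peaks)
  if (!"name" %in% names(peaks) || anyNA(peaks$name)) {
    peaks$name <- sprintf("peak_%05d", seq_len(nrow(peaks)))
  }
  anchor <- as.integer((peaks$start + peaks$end) %/% 2L)
  # candidate search: anchor point (or whole peak for nearest_edge) against
  # the window [tss - w, tss + w], as half-open intervals
  pts <- if (cfg$anchor == "peak_center") {
    tibble(chrom = peaks$chrom, start = anchor, end = anchor + 1L)
  } else {
    tibble(chrom = peaks$chrom, start = peaks$start, end = peaks$end)
  }
  win <- tibble(chrom = genes$chrom,
                start = pmax(0L, genes$tss - cfg$window_bp),
                end = genes$tss + cfg$window_bp + 1L)
  hits <- overlap_pairs(pts, win)
  if (cfg$anchor == "nearest_edge") {
    # anchor is the edge closest to each candidate TSS; recompute per pair
    tss <- genes$tss[hits$idx_b]
    s <- peaks$start[hits$idx_a]; e <- peaks$end[hits$idx_a] - 1L
    anchor_pair <- ifelse(tss < s, s, ifelse(tss > e, e, tss))
    signed <- anchor_pair - tss
  } else {
    signed <- anchor[hits$idx_a] - genes$tss[hits$idx_b]
  }
  out <- tibble(chrom = peaks$chrom[hits$idx_a],
                start = peaks$start[hits$idx_a],
                end = peaks$end[hits$idx_a],
                name = peaks$name[hits$idx_a],
                gene_id = genes$gene_id[hits$idx_b],
                signed_distance = as.integer(signed))
  out <- filter(out, abs(.data$signed_distance) <= cfg$window_bp)
  out$abs_distance <- abs(out$signed_distance)
  out$locality <- classify_locality(out$abs_distance, cfg$proximal_cutoff_bp)
  arrange(out, .data$gene_id, .data$signed_distance, .data$name)
}

empty_gre <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         name = character(), gene_id = character(),
         signed_distance = integer(), abs_distance = integer(),
         locality = character())
}

#' Classify an association distance as proximal or distal
#'
#' Proximal means at or below the cutoff (default 3 kb, inclusive);
#' distal covers cutoff+1 up to the window.
#'
#' @param abs_distance Non-negative distances in bp.
#' @param cutoff Inclusive proximal cutoff in bp.
#' @return Character vector over `proximal`, `distal`.
#' @export
classify_locality <- function(abs_distance, cutoff = 3000L) {
  if (any(abs_distance < 0)) {
    abort("abs_distance must be non-negative", class = "gretarget_validation_error")
  }
  ifelse(abs_distance <= cutoff, "proximal", "distal")
}

#' Fraction of associations that are distal
#'
#' @param gres GRE tibble from [assign_peaks_to_genes()].
#' @return A real in `[0, 1]`.
#' @export
distal_fraction <- function(gres) {
  if (nrow(gres) == 0) {
    abort("distal_fraction is undefined for an empty association set",
          class = "gretarget_undefined_error")
  }
  mean(gres$locality == "distal")
}

#' Filter associations by open-chromatin overlap
#'
#' Keeps associations whose peak overlaps accessible chromatin. With
#' `mode = "any"` one overlapping region in any supplied set suffices; with
#' `mode = "intersection"` the peak must overlap at least one region in
#' *every* set (the "common between cell types" criterion).
#'
#' @param gres GRE tibble.
#' @param oc_sets A single open-chromatin tibble or a list of them
#'   (columns `chrom`, `start`, `end`, optionally `chromatin_class`).
#' @param mode `"any"` or `"intersection"`.
#' @return The filtered GRE tibble.
#' @export
filter_by_open_chromatin <- function(gres, oc_sets, mode = c("any", "intersection")) {
  mode <- match.arg(mode)
  if (is.data.frame(oc_sets)) oc_sets <- list(oc_sets)
  if (length(oc_sets) == 0) {
    abort("oc_sets must contain at least one region set",
          class = "gretarget_validation_error")
  }
  if (nrow(gres) == 0) return(gres)
  ov <- vapply(oc_sets, function(oc) {
    validate_intervals(oc, what = "open-chromatin")
    hit <- rep(FALSE, nrow(gres))
    hit[unique(overlap_pairs(gres, oc)$idx_a)] <- TRUE
    hit
  }, logical(nrow(gres)))
  ov <- matrix(ov, nrow = nrow(gres))
  keep <- if (mode == "any") rowSums(ov) >= 1 else rowSums(ov) == length(oc_sets)
  gres[keep, , drop = FALSE]
}
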