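#' Configuration for the synthetic input universe
#'
#' Describes a miniature regulatory landscape with a planted set of direct
#' factor targets: genes laid out on a small genome, ChIP peaks placed
#' around them at distal-biased TSS distances, open-chromatin regions,
#' enhancer-target links, peak sequences with planted motif instances, a
#' differential-expression table, and bulk/single-cell expression matrices.
#' Direct targets receive more peaks, more open-chromatin and enhancer
#' support, more planted motifs and larger expression changes than
#' background genes; indirect DE genes change expression without extra
#' regulatory support. Defaults mimic distal factor regulation (about 95%
#' of associations beyond 3 kb of the TSS).
#'
#' @param n_genes Number of genes (default 1000).
#' @param n_chroms Number of chromosomes the genes are spread over.
#' @param genome_span_bp Length of each synthetic chromosome.
#' @param n_direct_targets Number of planted direct-target genes.
#' @param peak_rate_direct,peak_rate_background Expected (Poisson) peaks
#'   per direct-target / background gene.
#' @param proximal_prob Probability that a peak-TSS distance is proximal
#'   (uniform within the 3 kb cutoff); otherwise the absolute distance is
#'   log-uniform on (3000, `max_distance_bp`], favouring 3-50 kb.
#' @param max_distance_bp Largest planted peak-TSS distance.
#' @param peak_width_range Uniform range of peak widths in bp.
#' @param oc_overlap_prob_direct,oc_overlap_prob_background Probability
#'   that a peak receives an overlapping open-chromatin region.
#' @param class_frequencies Named probabilities of chromatin classes; the
#'   emitted class-weight table uses these frequencies as weights.
#' @param n_background_oc Unlinked open-chromatin regions scattered over
#'   the genome.
#' @param enhancer_link_prob_direct,enhancer_link_prob_background
#'   Probability that a peak receives an overlapping enhancer targeting its
#'   gene.
#' @param enhancer_score_meanlog,enhancer_score_sdlog Log-normal parameters
#'   of enhancer association scores.
#' @param n_decoy_enhancers Enhancers placed at random positions with
#'   random target genes.
#' @param motif_plant_prob_direct,motif_plant_prob_background Probability
#'   that a peak sequence carries a planted consensus motif instance.
#' @param pwm Motif used for planting and scanning; default a 15-bp
#'   inverted-repeat nuclear-receptor-like matrix, see [default_gbs_pwm()].
#' @param gc GC content of the 0-order background sequences.
#' @param lfc_direct_mean,lfc_direct_sd Normal parameters of the absolute
#'   log2 fold change of direct targets (sign random).
#' @param lfc_indirect_mean,lfc_indirect_sd Same for indirect DE genes.
#' @param frac_indirect_de Fraction of non-direct genes that are DE.
#' @param lfc_null_sd Log2FC spread of non-DE genes.
#' @param n_samples_per_group Bulk samples per group (control/treated).
#' @param n_cells Cells in the single-cell RPKM matrix.
#' @param sc_expressed_prob Probability that a gene is planted as expressed
#'   in the single-cell matrix (guaranteed > 1 RPKM in at least one cell).
#' @param with_open_chromatin,with_enhancers,with_sequences,with_matrices
#'   Toggles for optional output streams (per-stream RNG seeding keeps the
#'   other streams identical when one is disabled).
#' @param seed Master seed; every output stream derives its own seed from
#'   it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 1000L, n_chroms = 4L,
                             genome_span_bp = 5e7,
                             n_direct_targets = 50L,
                             peak_rate_direct = 5, peak_rate_background = 1,
                             proximal_prob = 0.05, max_distance_bp = 140000L,
                             peak_width_range = c(200L, 1000L),
                             oc_overlap_prob_direct = 0.9,
                             oc_overlap_prob_background = 0.25,
                             class_frequencies = c(active_promoter = 0.15,
                                                   active_enhancer = 0.40,
                                                   weak_enhancer = 0.30,
                                                   quiescent = 0.15),
                             n_background_oc = 500L,
                             enhancer_link_prob_direct = 0.8,
                             enhancer_link_prob_background = 0.1,
                             enhancer_score_meanlog = 2,
                             enhancer_score_sdlog = 0.5,
                             n_decoy_enhancers = 200L,
                             motif_plant_prob_direct = 0.9,
                             motif_plant_prob_background = 0.1,
                             pwm = default_gbs_pwm(),
                             gc = 0.41,
                             lfc_direct_mean = 2.5, lfc_direct_sd = 0.6,
                             lfc_indirect_mean = 1.2, lfc_indirect_sd = 0.4,
                             frac_indirect_de = 0.25, lfc_null_sd = 0.15,
                             n_samples_per_group = 4L, n_cells = 30L,
                             sc_expressed_prob = 0.7,
                             with_open_chromatin = TRUE, with_enhancers = TRUE,
                             with_sequences = TRUE, with_matrices = TRUE,
                             seed = 17L) {
  cfg <- as.list(environment())
  probs <- c(proximal_prob, oc_overlap_prob_direct, oc_overlap_prob_background,
             enhancer_link_prob_direct, enhancer_link_prob_background,
             motif_plant_prob_direct, motif_plant_prob_background,
             frac_indirect_de, sc_expressed_prob, gc)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]", class = "gretarget_validation_error")
  }
  if (n_direct_targets >= n_genes) {
    abort("n_direct_targets must be smaller than n_genes",
          class = "gretarget_validation_error")
  }
  if (abs(sum(class_frequencies) - 1) > 1e-6 || is.null(names(class_frequencies))) {
    abort("class_frequencies must be named and sum to 1",
          class = "gretarget_validation_error")
  }
  genes_per_chrom <- ceiling(n_genes / n_chroms)
  margin <- max_distance_bp + max(peak_width_range) + 1000
  if (genome_span_bp < 2 * margin + genes_per_chrom) {
    abort("genome_span_bp too small for the requested peak distances",
          class = "gretarget_validation_error")
  }
  structure(cfg, class = "synthetic_config")
}

#' Default primary-factor position weight matrix
#'
#' A 15-position inverted-repeat matrix of the kind bound by steroid
#' hormone receptors (two 6-bp half sites separated by a 3-bp spacer):
#' informative positions carry 0.85 on the consensus base, the spacer is
#' uniform.
#'
#' @param motif_id Identifier.
#' @return A [pwm()] object.
#' @export
default_gbs_pwm <- function(motif_id = "GBS") {
  consensus <- strsplit("AGAACANNNTGTTCT", "")[[1]]
  m <- vapply(consensus, function(b) {
    if (b == "N") rep(0.25, 4)
    else {
      p <- rep(0.05, 4)
      p[match(b, BASES)] <- 0.85
      p
    }
  }, numeric(4))
  pwm(m, motif_id = motif_id)
}

#' Generate a complete synthetic input bundle with ground truth
#'
#' Draws a full miniature input universe under a [synthetic_config()]: a
#' gene table with DE statistics, ChIP peaks, open-chromatin regions with a
#' class-weight table, enhancer-target links, peak sequences with planted
#' motif instances at recorded offsets, bulk counts and a single-cell RPKM
#' matrix — together with the planted truth needed to measure recovery.
#' Identical configurations (including the seed) produce identical bundles;
#' each output stream uses its own derived RNG seed, so disabling one
#' stream never perturbs the others.
#'
#' @param cfg A [synthetic_config()].
#' @return A list of class `synthetic_bundle` with elements `genes`,
#'   `peaks`, `open_chromatin`, `class_weights`, `enhancers`, `sequences`,
#'   `pwm`, `counts`, `rpkm`, `truth`, `config`.
#' @export
simulate_target_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  genes <- with_stream_seed(cfg$seed, "genes", synth_genes(cfg))
  expr <- with_stream_seed(cfg$seed, "expression", synth_expression(cfg, genes))
  genes <- left_join(genes, expr, by = "gene_id")
  genes$de_status <- de_status(genes$log2fc, genes$padj)
  peaks <- with_stream_seed(cfg$seed, "peaks", synth_peaks(cfg, genes))
  oc <- if (cfg$with_open_chromatin) {
    with_stream_seed(cfg$seed, "open_chromatin", synth_open_chromatin(cfg, peaks))
  } else NULL
  enh <- if (cfg$with_enhancers) {
    with_stream_seed(cfg$seed, "enhancers", synth_enhancers(cfg, peaks, genes))
  } else NULL
  seqs <- if (cfg$with_sequences) {
    with_stream_seed(cfg$seed, "sequences", synth_sequences(cfg, peaks))
  } else NULL
  counts <- rpkm <- sc_expressed <- NULL
  if (cfg$with_matrices) {
    counts <- with_stream_seed(cfg$seed, "counts", synth_counts(cfg, genes))
    sc <- with_stream_seed(cfg$seed, "rpkm", synth_rpkm(cfg, genes))
    rpkm <- sc$matrix
    sc_expressed <- sc$expressed_ids
  }
  truth <- list(direct_target_ids = genes$gene_id[genes$role == "direct"],
                indirect_de_ids = genes$gene_id[genes$role == "indirect"],
                planted_motifs = if (is.null(seqs)) NULL else seqs$planted,
                sc_expressed_ids = sc_expressed)
  structure(list(genes = select(genes, -"role"),
                 peaks = select(peaks, -"role", -"gene_id"),
                 peak_gene_truth = select(peaks, "name", "gene_id", "role"),
                 open_chromatin = oc, class_weights = class_weights_of(cfg),
                 enhancers = enh,
                 sequences = if (is.null(seqs)) NULL else seqs$sequences,
                 pwm = cfg$pwm, counts = counts, rpkm = rpkm,
                 truth = truth, config = cfg),
            class = "synthetic_bundle")
}

#' Null bundle: DE labels independent of regulatory features
#'
#' Generates the same bundle as [simulate_target_dataset()] (identical
#' marginals, peaks, annotation and sequences at the same seed), then
#' permutes the expression columns (`log2fc`, `padj`, `de_status`) across
#' genes so DE labels carry no information about peak placement. Used for
#' type-I-error experiments on the function-prediction test and for null
#' rank-product enrichment.
#'
#' @param cfg A [synthetic_config()].
#' @return A `synthetic_bundle` whose truth records the permutation.
#' @export
simulate_null_dataset <- function(cfg = synthetic_config()) {
  bundle <- simulate_target_dataset(cfg)
  n <- nrow(bundle$genes)
  perm <- with_stream_seed(cfg$seed, "null_permutation", sample.int(n))
  bundle$genes$log2fc <- bundle$genes$log2fc[perm]
  bundle$genes$padj <- bundle$genes$padj[perm]
  bundle$genes$de_status <- bundle$genes$de_status[perm]
  bundle$truth$null_permutation <- perm
  bundle
}

class_weights_of <- function(cfg) {
  tibble(chromatin_class = names(cfg$class_frequencies),
         weight = unname(cfg$class_frequencies))
}

synth_genes <- function(cfg) {
  n <- cfg$n_genes
  chrom_of <- sprintf("chr%d", rep(seq_len(cfg$n_chroms), length.out = n))
  per_chrom <- table(chrom_of)
  margin <- cfg$max_distance_bp + max(cfg$peak_width_range) + 1000
  tss <- integer(n)
  for (ch in names(per_chrom)) {
    idx <- which(chrom_of == ch)
    k <- length(idx)
    spacing <- (cfg$genome_span_bp - 2 * margin) / (k + 1)
    base <- margin + spacing * seq_len(k)
    tss[idx] <- as.integer(round(base + runif(k, -spacing / 4, spacing / 4)))
  }
  role <- rep("background", n)
  direct <- sample.int(n, cfg$n_direct_targets)
  role[direct] <- "direct"
  rest <- setdiff(seq_len(n), direct)
  indirect <- rest[runif(length(rest)) < cfg$frac_indirect_de]
  role[indirect] <- "indirect"
  tibble(gene_id = sprintf("gene_%04d", seq_len(n)),
         symbol = sprintf("SYN%04d", seq_len(n)),
         chrom = chrom_of, strand = sample(c("+", "-"), n, replace = TRUE),
         tss = tss, role = role)
}

synth_expression <- function(cfg, genes) {
  n <- nrow(genes)
  mag <- numeric(n)
  padj <- numeric(n)
  is_dir <- genes$role == "direct"
  is_ind <- genes$role == "indirect"
  is_bg <- !is_dir & !is_ind
  mag[is_dir] <- abs(rnorm(sum(is_dir), cfg$lfc_direct_mean, cfg$lfc_direct_sd))
  mag[is_ind] <- abs(rnorm(sum(is_ind), cfg$lfc_indirect_mean, cfg$lfc_indirect_sd))
  mag[is_bg] <- abs(rnorm(sum(is_bg), 0, cfg$lfc_null_sd))
  sign <- sample(c(-1, 1), n, replace = TRUE)
  padj[is_dir | is_ind] <- runif(sum(is_dir | is_ind), 1e-6, 0.01)
  padj[is_bg] <- runif(sum(is_bg), 0.1, 1)
  tibble(gene_id = genes$gene_id, log2fc = sign * mag, padj = padj)
}

synth_peaks <- function(cfg, genes) {
  rate <- ifelse(genes$role == "direct", cfg$peak_rate_direct,
                 cfg$peak_rate_background)
  n_peaks <- rpois(nrow(genes), rate)
  gene_idx <- rep(seq_len(nrow(genes)), n_peaks)
  m <- length(gene_idx)
  if (m == 0) {
    abort("configuration produced zero peaks", class = "gretarget_validation_error")
  }
  proximal <- runif(m) < cfg$proximal_prob
  d <- ifelse(proximal,
              runif(m, 0, 3000),
              exp(runif(m, log(3001), log(cfg$max_distance_bp))))
  signed <- as.integer(round(d)) * sample(c(-1L, 1L), m, replace = TRUE)
  width <- as.integer(round(runif(m, cfg$peak_width_range[1], cfg$peak_width_range[2])))
  center <- genes$tss[gene_idx] + signed
  start <- pmax(0L, as.integer(center - width %/% 2L))
  tibble(chrom = genes$chrom[gene_idx], start = start,
         end = start + width,
         name = sprintf("peak_%05d", seq_len(m)),
         gene_id = genes$gene_id[gene_idx],
         role = genes$role[gene_idx])
}

synth_open_chromatin <- function(cfg, peaks) {
  p <- ifelse(peaks$role == "direct", cfg$oc_overlap_prob_direct,
              cfg$oc_overlap_prob_background)
  linked <- runif(nrow(peaks)) < p
  lp <- peaks[linked, , drop = FALSE]
  center <- (lp$start + lp$end) %/% 2L
  start <- pmax(0L, as.integer(center - round(runif(nrow(lp), 100, 400))))
  width <- as.integer(round(runif(nrow(lp), 200, 800)))
  linked_oc <- tibble(chrom = lp$chrom, start = start, end = start + width)
  n_bg <- cfg$n_background_oc
  bg_start <- as.integer(round(runif(n_bg, 0, cfg$genome_span_bp - 1000)))
  bg_oc <- tibble(chrom = sprintf("chr%d", sample.int(cfg$n_chroms, n_bg, replace = TRUE)),
                  start = bg_start,
                  end = bg_start + as.integer(round(runif(n_bg, 200, 800))))
  oc <- bind_rows(linked_oc, bg_oc)
  oc$chromatin_class <- sample(names(cfg$class_frequencies), nrow(oc),
                               replace = TRUE, prob = cfg$class_frequencies)
  arrange(oc, .data$chrom, .data$start)
}

synth_enhancers <- function(cfg, peaks, genes) {
  p <- ifelse(peaks$role == "direct", cfg$enhancer_link_prob_direct,
              cfg$enhancer_link_prob_background)
  linked <- runif(nrow(peaks)) < p
  lp <- peaks[linked, , drop = FALSE]
  center <- (lp$start + lp$end) %/% 2L
  start <- pmax(0L, as.integer(center - round(runif(nrow(lp), 100, 500))))
  width <- as.integer(round(runif(nrow(lp), 300, 1200)))
  linked_enh <- tibble(chrom = lp$chrom, start = start, end = start + width,
                       target_gene = lp$gene_id,
                       association_score = rlnorm(nrow(lp),
                                                  cfg$enhancer_score_meanlog,
                                                  cfg$enhancer_score_sdlog))
  n_decoy <- cfg$n_decoy_enhancers
  d_start <- as.integer(round(runif(n_decoy, 0, cfg$genome_span_bp - 2000)))
  decoys <- tibble(chrom = sprintf("chr%d", sample.int(cfg$n_chroms, n_decoy, replace = TRUE)),
                   start = d_start,
                   end = d_start + as.integer(round(runif(n_decoy, 300, 1200))),
                   target_gene = sample(genes$gene_id, n_decoy, replace = TRUE),
                   association_score = rlnorm(n_decoy, cfg$enhancer_score_meanlog,
                                              cfg$enhancer_score_sdlog))
  arrange(bind_rows(linked_enh, decoys), .data$chrom, .data$start)
}

synth_sequences <- function(cfg, peaks) {
  consensus <- pwm_consensus(cfg$pwm)
  consensus <- gsub("N", "A", consensus)  # spacer positions are uniform
  L <- nchar(consensus)
  p <- ifelse(peaks$role == "direct", cfg$motif_plant_prob_direct,
              cfg$motif_plant_prob_background)
  plant <- runif(nrow(peaks)) < p
  base_probs <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2,
                  G = cfg$gc / 2, T = (1 - cfg$gc) / 2)
  widths <- peaks$end - peaks$start
  seqs <- vapply(widths, function(w) {
    paste(sample(BASES, w, replace = TRUE, prob = base_probs), collapse = "")
  }, character(1))
  offsets <- rep(NA_integer_, nrow(peaks))
  strands <- rep(NA_character_, nrow(peaks))
  for (i in which(plant)) {
    w <- widths[i]
    if (w < L) next
    off <- sample.int(w - L + 1L, 1L) - 1L
    st <- sample(c("+", "-"), 1L)
    ins <- if (st == "+") consensus else revcomp(consensus)
    substr(seqs[i], off + 1L, off + L) <- ins
    offsets[i] <- off
    strands[i] <- st
  }
  planted <- tibble(name = peaks$name[plant & !is.na(offsets)],
                    offset = offsets[plant & !is.na(offsets)],
                    strand = strands[plant & !is.na(offsets)])
  list(sequences = tibble(seq_id = peaks$name, seq = seqs), planted = planted)
}

synth_counts <- function(cfg, genes) {
  n <- nrow(genes)
  k <- cfg$n_samples_per_group
  mu <- rlnorm(n, meanlog = 5, sdlog = 1)
  m <- matrix(rpois(n * 2 * k, rep(mu, 2 * k)), nrow = n)
  rownames(m) <- genes$gene_id
  colnames(m) <- c(sprintf("ctrl_%d", seq_len(k)), sprintf("trt_%d", seq_len(k)))
  m
}

synth_rpkm <- function(cfg, genes) {
  n <- nrow(genes)
  expressed <- runif(n) < cfg$sc_expressed_prob
  m <- matrix(0, nrow = n, ncol = cfg$n_cells,
              dimnames = list(genes$gene_id, sprintf("cell_%02d", seq_len(cfg$n_cells))))
  for (i in which(expressed)) {
    on <- runif(cfg$n_cells) < 0.5
    m[i, on] <- rlnorm(sum(on), meanlog = 1, sdlog = 1)
    guaranteed <- sample.int(cfg$n_cells, 1)
    m[i, guaranteed] <- 1 + rlnorm(1, meanlog = 0, sdlog = 0.5)
  }
  low <- which(!expressed)
  m[low, ] <- matrix(runif(length(low) * cfg$n_cells, 0, 1),
                     nrow = length(low))
  list(matrix = m, expressed_ids = genes$gene_id[expressed])
}

#' Write a synthetic bundle to disk in the pipeline's standard formats
#'
#' Emits `peaks.bed`, `open_chromatin.bed` (class label in column 4),
#' `genes.tsv` (with DE statistics), `enhancers.tsv`,
#' `class_weights.tsv`, `sequences.fa`, `motif.meme`, `counts.tsv`,
#' `rpkm.tsv` and `truth.tsv`. Every file re-reads cleanly through the
#' package's own readers, and identical seeds produce byte-identical files.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c()
  p <- function(f) file.path(dir, f)
  write_bed(bundle$peaks, p("peaks.bed")); paths["peaks"] <- p("peaks.bed")
  readr::write_tsv(bundle$genes, p("genes.tsv"), progress = FALSE)
  paths["genes"] <- p("genes.tsv")
  if (!is.null(bundle$open_chromatin)) {
    write_bed(bundle$open_chromatin, p("open_chromatin.bed"))
    paths["open_chromatin"] <- p("open_chromatin.bed")
    readr::write_tsv(bundle$class_weights, p("class_weights.tsv"), progress = FALSE)
    paths["class_weights"] <- p("class_weights.tsv")
  }
  if (!is.null(bundle$enhancers)) {
    readr::write_tsv(bundle$enhancers, p("enhancers.tsv"), progress = FALSE)
    paths["enhancers"] <- p("enhancers.tsv")
  }
  if (!is.null(bundle$sequences)) {
    write_fasta(bundle$sequences, p("sequences.fa"))
    paths["sequences"] <- p("sequences.fa")
    write_meme_motifs(bundle$pwm, p("motif.meme"))
    paths["motif"] <- p("motif.meme")
  }
  if (!is.null(bundle$counts)) {
    write_expression_matrix(bundle$counts, p("counts.tsv"))
    paths["counts"] <- p("counts.tsv")
    write_expression_matrix(bundle$rpkm, p("rpkm.tsv"))
    paths["rpkm"] <- p("rpkm.tsv")
  }
  truth_tab <- tibble(gene_id = bundle$genes$gene_id,
                      is_direct_target = bundle$genes$gene_id %in%
                        bundle$truth$direct_target_ids,
                      is_indirect_de = bundle$genes$gene_id %in%
                        bundle$truth$indirect_de_ids)
  readr::write_tsv(truth_tab, p("truth.tsv"), progress = FALSE)
  paths["truth"] <- p("truth.tsv")
  invisible(paths)
}
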