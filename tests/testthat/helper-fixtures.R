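# Shared fixtures and independent brute-force oracles.

random_intervals <- function(n, chroms = c("chr1", "chr2", "chrX")) {
  start <- sample.int(1e6, n)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start,
                 end = start + sample.int(5000, n),
                 name = sprintf("iv_%04d", seq_len(n)),
                 score = round(stats::runif(n, 0, 1000), 3),
                 strand = sample(c("+", "-", "."), n, replace = TRUE))
}

random_pwm <- function(L, seed = NULL, background = rep(0.25, 4)) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rgamma(4 * L, shape = 1), nrow = 4)
  m <- sweep(m, 2, colSums(m), "/")
  pwm(m, motif_id = sprintf("rand_%d", L), background = background)
}

one_hot_pwm <- function(kmer) {
  bases <- strsplit(kmer, "")[[1]]
  m <- vapply(bases, function(b) {
    p <- rep(1e-9, 4)
    p[match(b, c("A", "C", "G", "T"))] <- 1 - 3e-9
    p
  }, numeric(4))
  pwm(m, motif_id = "one_hot", pseudocount = 0)
}

# oracle: per-position log2 odds summation, no shared code with the package
oracle_log_odds <- function(p, kmer) {
  bases <- strsplit(kmer, "")[[1]]
  total <- 0
  for (i in seq_along(bases)) {
    j <- match(bases[i], c("A", "C", "G", "T"))
    total <- total + log2(p$prob[j, i] / p$background[[j]])
  }
  unname(total)
}

# oracle: exhaustive enumeration of all 4^L kmers; returns a function
# p(score) = Pr[discretised score >= discretised s] under the background
oracle_enumeration <- function(p, granularity = 1e-3) {
  L <- ncol(p$prob)
  grid <- expand.grid(rep(list(1:4), L))
  S <- log2(sweep(p$prob, 1, p$background, "/"))
  ints <- round(S / granularity)
  scores <- apply(grid, 1, function(codes) sum(ints[cbind(codes, seq_len(L))]))
  probs <- apply(grid, 1, function(codes) prod(p$background[codes]))
  function(s_int) sum(probs[scores >= s_int])
}

# oracle: all-pairs peak-gene scan with plain arithmetic
oracle_assign <- function(peaks, genes, window, cutoff = 3000) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      center <- (peaks$start[i] + peaks$end[i]) %/% 2
      d <- center - genes$tss[j]
      if (abs(d) <= window) {
        out[[length(out) + 1]] <- tibble::tibble(
          name = peaks$name[i], gene_id = genes$gene_id[j],
          signed_distance = as.integer(d),
          locality = if (abs(d) <= cutoff) "proximal" else "distal")
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(name = character(), gene_id = character(),
                          signed_distance = integer(), locality = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), gene_id, signed_distance, name)
}

# oracle: double-loop half-open overlap test
oracle_overlaps <- function(a, b) {
  hit <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  hit
}

tiny_gene_table <- function() {
  tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
    symbol = NA_character_,
    chrom = "chr1",
    strand = c("+", "-", "+", "+", "-", "+"),
    tss = c(1e6, 2e6, 3e6, 4e6, 5e6, 6e6),
    log2fc = c(2, -1.5, 0.1, 3, -2, 0.05),
    padj = c(0.01, 0.02, 0.6, 0.001, 0.03, 0.9),
    de_status = c("up", "down", "not_de", "up", "down", "not_de"))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
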