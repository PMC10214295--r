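# PWM scanning with exact null p-values.
#
# Scores are log2 odds of the pseudocounted motif probability over a
# 0-order background. P-values are exact tail probabilities of the window
# score under i.i.d. background letters, computed by dynamic programming on
# a discretised score grid (default granularity 1/1000 bit); scanning is
# done in the same integer score space so looked-up p-values are exact for
# the discretised score.

BASES <- c("A", "C", "G", "T")

# integer-coded sequence: A=1 C=2 G=3 T=4, NA for anything else
encode_dna <- function(seq) {
  codes <- match(strsplit(toupper(seq), "")[[1]], BASES)
  codes
}

pwm_score_matrix <- function(pwm) {
  log2(sweep(pwm$prob, 1, pwm$background, "/"))
}

#' Log-odds score of a single k-mer against a PWM
#'
#' Sum over positions of `log2(P_i(base) / background(base))` with
#' pseudocounted probabilities `P`.
#'
#' @param pwm A [pwm()] object.
#' @param kmer A string over A/C/G/T of length `length(pwm)`.
#' @return A real score in bits.
#' @export
log_odds_score <- function(pwm, kmer) {
  codes <- encode_dna(kmer)
  L <- ncol(pwm$prob)
  if (length(codes) != L) {
    abort(sprintf("kmer length %d does not match motif width %d",
                  length(codes), L),
          class = "gretarget_validation_error")
  }
  if (anyNA(codes)) {
    abort("kmer contains a non-ACGT base", class = "gretarget_validation_error")
  }
  S <- pwm_score_matrix(pwm)
  sum(S[cbind(codes, seq_len(L))])
}

#' Exact PWM score null distribution and p-values
#'
#' Computes the full distribution of the window log-odds score under
#' i.i.d. background letters by dynamic programming over integer-discretised
#' per-column scores, and from it the survival function
#' `p(s) = Pr[score >= s]`. The discretisation granularity is the only
#' approximation; the distribution is exact on the integer grid.
#'
#' @param pwm A [pwm()] object.
#' @param granularity Score grid step in bits (default 0.001).
#' @param max_cells Guard on the DP table size; exceeding it raises a
#'   resource error advising a coarser granularity.
#' @return A list of class `pwm_pvalue_table` with elements `granularity`,
#'   `min_int` (integer score of the first cell), `pmf`, `sf` (survival,
#'   aligned with `pmf`), and the integer score matrix `ints` used for
#'   scanning.
#' @export
exact_pvalue_table <- function(pwm, granularity = 1e-3, max_cells = 5e7) {
  if (granularity <= 0) {
    abort("granularity must be positive", class = "gretarget_validation_error")
  }
  S <- pwm_score_matrix(pwm)
  ints <- round(S / granularity)
  L <- ncol(ints)
  span <- sum(apply(ints, 2, max) - apply(ints, 2, min)) + 1
  if (span > max_cells) {
    abort(sprintf(paste0("discretised score range (%d cells) exceeds max_cells; ",
                         "use a coarser granularity"), span),
          class = "gretarget_resource_error")
  }
  bg <- pwm$background
  cur <- 1
  cur_lo <- 0
  for (i in seq_len(L)) {
    ki <- ints[, i]
    kmin <- min(ki)
    new <- numeric(length(cur) + max(ki) - kmin)
    for (j in 1:4) {
      sh <- ki[j] - kmin
      idx <- seq_along(cur) + sh
      new[idx] <- new[idx] + cur * bg[j]
    }
    cur <- new
    cur_lo <- cur_lo + kmin
  }
  sf <- rev(cumsum(rev(cur)))
  structure(list(granularity = granularity, min_int = cur_lo,
                 pmf = cur, sf = sf, ints = ints),
            class = "pwm_pvalue_table")
}

# p-value of an integer window score against a table; scores below the
# attainable minimum get p = 1, above the maximum p = 0 cannot occur for
# scanned windows (every window score is attainable).
lookup_pvalue <- function(tab, int_score) {
  idx <- int_score - tab$min_int + 1
  idx <- pmax(1, pmin(length(tab$sf), idx))
  tab$sf[idx]
}

revcomp <- function(seq) {
  flipped <- chartr("ACGTNacgtn", "TGCANtgcan", seq)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Scan a DNA sequence for PWM matches
#'
#' Slides the motif over every window of the sequence (and of its reverse
#' complement when `both_strands`) and reports windows whose exact null
#' p-value is below `p_threshold` (strict `<`; default 1e-4, the stringent
#' retention threshold). Offsets are 0-based on the forward strand;
#' overlapping hits are allowed. Windows containing non-ACGT bases are
#' skipped by default, or scored with zero log-odds contribution at the
#' ambiguous position when `ambiguous = "background"`.
#'
#' @param pwm A [pwm()] object.
#' @param seq DNA string.
#' @param p_threshold Retention threshold on the exact p-value (strict `<`).
#' @param both_strands Scan the reverse complement too?
#' @param seq_id Identifier recorded in the output.
#' @param table Optional precomputed [exact_pvalue_table()] (reuse across
#'   sequences for speed).
#' @param ambiguous `"skip"` (default) or `"background"`.
#' @return A tibble of hits: `seq_id`, `offset`, `strand`, `score` (bits,
#'   on the discretised grid), `p_value`, sorted by offset.
#' @export
scan_sequence <- function(pwm, seq, p_threshold = 1e-4, both_strands = TRUE,
                          seq_id = "seq", table = NULL,
                          ambiguous = c("skip", "background")) {
  ambiguous <- match.arg(ambiguous)
  if (p_threshold <= 0 || p_threshold >= 1) {
    abort("p_threshold must lie in (0, 1)", class = "gretarget_validation_error")
  }
  if (is.null(table)) table <- exact_pvalue_table(pwm)
  L <- ncol(table$ints)
  strands <- if (both_strands) c("+", "-") else "+"
  n <- nchar(seq)
  hits <- lapply(strands, function(st) {
    s <- if (st == "+") seq else revcomp(seq)
    sc <- window_int_scores(table$ints, s, ambiguous)
    if (length(sc) == 0) return(NULL)
    p <- lookup_pvalue(table, sc)
    keep <- which(!is.na(sc) & p < p_threshold)
    if (length(keep) == 0) return(NULL)
    off <- keep - 1L                       # 0-based on scanned strand
    if (st == "-") off <- n - L - off      # map back to forward coordinates
    tibble(seq_id = seq_id, offset = as.integer(off), strand = st,
           score = sc[keep] * table$granularity, p_value = p[keep])
  })
  out <- bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble(seq_id = character(), offset = integer(), strand = character(),
                  score = double(), p_value = double()))
  }
  arrange(out, .data$offset, .data$strand)
}

# integer window scores for all windows of a sequence (NA where a window is
# skipped because of an ambiguous base)
window_int_scores <- function(ints, seq, ambiguous = "skip") {
  codes <- encode_dna(seq)
  L <- ncol(ints)
  W <- length(codes) - L + 1
  if (W <= 0) return(numeric(0))
  sc <- numeric(W)
  nas <- logical(W)
  base_idx <- seq_len(W)
  for (i in seq_len(L)) {
    ci <- codes[base_idx + i - 1L]
    miss <- is.na(ci)
    if (any(miss)) {
      if (ambiguous == "skip") nas <- nas | miss
      ci[miss] <- 1L  # placeholder; contributes 0 below
      contrib <- ints[cbind(ci, i)]
      contrib[miss] <- 0
    } else {
      contrib <- ints[cbind(ci, i)]
    }
    sc <- sc + contrib
  }
  sc[nas] <- NA
  sc
}

#' Composite response-element statistics
#'
#' Summarises, over a set of binding regions, how often the primary motif is
#' present at a stringent and at a lenient threshold, how often at least one
#' auxiliary-family motif is present, and how often an auxiliary motif is
#' present among regions lacking even the lenient primary match (the
#' composite-element picture in which auxiliary factors such as AP-1,
#' ETS/TEAD and FOX substitute for or accompany the primary site).
#'
#' @param region_hits Tibble with one row per region and logical columns
#'   `stringent_primary`, `lenient_primary`, `any_auxiliary`.
#' @return A one-row tibble: `n_regions`, `frac_stringent_primary`,
#'   `frac_lenient_primary`, `frac_any_auxiliary`,
#'   `frac_auxiliary_given_no_primary` (NA when every region has a lenient
#'   primary match).
#' @export
composite_element_stats <- function(region_hits) {
  req <- c("stringent_primary", "lenient_primary", "any_auxiliary")
  missing <- setdiff(req, names(region_hits))
  if (length(missing) > 0) {
    abort(sprintf("region_hits lacks column(s): %s", paste(missing, collapse = ", ")),
          class = "gretarget_schema_error")
  }
  if (nrow(region_hits) == 0) {
    abort("composite statistics are undefined over zero regions",
          class = "gretarget_undefined_error")
  }
  if (any(region_hits$stringent_primary & !region_hits$lenient_primary)) {
    abort("stringent primary hits must be a subset of lenient hits",
          class = "gretarget_validation_error")
  }
  no_primary <- !region_hits$lenient_primary
  tibble(
    n_regions = nrow(region_hits),
    frac_stringent_primary = mean(region_hits$stringent_primary),
    frac_lenient_primary = mean(region_hits$lenient_primary),
    frac_any_auxiliary = mean(region_hits$any_auxiliary),
    frac_auxiliary_given_no_primary =
      if (any(no_primary)) mean(region_hits$any_auxiliary[no_primary]) else NA_real_
  )
}

#' Per-region motif presence flags from sequence scanning
#'
#' Scans each region sequence with the primary PWM at a stringent and a
#' lenient p-value threshold and with a set of auxiliary PWMs, producing the
#' logical flag table consumed by [composite_element_stats()].
#'
#' @param sequences Tibble with `seq_id`, `seq`.
#' @param primary_pwm The primary-factor [pwm()].
#' @param auxiliary_pwms List of auxiliary [pwm()] objects (may be empty).
#' @param stringent_p,lenient_p Retention thresholds (strict `<`).
#' @return Tibble with `seq_id` and the three logical flag columns.
#' @export
scan_region_hits <- function(sequences, primary_pwm, auxiliary_pwms = list(),
                             stringent_p = 1e-4, lenient_p = 1e-3) {
  if (stringent_p > lenient_p) {
    abort("stringent_p must not exceed lenient_p",
          class = "gretarget_validation_error")
  }
  ptab <- exact_pvalue_table(primary_pwm)
  atabs <- lapply(auxiliary_pwms, exact_pvalue_table)
  rows <- purrr::map2(sequences$seq_id, sequences$seq, function(id, s) {
    prim <- scan_sequence(primary_pwm, s, p_threshold = lenient_p,
                          seq_id = id, table = ptab)
    aux <- any(vapply(seq_along(atabs), function(i) {
      nrow(scan_sequence(auxiliary_pwms[[i]], s, p_threshold = stringent_p,
                         seq_id = id, table = atabs[[i]])) > 0
    }, logical(1)))
    tibble(seq_id = id,
           stringent_primary = any(prim$p_value < stringent_p),
           lenient_primary = nrow(prim) > 0,
           any_auxiliary = isTRUE(aux))
  })
  bind_rows(rows)
}
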