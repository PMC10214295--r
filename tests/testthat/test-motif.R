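test_that("log-odds scoring matches the per-position summation oracle", {
  set.seed(31)
  for (L in c(1, 4, 9, 15)) {
    p <- random_pwm(L)
    for (r in 1:5) {
      kmer <- random_dna(L)
      expect_equal(log_odds_score(p, kmer), oracle_log_odds(p, kmer),
                   tolerance = 1e-12)
    }
  }
  # uniform column against uniform background scores zero at that position
  u <- pwm(matrix(0.25, nrow = 4, ncol = 1), pseudocount = 0)
  expect_equal(log_odds_score(u, "C"), 0)
})

test_that("exact p-value table reproduces closed forms for one-hot motifs", {
  for (k in c(3, 5, 8)) {
    p <- one_hot_pwm(strrep("A", k))
    tab <- exact_pvalue_table(p)
    max_int <- sum(apply(tab$ints, 2, max))
    expect_equal(gretarget:::lookup_pvalue(tab, max_int), 0.25^k,
                 tolerance = 1e-9)
    min_int <- sum(apply(tab$ints, 2, min))
    expect_equal(gretarget:::lookup_pvalue(tab, min_int), 1)
    expect_equal(sum(tab$pmf), 1, tolerance = 1e-9)
  }
})

test_that("dynamic-programming null equals exhaustive enumeration for L <= 8", {
  set.seed(37)
  pwms <- list(random_pwm(3), random_pwm(5),
               random_pwm(8, background = c(0.2, 0.3, 0.3, 0.2)),
               one_hot_pwm("ACGTAC"))
  for (p in pwms) {
    tab <- exact_pvalue_table(p)
    enum_p <- oracle_enumeration(p)
    lo <- sum(apply(tab$ints, 2, min))
    hi <- sum(apply(tab$ints, 2, max))
    probe <- unique(round(seq(lo, hi, length.out = 25)))
    for (s in probe) {
      expect_equal(gretarget:::lookup_pvalue(tab, s), enum_p(s),
                   tolerance = 1e-9)
    }
  }
})

test_that("p-values are monotone non-increasing in score", {
  set.seed(41)
  tab <- exact_pvalue_table(random_pwm(10))
  expect_true(all(diff(tab$sf) <= 1e-15))
})

test_that("scanning finds planted consensus sites on both strands", {
  p <- default_gbs_pwm()
  cons <- gsub("N", "A", pwm_consensus(p))
  set.seed(43)
  seq <- random_dna(200)
  substr(seq, 11, 10 + nchar(cons)) <- cons
  hits <- scan_sequence(p, seq, p_threshold = 1e-4)
  fwd <- hits[hits$strand == "+", ]
  expect_true(10 %in% fwd$offset)
  # reverse complement of the whole sequence mirrors the hit set
  rc_hits <- scan_sequence(p, gretarget:::revcomp(seq), p_threshold = 1e-4)
  L <- length(p)
  expect_setequal(nchar(seq) - L - hits$offset, rc_hits$offset)
  expect_equal(sort(hits$p_value), sort(rc_hits$p_value))
  # a planted reverse-complement instance is reported on the minus strand
  seq2 <- random_dna(120)
  substr(seq2, 31, 30 + nchar(cons)) <- gretarget:::revcomp(cons)
  h2 <- scan_sequence(p, seq2, p_threshold = 1e-4)
  expect_true(any(h2$offset == 30 & h2$strand == "-"))
})

test_that("raising the p threshold never removes hits", {
  p <- default_gbs_pwm()
  set.seed(47)
  seq <- random_dna(3000)
  strict <- scan_sequence(p, seq, p_threshold = 1e-4)
  loose <- scan_sequence(p, seq, p_threshold = 1e-3)
  key <- function(h) paste(h$offset, h$strand)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("sequences shorter than the motif yield no hits", {
  p <- default_gbs_pwm()
  expect_equal(nrow(scan_sequence(p, "ACGT")), 0L)
})

test_that("false-positive count on background sequence matches the exact null", {
  p <- random_pwm(8, seed = 53)
  tab <- exact_pvalue_table(p)
  # expected per-window hit probability is the largest attainable p below
  # the threshold (the discrete null cannot realise 1e-4 exactly)
  thr <- 1e-3
  p_star <- max(tab$sf[tab$sf < thr])
  set.seed(59)
  n_seq <- 200; len <- 1000; L <- 8
  counts <- vapply(seq_len(n_seq), function(i) {
    nrow(scan_sequence(p, random_dna(len), p_threshold = thr, table = tab))
  }, numeric(1))
  expected <- 2 * (len - L + 1) * p_star * n_seq
  sd3 <- 3 * sqrt(expected)  # Poisson-scale spread
  expect_lt(abs(sum(counts) - expected), sd3)
})

test_that("composite-element statistics match direct fraction computation", {
  rh <- tibble::tibble(stringent_primary = c(FALSE, FALSE, TRUE, FALSE),
                       lenient_primary = c(TRUE, FALSE, TRUE, FALSE),
                       any_auxiliary = c(TRUE, TRUE, FALSE, FALSE))
  s <- composite_element_stats(rh)
  expect_equal(s$frac_lenient_primary, 0.5)
  expect_equal(s$frac_any_auxiliary, 0.5)
  expect_equal(s$frac_stringent_primary, 0.25)
  expect_equal(s$frac_auxiliary_given_no_primary, 0.5)
  all_p <- tibble::tibble(stringent_primary = TRUE, lenient_primary = TRUE,
                          any_auxiliary = FALSE)
  s2 <- composite_element_stats(all_p)
  expect_equal(s2$frac_stringent_primary, 1)
  expect_equal(s2$frac_lenient_primary, 1)
  expect_true(is.na(s2$frac_auxiliary_given_no_primary))
  expect_error(composite_element_stats(rh[0, ]),
               class = "gretarget_undefined_error")
  expect_error(composite_element_stats(
    tibble::tibble(stringent_primary = TRUE, lenient_primary = FALSE,
                   any_auxiliary = FALSE)),
    class = "gretarget_validation_error")
})

test_that("composite fractions recover planting probabilities at n = 1000", {
  set.seed(61)
  n <- 1000
  stringent <- runif(n) < 0.4
  lenient <- stringent | (runif(n) < (0.8 - 0.4) / 0.6)  # marginal 0.8
  aux <- runif(n) < 0.95
  s <- composite_element_stats(tibble::tibble(
    stringent_primary = stringent, lenient_primary = lenient,
    any_auxiliary = aux))
  expect_lt(abs(s$frac_stringent_primary - 0.4), 3 * sqrt(0.4 * 0.6 / n))
  expect_lt(abs(s$frac_lenient_primary - 0.8), 3 * sqrt(0.8 * 0.2 / n))
  expect_lt(abs(s$frac_any_auxiliary - 0.95), 3 * sqrt(0.95 * 0.05 / n))
})

test_that("scan_region_hits builds the flag table from planted sequences", {
  primary <- default_gbs_pwm()
  cons <- gsub("N", "A", pwm_consensus(primary))
  aux <- one_hot_pwm("TGACTCAG")  # AP-1-like
  set.seed(67)
  s1 <- random_dna(300); substr(s1, 51, 50 + nchar(cons)) <- cons
  s2 <- random_dna(300); substr(s2, 101, 108) <- "TGACTCAG"
  s3 <- random_dna(300)
  rh <- scan_region_hits(tibble::tibble(seq_id = c("r1", "r2", "r3"),
                                        seq = c(s1, s2, s3)),
                         primary, list(aux))
  expect_true(rh$stringent_primary[rh$seq_id == "r1"])
  expect_true(rh$any_auxiliary[rh$seq_id == "r2"])
  expect_false(rh$lenient_primary[rh$seq_id == "r2"])
})
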