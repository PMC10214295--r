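gre_row <- function(name, gene, start, end, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = as.integer(start), end = as.integer(end),
                 name = name, gene_id = gene, signed_distance = 0L,
                 abs_distance = 0L, locality = "proximal")
}

test_that("open chromatin score sums per-site max class weights", {
  w <- c(low = 0.3, high = 0.8, top = 0.9)
  oc <- tibble::tibble(chrom = "chr1", start = c(100L, 150L, 900L),
                       end = c(300L, 250L, 1000L),
                       chromatin_class = c("high", "top", "low"))
  one <- gre_row("p1", "g1", 120, 220)
  expect_equal(open_chromatin_score(one, oc[1, ], w)$open_chromatin_score, 0.8)
  two <- dplyr::bind_rows(one, gre_row("p2", "g1", 150, 280))
  expect_equal(open_chromatin_score(two, oc[1, ], w)$open_chromatin_score, 1.6)
  # stacked annotations: max rule picks 0.9, sum rule adds
  s_max <- open_chromatin_score(one, oc, w, rule = "max")
  expect_equal(s_max$open_chromatin_score, 0.9)
  s_sum <- open_chromatin_score(one, oc, w, rule = "sum")
  expect_equal(s_sum$open_chromatin_score, 0.8 + 0.9)
  expect_error(open_chromatin_score(one, dplyr::mutate(oc, chromatin_class = "mystery"), w),
               class = "gretarget_config_error")
})

test_that("enhancer-target score only counts enhancers targeting the same gene", {
  links <- tibble::tibble(chrom = "chr1", start = c(100L, 100L),
                          end = c(400L, 400L),
                          target_gene = c("g1", "g2"),
                          association_score = c(12.5, 99))
  g1 <- gre_row("p1", "g1", 150, 350)
  expect_equal(enhancer_target_score(g1, links[1, ])$enhancer_target_score, 12.5)
  expect_equal(enhancer_target_score(g1, links[2, ])$enhancer_target_score, 0)
  expect_equal(enhancer_target_score(g1, links)$enhancer_target_score, 12.5)
})

test_that("enhancer-target score equals the double-loop brute force", {
  set.seed(83)
  gres <- random_intervals(60)[, c("chrom", "start", "end", "name")]
  gres$gene_id <- sample(sprintf("g%d", 1:8), 60, replace = TRUE)
  links <- random_intervals(40)[, c("chrom", "start", "end")]
  links$target_gene <- sample(sprintf("g%d", 1:8), 40, replace = TRUE)
  links$association_score <- round(runif(40, 0, 20), 2)
  got <- enhancer_target_score(gres, links)
  want <- vapply(got$gene_id, function(g) {
    total <- 0
    for (i in which(gres$gene_id == g)) {
      for (j in seq_len(nrow(links))) {
        if (links$target_gene[j] == g && gres$chrom[i] == links$chrom[j] &&
            gres$start[i] < links$end[j] && links$start[j] < gres$end[i]) {
          total <- total + links$association_score[j]
        }
      }
    }
    total
  }, numeric(1))
  expect_equal(got$enhancer_target_score, unname(want))
})

test_that("motif number totals retained hits across a gene's sites", {
  gres <- dplyr::bind_rows(gre_row("p1", "g1", 1, 100),
                           gre_row("p2", "g1", 200, 300),
                           gre_row("p3", "g2", 400, 500))
  hits <- tibble::tibble(seq_id = c("p1", rep("p2", 3)))
  m <- motif_number(gres, hits)
  expect_equal(m$motif_count[m$gene_id == "g1"], 4L)
  expect_equal(m$motif_count[m$gene_id == "g2"], 0L)
})

test_that("feature scaling follows the min-max formula with degenerate rule", {
  expect_equal(feature_scale(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(feature_scale(c(5, 5, 5)), c(0, 0, 0))
  set.seed(89)
  v <- rnorm(50)
  expect_equal(feature_scale(v), (v - min(v)) / (max(v) - min(v)))
})

test_that("NAS is the sum of the three normalized features with bounds check", {
  expect_equal(normalized_annotation_score(0.5, 1.0, 0.25), 1.75)
  expect_equal(normalized_annotation_score(0, 0, 0), 0)
  expect_error(normalized_annotation_score(1.2, 0, 0),
               class = "gretarget_validation_error")
})

test_that("rank product matches hand-computed values including ties", {
  dec <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)
  nas <- c(3, 2.9, 2.8, 2.7, 2.6, 2.5, 2.4, 2.3, 2.2, 2.1)
  rp <- rank_product(dec, nas)
  expect_equal(rp$rank_product[1], 0.01)   # rank 1 on both, n = 10
  expect_equal(rp$rank_product[10], 1.0)   # rank 10 on both
  # 2-way tie at the top: both share rank 1.5
  dec2 <- c(5, 5, 3, 2); nas2 <- c(9, 8, 7, 6)
  rp2 <- rank_product(dec2, nas2)
  expect_equal(rp2$rank_dec[1:2], c(1.5, 1.5))
  expect_equal(rp2$rank_product[1], (1.5 / 4) * (1 / 4))
  expect_equal(rp2$rank_product[2], (1.5 / 4) * (2 / 4))
  expect_error(rank_product(1:3, 1:4), class = "gretarget_validation_error")
})

test_that("rank product stays within [1/n^2, 1]", {
  set.seed(97)
  for (r in 1:5) {
    n <- sample(3:40, 1)
    rp <- rank_product(rnorm(n), rnorm(n))
    expect_true(all(rp$rank_product >= 1 / n^2 - 1e-12))
    expect_true(all(rp$rank_product <= 1 + 1e-12))
  }
})

make_mini_universe <- function() {
  genes <- tibble::tibble(
    gene_id = c("hero", "mid", "dud"),
    chrom = "chr1", strand = "+",
    tss = c(100000L, 400000L, 700000L),
    log2fc = c(4, 1.5, 1.0), padj = c(0.001, 0.01, 0.01),
    de_status = c("up", "up", "up"))
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(101000L, 105000L, 110000L, 401000L),
    end = c(101400L, 105400L, 110400L, 401400L),
    name = c("pk1", "pk2", "pk3", "pk4"))
  oc <- tibble::tibble(chrom = "chr1",
                       start = c(101000L, 105000L, 110000L),
                       end = c(101400L, 105400L, 110400L),
                       chromatin_class = "open")
  w <- c(open = 0.9)
  enh <- tibble::tibble(chrom = "chr1", start = c(101000L, 105000L),
                        end = c(101500L, 105500L),
                        target_gene = "hero", association_score = c(10, 15))
  p <- default_gbs_pwm()
  cons <- gsub("N", "A", pwm_consensus(p))
  set.seed(101)
  seqs <- tibble::tibble(
    seq_id = peaks$name,
    seq = vapply(seq_len(4), function(i) random_dna(400), character(1)))
  substr(seqs$seq[1], 50, 49 + nchar(cons)) <- cons
  substr(seqs$seq[2], 50, 49 + nchar(cons)) <- cons
  list(genes = genes, peaks = peaks, oc = oc, w = w, enh = enh,
       pwm = p, seqs = seqs)
}

test_that("a gene dominant on every feature and fold change ranks first", {
  u <- make_mini_universe()
  r <- rank_direct_targets(u$genes, u$peaks, u$oc, u$w, u$enh, u$pwm, u$seqs)
  expect_equal(r$gene_id[1], "hero")
  expect_equal(r$rank_product[1], (1 / 3) * (1 / 3))
  # zero-GRE gene stays in the ranking with all-zero annotation scores
  dud <- r[r$gene_id == "dud", ]
  expect_equal(dud$n_gres, 0L)
  expect_equal(dud$nas, 0)
  expect_equal(nrow(r), 3L)
})

test_that("the ranking table is invariant under input row permutation", {
  u <- make_mini_universe()
  r1 <- rank_direct_targets(u$genes, u$peaks, u$oc, u$w, u$enh, u$pwm, u$seqs)
  set.seed(103)
  r2 <- rank_direct_targets(u$genes[c(3, 1, 2), ], u$peaks[sample.int(4), ],
                            u$oc[sample.int(3), ], u$w, u$enh[2:1, ],
                            u$pwm, u$seqs[sample.int(4), ])
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("ranking requires differentially expressed genes", {
  u <- make_mini_universe()
  genes <- dplyr::mutate(u$genes, de_status = "not_de")
  expect_error(rank_direct_targets(genes, u$peaks, u$oc, u$w, u$enh, u$pwm, u$seqs),
               class = "gretarget_validation_error")
})

test_that("NAS-only mode excludes genes without open-chromatin support", {
  u <- make_mini_universe()
  # mid's peak (pk4) overlaps no open chromatin: hard filter removes the gene
  r <- rank_tf_targets_nas_only(u$genes, u$peaks, u$oc, u$w,
                                enhancers = u$enh, pwm = u$pwm, sequences = u$seqs)
  expect_true("hero" %in% r$gene_id)
  expect_false("mid" %in% r$gene_id)
  expect_false("dud" %in% r$gene_id)
})

test_that("widening the NAS-only window never shrinks the candidate set", {
  b <- simulate_target_dataset(synthetic_config(n_genes = 150, n_direct_targets = 8,
                                                seed = 5, with_matrices = FALSE))
  w <- stats::setNames(b$class_weights$weight, b$class_weights$chromatin_class)
  narrow <- rank_tf_targets_nas_only(b$genes, b$peaks, b$open_chromatin, w,
                                     cfg = window_config(window_bp = 100000L))
  wide <- rank_tf_targets_nas_only(b$genes, b$peaks, b$open_chromatin, w,
                                   cfg = window_config(window_bp = 150000L))
  expect_true(all(narrow$gene_id %in% wide$gene_id))
})

test_that("glance and autoplot summarise a ranking", {
  u <- make_mini_universe()
  r <- rank_direct_targets(u$genes, u$peaks, u$oc, u$w, u$enh, u$pwm, u$seqs)
  g <- glance(r)
  expect_equal(g$mode, "rank_product")
  expect_equal(g$n_genes, 3L)
  expect_s3_class(autoplot(r), "ggplot")
})
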