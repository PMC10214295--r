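test_that("peak-to-gene association matches the direct distance examples", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 1000000L)
  peak_at <- function(center) tibble::tibble(chrom = "chr1",
                                             start = center - 100L,
                                             end = center + 100L,
                                             name = "p")
  g <- assign_peaks_to_genes(peak_at(1050000L), genes)
  expect_equal(g$abs_distance, 50000L)
  expect_equal(g$locality, "distal")
  expect_equal(nrow(assign_peaks_to_genes(peak_at(1151000L), genes)), 0L)
  # exactly at the window edge is kept (inclusive)
  expect_equal(nrow(assign_peaks_to_genes(peak_at(1150000L), genes)), 1L)
})

test_that("association equals the all-pairs brute-force scan on random input", {
  set.seed(7)
  peaks <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 100, replace = TRUE),
                          start = sample.int(3e6, 100))
  peaks$end <- peaks$start + sample.int(1000, 100)
  peaks$name <- sprintf("p%03d", 1:100)
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:20),
                          chrom = sample(c("chr1", "chr2"), 20, replace = TRUE),
                          tss = sample.int(3e6, 20))
  got <- assign_peaks_to_genes(peaks, genes, window_config(window_bp = 150000L))
  want <- oracle_assign(peaks, genes, window = 150000)
  expect_equal(got[, c("name", "gene_id", "signed_distance", "locality")],
               want)
})

test_that("association is deterministic and input-order invariant", {
  set.seed(11)
  peaks <- random_intervals(60)[, c("chrom", "start", "end", "name")]
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:15),
                          chrom = sample(c("chr1", "chr2", "chrX"), 15, replace = TRUE),
                          tss = sample.int(1e6, 15))
  a <- assign_peaks_to_genes(peaks, genes)
  b <- assign_peaks_to_genes(peaks[sample.int(60), ], genes[sample.int(15), ])
  expect_equal(a, b)
})

test_that("shrinking the window never adds associations", {
  set.seed(13)
  peaks <- random_intervals(80)[, c("chrom", "start", "end", "name")]
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:10),
                          chrom = sample(c("chr1", "chr2"), 10, replace = TRUE),
                          tss = sample.int(1e6, 10))
  keys <- function(g) paste(g$name, g$gene_id)
  wide <- assign_peaks_to_genes(peaks, genes, window_config(window_bp = 150000L))
  for (w in c(100000L, 50000L, 10000L)) {
    narrow <- assign_peaks_to_genes(peaks, genes, window_config(window_bp = w))
    expect_true(all(keys(narrow) %in% keys(wide)))
    wide <- narrow
  }
})

test_that("empty gene list yields an empty result with a warning", {
  peaks <- tibble::tibble(chrom = "chr1", start = 1L, end = 10L)
  genes <- tibble::tibble(gene_id = character(), chrom = character(), tss = integer())
  expect_warning(g <- assign_peaks_to_genes(peaks, genes), "empty gene list")
  expect_equal(nrow(g), 0L)
})

test_that("locality boundaries follow the inclusive 3 kb proximal cutoff", {
  expect_equal(classify_locality(c(0L, 3000L, 3001L)),
               c("proximal", "proximal", "distal"))
  expect_error(classify_locality(-1L), class = "gretarget_validation_error")
})

test_that("distal_fraction counts distal associations and rejects empty input", {
  g <- tibble::tibble(locality = c(rep("distal", 19), "proximal"))
  expect_equal(distal_fraction(g), 0.95)
  expect_equal(distal_fraction(tibble::tibble(locality = rep("proximal", 4))), 0)
  expect_error(distal_fraction(g[0, ]), class = "gretarget_undefined_error")
})

test_that("half-open overlap predicate matches exhaustive small-case enumeration", {
  cases <- expand.grid(a = 0:4, b = 0:4, c = 0:4, d = 0:4)
  cases <- cases[cases$a < cases$b & cases$c < cases$d, ]
  for (i in seq_len(nrow(cases))) {
    x <- tibble::tibble(chrom = "c", start = cases$a[i], end = cases$b[i])
    y <- tibble::tibble(chrom = "c", start = cases$c[i], end = cases$d[i])
    expect_identical(nrow(gretarget:::overlap_pairs(x, y)) == 1L,
                     cases$a[i] < cases$d[i] && cases$c[i] < cases$b[i])
  }
})

test_that("open-chromatin filtering honours any/intersection semantics", {
  gres <- tibble::tibble(chrom = "chr1", start = c(100L, 5000L), end = c(300L, 5200L),
                         name = c("p1", "p2"), gene_id = "g1",
                         signed_distance = 0L, abs_distance = 0L,
                         locality = "proximal")
  islet <- tibble::tibble(chrom = "chr1", start = 150L, end = 250L)
  endoc <- tibble::tibble(chrom = "chr1", start = c(120L, 5100L), end = c(180L, 5400L))
  # p1 overlaps both sets, p2 only endoc
  both <- filter_by_open_chromatin(gres, list(islet, endoc), mode = "intersection")
  expect_equal(both$name, "p1")
  any_ <- filter_by_open_chromatin(gres, list(islet, endoc), mode = "any")
  expect_equal(any_$name, c("p1", "p2"))
})

test_that("open-chromatin filtering equals the brute-force double loop", {
  set.seed(29)
  gres <- random_intervals(120)[, c("chrom", "start", "end", "name")]
  gres$gene_id <- "g"
  oc1 <- random_intervals(40)[, c("chrom", "start", "end")]
  oc2 <- random_intervals(40)[, c("chrom", "start", "end")]
  got_any <- filter_by_open_chromatin(gres, list(oc1, oc2), mode = "any")
  got_int <- filter_by_open_chromatin(gres, list(oc1, oc2), mode = "intersection")
  h1 <- oracle_overlaps(gres, oc1); h2 <- oracle_overlaps(gres, oc2)
  expect_equal(got_any$name, gres$name[h1 | h2])
  expect_equal(got_int$name, gres$name[h1 & h2])
})
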