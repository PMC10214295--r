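#' Read a BED file of genomic intervals
#'
#' Parses BED3/BED4/BED6 into a tibble of half-open, 0-based intervals.
#' Coordinates are taken verbatim: no chromosome-name normalisation is
#' applied, and 1-based inputs must be converted with `one_based = TRUE`
#' at this boundary.
#'
#' @param path Path to a tab-separated BED file without header.
#' @param expect_class_column If `TRUE`, column 4 is interpreted as a
#'   chromatin-class label and returned as `chromatin_class` (open-chromatin
#'   dialect) instead of `name`.
#' @param one_based If `TRUE`, input coordinates are 1-based inclusive and
#'   are converted to the package's 0-based half-open convention.
#' @return A tibble with columns `chrom`, `start`, `end`, then `name`,
#'   `score`, `strand` (BED dialect) or `chromatin_class` (open-chromatin
#'   dialect). Absent optional fields are `NA`.
#' @examples
#' p <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tpeakA", p)
#' read_bed(p)
#' @export
read_bed <- function(path, expect_class_column = FALSE, one_based = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("BED file not found: %s", path), class = "gretarget_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = double(), strand = character())
    if (expect_class_column) {
      out <- select(rename(out, chromatin_class = "name"),
                    "chrom", "start", "end", "chromatin_class")
    }
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("malformed BED record at line %d: fewer than 3 columns",
                  which(nf < 3)[1]),
          class = "gretarget_parse_error")
  }
  col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, character(1))
  start <- suppressWarnings(as.integer(col(2)))
  end <- suppressWarnings(as.integer(col(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    abort(sprintf("malformed BED record at line %d: non-integer coordinates", bad[1]),
          class = "gretarget_parse_error")
  }
  if (one_based) start <- start - 1L
  out <- tibble(chrom = col(1), start = start, end = end,
                name = col(4),
                score = suppressWarnings(as.double(col(5))),
                strand = col(6))
  out$name[!is.na(out$name) & out$name == "."] <- NA_character_
  out$strand[!out$strand %in% c("+", "-", ".")] <- NA_character_
  validate_intervals(out, what = "BED")
  if (expect_class_column) {
    if (any(is.na(out$name))) {
      abort("expect_class_column = TRUE but a record lacks column 4",
            class = "gretarget_parse_error")
    }
    out <- select(rename(out, chromatin_class = "name"),
                  "chrom", "start", "end", "chromatin_class")
  }
  out
}

#' Write intervals to a BED file
#'
#' Inverse of [read_bed()]: writes 0-based half-open records; reading the
#' file back yields the identical tibble.
#'
#' @param x A tibble of intervals (`chrom`, `start`, `end`, optionally
#'   `name`/`chromatin_class`, `score`, `strand`).
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, what = "BED")
  pick <- function(nm, default) if (nm %in% names(x)) x[[nm]] else rep(default, nrow(x))
  name <- if ("chromatin_class" %in% names(x)) x$chromatin_class else pick("name", NA_character_)
  score <- pick("score", NA_real_)
  strand <- pick("strand", NA_character_)
  fmt_num <- function(v) ifelse(is.na(v), NA_character_, format(v, digits = 15, scientific = FALSE, trim = TRUE))
  m <- cbind(x$chrom, x$start, x$end, name, fmt_num(score), strand)
  # trim trailing all-NA columns so BED3/BED4/BED6 round-trip exactly
  keep <- 3
  for (j in 4:6) if (any(!is.na(m[, j]))) keep <- j
  if (nrow(x) == 0) keep <- if ("chromatin_class" %in% names(x)) 4 else 6
  m <- m[, seq_len(keep), drop = FALSE]
  m[is.na(m)] <- "."
  writeLines(apply(m, 1, paste, collapse = "\t"), path)
  invisible(x)
}
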