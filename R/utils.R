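# Shared internal helpers: interval validation, overlap joins, seed streams.

# Columns every interval tibble carries; name/score/strand are optional on
# input and filled with NA when absent.
interval_cols <- c("chrom", "start", "end")

validate_intervals <- function(x, what = "interval") {
  if (!is.data.frame(x)) {
    abort(sprintf("%s input must be a data frame", what),
          class = "gretarget_validation_error")
  }
  missing <- setdiff(interval_cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s input lacks column(s): %s", what,
                  paste(missing, collapse = ", ")),
          class = "gretarget_schema_error")
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    abort(sprintf("%s records with empty chrom", what),
          class = "gretarget_validation_error")
  }
  if (any(x$start < 0)) {
    abort(sprintf("%s records with negative start", what),
          class = "gretarget_validation_error")
  }
  bad <- which(x$start >= x$end)
  if (length(bad) > 0) {
    abort(sprintf("%s record %d has start >= end (%d >= %d)", what,
                  bad[1], x$start[bad[1]], x$end[bad[1]]),
          class = "gretarget_validation_error")
  }
  invisible(x)
}

# Overlap join between two interval tibbles under BED half-open coordinates:
# [a,b) and [c,d) overlap iff a < d and c < b (>= 1 shared base).
# Returns a tibble of row indices (idx_a, idx_b).
overlap_pairs <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(idx_a = integer(), idx_b = integer()))
  }
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  res <- lapply(chroms, function(ch) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    # IRanges is 1-based closed; half-open [s,e) maps to [s+1, e]
    ra <- IRanges::IRanges(start = a$start[ia] + 1L, end = a$end[ia])
    rb <- IRanges::IRanges(start = b$start[ib] + 1L, end = b$end[ib])
    hits <- IRanges::findOverlaps(ra, rb)
    tibble(idx_a = ia[S4Vectors::queryHits(hits)],
           idx_b = ib[S4Vectors::subjectHits(hits)])
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) tibble(idx_a = integer(), idx_b = integer()) else out
}

# Deterministic per-stream seeds derived from one master seed so that adding
# or skipping one output stream never perturbs the others. Offsets are fixed
# per stream label; results stay well below 2^31.
stream_seed <- function(seed, stream) {
  offsets <- c(genes = 1L, peaks = 2L, open_chromatin = 3L, enhancers = 4L,
               sequences = 5L, expression = 6L, counts = 7L, rpkm = 8L,
               null_permutation = 9L)
  if (!stream %in% names(offsets)) {
    abort(sprintf("unknown RNG stream '%s'", stream))
  }
  (as.integer(seed) %% 2013265L) * 1000L + offsets[[stream]]
}

with_stream_seed <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, stream))
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
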