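#' Construct a position weight matrix object
#'
#' A `pwm` stores per-position base probabilities over A, C, G, T together
#' with a 0-order background model and the pseudocount used to regularise
#' the probabilities before log-odds scoring. Pseudocounts are applied as
#' `p' = (p + pseudocount * background) / (1 + pseudocount)`, so every
#' column sums to one after regularisation.
#'
#' @param matrix A 4 x L numeric matrix of probabilities, rows named
#'   A, C, G, T (or an L x 4 matrix, transposed automatically).
#' @param motif_id Identifier string.
#' @param background Length-4 background probabilities (A, C, G, T);
#'   defaults to uniform.
#' @param pseudocount Non-negative regularisation weight (default 0.1).
#' @param tol Tolerance for the column-sum check on the input matrix.
#' @return An object of class `pwm`.
#' @examples
#' m <- matrix(c(0.97, 0.01, 0.01, 0.01), nrow = 4,
#'             dimnames = list(c("A", "C", "G", "T"), NULL))
#' pwm(m, motif_id = "one_hot_A")
#' @export
pwm <- function(matrix, motif_id = "motif", background = rep(0.25, 4),
                pseudocount = 0.1, tol = 0.01) {
  if (nrow(matrix) != 4 && ncol(matrix) == 4) matrix <- t(matrix)
  if (nrow(matrix) != 4) {
    abort("PWM matrix must have 4 rows (A, C, G, T)",
          class = "gretarget_validation_error")
  }
  if (ncol(matrix) < 1) {
    abort("PWM must have at least one column", class = "gretarget_validation_error")
  }
  rownames(matrix) <- c("A", "C", "G", "T")
  sums <- colSums(matrix)
  if (any(abs(sums - 1) > tol)) {
    abort(sprintf("PWM column %d sums to %.4f, not ~1", which(abs(sums - 1) > tol)[1],
                  sums[which(abs(sums - 1) > tol)[1]]),
          class = "gretarget_validation_error")
  }
  background <- as.double(background)
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-6 || any(background <= 0)) {
    abort("background must be 4 positive probabilities summing to 1",
          class = "gretarget_validation_error")
  }
  names(background) <- c("A", "C", "G", "T")
  if (pseudocount < 0) {
    abort("pseudocount must be non-negative", class = "gretarget_validation_error")
  }
  prob <- sweep(matrix, 1, background * pseudocount, "+") / (1 + pseudocount)
  prob <- sweep(prob, 2, colSums(prob), "/")
  structure(list(motif_id = motif_id, raw = matrix, prob = prob,
                 background = background, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s: %d positions, pseudocount %g\n",
              x$motif_id, ncol(x$prob), x$pseudocount))
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' @export
length.pwm <- function(x) ncol(x$prob)

#' Consensus sequence of a PWM (argmax base per position)
#' @param x A [pwm()] object.
#' @return A character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$prob)[apply(x$prob, 2, which.max)], collapse = "")
}

#' Read motifs in MEME minimal format
#'
#' Parses the MEME minimal text format (version line, optional alphabet,
#' strands and background lines, then one letter-probability matrix per
#' motif). When the file carries no background line a uniform background is
#' assumed.
#'
#' @param path Path to a MEME-format motif file.
#' @param pseudocount Pseudocount applied to each parsed matrix.
#' @return A named list of [pwm()] objects.
#' @export
read_meme_motifs <- function(path, pseudocount = 0.1) {
  if (!file.exists(path)) {
    abort(sprintf("MEME file not found: %s", path), class = "gretarget_io_error")
  }
  lines <- trimws(readLines(path))
  if (!any(grepl("^MEME version", lines))) {
    abort("not a MEME minimal-format file (missing 'MEME version' line)",
          class = "gretarget_parse_error")
  }
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) == 1 && bg_at < length(lines)) {
    toks <- strsplit(lines[bg_at + 1], "\\s+")[[1]]
    vals <- suppressWarnings(as.double(toks[c(FALSE, TRUE)]))
    bases <- toks[c(TRUE, FALSE)]
    if (!anyNA(vals) && setequal(bases, c("A", "C", "G", "T"))) {
      background <- vals[match(c("A", "C", "G", "T"), bases)]
      background <- background / sum(background)
    }
  }
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0) {
    abort("MEME file contains no MOTIF blocks", class = "gretarget_parse_error")
  }
  motifs <- lapply(seq_along(starts), function(k) {
    id <- strsplit(lines[starts[k]], "\\s+")[[1]][2]
    from <- starts[k]
    to <- if (k < length(starts)) starts[k + 1] - 1 else length(lines)
    block <- lines[from:to]
    hdr <- grep("^letter-probability matrix", block)
    if (length(hdr) != 1) {
      abort(sprintf("motif %s lacks a letter-probability matrix header", id),
            class = "gretarget_parse_error")
    }
    rows <- block[(hdr + 1):length(block)]
    rows <- rows[grepl("^[0-9.eE+\\-]+(\\s+[0-9.eE+\\-]+){3}$", rows)]
    if (length(rows) == 0) {
      abort(sprintf("motif %s has an empty probability matrix", id),
            class = "gretarget_parse_error")
    }
    m <- do.call(rbind, lapply(strsplit(rows, "\\s+"), as.double))
    pwm(t(m), motif_id = id, background = background, pseudocount = pseudocount)
  })
  setNames(motifs, vapply(motifs, function(p) p$motif_id, character(1)))
}

#' Write motifs in MEME minimal format
#'
#' @param motifs A [pwm()] object or list of them.
#' @param path Output path.
#' @return `motifs`, invisibly.
#' @export
write_meme_motifs <- function(motifs, path) {
  if (inherits(motifs, "pwm")) motifs <- list(motifs)
  bg <- motifs[[1]]$background
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3], bg[4]),
               ""), con)
  for (p in motifs) {
    writeLines(sprintf("MOTIF %s", p$motif_id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       ncol(p$raw)), con)
    writeLines(apply(p$raw, 2, function(col) paste(sprintf("%.9f", col), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(motifs)
}
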