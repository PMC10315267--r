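blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Global protein alignment with affine gaps (needle semantics)
#'
#' Optimal global alignment under three-state affine-gap dynamic programming:
#' a gap of length L costs `gap_open + L * gap_extend`, and terminal gaps are
#' free unless `penalize_end_gaps = TRUE` (matching the EMBOSS needle
#' defaults). Percent identity is computed over the full alignment length,
#' gap columns included. The traceback is deterministic (ties prefer an
#' aligned pair, then a gap in `a`, then a gap in `b`); the score itself does
#' not depend on the tie-break.
#'
#' @param a,b Protein sequences (single non-empty strings, or named
#'   length-one vectors as returned by [read_fasta()]).
#' @param matrix Substitution matrix with residue dimnames; default BLOSUM62.
#' @param gap_open Gap opening penalty (default 10).
#' @param gap_extend Gap extension penalty per position (default 0.5).
#' @param penalize_end_gaps Charge terminal gaps too (default `FALSE`).
#' @return An `alignment_result` object with `aligned_a`, `aligned_b`,
#'   `score`, `identity_count`, `alignment_length`, `percent_identity`.
#' @export
global_affine_align <- function(a, b, matrix = NULL, gap_open = 10,
                                gap_extend = 0.5, penalize_end_gaps = FALSE) {
  if (is.null(matrix)) matrix <- blosum62_matrix()
  prep <- function(s, label) {
    if (!is.character(s) || length(s) != 1 || is.na(s) || nchar(s) == 0) {
      abort(sprintf("Sequence '%s' must be a single non-empty string.", label))
    }
    ch <- strsplit(toupper(s), "")[[1]]
    idx <- match(ch, rownames(matrix))
    if (anyNA(idx)) {
      pos <- which(is.na(idx))[1]
      abort(sprintf("Unknown residue '%s' at position %d of sequence '%s'.",
                    ch[pos], pos, label))
    }
    list(chars = ch, idx = idx - 1L)
  }
  pa <- prep(unname(a), "a")
  pb <- prep(unname(b), "b")
  res <- affine_align_cpp(pa$idx, pb$idx, matrix, gap_open, gap_extend,
                          penalize_end_gaps)
  col_a <- rep("-", length(res$a_index))
  col_b <- rep("-", length(res$b_index))
  col_a[res$a_index >= 0] <- pa$chars[res$a_index[res$a_index >= 0] + 1L]
  col_b[res$b_index >= 0] <- pb$chars[res$b_index[res$b_index >= 0] + 1L]
  ident <- sum(col_a == col_b & col_a != "-")
  len <- length(col_a)
  structure(
    list(
      aligned_a = paste(col_a, collapse = ""),
      aligned_b = paste(col_b, collapse = ""),
      score = res$score,
      identity_count = as.integer(ident),
      alignment_length = as.integer(len),
      percent_identity = 100 * ident / len,
      gap_open = gap_open,
      gap_extend = gap_extend,
      penalize_end_gaps = penalize_end_gaps,
      names = c(a = names(a) %||% "a", b = names(b) %||% "b")
    ),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, width = 60, ...) {
  cat(sprintf("<alignment_result> %s vs %s\n", x$names[["a"]], x$names[["b"]]))
  cat(sprintf("  score %.1f | length %d | identity %d/%d (%.1f%%)\n",
              x$score, x$alignment_length, x$identity_count,
              x$alignment_length, x$percent_identity))
  a <- strsplit(x$aligned_a, "")[[1]]
  b <- strsplit(x$aligned_b, "")[[1]]
  marks <- ifelse(a == b & a != "-", "|", " ")
  for (s in seq(1, length(a), by = width)) {
    e <- min(s + width - 1, length(a))
    cat("  ", paste(a[s:e], collapse = ""), "\n", sep = "")
    cat("  ", paste(marks[s:e], collapse = ""), "\n", sep = "")
    cat("  ", paste(b[s:e], collapse = ""), "\n\n", sep = "")
  }
  invisible(x)
}

#' @rdname global_affine_align
#' @param x An `alignment_result` object.
#' @param ... Unused.
#' @export
tidy.alignment_result <- function(x, ...) {
  tibble(
    name_a = x$names[["a"]], name_b = x$names[["b"]], score = x$score,
    alignment_length = x$alignment_length, identity_count = x$identity_count,
    percent_identity = x$percent_identity
  )
}

#' Write an alignment as plain text plus a one-line TSV summary
#'
#' @param x An `alignment_result` object.
#' @param path Output path for the plain-text alignment; the summary is
#'   written next to it as `<path>.tsv`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path) {
  stopifnot(inherits(x, "alignment_result"))
  con <- file(path, "w")
  on.exit(close(con))
  sink(con)
  print(x)
  sink()
  readr::write_tsv(tidy(x), paste0(path, ".tsv"), progress = FALSE)
  invisible(path)
}
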