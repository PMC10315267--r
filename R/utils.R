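#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble is_tibble
NULL

# AGI locus identifiers: AT + chromosome (1-5, C, M) + G + 5 digits.
.agi_pattern <- "^AT[1-5CM]G[0-9]{5}$"

is_agi_locus <- function(x) grepl(.agi_pattern, toupper(x))

assert_agi <- function(x, what = "locus") {
  bad <- unique(x[!is_agi_locus(x)])
  if (length(bad) > 0) {
    abort(sprintf(
      "Invalid AGI %s identifier(s): %s (expected 'AT#G#####').",
      what, paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  toupper(x)
}

assert_count_values <- function(x, where) {
  if (any(is.na(x))) {
    i <- which(is.na(x))[1]
    abort(sprintf("Unparseable or missing count at %s.", where(i)))
  }
  if (any(x < 0) || any(x != trunc(x))) {
    i <- which(x < 0 | x != trunc(x))[1]
    abort(sprintf("Counts must be non-negative integers; offending cell at %s.", where(i)))
  }
  invisible(x)
}

# deterministic ordering used for reported interactor sets:
# descending maximum spectra, ties broken by locus
order_by_spectra <- function(max_spectra, locus) {
  order(-max_spectra, locus, method = "radix")
}
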