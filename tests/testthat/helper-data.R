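# small in-code fixture builders

# spectral-count object from a named count specification:
# counts: matrix with rownames = loci, colnames = run ids (BAIT_ZT<t>_<rep>)
make_counts <- function(counts, unique_peptides = NULL) {
  runs <- chronoprot:::parse_run_headers(colnames(counts))
  proteins <- tibble::tibble(
    protein_name = rownames(counts),
    agi_locus = rownames(counts),
    mw_kda = 50,
    cycling = NA
  )
  spectral_counts(proteins, runs, counts, unique_peptides = unique_peptides)
}

# cosine trace sampled hourly
make_trace <- function(hours = 120, period = 24, peak = 4, amp = 2,
                       base = 5, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, hours - 1)
  y <- base + amp * cos(2 * pi * (t - peak) / period)
  if (noise_sd > 0) y <- y + stats::rnorm(length(t), 0, noise_sd)
  data.frame(time_h = t, luminescence = y)
}

random_peptides <- function(n, len = 9, seed = 1) {
  set.seed(seed)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  vapply(seq_len(n), function(i) {
    paste(sample(aa, len, replace = TRUE), collapse = "")
  }, "")
}
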