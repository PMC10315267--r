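#' Spectral-count matrices for APMS experiments
#'
#' A `spectral_counts` object holds an integer matrix of total MS/MS spectra
#' (proteins x purification runs) together with the two metadata tables that
#' make it interpretable: one row per protein (AGI locus, name, molecular
#' weight, optional cycling flag) and one row per run (bait, Zeitgeber time,
#' replicate, control status). Optionally a matching matrix of unique-peptide
#' counts is attached; evidence filtering uses it when present.
#'
#' @param proteins A data frame with columns `agi_locus`, `protein_name`,
#'   `mw_kda` and optionally `cycling` (logical, `NA` = unknown).
#' @param runs A data frame with columns `run_id`, `bait`, `timepoint_zt`,
#'   `replicate`, `is_control`.
#' @param counts Integer matrix of total spectra, `nrow(proteins)` x
#'   `nrow(runs)`.
#' @param unique_peptides Optional integer matrix of unique-peptide counts,
#'   same shape as `counts`, element-wise `<= counts`.
#'
#' @return A validated `spectral_counts` object.
#' @export
spectral_counts <- function(proteins, runs, counts, unique_peptides = NULL) {
  proteins <- as_tibble(proteins)
  runs <- as_tibble(runs)
  if (!"cycling" %in% names(proteins)) proteins$cycling <- NA
  proteins$cycling <- as.logical(proteins$cycling)
  proteins$agi_locus <- assert_agi(proteins$agi_locus)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (!is.null(unique_peptides)) {
    unique_peptides <- as.matrix(unique_peptides)
    storage.mode(unique_peptides) <- "integer"
  }
  x <- structure(
    list(
      proteins = proteins[, c("protein_name", "agi_locus", "mw_kda", "cycling")],
      runs = runs[, c("run_id", "bait", "timepoint_zt", "replicate", "is_control")],
      counts = counts,
      unique_peptides = unique_peptides
    ),
    class = "spectral_counts"
  )
  validate_spectral_counts(x)
}

validate_spectral_counts <- function(x) {
  p <- x$proteins
  r <- x$runs
  dup <- p$agi_locus[duplicated(p$agi_locus)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate AGI locus in protein table: %s.",
                  paste(unique(dup), collapse = ", ")))
  }
  if (anyDuplicated(r$run_id)) {
    abort("Duplicate run_id in run table.")
  }
  if (any(r$timepoint_zt < 0 | r$timepoint_zt >= 24)) {
    abort("timepoint_zt must lie in [0, 24).")
  }
  if (!all(r$is_control == (tolower(r$bait) == "none"))) {
    abort("is_control must be TRUE exactly when bait is 'none'.")
  }
  keys <- r[!r$is_control, c("bait", "timepoint_zt", "replicate")]
  if (anyDuplicated(keys)) {
    abort("Non-control runs must be unique in (bait, timepoint_zt, replicate).")
  }
  if (nrow(x$counts) != nrow(p) || ncol(x$counts) != nrow(r)) {
    abort("Count matrix dimensions do not match protein/run tables.")
  }
  assert_count_values(as.vector(x$counts), function(i) {
    rc <- arrayInd(i, dim(x$counts))
    sprintf("protein %s, run %s", p$agi_locus[rc[1]], r$run_id[rc[2]])
  })
  dimnames(x$counts) <- list(p$agi_locus, r$run_id)
  if (!is.null(x$unique_peptides)) {
    if (!identical(dim(x$unique_peptides), dim(x$counts))) {
      abort("unique_peptides matrix must match the count matrix shape.")
    }
    assert_count_values(as.vector(x$unique_peptides), function(i) {
      rc <- arrayInd(i, dim(x$counts))
      sprintf("protein %s, run %s (unique_peptides)", p$agi_locus[rc[1]], r$run_id[rc[2]])
    })
    if (any(x$unique_peptides > x$counts)) {
      abort("unique_peptides may not exceed total spectra for any cell.")
    }
    dimnames(x$unique_peptides) <- dimnames(x$counts)
  }
  x
}

#' @export
print.spectral_counts <- function(x, ...) {
  nc <- sum(x$runs$is_control)
  cat(sprintf(
    "<spectral_counts> %d proteins x %d runs (%d control)%s\n",
    nrow(x$proteins), nrow(x$runs), nc,
    if (is.null(x$unique_peptides)) "" else ", with unique peptides"
  ))
  grp <- unique(x$runs[!x$runs$is_control, c("bait", "timepoint_zt")])
  if (nrow(grp) > 0) {
    cat("  groups:", paste(sprintf("%s@ZT%g", grp$bait, grp$timepoint_zt),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn spectral_counts Long tidy view: one row per (protein, run) with
#'   all protein and run metadata joined on.
#' @param x A `spectral_counts` object.
#' @param ... Unused.
#' @export
as_tibble.spectral_counts <- function(x, ...) {
  long <- tidyr::expand_grid(
    agi_locus = x$proteins$agi_locus,
    run_id = x$runs$run_id
  )
  long$total_spectra <- as.vector(t(x$counts))
  if (!is.null(x$unique_peptides)) {
    long$unique_peptides <- as.vector(t(x$unique_peptides))
  }
  long <- dplyr::left_join(long, x$proteins, by = "agi_locus")
  dplyr::left_join(long, x$runs, by = "run_id")
}

# parse wide-format run headers BAIT_ZT<t>_<rep>; bait "none" marks controls
.run_header_pattern <- "^(.+)_ZT([0-9]+(?:\\.[0-9]+)?)_([0-9]+)$"

parse_run_headers <- function(ids) {
  m <- regmatches(ids, regexec(.run_header_pattern, ids))
  bad <- ids[vapply(m, length, 1L) != 4L]
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown run column(s) %s: expected 'BAIT_ZT<t>_<rep>' (use the long dialect with a run table otherwise).",
      paste(bad, collapse = ", ")
    ))
  }
  tibble(
    run_id = ids,
    bait = vapply(m, `[`, "", 2L),
    timepoint_zt = as.numeric(vapply(m, `[`, "", 3L)),
    replicate = as.integer(vapply(m, `[`, "", 4L)),
    is_control = tolower(vapply(m, `[`, "", 2L)) == "none"
  )
}

#' Read a spectral-count table
#'
#' Reads proteins x runs total-spectra tables in either of two dialects.
#' `"wide"`: one row per protein with metadata columns (`protein_name`,
#' `agi_locus`, `mw_kda`, optional `cycling`) followed by one count column per
#' run named `BAIT_ZT<t>_<rep>` (bait `none` marks a negative-control run).
#' `"long"`: columns `agi_locus`, `run_id`, `total_spectra` (optional
#' `unique_peptides`, `protein_name`, `mw_kda`, `cycling`) plus a sidecar run
#' table giving `run_id`, `bait`, `timepoint_zt`, `replicate`.
#'
#' Counts that do not parse as non-negative integers are an error naming the
#' offending cell, never a silent zero.
#'
#' @param path Path to a tab-separated table.
#' @param dialect `"wide"` or `"long"`.
#' @param run_table For the long dialect: path to the run-metadata TSV, or a
#'   data frame.
#' @return A [spectral_counts] object.
#' @export
read_spectral_counts <- function(path, dialect = c("wide", "long"),
                                 run_table = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (dialect == "wide") {
    meta_cols <- intersect(c("protein_name", "agi_locus", "mw_kda", "cycling"),
                           names(raw))
    if (!all(c("protein_name", "agi_locus") %in% meta_cols)) {
      abort("Wide tables need 'protein_name' and 'agi_locus' columns.")
    }
    run_cols <- setdiff(names(raw), meta_cols)
    runs <- parse_run_headers(run_cols)
    proteins <- tibble(
      protein_name = raw$protein_name,
      agi_locus = raw$agi_locus,
      mw_kda = if ("mw_kda" %in% meta_cols) as.numeric(raw$mw_kda) else NA_real_,
      cycling = if ("cycling" %in% meta_cols) as.logical(raw$cycling) else NA
    )
    counts <- matrix(0L, nrow(raw), length(run_cols))
    for (j in seq_along(run_cols)) {
      v <- suppressWarnings(as.numeric(raw[[run_cols[j]]]))
      if (nrow(raw) > 0) {
        assert_count_values(v, function(i) {
          sprintf("row %d (%s), column %s", i, raw$agi_locus[i], run_cols[j])
        })
      }
      counts[, j] <- as.integer(v)
    }
    return(spectral_counts(proteins, runs, counts))
  }
  # long dialect
  if (is.null(run_table)) abort("The long dialect requires a sidecar run table.")
  runs <- if (is.data.frame(run_table)) {
    as_tibble(run_table)
  } else {
    readr::read_tsv(run_table, show_col_types = FALSE, progress = FALSE)
  }
  if (!"is_control" %in% names(runs)) {
    runs$is_control <- tolower(runs$bait) == "none"
  }
  need <- c("agi_locus", "run_id", "total_spectra")
  if (!all(need %in% names(raw))) {
    abort(sprintf("Long tables need columns: %s.", paste(need, collapse = ", ")))
  }
  unknown <- setdiff(unique(raw$run_id), runs$run_id)
  if (length(unknown) > 0) {
    abort(sprintf("Run id(s) not in the run table: %s.",
                  paste(unknown, collapse = ", ")))
  }
  loci <- unique(raw$agi_locus)
  prot_meta <- raw[!duplicated(raw$agi_locus),
                   intersect(c("agi_locus", "protein_name", "mw_kda", "cycling"),
                             names(raw)), drop = FALSE]
  proteins <- tibble(
    agi_locus = prot_meta$agi_locus,
    protein_name = if ("protein_name" %in% names(prot_meta)) {
      prot_meta$protein_name
    } else prot_meta$agi_locus,
    mw_kda = if ("mw_kda" %in% names(prot_meta)) as.numeric(prot_meta$mw_kda) else NA_real_,
    cycling = if ("cycling" %in% names(prot_meta)) as.logical(prot_meta$cycling) else NA
  )
  counts <- matrix(0L, length(loci), nrow(runs),
                   dimnames = list(loci, runs$run_id))
  v <- suppressWarnings(as.numeric(raw$total_spectra))
  if (nrow(raw) > 0) {
    assert_count_values(v, function(i) {
      sprintf("row %d (%s, %s)", i, raw$agi_locus[i], raw$run_id[i])
    })
  }
  counts[cbind(match(raw$agi_locus, loci), match(raw$run_id, runs$run_id))] <-
    as.integer(v)
  up <- NULL
  if ("unique_peptides" %in% names(raw)) {
    up <- matrix(0L, length(loci), nrow(runs), dimnames = dimnames(counts))
    u <- suppressWarnings(as.numeric(raw$unique_peptides))
    assert_count_values(u, function(i) {
      sprintf("row %d (%s, %s; unique_peptides)", i, raw$agi_locus[i], raw$run_id[i])
    })
    up[cbind(match(raw$agi_locus, loci), match(raw$run_id, runs$run_id))] <-
      as.integer(u)
  }
  spectral_counts(proteins, runs, counts, unique_peptides = up)
}

#' Write a spectral-count table (wide dialect)
#'
#' Inverse of [read_spectral_counts()] for the wide dialect; a write/read
#' round trip reproduces counts and metadata exactly.
#'
#' @param x A [spectral_counts] object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_spectral_counts <- function(x, path) {
  wide <- as.data.frame(x$counts)
  out <- cbind(
    x$proteins[, c("protein_name", "agi_locus", "mw_kda", "cycling")],
    wide
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Packaged APMS fixture tables
#'
#' Curated spectral-count tables for the three time-of-day APMS experiments
#' shipped with the package: `"table1"` (RVE8/LNK1/LNK2-HFC baits at ZT5, 31
#' proteins x 6 runs), `"table2"` (same baits at ZT9, 32 x 6) and `"table3"`
#' (YFP-COR27/GFP-COR28 baits at ZT9, 21 x 8). The tables are already
#' control-subtracted (proteins seen in the GFP-HFC or Col-0 negative controls
#' were removed upstream) and report total spectra only, so evidence filtering
#' on them is a no-op by contract. The `cycling` flag records whether the
#' encoding mRNA is circadian regulated in constant light.
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`.
#' @return A [spectral_counts] object.
#' @export
load_table_fixture <- function(name) {
  files <- c(
    table1 = "apms_rvelnk_zt5.tsv",
    table2 = "apms_rvelnk_zt9.tsv",
    table3 = "apms_cor_zt9.tsv"
  )
  if (!is.character(name) || length(name) != 1 || !name %in% names(files)) {
    abort(sprintf("Unknown fixture '%s'; valid names: %s.",
                  paste(name, collapse = ","), paste(names(files), collapse = ", ")))
  }
  path <- system.file("extdata", files[[name]], package = "chronoprot",
                      mustWork = TRUE)
  read_spectral_counts(path, dialect = "wide")
}

#' Read luciferase luminescence traces
#'
#' Expects a CSV with columns `time_h`, `luminescence`, `plant_id`,
#' `genotype`, `condition_segment` (one reading per plant per sampling
#' interval). Within each plant, times must be strictly increasing and evenly
#' spaced (tolerance 1 s).
#'
#' @param path CSV path.
#' @return A tibble ordered by plant and time, one row per reading.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_h", "luminescence", "plant_id", "genotype", "condition_segment")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("Trace file lacks column(s): %s.", paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) return(as_tibble(df))
  df <- dplyr::arrange(df, .data$plant_id)
  tol_h <- 1 / 3600
  for (pid in unique(df$plant_id)) {
    tt <- df$time_h[df$plant_id == pid]
    if (anyDuplicated(tt)) {
      abort(sprintf("Duplicated (plant, time) reading for plant '%s'.", pid))
    }
    if (is.unsorted(tt, strictly = TRUE)) {
      abort(sprintf("Non-monotone time within plant '%s'.", pid))
    }
    if (length(tt) > 2) {
      dt <- diff(tt)
      if (max(dt) - min(dt) > tol_h) {
        abort(sprintf("Mixed sampling intervals within plant '%s'.", pid))
      }
    }
  }
  df
}

#' Read a flat two-column annotation map
#'
#' @param path TSV with columns `agi_locus` and `term` (header optional when
#'   exactly two columns).
#' @return A tibble with columns `agi_locus`, `term`.
#' @export
read_annotation_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("agi_locus", "term") %in% names(df))) {
    if (ncol(df) == 2) names(df) <- c("agi_locus", "term")
    else abort("Annotation map needs columns 'agi_locus' and 'term'.")
  }
  df$agi_locus <- assert_agi(df$agi_locus)
  as_tibble(df[, c("agi_locus", "term")])
}

#' Read a gene -> cycling flag map
#'
#' @param path TSV with columns `agi_locus` and `cycling` (logical).
#' @return A tibble with columns `agi_locus`, `cycling`.
#' @export
read_cycling_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("agi_locus", "cycling") %in% names(df))) {
    if (ncol(df) == 2) names(df) <- c("agi_locus", "cycling")
    else abort("Cycling map needs columns 'agi_locus' and 'cycling'.")
  }
  df$agi_locus <- assert_agi(df$agi_locus)
  df$cycling <- as.logical(df$cycling)
  as_tibble(df[, c("agi_locus", "cycling")])
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA path (wrapped or unwrapped).
#' @return A named character vector of upper-case amino-acid sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  ss <- Biostrings::readAAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}
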