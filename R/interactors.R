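#' Evidence thresholds for protein identification
#'
#' Thresholds applied when peptide-level evidence is available: peptide
#' identifications must exceed `min_peptide_probability` with a local FDR
#' below `max_peptide_fdr`, protein identifications must exceed
#' `min_protein_probability`, and a protein must be supported by at least
#' `min_unique_peptides` unique peptides in some replicate of a bait x
#' timepoint group -- except that single-peptide proteins are rescued when
#' identified in at least `replicate_exception_min_runs` replicates of the
#' group.
#'
#' @param min_peptide_probability Minimum peptide probability (default 0.95).
#' @param max_peptide_fdr Maximum peptide local FDR (default 0.01).
#' @param min_protein_probability Minimum protein probability (default 0.999).
#' @param min_unique_peptides Unique peptides required in one replicate
#'   (default 2).
#' @param replicate_exception_min_runs Replicates that rescue a one-peptide
#'   identification (default 2, i.e. "more than one replicate").
#' @return An `evidence_thresholds` list.
#' @export
evidence_thresholds <- function(min_peptide_probability = 0.95,
                                max_peptide_fdr = 0.01,
                                min_protein_probability = 0.999,
                                min_unique_peptides = 2L,
                                replicate_exception_min_runs = 2L) {
  stopifnot(
    min_peptide_probability > 0, min_peptide_probability <= 1,
    max_peptide_fdr > 0, max_peptide_fdr <= 1,
    min_protein_probability > 0, min_protein_probability <= 1,
    min_unique_peptides >= 1, replicate_exception_min_runs >= 1
  )
  structure(
    list(
      min_peptide_probability = min_peptide_probability,
      max_peptide_fdr = max_peptide_fdr,
      min_protein_probability = min_protein_probability,
      min_unique_peptides = as.integer(min_unique_peptides),
      replicate_exception_min_runs = as.integer(replicate_exception_min_runs)
    ),
    class = "evidence_thresholds"
  )
}

# unique-peptide matrix from a peptide-level table, after probability/FDR cuts
peptides_to_unique_matrix <- function(x, peptide_table, thresholds) {
  pt <- as_tibble(peptide_table)
  need <- c("run_id", "agi_locus", "peptide")
  if (!all(need %in% names(pt))) {
    abort(sprintf("Peptide table needs columns: %s.", paste(need, collapse = ", ")))
  }
  unknown <- setdiff(unique(pt$run_id), x$runs$run_id)
  if (length(unknown) > 0) {
    abort(sprintf("Peptide table references unknown run(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  keep <- rep(TRUE, nrow(pt))
  if ("probability" %in% names(pt)) {
    keep <- keep & pt$probability > thresholds$min_peptide_probability
  }
  if ("fdr" %in% names(pt)) keep <- keep & pt$fdr < thresholds$max_peptide_fdr
  if ("protein_probability" %in% names(pt)) {
    keep <- keep & pt$protein_probability > thresholds$min_protein_probability
  }
  pt <- pt[keep, ]
  pt <- dplyr::distinct(pt, .data$run_id, .data$agi_locus, .data$peptide)
  tab <- dplyr::count(pt, .data$agi_locus, .data$run_id)
  up <- matrix(0L, nrow(x$proteins), nrow(x$runs), dimnames = dimnames(x$counts))
  hit <- tab$agi_locus %in% rownames(up)
  up[cbind(match(tab$agi_locus[hit], rownames(up)),
           match(tab$run_id[hit], colnames(up)))] <- as.integer(tab$n[hit])
  up
}

#' Apply the replicate evidence rule
#'
#' Within each bait x timepoint group, a protein identification is kept when
#' some replicate shows at least `min_unique_peptides` unique peptides, or
#' when at least one peptide is seen in `replicate_exception_min_runs` or more
#' replicates of the group. Counts of failing identifications are zeroed for
#' that group; proteins failing everywhere are dropped. When neither a
#' `unique_peptides` matrix nor a peptide table is available, the input is
#' returned unchanged with a message (curated tables are post-threshold).
#'
#' @param x A [spectral_counts] object.
#' @param thresholds An [evidence_thresholds] object.
#' @param peptide_table Optional per-run peptide records with columns
#'   `run_id`, `agi_locus`, `peptide` and optionally `probability`, `fdr`,
#'   `protein_probability`.
#' @return A filtered [spectral_counts] object.
#' @export
apply_evidence_filter <- function(x, thresholds = evidence_thresholds(),
                                  peptide_table = NULL) {
  stopifnot(inherits(x, "spectral_counts"))
  up <- x$unique_peptides
  if (!is.null(peptide_table)) {
    up <- peptides_to_unique_matrix(x, peptide_table, thresholds)
  }
  if (is.null(up)) {
    inform("No peptide-level evidence available; evidence filtering skipped.")
    return(x)
  }
  # the rule applies to bait x timepoint groups only: negative-control
  # identifications are consumed as-is, so that a single control spectrum
  # still excludes a protein downstream (presence-based exclusion)
  bait_runs <- which(!x$runs$is_control)
  groups <- split(bait_runs,
                  paste(x$runs$bait[bait_runs], x$runs$timepoint_zt[bait_runs],
                        sep = "@"))
  counts <- x$counts
  up_out <- up
  for (cols in groups) {
    g <- up[, cols, drop = FALSE]
    pass <- apply(g, 1L, function(v) {
      any(v >= thresholds$min_unique_peptides) ||
        sum(v >= 1L) >= thresholds$replicate_exception_min_runs
    })
    counts[!pass, cols] <- 0L
    up_out[!pass, cols] <- 0L
  }
  keep <- rowSums(counts) > 0L | rowSums(up_out) > 0L
  spectral_counts(x$proteins[keep, ], x$runs,
                  counts[keep, , drop = FALSE],
                  unique_peptides = up_out[keep, , drop = FALSE])
}

#' Remove proteins identified in negative-control purifications
#'
#' A protein with one or more spectra in any negative-control run (GFP-tag or
#' untransformed background) is excluded everywhere: presence in a control
#' marks it as nonspecific binding regardless of its counts with the baits.
#' Control runs themselves are dropped from the output. Idempotent.
#'
#' @param x A [spectral_counts] object.
#' @return A [spectral_counts] object without control-listed proteins or
#'   control runs. If `x` carries no control runs, it is returned unchanged
#'   with a warning.
#' @export
subtract_controls <- function(x) {
  stopifnot(inherits(x, "spectral_counts"))
  ctrl <- x$runs$is_control
  if (!any(ctrl)) {
    warn("No control runs present; control subtraction skipped.")
    return(x)
  }
  in_ctrl <- rowSums(x$counts[, ctrl, drop = FALSE] >= 1L) > 0L
  spectral_counts(
    x$proteins[!in_ctrl, ],
    x$runs[!ctrl, ],
    x$counts[!in_ctrl, !ctrl, drop = FALSE],
    unique_peptides = if (is.null(x$unique_peptides)) NULL else
      x$unique_peptides[!in_ctrl, !ctrl, drop = FALSE]
  )
}

#' Call interactors for one bait at one timepoint
#'
#' Reports every protein with at least one spectrum in at least one replicate
#' of the requested bait x timepoint group. Assumes the matrix has already
#' been control-subtracted and evidence-filtered. Rows are ordered by
#' descending maximum spectra, ties broken by locus.
#'
#' @param x A [spectral_counts] object.
#' @param bait Bait name as recorded in the run table.
#' @param timepoint_zt Zeitgeber time of the group.
#' @return A tibble of class `interactor_call` with columns `agi_locus`,
#'   `protein_name`, `bait`, `timepoint_zt`, `per_replicate` (list column of
#'   counts in replicate order), `max_spectra`, `total_spectra`.
#' @export
call_interactors <- function(x, bait, timepoint_zt) {
  stopifnot(inherits(x, "spectral_counts"))
  sel <- !x$runs$is_control & x$runs$bait == bait &
    x$runs$timepoint_zt == timepoint_zt
  if (!any(sel)) {
    grp <- unique(x$runs[!x$runs$is_control, c("bait", "timepoint_zt")])
    abort(sprintf(
      "No runs for bait '%s' at ZT%g. Available groups: %s.",
      bait, timepoint_zt,
      paste(sprintf("%s@ZT%g", grp$bait, grp$timepoint_zt), collapse = ", ")
    ))
  }
  cols <- which(sel)[order(x$runs$replicate[sel])]
  sub <- x$counts[, cols, drop = FALSE]
  max_s <- apply(sub, 1L, max)
  keep <- which(max_s >= 1L)
  keep <- keep[order_by_spectra(max_s[keep], x$proteins$agi_locus[keep])]
  out <- tibble(
    agi_locus = x$proteins$agi_locus[keep],
    protein_name = x$proteins$protein_name[keep],
    bait = bait,
    timepoint_zt = timepoint_zt,
    per_replicate = lapply(keep, function(i) unname(sub[i, ])),
    max_spectra = as.integer(max_s[keep]),
    total_spectra = as.integer(rowSums(sub)[keep])
  )
  class(out) <- c("interactor_call", class(out))
  attr(out, "bait") <- bait
  attr(out, "timepoint_zt") <- timepoint_zt
  out
}

#' Classify interactors by time of day
#'
#' Pools interactor calls (by AGI locus, across baits) within each of two
#' timepoints and labels every locus `early_only`, `late_only` or `shared`.
#' Per-bait pairwise partitions are returned alongside the pooled one.
#'
#' @param early One `interactor_call` or a list of them, all at the earlier
#'   timepoint.
#' @param late Same for the later timepoint.
#' @return A `time_classification` object: list with `labels` (tibble
#'   `agi_locus`, `label`, plus one logical column per bait x timepoint),
#'   `counts` (named integer vector), `per_bait` (tibble `bait`, `label`,
#'   `agi_locus`), `early_zt`, `late_zt`. [generics::tidy()] returns the
#'   label table; [generics::glance()] the pooled counts.
#' @export
classify_timepoints <- function(early, late) {
  as_list <- function(z) if (inherits(z, "interactor_call")) list(z) else z
  early <- as_list(early)
  late <- as_list(late)
  zt_of <- function(calls) {
    z <- unique(vapply(calls, function(d) {
      attr(d, "timepoint_zt") %||% d$timepoint_zt[1]
    }, 1.0))
    z <- z[!is.na(z)]
    if (length(z) != 1) abort("Calls within one timepoint arm must share one ZT.")
    z
  }
  early_zt <- zt_of(early)
  late_zt <- zt_of(late)
  if (early_zt == late_zt) {
    abort("The two arms must be at distinct timepoints.")
  }
  early_df <- dplyr::bind_rows(early)
  late_df <- dplyr::bind_rows(late)
  e_set <- unique(early_df$agi_locus)
  l_set <- unique(late_df$agi_locus)
  all_loci <- sort(union(e_set, l_set))
  label <- dplyr::case_when(
    all_loci %in% e_set & all_loci %in% l_set ~ "shared",
    all_loci %in% e_set ~ "early_only",
    TRUE ~ "late_only"
  )
  labels <- tibble(agi_locus = all_loci, label = label)
  both <- dplyr::bind_rows(early_df, late_df)
  flag <- both |>
    dplyr::distinct(.data$agi_locus, .data$bait, .data$timepoint_zt) |>
    dplyr::mutate(col = sprintf("%s_zt%g", .data$bait, .data$timepoint_zt),
                  seen = TRUE) |>
    dplyr::select("agi_locus", "col", "seen") |>
    tidyr::pivot_wider(names_from = "col", values_from = "seen",
                       values_fill = FALSE)
  labels <- dplyr::left_join(labels, flag, by = "agi_locus")
  per_bait <- both |>
    dplyr::distinct(.data$bait, .data$agi_locus, .data$timepoint_zt) |>
    dplyr::group_by(.data$bait, .data$agi_locus) |>
    dplyr::summarise(
      label = if (dplyr::n() == 2) "shared"
      else if (.data$timepoint_zt[1] == early_zt) "early_only" else "late_only",
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$bait, .data$label, .data$agi_locus)
  counts <- c(
    early_only = sum(label == "early_only"),
    late_only = sum(label == "late_only"),
    shared = sum(label == "shared"),
    union = length(all_loci)
  )
  structure(
    list(labels = labels, counts = counts, per_bait = per_bait,
         early_zt = early_zt, late_zt = late_zt),
    class = "time_classification"
  )
}

#' @export
print.time_classification <- function(x, ...) {
  cat(sprintf(
    "<time_classification> ZT%g vs ZT%g: %d early-only, %d late-only, %d shared (%d loci)\n",
    x$early_zt, x$late_zt, x$counts[["early_only"]], x$counts[["late_only"]],
    x$counts[["shared"]], x$counts[["union"]]
  ))
  invisible(x)
}

#' @rdname classify_timepoints
#' @param x A `time_classification` object.
#' @param ... Unused.
#' @export
tidy.time_classification <- function(x, ...) x$labels

#' @rdname classify_timepoints
#' @export
glance.time_classification <- function(x, ...) {
  tibble(
    early_zt = x$early_zt, late_zt = x$late_zt,
    n_early_only = x$counts[["early_only"]],
    n_late_only = x$counts[["late_only"]],
    n_shared = x$counts[["shared"]],
    n_union = x$counts[["union"]]
  )
}

#' Largest spectral count for a locus in one bait x timepoint group
#'
#' @param x A [spectral_counts] object.
#' @param bait,timepoint_zt Group selector.
#' @param target_locus AGI locus to look up.
#' @return Integer: the maximum total spectra across the group's replicates.
#' @export
bait_max_spectra <- function(x, bait, timepoint_zt, target_locus) {
  stopifnot(inherits(x, "spectral_counts"))
  target_locus <- assert_agi(target_locus)
  if (!target_locus %in% x$proteins$agi_locus) {
    abort(sprintf("Locus %s is not in the matrix.", target_locus))
  }
  sel <- !x$runs$is_control & x$runs$bait == bait &
    x$runs$timepoint_zt == timepoint_zt
  if (!any(sel)) {
    grp <- unique(x$runs[!x$runs$is_control, c("bait", "timepoint_zt")])
    abort(sprintf(
      "No runs for bait '%s' at ZT%g. Available groups: %s.",
      bait, timepoint_zt,
      paste(sprintf("%s@ZT%g", grp$bait, grp$timepoint_zt), collapse = ", ")
    ))
  }
  as.integer(max(x$counts[target_locus, sel]))
}

#' Fraction of a protein set encoded by cycling genes
#'
#' Loci absent from the cycling map are counted as unknown and excluded from
#' the denominator.
#'
#' @param loci Character vector of AGI loci.
#' @param cycling Either a tibble with columns `agi_locus`, `cycling` or a
#'   named logical vector.
#' @return A tibble with `n_cycling`, `n_annotated`, `n_unknown`, `fraction`
#'   (NA when nothing is annotated).
#' @export
cycling_fraction <- function(loci, cycling) {
  loci <- unique(assert_agi(loci))
  if (is.data.frame(cycling)) {
    cyc <- stats::setNames(as.logical(cycling$cycling), toupper(cycling$agi_locus))
  } else {
    cyc <- stats::setNames(as.logical(cycling), toupper(names(cycling)))
  }
  flags <- cyc[loci]
  annotated <- !is.na(flags)
  n_ann <- sum(annotated)
  n_cyc <- sum(flags[annotated])
  tibble(
    n_cycling = n_cyc,
    n_annotated = n_ann,
    n_unknown = length(loci) - n_ann,
    fraction = if (n_ann > 0) n_cyc / n_ann else NA_real_
  )
}
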