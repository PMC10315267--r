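#' Combine spectral-count matrices
#'
#' Concatenates the runs of several experiments over the union of their
#' proteins (absent counts are zero; protein metadata taken from the first
#' matrix that carries the locus). Run ids must be unique across inputs.
#'
#' @param ... [spectral_counts] objects.
#' @return A single [spectral_counts] object.
#' @export
bind_spectral_counts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) && !inherits(xs[[1]], "spectral_counts")) {
    xs <- xs[[1]]
  }
  stopifnot(length(xs) >= 1, all(vapply(xs, inherits, TRUE, "spectral_counts")))
  proteins <- dplyr::bind_rows(lapply(xs, `[[`, "proteins"))
  proteins <- proteins[!duplicated(proteins$agi_locus), ]
  runs <- dplyr::bind_rows(lapply(xs, `[[`, "runs"))
  counts <- matrix(0L, nrow(proteins), nrow(runs),
                   dimnames = list(proteins$agi_locus, runs$run_id))
  has_up <- all(vapply(xs, function(x) !is.null(x$unique_peptides), TRUE))
  up <- if (has_up) counts else NULL
  for (x in xs) {
    ri <- match(x$proteins$agi_locus, proteins$agi_locus)
    ci <- match(x$runs$run_id, runs$run_id)
    counts[ri, ci] <- x$counts
    if (has_up) up[ri, ci] <- x$unique_peptides
  }
  spectral_counts(proteins, runs, counts, unique_peptides = up)
}

#' Run the interactor-calling pipeline end to end
#'
#' Executes read -> evidence filter -> control subtraction -> per-group
#' interactor calls -> two-timepoint classification -> cycling-fraction
#' cross-reference -> term enrichment, writing every stage's table plus a JSON
#' manifest. Any stage error aborts with the stage name in the message.
#'
#' @param config A named list (or path to a JSON file) with entries:
#'   `counts` (path, or character vector of paths, to count tables),
#'   `dialect` (`"wide"`/`"long"`, default wide), `run_table` (long dialect
#'   only), `early_zt` and `late_zt` (the two timepoints; default the two
#'   smallest present), `cycling_map` (optional TSV path), `annotation`
#'   (optional TSV path), `enrich_label` (which classification label to
#'   enrich, default `"late_only"`), `correction` (`"none"`/`"bh"`),
#'   `thresholds` (optional list passed to [evidence_thresholds()]),
#'   `out_dir` (output directory, required), `seed` (recorded in the
#'   manifest).
#' @return The manifest, invisibly (also written to `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("Config file not found: %s", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) abort("[stage config] 'out_dir' is required.")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("chronoprot")),
    r_version = as.character(getRversion()),
    seed = config$seed %||% NA,
    config = config[setdiff(names(config), "out_dir")],
    stages = list()
  )

  mats <- stage("read", {
    paths <- config$counts
    if (is.null(paths)) abort("'counts' path(s) required.")
    lapply(paths, read_spectral_counts,
           dialect = config$dialect %||% "wide",
           run_table = config$run_table)
  })
  x <- stage("read", bind_spectral_counts(mats))
  manifest$stages$read <- list(proteins = nrow(x$proteins), runs = nrow(x$runs))
  population <- x$proteins$agi_locus # detected proteome, pre-filter background

  thr <- do.call(evidence_thresholds, config$thresholds %||% list())
  x <- stage("evidence_filter", apply_evidence_filter(x, thr))
  manifest$stages$evidence_filter <- list(proteins = nrow(x$proteins))

  x <- stage("subtract_controls", withCallingHandlers(
    subtract_controls(x),
    warning = function(w) invokeRestart("muffleWarning")
  ))
  manifest$stages$subtract_controls <- list(proteins = nrow(x$proteins),
                                            runs = nrow(x$runs))

  groups <- unique(x$runs[!x$runs$is_control, c("bait", "timepoint_zt")])
  calls <- stage("call_interactors", purrr::map(seq_len(nrow(groups)), function(i) {
    call_interactors(x, groups$bait[i], groups$timepoint_zt[i])
  }))
  calls_df <- dplyr::bind_rows(calls) |>
    dplyr::mutate(per_replicate = vapply(.data$per_replicate, paste,
                                         "", collapse = ","))
  readr::write_tsv(calls_df, file.path(config$out_dir, "interactors.tsv"),
                   progress = FALSE)
  manifest$stages$call_interactors <- list(groups = nrow(groups),
                                           calls = nrow(calls_df))

  zts <- sort(unique(groups$timepoint_zt))
  early_zt <- config$early_zt %||% zts[1]
  late_zt <- config$late_zt %||% zts[2]
  cls <- stage("classify", {
    call_zt <- vapply(calls, function(d) attr(d, "timepoint_zt"), 1.0)
    is_early <- call_zt == early_zt
    is_late <- call_zt == late_zt
    classify_timepoints(calls[is_early], calls[is_late])
  })
  readr::write_tsv(tidy(cls), file.path(config$out_dir, "classification.tsv"),
                   progress = FALSE)
  jsonlite::write_json(as.list(cls$counts),
                       file.path(config$out_dir, "venn_counts.json"),
                       auto_unbox = TRUE)
  manifest$stages$classify <- as.list(cls$counts)

  if (!is.null(config$cycling_map)) {
    cyc <- stage("cycling_fraction", {
      cmap <- read_cycling_map(config$cycling_map)
      purrr::map_dfr(c("early_only", "late_only", "shared"), function(lab) {
        loci <- cls$labels$agi_locus[cls$labels$label == lab]
        if (length(loci) == 0) return(NULL)
        dplyr::mutate(cycling_fraction(loci, cmap), label = lab, .before = 1)
      })
    })
    readr::write_tsv(cyc, file.path(config$out_dir, "cycling.tsv"),
                     progress = FALSE)
    manifest$stages$cycling_fraction <- list(rows = nrow(cyc))
  }

  if (!is.null(config$annotation)) {
    enr <- stage("enrichment", {
      ann <- read_annotation_map(config$annotation)
      lab <- config$enrich_label %||% "late_only"
      study <- cls$labels$agi_locus[cls$labels$label == lab]
      enrich_terms(study, population, ann,
                   correction = config$correction %||% "none")
    })
    readr::write_tsv(enr, file.path(config$out_dir, "enrichment.tsv"),
                     progress = FALSE)
    manifest$stages$enrichment <- list(terms = nrow(enr))
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
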