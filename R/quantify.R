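#' Normalize western-blot densitometry to loading and biorep maximum
#'
#' Gray values are inverted against the image maximum (`2^bit_depth - 1`,
#' 255 for 8-bit scans), so darker bands score higher. The background ROI's
#' inverted density is subtracted from the band's to give the net density,
#' the band net is divided by the loading-control net, and within each
#' (genotype, biorep) the ratios are rescaled so the maximum equals 100.
#'
#' @param series Data frame with columns `band_mean_gray`,
#'   `band_bg_mean_gray`, `loading_mean_gray`, `loading_bg_mean_gray`,
#'   `timepoint_zt`, `genotype`, `biorep` (one row per lane; ROIs of equal
#'   area assumed upstream).
#' @param bit_depth Scan bit depth (default 8).
#' @return The input tibble plus columns `net_band`, `net_loading`, `ratio`,
#'   `normalized` (max = 100 per genotype x biorep).
#' @export
normalize_blot <- function(series, bit_depth = 8) {
  stopifnot(is.data.frame(series))
  need <- c("band_mean_gray", "band_bg_mean_gray", "loading_mean_gray",
            "loading_bg_mean_gray", "timepoint_zt", "genotype", "biorep")
  missing <- setdiff(need, names(series))
  if (length(missing) > 0) {
    abort(sprintf("Densitometry table lacks column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(series) == 0) abort("Empty densitometry series.")
  maxval <- 2^bit_depth - 1
  gray <- unlist(series[, need[1:4]], use.names = FALSE)
  if (any(gray < 0 | gray > maxval)) {
    abort(sprintf("Gray values must lie in [0, %d].", maxval))
  }
  out <- as_tibble(series)
  # inversion (maxval - gray) cancels in the subtraction: net = bg - roi
  out$net_band <- out$band_bg_mean_gray - out$band_mean_gray
  out$net_loading <- out$loading_bg_mean_gray - out$loading_mean_gray
  bad <- which(out$net_loading <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "Non-positive net loading density for lane %s (genotype %s, biorep %s, ZT%g).",
      bad[1], out$genotype[bad[1]], out$biorep[bad[1]], out$timepoint_zt[bad[1]]
    ))
  }
  out$ratio <- out$net_band / out$net_loading
  out |>
    dplyr::group_by(.data$genotype, .data$biorep) |>
    dplyr::mutate(normalized = {
      m <- max(.data$ratio)
      if (m > 0) 100 * .data$ratio / m else 0 * .data$ratio
    }) |>
    dplyr::ungroup()
}

#' Dual-luciferase fold change with Welch tests
#'
#' Per reading, the plate background is subtracted from both channels and the
#' firefly signal is divided by the renilla signal (which absorbs infection
#' efficiency). Each reading's ratio is then divided by the mean no-effector
#' ratio -- per leaf when `leaf_id` is present (the assay inoculates the
#' no-effector mix into a quadrant of the same leaf), per experiment otherwise
#' -- so the reporter-alone fold change is 1 by construction. Effector
#' combinations are compared by Welch's unpaired t-test.
#'
#' @param readings Data frame with columns `firefly_intensity`,
#'   `renilla_intensity`, `firefly_bg`, `renilla_bg`, `effector_combination`,
#'   `experiment_id` and optionally `leaf_id`.
#' @param reference Label of the no-effector combination (default
#'   `"no effector"`).
#' @param contrasts Optional list of length-2 character vectors naming
#'   combination pairs to test; default tests every combination against every
#'   other (all pairs).
#' @return A `dualluc_result` object; `tidy()` gives per-reading folds,
#'   `glance()` the per-combination summary, `$tests` the Welch table.
#' @export
dualluc_fold_change <- function(readings, reference = "no effector",
                                contrasts = NULL) {
  stopifnot(is.data.frame(readings))
  need <- c("firefly_intensity", "renilla_intensity", "firefly_bg",
            "renilla_bg", "effector_combination", "experiment_id")
  missing <- setdiff(need, names(readings))
  if (length(missing) > 0) {
    abort(sprintf("Plate table lacks column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  df <- as_tibble(readings)
  df$net_firefly <- df$firefly_intensity - df$firefly_bg
  df$net_renilla <- df$renilla_intensity - df$renilla_bg
  drop <- df$net_renilla <= 0
  if (any(drop)) {
    warn(sprintf("Excluding %d reading(s) with non-positive net renilla signal.",
                 sum(drop)))
    df <- df[!drop, ]
  }
  df$ratio <- df$net_firefly / df$net_renilla
  no_ref <- setdiff(unique(df$experiment_id),
                    unique(df$experiment_id[df$effector_combination == reference]))
  if (length(no_ref) > 0 || !reference %in% df$effector_combination) {
    abort(sprintf("Experiment(s) without a '%s' group: %s.", reference,
                  paste(if (length(no_ref)) no_ref else "(all)", collapse = ", ")))
  }
  per_leaf <- "leaf_id" %in% names(df) && !anyNA(df$leaf_id)
  if (per_leaf) {
    leaf_ref <- df |>
      dplyr::filter(.data$effector_combination == reference) |>
      dplyr::group_by(.data$experiment_id, .data$leaf_id) |>
      dplyr::summarise(ref_ratio = mean(.data$ratio), .groups = "drop")
    if (!all(unique(df$leaf_id) %in% leaf_ref$leaf_id)) {
      inform("Some leaves lack a no-effector quadrant; normalizing those per experiment.")
    }
    exp_ref <- df |>
      dplyr::filter(.data$effector_combination == reference) |>
      dplyr::group_by(.data$experiment_id) |>
      dplyr::summarise(exp_ratio = mean(.data$ratio), .groups = "drop")
    df <- df |>
      dplyr::left_join(leaf_ref, by = c("experiment_id", "leaf_id")) |>
      dplyr::left_join(exp_ref, by = "experiment_id") |>
      dplyr::mutate(fold = .data$ratio / dplyr::coalesce(.data$ref_ratio,
                                                         .data$exp_ratio)) |>
      dplyr::select(-"ref_ratio", -"exp_ratio")
  } else {
    df <- df |>
      dplyr::group_by(.data$experiment_id) |>
      dplyr::mutate(fold = .data$ratio /
                      mean(.data$ratio[.data$effector_combination == reference])) |>
      dplyr::ungroup()
  }
  summary <- df |>
    dplyr::group_by(.data$effector_combination) |>
    dplyr::summarise(mean_fold = mean(.data$fold), sd_fold = stats::sd(.data$fold),
                     n = dplyr::n(), .groups = "drop")
  combos <- unique(df$effector_combination)
  if (is.null(contrasts)) {
    contrasts <- if (length(combos) > 1) {
      ci <- utils::combn(sort(combos), 2)
      lapply(seq_len(ncol(ci)), function(j) ci[, j])
    } else list()
  }
  tests <- purrr::map_dfr(contrasts, function(pair) {
    a <- df$fold[df$effector_combination == pair[1]]
    b <- df$fold[df$effector_combination == pair[2]]
    w <- welch_t(a, b)
    tibble(combination_a = pair[1], combination_b = pair[2],
           mean_a = mean(a), mean_b = mean(b),
           t = w$t, df = w$df, p_value = w$p_value)
  })
  structure(list(readings = df, summary = summary, tests = tests,
                 reference = reference),
            class = "dualluc_result")
}

#' @export
print.dualluc_result <- function(x, ...) {
  cat(sprintf("<dualluc_result> reference '%s'\n", x$reference))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %s: fold %.2f +/- %.2f (n = %d)\n",
                x$summary$effector_combination[i], x$summary$mean_fold[i],
                x$summary$sd_fold[i], x$summary$n[i]))
  }
  invisible(x)
}

#' @rdname dualluc_fold_change
#' @param x A `dualluc_result` object.
#' @param ... Unused.
#' @export
tidy.dualluc_result <- function(x, ...) x$readings

#' @rdname dualluc_fold_change
#' @export
glance.dualluc_result <- function(x, ...) x$summary
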