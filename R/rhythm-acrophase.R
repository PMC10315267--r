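#' Daily acrophase of a reporter trace
#'
#' Splits a trace into consecutive windows of `cycle_h` hours (anchored at
#' `anchor_h`, by default the first sampled time, i.e. the start of the
#' condition segment) and reports, for each complete window, the time of the
#' maximum of the moving-average-smoothed signal, modulo `cycle_h`.
#'
#' @param trace Data frame with columns `time_h`, `luminescence`.
#' @param cycle_h Cycle length in hours (default 24).
#' @param smooth_window_h Moving-average width in hours (default 3).
#' @param anchor_h Window anchor; defaults to the first time point.
#' @return A tibble with columns `day` (0-based window index), `acrophase`
#'   (hours in `[0, cycle_h)`, `NA` when the window is flat) and `flagged`.
#' @export
daily_acrophase <- function(trace, cycle_h = 24, smooth_window_h = 3,
                            anchor_h = NULL) {
  stopifnot(is.data.frame(trace),
            all(c("time_h", "luminescence") %in% names(trace)))
  t <- as.numeric(trace$time_h)
  y <- as.numeric(trace$luminescence)
  o <- order(t)
  t <- t[o]; y <- y[o]
  anchor_h <- anchor_h %||% t[1]
  dt <- stats::median(diff(t))
  w <- max(1L, round(smooth_window_h / dt))
  if (w %% 2 == 0) w <- w + 1L
  ys <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
  # shrink the window at the edges instead of dropping readings
  half <- (w - 1L) / 2L
  for (i in which(is.na(ys))) {
    lo <- max(1L, i - half); hi <- min(length(y), i + half)
    ys[i] <- mean(y[lo:hi])
  }
  # the last sample covers [max(t), max(t) + dt); count complete windows
  n_days <- floor(((max(t) - anchor_h) + dt + 1e-9) / cycle_h)
  if (n_days < 1) abort("Trace shorter than one cycle; no acrophase window.")
  purrr::map_dfr(seq_len(n_days) - 1L, function(d) {
    inw <- t >= anchor_h + d * cycle_h & t < anchor_h + (d + 1) * cycle_h
    yy <- ys[inw]; tt <- t[inw]
    if (length(yy) == 0 || diff(range(yy)) < 1e-12 * (1 + abs(mean(yy)))) {
      tibble(day = d, acrophase = NA_real_, flagged = TRUE)
    } else {
      tibble(day = d, acrophase = tt[which.max(yy)] %% cycle_h, flagged = FALSE)
    }
  })
}

#' Acrophase series for a collection of traces
#'
#' Applies [daily_acrophase()] to every plant and returns the per
#' (genotype, day) acrophase values across plants, the substrate for
#' [compare_acrophases()] and [rayleigh()].
#'
#' @param traces Tibble with columns `plant_id`, `genotype`, `time_h`,
#'   `luminescence` (optionally `condition_segment`; when present, only rows
#'   matching `segment` are used and windows anchor at the segment start).
#' @param segment Optional `condition_segment` label to restrict to.
#' @inheritParams daily_acrophase
#' @return A tibble with columns `genotype`, `plant_id`, `day`, `acrophase`,
#'   `flagged`.
#' @export
acrophase_series <- function(traces, cycle_h = 24, smooth_window_h = 3,
                             segment = NULL) {
  stopifnot(is.data.frame(traces))
  if (!is.null(segment)) {
    traces <- traces[traces$condition_segment == segment, ]
    if (nrow(traces) == 0) abort(sprintf("No rows in segment '%s'.", segment))
  }
  traces |>
    dplyr::group_by(.data$genotype, .data$plant_id) |>
    dplyr::group_modify(function(d, key) {
      daily_acrophase(d, cycle_h = cycle_h, smooth_window_h = smooth_window_h)
    }) |>
    dplyr::ungroup()
}

#' Rayleigh test of phase clustering
#'
#' Phases (hours) are mapped to angles on the cycle; `R` is the mean resultant
#' length (1 = all phases identical, 0 = dispersed), the mean phase is the
#' resultant's argument, and the p-value uses the standard large-sample
#' approximation `p = exp(sqrt(1 + 4n + 4(n^2 - Rn^2)) - (1 + 2n))` with
#' `Rn = n * R`.
#'
#' @param phases Numeric vector of phases in hours (reduced mod `cycle_h`).
#' @param cycle_h Cycle length in hours.
#' @return A tibble with columns `n`, `R`, `mean_phase_h`, `p_value`.
#' @export
rayleigh <- function(phases, cycle_h = 24) {
  phases <- phases[!is.na(phases)]
  n <- length(phases)
  if (n < 1) abort("Rayleigh test needs at least one phase.")
  theta <- 2 * pi * (phases %% cycle_h) / cycle_h
  z <- sum(exp(1i * theta)) / n
  R <- Mod(z)
  mean_phase <- (Arg(z) * cycle_h / (2 * pi)) %% cycle_h
  Rn <- n * R
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  tibble(n = n, R = R, mean_phase_h = mean_phase, p_value = min(1, p))
}

#' Welch's unpaired two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] with Welch-Satterthwaite degrees of
#' freedom, hardened for the degenerate zero-variance limits (identical
#' samples give `t = 0, p = 1`; separated constant samples give `p = 0`).
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A tibble with columns `t`, `df`, `p_value`.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("welch_t needs at least 2 observations per sample.")
  }
  se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
  # same near-constancy threshold stats::t.test applies before erroring
  degenerate <- sqrt(se2) < 10 * .Machine$double.eps *
    max(abs(mean(a)), abs(mean(b)), 1e-300)
  if (se2 <= 0 || degenerate) {
    d <- mean(a) - mean(b)
    return(tibble(
      t = if (d == 0) 0 else sign(d) * Inf,
      df = length(a) + length(b) - 2,
      p_value = if (d == 0) 1 else 0
    ))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Compare acrophases to a reference genotype, day by day
#'
#' For every day, each genotype's acrophases are compared to the reference
#' genotype's by Welch's unpaired t-test, after unwrapping all of that day's
#' phases into the reference mean's half-cycle neighbourhood (so a 1 h and a
#' 23 h acrophase are 2 h apart, not 22). The resynchronization day of a
#' genotype is the first day from which every subsequent tested day is
#' non-significant at `alpha`.
#'
#' @param series Tibble with columns `genotype`, `day`, `acrophase` (one row
#'   per plant per day), e.g. from [acrophase_series()].
#' @param reference_genotype Reference level present on every compared day.
#' @param cycle_h Cycle length for unwrapping.
#' @param alpha Significance level (default 0.05).
#' @return An `acrophase_comparison` object; `tidy()` gives the per
#'   (genotype, day) test table (`untestable` marks days with n < 2 in either
#'   group), `glance()` the per-genotype resynchronization day (`NA` = never).
#' @export
compare_acrophases <- function(series, reference_genotype, cycle_h = 24,
                               alpha = 0.05) {
  stopifnot(is.data.frame(series),
            all(c("genotype", "day", "acrophase") %in% names(series)))
  series <- series[!is.na(series$acrophase), ]
  if (!reference_genotype %in% series$genotype) {
    abort(sprintf("Reference genotype '%s' absent from the series.",
                  reference_genotype))
  }
  days <- sort(unique(series$day))
  others <- setdiff(unique(series$genotype), reference_genotype)
  tests <- purrr::map_dfr(days, function(d) {
    ref <- series$acrophase[series$genotype == reference_genotype &
                              series$day == d]
    if (length(ref) == 0) {
      abort(sprintf("Reference genotype missing on day %s.", d))
    }
    center <- rayleigh(ref, cycle_h)$mean_phase_h
    unwrap <- function(v) v - cycle_h * round((v - center) / cycle_h)
    ref_u <- unwrap(ref)
    purrr::map_dfr(others, function(g) {
      v <- series$acrophase[series$genotype == g & series$day == d]
      if (length(v) < 2 || length(ref) < 2) {
        return(tibble(genotype = g, day = d, n = length(v), n_ref = length(ref),
                      mean_offset_h = if (length(v)) mean(unwrap(v)) - mean(ref_u)
                      else NA_real_,
                      t = NA_real_, df = NA_real_, p_value = NA_real_,
                      untestable = TRUE))
      }
      w <- welch_t(unwrap(v), ref_u)
      tibble(genotype = g, day = d, n = length(v), n_ref = length(ref),
             mean_offset_h = mean(unwrap(v)) - mean(ref_u),
             t = w$t, df = w$df, p_value = w$p_value, untestable = FALSE)
    })
  })
  resync <- tests |>
    dplyr::group_by(.data$genotype) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::summarise(resync_day = {
      okv <- !is.na(.data$p_value) & .data$p_value >= alpha
      # first day such that this and every later day is non-significant
      suffix_ok <- rev(cumprod(rev(okv))) > 0
      if (any(suffix_ok)) .data$day[which(suffix_ok)[1]] else NA_real_
    }, .groups = "drop")
  structure(list(tests = tests, resync = resync, alpha = alpha,
                 reference = reference_genotype, cycle_h = cycle_h),
            class = "acrophase_comparison")
}

#' @export
print.acrophase_comparison <- function(x, ...) {
  cat(sprintf("<acrophase_comparison> vs '%s', %d genotype-day tests\n",
              x$reference, nrow(x$tests)))
  for (i in seq_len(nrow(x$resync))) {
    rd <- x$resync$resync_day[i]
    cat(sprintf("  %s: resynchronized %s\n", x$resync$genotype[i],
                if (is.na(rd)) "never" else sprintf("on day %g", rd)))
  }
  invisible(x)
}

#' @rdname compare_acrophases
#' @param x An `acrophase_comparison` object.
#' @param ... Unused.
#' @export
tidy.acrophase_comparison <- function(x, ...) {
  dplyr::mutate(x$tests,
                significant = !is.na(.data$p_value) & .data$p_value < x$alpha)
}

#' @rdname compare_acrophases
#' @export
glance.acrophase_comparison <- function(x, ...) x$resync
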