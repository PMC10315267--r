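#' @importFrom ggplot2 autoplot ggplot aes
NULL

#' Plot a rhythm fit: data and fitted cosine components
#'
#' @param object A `rhythm_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rhythm_fit <- function(object, ...) {
  df <- object$trace
  df$fitted <- object$fitted
  ggplot(df, aes(x = .data$time_h)) +
    ggplot2::geom_point(aes(y = .data$luminescence),
                        size = 0.7, alpha = 0.6) +
    ggplot2::geom_line(aes(y = .data$fitted), colour = "#2166ac") +
    ggplot2::labs(
      x = "Time (h)", y = "Luminescence (a.u.)",
      title = if (is.na(object$period_h)) "Arrhythmic trace" else
        sprintf("Period %.2f h, acrophase CT %.1f, RAE %.2f",
                object$period_h, object$acrophase_ct, object$rae)
    )
}

#' Plot the pooled timepoint classification as bars
#'
#' @param object A `time_classification` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.time_classification <- function(object, ...) {
  df <- tibble(
    label = factor(c("early_only", "shared", "late_only"),
                   levels = c("early_only", "shared", "late_only")),
    n = object$counts[c("early_only", "shared", "late_only")]
  )
  ggplot(df, aes(x = .data$label, y = .data$n)) +
    ggplot2::geom_col(fill = "#4d4d4d") +
    ggplot2::labs(
      x = NULL, y = "Loci",
      title = sprintf("Interactors at ZT%g vs ZT%g",
                      object$early_zt, object$late_zt)
    )
}

#' Plot acrophase comparisons per day
#'
#' Mean acrophase offset from the reference per genotype and day, with
#' significance asterisks from the Welch tests.
#'
#' @param object An `acrophase_comparison` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.acrophase_comparison <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$day, y = .data$mean_offset_h,
                 colour = .data$genotype)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(
      data = df[df$significant & !df$untestable, ],
      ggplot2::aes(label = "*"), vjust = -0.4, show.legend = FALSE
    ) +
    ggplot2::labs(
      x = "Entrainment day",
      y = sprintf("Acrophase offset vs %s (h)", object$reference)
    )
}

#' Rayleigh plot of phases on the cycle
#'
#' Unit-circle plot of individual phases with the mean resultant vector;
#' the vector's length is the Rayleigh R.
#'
#' @param phases Numeric vector of phases (hours).
#' @param cycle_h Cycle length in hours.
#' @return A ggplot.
#' @export
plot_rayleigh <- function(phases, cycle_h = 24) {
  r <- rayleigh(phases, cycle_h)
  pts <- tibble(phase = phases %% cycle_h)
  res <- tibble(phase = r$mean_phase_h, R = r$R)
  ggplot(pts, aes(x = .data$phase, y = 1)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_segment(
      data = res,
      ggplot2::aes(x = .data$phase, xend = .data$phase, y = 0, yend = .data$R),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "in")),
      colour = "#b2182b", linewidth = 0.8
    ) +
    ggplot2::scale_x_continuous(limits = c(0, cycle_h),
                                breaks = seq(0, cycle_h, by = cycle_h / 4)) +
    ggplot2::scale_y_continuous(limits = c(0, 1.05)) +
    ggplot2::coord_polar() +
    ggplot2::labs(x = "Phase (h)", y = NULL,
                  title = sprintf("R = %.2f, p = %.3g", r$R, r$p_value))
}

#' Plot dual-luciferase fold changes
#'
#' @param object A `dualluc_result` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dualluc_result <- function(object, ...) {
  ggplot(object$readings,
         aes(x = .data$effector_combination, y = .data$fold)) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5, size = 0.9) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.4, colour = "#2166ac") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = NULL, y = "Fold change (firefly/renilla, ref = 1)")
}
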