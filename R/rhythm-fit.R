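#' Fourier-seeded nonlinear least-squares rhythm fit (FFT-NLLS)
#'
#' Estimates circadian period, amplitude and acrophase of a uniformly sampled
#' luminescence trace. The procedure: (1) least-squares linear detrend;
#' (2) discrete Fourier transform of the detrended series (zero-padded for a
#' finer frequency grid) yields candidate periods at spectral peaks inside the
#' search window, strongest first; (3) cosine components
#' `y(t) = c + sum_i A_i cos(2*pi*(t - phi_i)/tau_i)` are fitted by nonlinear
#' least squares (variable projection: linear in the cos/sin coefficients,
#' numerical optimisation over the periods), adding components while the
#' F-test on residual SSE is significant at `alpha` and at most
#' `max_components`; (4) each component's relative amplitude error (RAE) is
#' the half-width of its 95% amplitude confidence interval, from the
#' linearised covariance at the optimum, divided by the amplitude; (5) the
#' in-window component with the smallest RAE is reported, and the trace is
#' called rhythmic when that RAE is below `rae_threshold`.
#'
#' @param trace Data frame with columns `time_h` and `luminescence`
#'   (uniformly sampled; span must be at least twice the minimum period).
#' @param window Period search window in hours, default `c(15, 35)`.
#' @param rae_threshold Rhythmicity cutoff on RAE, default 0.6.
#' @param max_components Maximum number of cosine components, default 5.
#' @param alpha Significance level of the component-addition F-test.
#' @return A `rhythm_fit` object with fields `period_h`, `amplitude`,
#'   `acrophase_ct`, `rae`, `n_components`, `residual_sse`, `rhythmic` and a
#'   `components` tibble. A constant (or spectrally empty) trace returns
#'   `rhythmic = FALSE` with `NA` period, no error.
#' @export
fit_fft_nlls <- function(trace, window = c(15, 35), rae_threshold = 0.6,
                         max_components = 5L, alpha = 0.05) {
  stopifnot(is.data.frame(trace),
            all(c("time_h", "luminescence") %in% names(trace)))
  t <- as.numeric(trace$time_h)
  y <- as.numeric(trace$luminescence)
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 8) abort("Trace too short to fit.")
  span <- max(t) - min(t)
  if (span < 2 * window[1]) {
    abort(sprintf("Trace span %.1f h is shorter than twice the minimum period (%.1f h).",
                  span, window[1]))
  }

  # (1) linear detrend
  fit0 <- stats::lm.fit(cbind(1, t), y)
  r <- fit0$residuals
  empty_fit <- function() {
    structure(
      list(period_h = NA_real_, amplitude = NA_real_, acrophase_ct = NA_real_,
           rae = NA_real_, n_components = 0L, residual_sse = sum(r^2),
           rhythmic = FALSE,
           components = tibble(period_h = numeric(), amplitude = numeric(),
                               acrophase_ct = numeric(), rae = numeric()),
           window = window, rae_threshold = rae_threshold,
           trace = tibble(time_h = t, luminescence = y),
           trend = stats::setNames(fit0$coefficients, c("intercept", "slope")),
           fitted = fit0$fitted.values),
      class = "rhythm_fit"
    )
  }
  if (stats::sd(r) < 1e-12 * (1 + abs(mean(y)))) return(empty_fit())

  # (2) candidate periods from the zero-padded periodogram
  dt <- stats::median(diff(t))
  npad <- 8 * 2^ceiling(log2(length(r)))
  pw <- Mod(stats::fft(c(r - mean(r), rep(0, npad - length(r)))))[
    2:floor(npad / 2)]^2
  freq <- (seq_along(pw)) / (npad * dt)
  per <- 1 / freq
  inside <- per >= window[1] & per <= window[2]
  is_peak <- c(FALSE, diff(sign(diff(pw))) < 0, FALSE) # local maxima
  cand <- per[inside & is_peak]
  cand <- cand[order(-pw[inside & is_peak])]
  if (length(cand) == 0) {
    cand <- per[inside][which.max(pw[inside])] # strongest in-window bin
  }
  if (length(cand) == 0) return(empty_fit())

  # variable projection: given periods, solve the linear coefficients
  # (intercept, trend slope, cos/sin pair per component) in closed form
  design <- function(taus) {
    X <- matrix(1, length(t), 2 + 2 * length(taus))
    X[, 2] <- t
    for (i in seq_along(taus)) {
      w <- 2 * pi / taus[i]
      X[, 2 * i + 1] <- cos(w * t)
      X[, 2 * i + 2] <- sin(w * t)
    }
    X
  }
  proj_sse <- function(taus) {
    if (any(taus < window[1]) || any(taus > window[2])) return(Inf)
    f <- stats::lm.fit(design(taus), y)
    sum(f$residuals^2)
  }
  refine <- function(taus) {
    if (length(taus) == 1) {
      o <- stats::optimize(function(p) proj_sse(p),
                           lower = max(window[1], taus - 2),
                           upper = min(window[2], taus + 2), tol = 1e-6)
      list(taus = o$minimum, sse = o$objective)
    } else {
      o <- stats::optim(taus, proj_sse, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
      list(taus = o$par, sse = o$value)
    }
  }

  # (3) add components while the F-test improves the fit
  nobs <- length(t)
  used <- refine(cand[1])
  k <- 1L
  sse_floor <- 1e-12 * sum((y - mean(y))^2) # numerically perfect already
  repeat {
    if (k >= max_components || k >= length(cand)) break
    if (used$sse <= sse_floor) break
    trial <- refine(c(used$taus, cand[k + 1]))
    p_new <- 2 + 3 * (k + 1)
    df2 <- nobs - p_new
    if (df2 <= 0) break
    fstat <- ((used$sse - trial$sse) / 3) / (trial$sse / df2)
    if (is.finite(fstat) &&
        stats::pf(fstat, 3, df2, lower.tail = FALSE) < alpha) {
      used <- trial
      k <- k + 1L
    } else break
  }
  taus <- unname(used$taus)
  X <- design(taus)
  lin <- stats::lm.fit(X, y)
  beta <- unname(lin$coefficients)
  sse <- sum(lin$residuals^2)
  p <- 2 + 3 * k
  dfree <- nobs - p

  # (4) linearised covariance over (c, slope, a_i, b_i, tau_i) at the optimum
  J <- matrix(0, nobs, p)
  J[, 1] <- 1
  J[, 2] <- t
  for (i in seq_len(k)) {
    w <- 2 * pi / taus[i]
    a <- beta[2 * i + 1]; b <- beta[2 * i + 2]
    J[, 3 * i] <- cos(w * t)
    J[, 3 * i + 1] <- sin(w * t)
    J[, 3 * i + 2] <- (w * t / taus[i]) * (a * sin(w * t) - b * cos(w * t))
  }
  sigma2 <- if (dfree > 0) sse / dfree else 0
  cov <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  comp <- purrr::map_dfr(seq_len(k), function(i) {
    a <- beta[2 * i + 1]; b <- beta[2 * i + 2]
    A <- sqrt(a^2 + b^2)
    phase <- (atan2(b, a) * taus[i] / (2 * pi)) %% taus[i]
    rae <- if (A <= 0) Inf else if (is.null(cov) || sigma2 <= 0) 0 else {
      g <- c(a, b) / A
      se_A <- sqrt(max(0, drop(t(g) %*% cov[c(3 * i, 3 * i + 1),
                                             c(3 * i, 3 * i + 1)] %*% g)))
      stats::qt(0.975, max(dfree, 1)) * se_A / A
    }
    tibble(period_h = taus[i], amplitude = A, acrophase_ct = phase, rae = rae)
  })

  # (5) report the in-window component with the smallest RAE
  best <- which.min(comp$rae)
  structure(
    list(
      period_h = comp$period_h[best],
      amplitude = comp$amplitude[best],
      acrophase_ct = comp$acrophase_ct[best],
      rae = comp$rae[best],
      n_components = k,
      residual_sse = sse,
      rhythmic = is.finite(comp$rae[best]) && comp$rae[best] < rae_threshold,
      components = comp,
      window = window,
      rae_threshold = rae_threshold,
      trace = tibble(time_h = t, luminescence = y),
      trend = stats::setNames(beta[1:2], c("intercept", "slope")),
      fitted = lin$fitted.values
    ),
    class = "rhythm_fit"
  )
}

#' @export
print.rhythm_fit <- function(x, ...) {
  if (is.na(x$period_h)) {
    cat("<rhythm_fit> arrhythmic (no resolvable in-window component)\n")
  } else {
    cat(sprintf(
      "<rhythm_fit> period %.2f h, amplitude %.3g, acrophase CT %.2f, RAE %.3f (%s; %d component%s)\n",
      x$period_h, x$amplitude, x$acrophase_ct, x$rae,
      if (x$rhythmic) "rhythmic" else "arrhythmic",
      x$n_components, if (x$n_components == 1) "" else "s"
    ))
  }
  invisible(x)
}

#' @rdname fit_fft_nlls
#' @param x A `rhythm_fit` object.
#' @param ... Unused.
#' @export
tidy.rhythm_fit <- function(x, ...) x$components

#' @rdname fit_fft_nlls
#' @export
glance.rhythm_fit <- function(x, ...) {
  tibble(
    period_h = x$period_h, amplitude = x$amplitude,
    acrophase_ct = x$acrophase_ct, rae = x$rae,
    n_components = x$n_components, residual_sse = x$residual_sse,
    rhythmic = x$rhythmic
  )
}

#' Fit rhythms for every plant in a trace table
#'
#' Convenience wrapper applying [fit_fft_nlls()] per `plant_id`.
#'
#' @param traces A tibble as returned by [read_traces()] or
#'   [simulate_traces()].
#' @inheritParams fit_fft_nlls
#' @return A tibble with one row per plant: `plant_id`, `genotype` (if
#'   present) and the [generics::glance()] columns of each fit.
#' @export
fit_rhythms <- function(traces, window = c(15, 35), rae_threshold = 0.6,
                        max_components = 5L, alpha = 0.05) {
  stopifnot(is.data.frame(traces))
  traces |>
    dplyr::group_by(.data$plant_id) |>
    dplyr::group_modify(function(d, key) {
      g <- glance(fit_fft_nlls(d, window = window,
                               rae_threshold = rae_threshold,
                               max_components = max_components, alpha = alpha))
      if ("genotype" %in% names(d)) g <- dplyr::mutate(g, genotype = d$genotype[1],
                                                       .before = 1)
      g
    }) |>
    dplyr::ungroup()
}
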