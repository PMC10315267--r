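#' Compare circadian periods across genotypes
#'
#' One-way ANOVA of period length by genotype followed by Tukey's honest
#' significant difference post hoc test, with a compact letter display:
#' genotypes sharing a letter are not significantly different at `alpha`.
#'
#' @param data A data frame with columns `genotype` and `period_h`, or a named
#'   list of numeric period vectors.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return A `period_anova` object; `glance()` gives the ANOVA F and p,
#'   `tidy()` the Tukey pairwise table, and `$letters` the compact letter
#'   display.
#' @export
compare_periods <- function(data, alpha = 0.05) {
  if (is.list(data) && !is.data.frame(data)) {
    data <- tibble(
      genotype = rep(names(data), lengths(data)),
      period_h = unlist(data, use.names = FALSE)
    )
  }
  stopifnot(is.data.frame(data),
            all(c("genotype", "period_h") %in% names(data)))
  data <- data[!is.na(data$period_h), ]
  data$genotype <- factor(data$genotype)
  sizes <- table(data$genotype)
  if (length(sizes) < 2) abort("Need at least two genotypes.")
  if (any(sizes < 2)) {
    abort(sprintf("Each genotype needs n >= 2 periods; offending: %s.",
                  paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  fit <- stats::aov(period_h ~ genotype, data = data)
  # zero-residual designs trip base R's perfect-fit warning; that case is
  # resolved explicitly below
  an <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  ssb <- an[["Sum Sq"]][1]
  ssw <- an[["Sum Sq"]][2]
  if (ssb <= .Machine$double.eps * (1 + ssw)) {
    fval <- 0
    pval <- 1
  } else {
    fval <- an[["F value"]][1]
    pval <- an[["Pr(>F)"]][1]
    if (!is.finite(fval)) { # zero within-group variance, separated means
      fval <- Inf
      pval <- 0
    }
  }
  tk <- stats::TukeyHSD(fit)$genotype
  lev <- levels(data$genotype)
  idx <- utils::combn(length(lev), 2) # row order used by TukeyHSD
  pairs <- tibble(
    contrast = rownames(tk),
    group1 = lev[idx[2, ]],
    group2 = lev[idx[1, ]],
    estimate = tk[, "diff"],
    conf_low = tk[, "lwr"],
    conf_high = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
  # zero-residual designs make Tukey p NaN; resolve by the separation limit
  bad <- !is.finite(pairs$p_adj)
  pairs$p_adj[bad] <- ifelse(abs(pairs$estimate[bad]) < 1e-12, 1, 0)
  means <- tapply(data$period_h, data$genotype, mean)
  letters <- cld_letters(means, pairs, alpha = alpha)
  structure(
    list(F = fval, p = pval, pairwise = pairs, letters = letters,
         means = tibble(genotype = names(means), mean_period_h = as.numeric(means),
                        n = as.integer(sizes[names(means)])),
         alpha = alpha),
    class = "period_anova"
  )
}

# compact letter display from Tukey pairwise p-values: sweep groups in mean
# order, keep maximal runs whose pairs are all non-significant
cld_letters <- function(means, pairs, alpha = 0.05) {
  g <- names(sort(means))
  k <- length(g)
  ns <- matrix(TRUE, k, k, dimnames = list(g, g))
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$group1[r]; b <- pairs$group2[r]
    ns[a, b] <- ns[b, a] <- pairs$p_adj[r] >= alpha
  }
  runs <- list()
  for (s in seq_len(k)) {
    e <- s
    while (e < k && all(ns[s:(e + 1), s:(e + 1)])) e <- e + 1
    runs[[s]] <- s:e
  }
  keep <- !vapply(seq_along(runs), function(i) {
    any(vapply(seq_along(runs), function(j) {
      j != i && all(runs[[i]] %in% runs[[j]])
    }, TRUE))
  }, TRUE)
  runs <- runs[keep]
  lab <- stats::setNames(rep("", k), g)
  for (i in seq_along(runs)) {
    lab[runs[[i]]] <- paste0(lab[runs[[i]]], letters[i])
  }
  tibble(genotype = g, letters = unname(lab))[match(names(means), g), ]
}

#' @export
print.period_anova <- function(x, ...) {
  cat(sprintf("<period_anova> F = %.3g, p = %.3g\n", x$F, x$p))
  df <- dplyr::left_join(x$means, x$letters, by = "genotype")
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %s: %.2f h (n = %d) %s\n", df$genotype[i],
                df$mean_period_h[i], df$n[i], df$letters[i]))
  }
  invisible(x)
}

#' @rdname compare_periods
#' @param x A `period_anova` object.
#' @param ... Unused.
#' @export
tidy.period_anova <- function(x, ...) x$pairwise

#' @rdname compare_periods
#' @export
glance.period_anova <- function(x, ...) {
  tibble(F = x$F, p_value = x$p, n_groups = nrow(x$means))
}
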