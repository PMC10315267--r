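#' Hypergeometric term enrichment of an interactor set
#'
#' One-sided (upper tail) hypergeometric test per annotation term: with a
#' population of `N` loci of which `K` carry the term, and a study set of `n`
#' loci of which `k` carry it, the reported p-value is `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`. Terms with no annotated locus in the
#' population are dropped. Rows are ordered by raw p-value, ties by term.
#'
#' @param study Character vector of AGI loci (must be a subset of
#'   `population`).
#' @param population Character vector of AGI loci forming the background;
#'   the conventional choice is every protein detected across all runs before
#'   filtering.
#' @param annotation A flat annotation map: tibble with columns `agi_locus`,
#'   `term` (see [read_annotation_map()]) or a named list term -> loci.
#' @param correction `"none"` (raw p-values, the default) or `"bh"`
#'   (Benjamini-Hochberg across the reported terms).
#' @return A tibble with columns `term`, `k`, `K`, `n`, `N`, `p_raw`, `p_adj`.
#' @export
enrich_terms <- function(study, population, annotation,
                         correction = c("none", "bh")) {
  correction <- match.arg(correction)
  study <- unique(assert_agi(study))
  population <- unique(assert_agi(population))
  if (length(study) == 0) abort("Empty study set.")
  outside <- setdiff(study, population)
  if (length(outside) > 0) {
    abort(sprintf("Study loci not in the population: %s.",
                  paste(utils::head(outside, 5), collapse = ", ")))
  }
  if (is.list(annotation) && !is.data.frame(annotation)) {
    annotation <- tibble(
      term = rep(names(annotation), lengths(annotation)),
      agi_locus = unlist(annotation, use.names = FALSE)
    )
  }
  annotation <- as_tibble(annotation)
  annotation$agi_locus <- assert_agi(annotation$agi_locus)
  annotation <- dplyr::distinct(annotation, .data$term, .data$agi_locus)
  annotation <- annotation[annotation$agi_locus %in% population, ]
  if (nrow(annotation) == 0) {
    abort("No annotated locus intersects the population.")
  }
  N <- length(population)
  n <- length(intersect(study, population))
  res <- annotation |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      k = sum(.data$agi_locus %in% study),
      K = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n = n,
      N = N,
      p_raw = stats::phyper(.data$k - 1L, .data$K, N - .data$K, n,
                            lower.tail = FALSE)
    ) |>
    dplyr::arrange(.data$p_raw, .data$term)
  res$p_adj <- if (correction == "bh") stats::p.adjust(res$p_raw, "BH") else res$p_raw
  res
}
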