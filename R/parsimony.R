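#' Parsimony grouping of proteins by shared peptide evidence
#'
#' Proteins that cannot be distinguished by their peptide evidence are
#' collapsed: identical peptide sets merge into one group, and a protein whose
#' peptide set is a strict subset of another's is absorbed into that
#' superset's group (its spectra are explainable by the superset protein).
#' Proteins that share peptides without nesting stay separate groups but are
#' linked into the same cluster, so a cluster is a connected component of the
#' shared-evidence graph and every protein appears exactly once.
#'
#' @param evidence A peptide-evidence map: either a tibble with columns
#'   `peptide`, `agi_locus` (one row per peptide-to-protein assignment) or a
#'   named list mapping peptide sequence to a character vector of loci.
#' @return A tibble with columns `agi_locus`, `group_id`, `group_representative`,
#'   `cluster_id`, `n_peptides`.
#' @export
group_by_parsimony <- function(evidence) {
  if (is.list(evidence) && !is.data.frame(evidence)) {
    evidence <- tibble(
      peptide = rep(names(evidence), lengths(evidence)),
      agi_locus = unlist(evidence, use.names = FALSE)
    )
  }
  evidence <- as_tibble(evidence)
  if (!all(c("peptide", "agi_locus") %in% names(evidence))) {
    abort("Evidence map needs columns 'peptide' and 'agi_locus'.")
  }
  if (nrow(evidence) == 0) abort("Empty peptide-evidence map.")
  if (any(!grepl("^[A-Z]+$", evidence$peptide))) {
    abort("Peptides must be non-empty upper-case amino-acid strings.")
  }
  evidence$agi_locus <- assert_agi(evidence$agi_locus)
  pepsets <- lapply(split(evidence$peptide, evidence$agi_locus), unique)
  loci <- names(pepsets)
  n <- length(loci)

  # group assignment: identical sets merge; strict subsets are absorbed into
  # the largest superset (ties by locus), following chains to a maximal set
  sizes <- lengths(pepsets)
  ord <- order(-sizes, loci, method = "radix")
  parent <- stats::setNames(loci, loci)
  for (i in seq_len(n)) {
    a <- ord[i]
    for (j in seq_len(i - 1L)) {
      b <- ord[j]
      if (sizes[b] >= sizes[a] && all(pepsets[[a]] %in% pepsets[[b]])) {
        parent[loci[a]] <- loci[b] # first candidate = largest, then smallest locus
        break
      }
    }
  }
  root <- function(v) {
    while (parent[[v]] != v) v <- parent[[v]]
    v
  }
  group_rep <- vapply(loci, root, "")
  group_id <- match(group_rep, sort(unique(group_rep)))

  # clusters: connected components over shared peptides
  comp <- seq_len(n)
  by_pep <- split(match(evidence$agi_locus, loci), evidence$peptide)
  find <- function(i) {
    while (comp[i] != i) i <- comp[i]
    i
  }
  for (members in by_pep) {
    members <- unique(members)
    r <- find(members[1])
    for (m in members[-1]) {
      rm <- find(m)
      if (rm != r) comp[max(r, rm)] <- min(r, rm)
      r <- min(r, rm)
    }
  }
  comp_root <- vapply(seq_len(n), find, 1L)
  cluster_id <- match(comp_root, sort(unique(comp_root)))

  tibble(
    agi_locus = loci,
    group_id = group_id,
    group_representative = unname(group_rep),
    cluster_id = cluster_id,
    n_peptides = unname(sizes)
  )
}
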