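two_rep_counts <- function(up1, up2, c1 = 5L, c2 = 5L) {
  cnt <- matrix(as.integer(c(max(c1, up1), max(c2, up2))), 1, 2,
                dimnames = list("AT1G00010", c("B_ZT5_1", "B_ZT5_2")))
  up <- matrix(as.integer(c(up1, up2)), 1, 2, dimnames = dimnames(cnt))
  make_counts(cnt, unique_peptides = up)
}

test_that("evidence rule keeps two-peptide or multi-replicate identifications", {
  kept <- apply_evidence_filter(two_rep_counts(2, 0))
  expect_equal(nrow(kept$proteins), 1)
  dropped <- apply_evidence_filter(two_rep_counts(1, 0))
  expect_equal(nrow(dropped$proteins), 0)
  rescued <- apply_evidence_filter(two_rep_counts(1, 1))
  expect_equal(nrow(rescued$proteins), 1)
  # rule applies per bait x timepoint group: one peptide split across
  # different groups is not a multi-replicate rescue
  cnt <- matrix(c(1L, 1L), 1, 2,
                dimnames = list("AT1G00010", c("B_ZT5_1", "B_ZT9_1")))
  up <- matrix(c(1L, 1L), 1, 2, dimnames = dimnames(cnt))
  split_groups <- apply_evidence_filter(make_counts(cnt, unique_peptides = up))
  expect_equal(nrow(split_groups$proteins), 0)
})

test_that("evidence filtering is monotone in min_unique_peptides", {
  set.seed(11)
  for (rep in 1:20) {
    cnt <- matrix(rpois(8, 3), 2, 4,
                  dimnames = list(c("AT1G00010", "AT2G00020"),
                                  c("B_ZT5_1", "B_ZT5_2", "B_ZT9_1", "B_ZT9_2")))
    up <- matrix(pmin(cnt, rpois(8, 1.5)), 2, 4, dimnames = dimnames(cnt))
    x <- make_counts(cnt, unique_peptides = up)
    kept <- lapply(1:4, function(m) {
      apply_evidence_filter(x, evidence_thresholds(min_unique_peptides = m))$proteins$agi_locus
    })
    for (m in 2:4) expect_true(all(kept[[m]] %in% kept[[m - 1]]))
  }
})

test_that("without peptide evidence the filter is a logged no-op", {
  cnt <- matrix(3L, 1, 1, dimnames = list("AT1G00010", "B_ZT5_1"))
  x <- make_counts(cnt)
  expect_message(y <- apply_evidence_filter(x), "skipped")
  expect_equal(y$counts, x$counts)
})

test_that("peptide tables are thresholded and checked against runs", {
  cnt <- matrix(c(6L, 6L), 1, 2,
                dimnames = list("AT1G00010", c("B_ZT5_1", "B_ZT5_2")))
  x <- make_counts(cnt)
  peps <- random_peptides(3)
  pt <- tibble::tibble(
    run_id = c("B_ZT5_1", "B_ZT5_1", "B_ZT5_1"),
    agi_locus = "AT1G00010",
    peptide = peps,
    probability = c(0.99, 0.99, 0.50), # third fails the probability cut
    fdr = c(0.001, 0.001, 0.001)
  )
  y <- apply_evidence_filter(x, peptide_table = pt)
  expect_equal(unname(y$unique_peptides["AT1G00010", "B_ZT5_1"]), 2L)
  expect_equal(nrow(y$proteins), 1)
  # failing both clauses once thresholds remove support
  pt$probability <- c(0.99, 0.5, 0.5)
  expect_equal(nrow(apply_evidence_filter(x, peptide_table = pt)$proteins), 0)
  pt$run_id[1] <- "nonexistent_run"
  expect_error(apply_evidence_filter(x, peptide_table = pt), "nonexistent_run")
})

test_that("control subtraction excludes on any control identification and is idempotent", {
  cnt <- matrix(as.integer(c(
    10, 12, 1, 0,   # seen once in a control -> removed
    10, 12, 0, 0,   # clean -> retained
    0, 3, 2, 2      # sticky -> removed
  )), 3, 4, byrow = TRUE,
  dimnames = list(c("AT1G00010", "AT2G00020", "AT3G00030"),
                  c("B_ZT5_1", "B_ZT5_2", "none_ZT5_1", "none_ZT5_2")))
  x <- make_counts(cnt)
  y <- subtract_controls(x)
  expect_equal(y$proteins$agi_locus, "AT2G00020")
  expect_false(any(y$runs$is_control))
  expect_equal(nrow(y$runs), 2)
  # idempotent (second call warns about missing controls, output unchanged)
  expect_warning(z <- subtract_controls(y), "skipped")
  expect_equal(z$counts, y$counts)
  # boundary: every protein control-listed
  allbg <- make_counts(matrix(
    as.integer(c(5, 1)), 1, 2,
    dimnames = list("AT1G00010", c("B_ZT5_1", "none_ZT5_1"))))
  e <- subtract_controls(allbg)
  expect_equal(nrow(e$proteins), 0)
  expect_equal(e$runs$run_id, "B_ZT5_1")
})

test_that("interactor calls reproduce the curated-table counts", {
  t1 <- load_table_fixture("table1")
  t2 <- load_table_fixture("table2")
  rve8_zt9 <- call_interactors(t2, "RVE8HFC", 9)
  expect_true(all(c("AT5G42900", "AT2G32950") %in% rve8_zt9$agi_locus))
  expect_equal(rve8_zt9$per_replicate[[which(rve8_zt9$agi_locus == "AT5G42900")]],
               c(4L, 7L)) # COR27
  expect_equal(rve8_zt9$per_replicate[[which(rve8_zt9$agi_locus == "AT2G32950")]],
               c(3L, 4L)) # COP1
  # COR27 is absent from every ZT5 pull-down
  expect_false("AT5G42900" %in% call_interactors(t1, "RVE8HFC", 5)$agi_locus)
  # ordering: descending max spectra, ties by locus
  expect_equal(rve8_zt9$max_spectra, sort(rve8_zt9$max_spectra, decreasing = TRUE))
  # all-zero group yields an empty call
  cnt <- matrix(c(0L, 0L, 3L, 3L), 1, 4,
                dimnames = list("AT1G00010",
                                c("B_ZT5_1", "B_ZT5_2", "B_ZT9_1", "B_ZT9_2")))
  expect_equal(nrow(call_interactors(make_counts(cnt), "B", 5)), 0)
  expect_error(call_interactors(t1, "NOSUCH", 5), "Available groups")
})

test_that("pooled two-timepoint classification matches the curated tables", {
  t1 <- load_table_fixture("table1")
  t2 <- load_table_fixture("table2")
  baits <- c("LNK1HFC", "LNK2HFC", "RVE8HFC")
  early <- lapply(baits, function(b) call_interactors(t1, b, 5))
  late <- lapply(baits, function(b) call_interactors(t2, b, 9))
  cls <- classify_timepoints(early, late)
  lab <- tidy(cls)
  get <- function(l) lab$label[lab$agi_locus == l]
  # the four evening-specific interactors
  expect_equal(get("AT5G42900"), "late_only") # COR27
  expect_equal(get("AT4G33980"), "late_only") # COR28
  expect_equal(get("AT2G32950"), "late_only") # COP1
  expect_equal(get("AT2G46340"), "late_only") # SPA1
  # the two all-day cold-response interactors
  expect_equal(get("AT3G55580"), "shared") # TCF1
  expect_equal(get("AT3G53830"), "shared") # RCC1L
  # set difference of the printed tables gives 10 evening-only loci
  expect_equal(unname(cls$counts["late_only"]), 10)
  # partition identity
  expect_equal(sum(cls$counts[c("early_only", "late_only", "shared")]),
               unname(cls$counts["union"]))
  # classification keys on locus, not name (PICALM3 vs ENTH/ANTH at AT5G35200)
  expect_equal(get("AT5G35200"), "shared")
  expect_error(classify_timepoints(early, early), "distinct timepoints")
})

test_that("per-bait partitions follow each bait's own calls", {
  t1 <- load_table_fixture("table1")
  t2 <- load_table_fixture("table2")
  cls <- classify_timepoints(
    list(call_interactors(t1, "RVE8HFC", 5)),
    list(call_interactors(t2, "RVE8HFC", 9))
  )
  pb <- cls$per_bait
  # COP1 only ever seen with RVE8 at ZT9
  expect_equal(pb$label[pb$agi_locus == "AT2G32950"], "late_only")
  # RVE6 with RVE8: ZT9 only (zero at ZT5 in the RVE8 runs)
  expect_equal(pb$label[pb$agi_locus == "AT5G52660"], "late_only")
})

test_that("bait self-capture maxima match the printed spectra", {
  t1 <- load_table_fixture("table1")
  t2 <- load_table_fixture("table2")
  expect_equal(bait_max_spectra(t2, "LNK1HFC", 9, "AT5G64170"), 621L)
  expect_equal(bait_max_spectra(t1, "LNK2HFC", 5, "AT3G54500"), 497L)
  # a locus with all-zero counts in the group gives zero
  expect_equal(bait_max_spectra(t2, "LNK2HFC", 9, "AT2G32950"), 0L) # COP1 zeros
  expect_error(bait_max_spectra(t1, "LNK1HFC", 5, "AT1G99999"), "AT1G99999")
})

test_that("cycling fraction counts annotated loci only", {
  cyc <- c(AT1G00010 = TRUE, AT2G00020 = TRUE, AT3G00030 = TRUE,
           AT4G00040 = FALSE)
  out <- cycling_fraction(names(cyc), cyc)
  expect_equal(out$fraction, 0.75)
  out2 <- cycling_fraction(c(names(cyc), "AT5G00050"), cyc)
  expect_equal(out2$n_unknown, 1)
  expect_equal(out2$fraction, 0.75)
  empty <- cycling_fraction(character(), cyc)
  expect_true(is.na(empty$fraction))
  expect_equal(empty$n_annotated, 0)
  # table3 against its own footnote flags: 12 of 21 cycling
  t3 <- load_table_fixture("table3")
  frac <- cycling_fraction(t3$proteins$agi_locus, t3$proteins)
  expect_equal(frac$fraction, 12 / 21)
})
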