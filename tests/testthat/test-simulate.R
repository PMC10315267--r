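test_that("generators are seed-deterministic and seed-sensitive", {
  c1 <- apms_sim_config(seed = 42)
  s1 <- simulate_apms(c1)
  s2 <- simulate_apms(apms_sim_config(seed = 42))
  expect_identical(s1$matrix$counts, s2$matrix$counts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_apms(apms_sim_config(seed = 43))
  expect_false(identical(s1$matrix$counts, s3$matrix$counts))
  t1 <- simulate_traces(trace_sim_config(seed = 7, n_plants = 2))
  t2 <- simulate_traces(trace_sim_config(seed = 7, n_plants = 2))
  expect_identical(t1$traces, t2$traces)
  q1 <- simulate_quant(seed = 5)
  q2 <- simulate_quant(seed = 5)
  expect_identical(q1$plates, q2$plates)
  expect_error(apms_sim_config(), "seed")
  expect_error(trace_sim_config(), "seed")
})

test_that("generated artifacts pass the corresponding readers' validation", {
  sim <- simulate_apms(apms_sim_config(seed = 1))
  expect_s3_class(sim$matrix, "spectral_counts") # constructor re-validates
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectral_counts(sim$matrix, path)
  rt <- read_spectral_counts(path, "wide")
  expect_equal(rt$counts, sim$matrix$counts)
  tr <- simulate_traces(trace_sim_config(seed = 2, n_plants = 2))
  tpath <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tr$traces, tpath)
  expect_equal(nrow(read_traces(tpath)), nrow(tr$traces))
  q <- simulate_quant(seed = 3)
  expect_s3_class(normalize_blot(q$densitometry), "tbl_df")
})

test_that("planted window-specific interactors classify by construction", {
  cfg <- apms_sim_config(
    baits = "B1",
    true_interactome = tibble::tibble(
      bait = "B1", agi_locus = "AT1G11111", capture_strength = 20,
      window_start = 8, window_end = 10 # covers ZT9 only
    ),
    n_background_proteins = 10, seed = 4
  )
  sim <- simulate_apms(cfg)
  clean <- subtract_controls(apply_evidence_filter(sim$matrix))
  cls <- classify_timepoints(
    list(call_interactors(clean, "B1", 5)),
    list(call_interactors(clean, "B1", 9))
  )
  expect_equal(tidy(cls)$label[tidy(cls)$agi_locus == "AT1G11111"], "late_only")
})

test_that("an all-background simulation yields empty interactor sets", {
  cfg <- apms_sim_config(
    baits = "B1",
    true_interactome = tibble::tibble(
      bait = character(), agi_locus = character(), capture_strength = numeric(),
      window_start = numeric(), window_end = numeric()
    ),
    n_background_proteins = 25, seed = 5
  )
  sim <- simulate_apms(cfg)
  clean <- subtract_controls(apply_evidence_filter(sim$matrix))
  expect_equal(nrow(call_interactors(clean, "B1", 5)), 0)
  expect_equal(nrow(call_interactors(clean, "B1", 9)), 0)
})

test_that("planted interactors are recovered perfectly over seeds", {
  for (seed in 1:10) {
    cfg <- apms_sim_config(seed = seed)
    sim <- simulate_apms(cfg)
    clean <- suppressMessages(subtract_controls(apply_evidence_filter(sim$matrix)))
    called <- purrr::map_dfr(unique(cfg$true_interactome$bait), function(b) {
      dplyr::bind_rows(lapply(cfg$timepoints, function(zt) {
        call_interactors(clean, b, zt)[, c("agi_locus", "bait", "timepoint_zt")]
      }))
    })
    truth <- sim$truth[sim$truth$role == "interactor", ]
    in_window <- function(zt, s, e) if (s <= e) zt >= s & zt < e else zt >= s | zt < e
    expected <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
      zts <- cfg$timepoints[in_window(cfg$timepoints, truth$window_start[i],
                                      truth$window_end[i])]
      tibble::tibble(agi_locus = truth$agi_locus[i], bait = truth$bait[i],
                     timepoint_zt = zts)
    })
    # recall 1: every planted (bait, window-timepoint, locus) is called
    expect_equal(nrow(dplyr::anti_join(
      expected, called, by = c("agi_locus", "bait", "timepoint_zt"))), 0)
    # zero background survival
    bg <- sim$truth$agi_locus[sim$truth$role == "background"]
    expect_equal(length(intersect(called$agi_locus, bg)), 0)
  }
})

test_that("trace generator honors its relock caricature", {
  # relock 0: offset constant across entrainment days
  cfg0 <- trace_sim_config(
    genotypes = tibble::tibble(genotype = "stuck", period_h = 26,
                               initial_offset_h = 5, relock_h_per_day = 0,
                               damping_h = 96),
    n_plants = 4, noise_sd = 0, seed = 11
  )
  sim0 <- simulate_traces(cfg0)
  expect_true(all(sim0$truth$offset_h == 5))
  ent <- sim0$traces[sim0$traces$condition_segment != "LL" &
                       sim0$traces$plant_id == sim0$traces$plant_id[1], ]
  ent$time_h <- ent$time_h - min(ent$time_h)
  ac <- daily_acrophase(ent)
  expect_equal(diff(range(ac$acrophase)), 0, tolerance = 0.5)
  # large relock: already at target on day 1
  cfgF <- trace_sim_config(
    genotypes = tibble::tibble(genotype = "fast", period_h = 24.6,
                               initial_offset_h = 5, relock_h_per_day = 24,
                               damping_h = 96),
    n_plants = 2, noise_sd = 0, seed = 12
  )
  simF <- simulate_traces(cfgF)
  expect_true(all(simF$truth$offset_h[simF$truth$day >= 1] == 0))
})

test_that("entrainment pipeline finds the configured resynchronization", {
  cfg <- trace_sim_config(seed = 19) # WT fast relock, mutant 6 h offset at 2 h/day
  sim <- simulate_traces(cfg)
  ent <- sim$traces[sim$traces$condition_segment != "LL", ]
  ent$time_h <- ent$time_h - min(ent$time_h)
  ser <- acrophase_series(ent)
  cmp <- compare_acrophases(ser, "WT")
  res <- glance(cmp)
  day_mut <- res$resync_day[res$genotype == "mutant"]
  # offset hits 0 on day 3 (6 - 2*3); significant before, aligned after
  expect_true(!is.na(day_mut) && day_mut <= 3)
  expect_true(tidy(cmp)$significant[tidy(cmp)$genotype == "mutant" &
                                      tidy(cmp)$day == 0])
})

test_that("evening-stabilization blots flag only the affected timepoints", {
  sim <- simulate_quant(seed = 23)
  norm <- normalize_blot(sim$densitometry)
  tests <- purrr::map_dfr(unique(norm$timepoint_zt), function(zt) {
    a <- norm$normalized[norm$genotype == "mutant" & norm$timepoint_zt == zt]
    b <- norm$normalized[norm$genotype == "WT" & norm$timepoint_zt == zt]
    dplyr::mutate(welch_t(a, b), timepoint_zt = zt)
  })
  flagged <- tests$timepoint_zt[tests$p_value < 0.05]
  affected <- unique(norm$timepoint_zt[norm$timepoint_zt >= sim$truth$effect_zt_min])
  # every stabilised timepoint flagged; unaffected mornings at most type-I noise
  expect_true(all(affected %in% flagged))
  expect_lte(sum(flagged < sim$truth$effect_zt_min), 1)
})

test_that("a zero-effect blot simulation flags at about the type-I rate", {
  hits <- 0; total <- 0
  for (seed in 1:40) {
    sim <- simulate_quant(seed = seed, blot_effect_fold = 1)
    norm <- normalize_blot(sim$densitometry)
    for (zt in unique(norm$timepoint_zt)) {
      a <- norm$normalized[norm$genotype == "mutant" & norm$timepoint_zt == zt]
      b <- norm$normalized[norm$genotype == "WT" & norm$timepoint_zt == zt]
      hits <- hits + (welch_t(a, b)$p_value < 0.05)
      total <- total + 1
    }
  }
  expect_gt(hits / total, 0.01)
  expect_lt(hits / total, 0.10)
})
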