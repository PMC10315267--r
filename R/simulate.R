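#' Configuration for a synthetic APMS experiment
#'
#' Defaults emulate the design of the time-of-day APMS experiments: three
#' tagged baits purified at ZT5 and ZT9 in two replicates each, plus negative
#' controls, with a planted interactome in which some preys are captured all
#' day and others only inside a time-of-day expression window. Spectral
#' counts are negative binomial (overdispersion is the norm for spectral
#' counting). Two guarantees make planted truth exactly recoverable: every
#' interactor receives at least one spectrum (and evidence-rule-passing
#' peptide support) inside its window, and every background protein is seen
#' in at least one negative-control run.
#'
#' @param baits Character vector of bait names.
#' @param timepoints Zeitgeber times sampled (hours).
#' @param replicates Replicates per bait x timepoint.
#' @param true_interactome Tibble with columns `bait`, `agi_locus`,
#'   `capture_strength`, `window_start`, `window_end` (ZT hours; a window
#'   covering `[0, 24)` means captured all day). Default: per bait one
#'   early-window prey, one late-window prey and two all-day preys.
#' @param n_background_proteins Sticky background proteins present in bait and
#'   control runs alike.
#' @param background_mean Mean spectral count of a background protein (its
#'   per-protein stickiness is gamma-distributed around this).
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param n_control_runs Number of negative-control purifications.
#' @param seed Mandatory RNG seed.
#' @return An `apms_sim_config` list.
#' @export
apms_sim_config <- function(baits = c("BAITA", "BAITB", "BAITC"),
                            timepoints = c(5, 9),
                            replicates = 2L,
                            true_interactome = NULL,
                            n_background_proteins = 40L,
                            background_mean = 3,
                            dispersion = 0.5,
                            n_control_runs = 2L,
                            seed) {
  if (missing(seed)) abort("apms_sim_config requires a seed.")
  stopifnot(length(timepoints) == 2, replicates >= 1, dispersion > 0,
            background_mean > 0, n_control_runs >= 1)
  if (is.null(true_interactome)) {
    true_interactome <- purrr::map_dfr(seq_along(baits), function(i) {
      base <- (i - 1) * 4
      tibble(
        bait = baits[i],
        agi_locus = sprintf("AT%dG%05d", (base %% 5) + 1, 10010 + base * 10 + 0:3),
        capture_strength = c(25, 25, 40, 15),
        window_start = c(min(timepoints) - 2, max(timepoints) - 2, 0, 0),
        window_end = c(min(timepoints) + 2, max(timepoints) + 2, 24, 24)
      )
    })
  }
  stopifnot(all(true_interactome$capture_strength > 0))
  structure(
    list(baits = baits, timepoints = sort(timepoints),
         replicates = as.integer(replicates),
         true_interactome = as_tibble(true_interactome),
         n_background_proteins = as.integer(n_background_proteins),
         background_mean = background_mean, dispersion = dispersion,
         n_control_runs = as.integer(n_control_runs), seed = as.integer(seed)),
    class = "apms_sim_config"
  )
}

rnbinom_mu <- function(n, mu, dispersion) {
  stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate an APMS spectral-count experiment with known truth
#'
#' @param config An [apms_sim_config].
#' @return A list with `matrix` (a [spectral_counts] with unique peptides) and
#'   `truth` (tibble: `agi_locus`, `role` in `interactor`/`background`,
#'   `bait`, `window_start`, `window_end`).
#' @export
simulate_apms <- function(config) {
  stopifnot(inherits(config, "apms_sim_config"))
  set.seed(config$seed)
  runs <- tidyr::expand_grid(
    bait = config$baits, timepoint_zt = config$timepoints,
    replicate = seq_len(config$replicates)
  )
  ctrl_zt <- rep(config$timepoints, length.out = config$n_control_runs)
  ctrl <- tibble(
    bait = "none",
    timepoint_zt = ctrl_zt,
    replicate = as.integer(stats::ave(seq_along(ctrl_zt), ctrl_zt,
                                      FUN = seq_along))
  )
  runs <- dplyr::bind_rows(runs, ctrl)
  runs$run_id <- sprintf("%s_ZT%g_%d", runs$bait, runs$timepoint_zt,
                         runs$replicate)
  runs$is_control <- runs$bait == "none"

  ti <- config$true_interactome
  int_loci <- unique(ti$agi_locus)
  bg_loci <- sprintf("AT%dG%05d", (seq_len(config$n_background_proteins) %% 5) + 1,
                     50000 + seq_len(config$n_background_proteins))
  loci <- c(int_loci, bg_loci)
  proteins <- tibble(
    protein_name = loci, agi_locus = loci,
    mw_kda = round(stats::runif(length(loci), 10, 150)), cycling = NA
  )
  counts <- matrix(0L, length(loci), nrow(runs),
                   dimnames = list(loci, runs$run_id))

  in_window <- function(zt, s, e) {
    if (s <= e) zt >= s & zt < e else (zt >= s | zt < e) # window may wrap midnight
  }
  for (r in seq_len(nrow(ti))) {
    spec <- ti[r, ]
    cols <- which(!runs$is_control & runs$bait == spec$bait &
                    in_window(runs$timepoint_zt, spec$window_start, spec$window_end))
    if (length(cols) == 0) next
    mu <- spec$capture_strength
    draw <- rnbinom_mu(length(cols), mu, config$dispersion)
    counts[spec$agi_locus, cols] <-
      counts[spec$agi_locus, cols] + as.integer(draw)
  }
  sticky <- stats::rgamma(length(bg_loci), shape = 2,
                          scale = config$background_mean / 2)
  for (i in seq_along(bg_loci)) {
    counts[bg_loci[i], ] <- as.integer(
      rnbinom_mu(nrow(runs), sticky[i], config$dispersion))
  }

  # generator guarantees (see the methods vignette): interactors are always
  # detectable in-window with evidence-passing support; background proteins
  # are always on the control list
  grp_cols <- split(seq_len(nrow(runs)),
                    paste(runs$bait, runs$timepoint_zt, sep = "@"))
  for (r in seq_len(nrow(ti))) {
    spec <- ti[r, ]
    for (zt in config$timepoints) {
      if (!in_window(zt, spec$window_start, spec$window_end)) next
      cols <- grp_cols[[paste(spec$bait, zt, sep = "@")]]
      if (max(counts[spec$agi_locus, cols]) < 2L) {
        counts[spec$agi_locus, cols[1]] <- 2L
      }
    }
  }
  ctrl_cols <- which(runs$is_control)
  for (i in seq_along(bg_loci)) {
    if (all(counts[bg_loci[i], ctrl_cols] == 0L)) {
      counts[bg_loci[i], sample(ctrl_cols, 1)] <- 1L
    }
  }

  # unique peptides grow with spectra; >= 2 whenever >= 2 spectra so the
  # evidence rule keeps exactly what the counts support
  up <- matrix(0L, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  pos <- counts > 0L
  up[pos] <- pmin(counts[pos],
                  ifelse(counts[pos] == 1L, 1L,
                         2L + stats::rpois(sum(pos), counts[pos] / 5)))

  truth <- dplyr::bind_rows(
    dplyr::mutate(ti[, c("agi_locus", "bait", "window_start", "window_end")],
                  role = "interactor"),
    tibble(agi_locus = bg_loci, bait = NA_character_,
           window_start = NA_real_, window_end = NA_real_, role = "background")
  )
  list(
    matrix = spectral_counts(proteins, runs, counts, unique_peptides = up),
    truth = truth
  )
}

#' Configuration for synthetic luciferase traces
#'
#' Emulates an imaging experiment: a free run in constant conditions followed
#' by an entrainment segment (temperature or photo cycles). Each genotype has
#' a free-running period, an initial acrophase offset from the entrainer
#' target, and a relock rate: under entrainment the offset shrinks linearly
#' by `relock_h_per_day` each cycle (a deliberate caricature of phase
#' resetting, sufficient to exercise the acrophase pipeline). Noise is
#' multiplicative Gaussian.
#'
#' @param genotypes Tibble with columns `genotype`, `period_h`,
#'   `initial_offset_h`, `relock_h_per_day`, `damping_h`.
#' @param n_plants Plants per genotype.
#' @param free_run_h,entrain_h Segment lengths in hours.
#' @param entrain_cycle_h Entrainer cycle length (default 24).
#' @param target_acrophase_h Acrophase the entrainer pulls toward (hours into
#'   the cycle).
#' @param schedule `"nonramping"` (step temperature changes) or `"ramping"`
#'   (gradual oscillation between the extremes); labels the segment only, the
#'   phase-pull caricature is identical.
#' @param noise_sd Multiplicative noise standard deviation (fraction).
#' @param sample_interval_h Sampling interval (default 1, one image per hour).
#' @param seed Mandatory RNG seed.
#' @return A `trace_sim_config` list.
#' @export
trace_sim_config <- function(genotypes = tibble(
                               genotype = c("WT", "mutant"),
                               period_h = c(24.6, 26.5),
                               initial_offset_h = c(1, 6),
                               relock_h_per_day = c(6, 2),
                               damping_h = c(96, 96)
                             ),
                             n_plants = 16L,
                             free_run_h = 72,
                             entrain_h = 120,
                             entrain_cycle_h = 24,
                             target_acrophase_h = 6,
                             schedule = c("nonramping", "ramping"),
                             noise_sd = 0.05,
                             sample_interval_h = 1,
                             seed) {
  if (missing(seed)) abort("trace_sim_config requires a seed.")
  schedule <- match.arg(schedule)
  genotypes <- as_tibble(genotypes)
  stopifnot(all(genotypes$period_h > 15 & genotypes$period_h < 35),
            all(genotypes$relock_h_per_day >= 0))
  structure(
    list(genotypes = genotypes, n_plants = as.integer(n_plants),
         free_run_h = free_run_h, entrain_h = entrain_h,
         entrain_cycle_h = entrain_cycle_h,
         target_acrophase_h = target_acrophase_h, schedule = schedule,
         noise_sd = noise_sd, sample_interval_h = sample_interval_h,
         seed = as.integer(seed)),
    class = "trace_sim_config"
  )
}

#' Simulate luciferase reporter traces with known truth
#'
#' @param config A [trace_sim_config].
#' @return A list with `traces` (tibble: `plant_id`, `genotype`, `time_h`,
#'   `luminescence`, `condition_segment`) and `truth` (tibble: per genotype
#'   and entrainment day, the planted acrophase offset from the target).
#' @export
simulate_traces <- function(config) {
  stopifnot(inherits(config, "trace_sim_config"))
  set.seed(config$seed)
  dt <- config$sample_interval_h
  cyc <- config$entrain_cycle_h
  t_free <- seq(0, config$free_run_h - dt, by = dt)
  t_ent <- seq(0, config$entrain_h - dt, by = dt)
  base <- 100
  amp <- 40
  traces <- purrr::map_dfr(seq_len(nrow(config$genotypes)), function(gi) {
    g <- config$genotypes[gi, ]
    purrr::map_dfr(seq_len(config$n_plants), function(p) {
      # free run: damped cosine at the genotype period, peak at initial offset
      # past the target acrophase
      phase0 <- config$target_acrophase_h + g$initial_offset_h
      y_free <- base + amp * exp(-t_free / g$damping_h) *
        cos(2 * pi * (t_free - phase0) / g$period_h)
      # entrainment: offset pulled toward 0 by relock_h_per_day each cycle
      day <- floor(t_ent / cyc)
      off <- sign(g$initial_offset_h) *
        pmax(0, abs(g$initial_offset_h) - g$relock_h_per_day * day)
      y_ent <- base + amp *
        cos(2 * pi * (t_ent - (config$target_acrophase_h + off)) / cyc)
      y <- c(y_free, y_ent)
      y <- pmax(0, y * (1 + stats::rnorm(length(y), 0, config$noise_sd)))
      tibble(
        plant_id = sprintf("%s_%02d", g$genotype, p),
        genotype = g$genotype,
        time_h = c(t_free, config$free_run_h + t_ent),
        luminescence = y,
        condition_segment = rep(c("LL", paste0("temp_", config$schedule)),
                                c(length(t_free), length(t_ent)))
      )
    })
  })
  truth <- purrr::map_dfr(seq_len(nrow(config$genotypes)), function(gi) {
    g <- config$genotypes[gi, ]
    days <- seq_len(ceiling(config$entrain_h / cyc)) - 1L
    tibble(
      genotype = g$genotype, day = days,
      offset_h = sign(g$initial_offset_h) *
        pmax(0, abs(g$initial_offset_h) - g$relock_h_per_day * days),
      target_acrophase_h = config$target_acrophase_h
    )
  })
  list(traces = traces, truth = truth)
}

#' Simulate densitometry and dual-luciferase inputs with known truth
#'
#' The densitometry arm emulates a 24 h western-blot time course in two
#' genotypes where the mutant stabilises the tagged protein from
#' `effect_zt_min` onward (abundance multiplied by `blot_effect_fold`); the
#' dual-luciferase arm emulates a transactivation assay where effector
#' combinations scale the firefly reporter multiplicatively and a per-leaf
#' infection-efficiency factor scales both channels (and therefore cancels in
#' the ratio).
#'
#' @param seed Mandatory RNG seed.
#' @param blot_effect_fold Mutant abundance multiplier at and after
#'   `effect_zt_min` (default 2; 1 = null simulation).
#' @param effect_zt_min First Zeitgeber time at which the stabilisation acts
#'   (default 9).
#' @param blot_bioreps Bioreps per genotype (default 4).
#' @param luc_effects Named multiplicative effects on the reporter, must
#'   include `"no effector"` = 1 (defaults: activation 3x, activation damped
#'   by a corepressor 1.5x).
#' @param luc_n_leaves Leaves per experiment (default 8).
#' @param luc_n_experiments Independent experiments (default 5).
#' @param noise_sd Multiplicative noise fraction (default 0.1).
#' @return A list with `densitometry`, `plates` and `truth`.
#' @export
simulate_quant <- function(seed,
                           blot_effect_fold = 2,
                           effect_zt_min = 9,
                           blot_bioreps = 4L,
                           luc_effects = c("no effector" = 1,
                                           "activator" = 3,
                                           "activator+corepressor" = 1.5),
                           luc_n_leaves = 8L,
                           luc_n_experiments = 5L,
                           noise_sd = 0.1) {
  if (missing(seed)) abort("simulate_quant requires a seed.")
  set.seed(as.integer(seed))
  zts <- seq(0, 21, by = 3)
  dens <- tidyr::expand_grid(
    genotype = c("WT", "mutant"), biorep = seq_len(blot_bioreps),
    timepoint_zt = zts
  )
  # diurnal abundance in net-gray units: sharp peak at ZT6 with low evening
  # levels (the tagged protein is degraded after midday), so a stabilising
  # mutation doubles the low evening signal without displacing the biorep
  # maximum used for the max = 100 normalization
  d <- abs(((dens$timepoint_zt - 6 + 12) %% 24) - 12)
  abundance <- 10 + 85 * exp(-d^2 / 4)
  abundance <- abundance *
    ifelse(dens$genotype == "mutant" & dens$timepoint_zt >= effect_zt_min,
           blot_effect_fold, 1)
  abundance <- abundance * stats::rlnorm(nrow(dens), 0, noise_sd)
  densitometry <- dplyr::mutate(
    dens,
    band_bg_mean_gray = 240,
    band_mean_gray = pmax(0, pmin(255, 240 - abundance)),
    loading_bg_mean_gray = 245,
    loading_mean_gray = pmax(0, pmin(
      255, 245 - 100 * stats::rlnorm(nrow(dens), 0, noise_sd / 2)))
  )

  stopifnot("no effector" %in% names(luc_effects))
  plates <- tidyr::expand_grid(
    experiment_id = sprintf("exp%d", seq_len(luc_n_experiments)),
    leaf_id = seq_len(luc_n_leaves),
    effector_combination = names(luc_effects)
  )
  plates$leaf_id <- paste(plates$experiment_id, plates$leaf_id, sep = "_leaf")
  infection <- stats::rlnorm(length(unique(plates$leaf_id)), 0, 0.5)
  names(infection) <- unique(plates$leaf_id)
  f <- infection[plates$leaf_id]
  eff <- luc_effects[plates$effector_combination]
  plates <- dplyr::mutate(
    plates,
    firefly_bg = 50,
    renilla_bg = 40,
    firefly_intensity = 50 + f * 400 * eff *
      stats::rlnorm(nrow(plates), 0, noise_sd),
    renilla_intensity = 40 + f * 300 *
      stats::rlnorm(nrow(plates), 0, noise_sd)
  )
  list(
    densitometry = as_tibble(densitometry),
    plates = as_tibble(plates),
    truth = list(blot_effect_fold = blot_effect_fold,
                 effect_zt_min = effect_zt_min,
                 luc_effects = luc_effects)
  )
}
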