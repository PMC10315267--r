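test_that("noiseless cosines are recovered to three significant figures", {
  for (tau in c(20, 24, 28)) {
    f <- fit_fft_nlls(make_trace(hours = 120, period = tau, peak = 4, amp = 2,
                                 base = 5))
    expect_equal(f$period_h, tau, tolerance = 5e-4)
    expect_equal(f$amplitude, 2, tolerance = 5e-4)
    expect_equal(f$acrophase_ct, 4, tolerance = 5e-3)
    expect_lt(f$rae, 0.01)
    expect_true(f$rhythmic)
  }
})

test_that("constant and too-short traces are handled per contract", {
  f <- fit_fft_nlls(data.frame(time_h = 0:119, luminescence = rep(7, 120)))
  expect_false(f$rhythmic)
  expect_true(is.na(f$period_h))
  expect_error(
    fit_fft_nlls(data.frame(time_h = 0:20, luminescence = rnorm(21))),
    "span"
  )
})

test_that("damped noisy simulations recover a 26.5 h period on average", {
  per <- vapply(1:20, function(s) {
    set.seed(s)
    t <- 0:119
    y <- 10 + 4 * exp(-t / 96) * cos(2 * pi * (t - 5) / 26.5) +
      rnorm(120, 0, 0.2) # sigma = 5% of amplitude
    fit_fft_nlls(data.frame(time_h = t, luminescence = y))$period_h
  }, 1.0)
  expect_lt(abs(mean(per) - 26.5), 0.2)
})

test_that("multi-plant wrapper returns one glance row per plant", {
  tr <- rbind(
    cbind(make_trace(72, period = 24), plant_id = "p1", genotype = "WT"),
    cbind(make_trace(72, period = 28), plant_id = "p2", genotype = "mut")
  )
  fits <- fit_rhythms(tr)
  expect_equal(nrow(fits), 2)
  expect_equal(sort(fits$genotype), c("WT", "mut") |> sort())
  expect_equal(fits$period_h[fits$plant_id == "p2"], 28, tolerance = 1e-3)
})

test_that("daily acrophase tracks the smoothed peak in each window", {
  # stationary peak at hour 2 of every cycle
  tr <- make_trace(hours = 96, period = 24, peak = 2)
  ac <- daily_acrophase(tr)
  expect_equal(ac$acrophase, rep(2, 4), tolerance = 1e-9)
  # drifting peak: +1 h per day (25 h period on a 24 h grid)
  tr2 <- make_trace(hours = 96, period = 25, peak = 2)
  ac2 <- daily_acrophase(tr2)
  expect_equal(ac2$acrophase, c(2, 3, 4, 5), tolerance = 1)
  # flat window flagged
  tr3 <- data.frame(time_h = 0:47, luminescence = rep(1, 48))
  ac3 <- daily_acrophase(tr3)
  expect_true(all(ac3$flagged))
  expect_true(all(is.na(ac3$acrophase)))
})

test_that("noisy acrophases average near the generator peak", {
  est <- vapply(1:50, function(s) {
    tr <- make_trace(hours = 48, period = 24, peak = 8, amp = 10, base = 100,
                     noise_sd = 1, seed = s)
    mean(daily_acrophase(tr)$acrophase)
  }, 1.0)
  expect_lt(abs(mean(est) - 8), 0.5)
})

test_that("Rayleigh statistic honors its exact invariants", {
  expect_equal(rayleigh(rep(7.5, 6))$R, 1)
  expect_equal(rayleigh(c(0, 12))$R, 0, tolerance = 1e-12)
  expect_equal(rayleigh(24 * (0:7) / 8)$R, 0, tolerance = 1e-12)
  expect_error(rayleigh(numeric()), "at least one")
  # rotation invariance of R; R always in [0, 1]
  set.seed(2)
  for (rep in 1:20) {
    ph <- runif(sample(2:12, 1), 0, 24)
    r0 <- rayleigh(ph)$R
    shift <- runif(1, 0, 24)
    expect_equal(rayleigh((ph + shift) %% 24)$R, r0, tolerance = 1e-10)
    expect_gte(r0, 0)
    expect_lte(r0, 1)
  }
  # clustered phases are significant at moderate n
  expect_lt(rayleigh(c(3, 3.2, 2.9, 3.1, 3, 3.05, 2.95, 3.1))$p_value, 0.001)
})

test_that("Welch test matches its limits and is symmetric", {
  w <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w$t, 0)
  expect_equal(w$p_value, 1)
  # separation limit: p -> 0 as jitter -> 0
  p_eps <- vapply(c(1e-1, 1e-3, 1e-5), function(eps) {
    welch_t(c(0, 0) + c(-eps, eps), c(1, 1) + c(-eps, eps))$p_value
  }, 1.0)
  expect_true(all(diff(p_eps) < 0))
  expect_lt(p_eps[3], 1e-8)
  expect_equal(welch_t(c(0, 0), c(1, 1))$p_value, 0)
  set.seed(4)
  a <- rnorm(8); b <- rnorm(6, 1)
  expect_equal(welch_t(a, b)$t, -welch_t(b, a)$t)
  expect_equal(welch_t(a, b)$p_value, welch_t(b, a)$p_value)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("Welch test agrees with the textbook formula on random cases", {
  set.seed(9)
  for (rep in 1:100) {
    a <- rnorm(sample(2:12, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:12, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    w <- welch_t(a, b)
    o <- oracle_welch(a, b)
    expect_equal(w$t, o$t, tolerance = 1e-10)
    expect_equal(w$df, o$df, tolerance = 1e-10)
    expect_equal(w$p_value, o$p, tolerance = 1e-10)
  }
})

test_that("period ANOVA separates distinct groups and letters shared ones", {
  same <- compare_periods(list(a = c(24, 24, 24), b = c(24, 24, 24)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  expect_equal(unique(same$letters$letters), "a")
  three <- compare_periods(list(
    a = c(24.0, 24.01, 23.99), b = c(24.01, 24.0, 23.99),
    c = c(27.0, 27.01, 26.99)
  ))
  expect_lt(three$p, 1e-6)
  lt <- setNames(three$letters$letters, three$letters$genotype)
  expect_equal(lt[["a"]], lt[["b"]])
  expect_false(lt[["c"]] == lt[["a"]])
  expect_error(compare_periods(list(a = 1:3)), "two genotypes")
  expect_error(compare_periods(list(a = 1:3, b = 2)), "n >= 2")
})

test_that("Tukey pairwise p-values track a max-T permutation approximation", {
  set.seed(21)
  values <- c(rnorm(6, 24, 0.4), rnorm(6, 24.4, 0.4), rnorm(6, 25.6, 0.4))
  groups <- rep(c("a", "b", "c"), each = 6)
  fit <- compare_periods(tibble::tibble(genotype = groups, period_h = values))
  perm <- oracle_tukey_perm(values, groups, n_perm = 1e4, seed = 1)
  expect_equal(unname(fit$pairwise$p_adj), unname(perm), tolerance = 0.02)
})

test_that("acrophase comparison finds the resynchronization day", {
  # identical genotypes: p = 1 every day, resynchronized from day 0
  set.seed(6)
  days <- 0:4
  mk <- function(geno, offsets, n = 16, sd = 0.3) {
    purrr::map_dfr(seq_along(days), function(i) {
      tibble::tibble(genotype = geno, day = days[i],
                     acrophase = (6 + offsets[i] + rnorm(n, 0, sd)) %% 24)
    })
  }
  ref <- mk("WT", rep(0, 5))
  same <- ref
  same$genotype <- "twin"
  twin_vs_ref <- compare_acrophases(rbind(ref, same), "WT")
  expect_true(all(tidy(twin_vs_ref)$p_value > 0.05))
  expect_equal(glance(twin_vs_ref)$resync_day, 0)
  # 6 h offset decaying 2 h/day resynchronizes by day 3
  dec <- mk("mut", pmax(0, 6 - 2 * days))
  cmp <- compare_acrophases(rbind(ref, dec), "WT")
  expect_lte(glance(cmp)$resync_day, 3)
  expect_true(tidy(cmp)$significant[tidy(cmp)$day == 0])
  # constant 6 h offset never resynchronizes
  stuck <- mk("stuck", rep(6, 5))
  expect_true(is.na(glance(compare_acrophases(rbind(ref, stuck), "WT"))$resync_day))
})

test_that("acrophase unwrapping spans the cycle boundary", {
  # reference near 23.8 h, mutant near 0.2 h: 0.4 h apart, not 23.6
  set.seed(8)
  ref <- tibble::tibble(genotype = "WT", day = 0,
                        acrophase = (23.8 + rnorm(12, 0, 0.1)) %% 24)
  mut <- tibble::tibble(genotype = "m", day = 0,
                        acrophase = (0.2 + rnorm(12, 0, 0.1)) %% 24)
  cmp <- tidy(compare_acrophases(rbind(ref, mut), "WT"))
  expect_lt(abs(cmp$mean_offset_h - 0.4), 0.2)
  # n < 2 on a day is flagged untestable
  solo <- tibble::tibble(genotype = "m2", day = 0, acrophase = 5)
  cmp2 <- tidy(compare_acrophases(rbind(ref, solo), "WT"))
  expect_true(cmp2$untestable[cmp2$genotype == "m2"])
})
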