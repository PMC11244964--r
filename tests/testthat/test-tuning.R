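test_that("interval rates do the arithmetic and conserve spike counts", {
  spikes <- spike_dataset(
    data.frame(neuron_id = 1L, region = "MIo",
               spike_time_s = c(0.01, 0.05, 0.09, 0.35)),
    neurons = data.frame(neuron_id = 1L, region = "MIo",
                         condition = "control", stable = TRUE),
    t_start = 0, t_end = 1)
  iv <- data.frame(t_start = c(0, 0.1, 0.3), t_end = c(0.1, 0.2, 0.4),
                   dx = 1, dy = 0, dz = 0, label = "A", degenerate = FALSE)
  rt <- interval_firing_rates(spikes, iv)
  expect_equal(unname(rt$rates[, 1]), c(30, 0, 10))  # 3 spikes / 100 ms
  # conservation across tiled windows
  iv2 <- data.frame(t_start = seq(0, 0.9, 0.1), t_end = seq(0.1, 1, 0.1),
                    dx = 1, dy = 0, dz = 0, label = "A", degenerate = FALSE)
  rt2 <- interval_firing_rates(spikes, iv2)
  expect_equal(sum(rt2$counts), 4)
  expect_error(interval_firing_rates(spikes,
    data.frame(t_start = 0.5, t_end = 1.5, dx = 1, dy = 0, dz = 0,
               label = "A", degenerate = FALSE)), "recording span")
})

test_that("the bootstrap modulation test rejects nulls at the nominal rate
           and detects planted tuning", {
  # constant rates: untuned
  rt_const <- make_rate_table(matrix(12, 80, 1), rep(letters[1:8], each = 10),
                              U = octant_centers()[rep(1:8, each = 10), ])
  res <- bootstrap_direction_test(rt_const, 1, n_boot = 200, seed = 1)
  expect_false(res$tuned)
  # all-zero rates: untuned with flag
  rt_zero <- make_rate_table(matrix(0, 80, 1), rep(letters[1:8], each = 10),
                             U = octant_centers()[rep(1:8, each = 10), ])
  expect_true(bootstrap_direction_test(rt_zero, 1, seed = 1)$all_zero)
  # too few intervals per direction: insufficient-data signal
  rt_small <- make_rate_table(matrix(rpois(16, 3), 16, 1),
                              rep(letters[1:8], each = 2),
                              U = octant_centers()[rep(1:8, each = 2), ])
  expect_true(bootstrap_direction_test(rt_small, 1, seed = 1)$insufficient_data)
  # power: depth/baseline = 2 with 40 intervals per octant
  set.seed(5)
  U <- octant_centers()[rep(1:8, each = 40), ]
  lam <- pmax(0, 5 + 10 * U %*% c(1, 0, 0))
  hits <- vapply(1:30, function(i) {
    r <- rpois(320, lam * 0.1) / 0.1
    rt <- make_rate_table(matrix(r, 320, 1), rep(letters[1:8], each = 40), U)
    bootstrap_direction_test(rt, 1, n_boot = 300, seed = i)$tuned
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("cosine fits are exact on noiseless model data and recover planted PDs", {
  U <- octant_centers()[rep(1:8, each = 5), ]
  r <- 10 + 5 * U[, 1]              # rate = 10 + 5 ux exactly
  rt <- make_rate_table(matrix(r, 40, 1), rep(letters[1:8], each = 5), U)
  fit <- cosine_fit(rt, 1)
  expect_equal(fit$coefficients, c(10, 5, 0, 0), tolerance = 1e-9)
  expect_equal(fit$pd, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(fit$directional_index, 10 / 15, tolerance = 1e-9)
  expect_true(fit$fits_cosine)
  # constant rate: nonsignificant, DI undefined-as-zero modulation
  rt0 <- make_rate_table(matrix(8, 40, 1), rep(letters[1:8], each = 5), U)
  fit0 <- cosine_fit(rt0, 1)
  expect_false(isTRUE(fit0$fits_cosine))
  # coplanar directions: degenerate signal
  Uc <- U; Uc[, 3] <- 0
  rtc <- make_rate_table(matrix(r, 40, 1), rep(letters[1:8], each = 5), Uc)
  expect_true(cosine_fit(rtc, 1)$degenerate)
  # DI invariant to positive scaling of all rates
  rts <- rt; rts$rates <- rt$rates * 4.2
  expect_equal(cosine_fit(rts, 1)$directional_index, fit$directional_index,
               tolerance = 1e-12)
})

test_that("PD recovery error shrinks with the number of intervals", {
  errs <- vapply(c(10, 25, 50), function(npo) {
    median(pd_recovery_errors(n_neurons = 12, n_per_octant = npo, seed = 53))
  }, numeric(1))
  expect_lt(errs[3], 10)
  expect_true(errs[3] < errs[1])
  expect_true(all(diff(errs) < 2))   # monotone within noise
})

test_that("bootstrap modal PD finds dominant directions and respects symmetry", {
  set.seed(6)
  lab <- rep(c("left", "middle", "right"), each = 30)
  r <- c(rpois(30, 20), rpois(30, 5), rpois(30, 5)) / 0.5
  rt <- make_rate_table(matrix(r, 90, 1), lab, U = matrix(NA_real_, 90, 3))
  res <- bootstrap_modal_pd(rt, 1, n_boot = 500, seed = 2)
  expect_equal(res$mode, "left")
  expect_gt(res$distribution[["left"]], 0.95)
  # exchangeable directions: shares average to 1/3 over independent datasets
  # (any single dataset favors whichever direction drew the larger sample mean)
  shares <- rowMeans(vapply(1:30, function(i) {
    r2 <- rpois(90, 10) / 0.5
    rt2 <- make_rate_table(matrix(r2, 90, 1), lab, U = matrix(NA_real_, 90, 3))
    bootstrap_modal_pd(rt2, 1, n_boot = 200, seed = i)$distribution
  }, numeric(3)))
  expect_true(all(abs(shares - 1 / 3) < 0.12))
  r2 <- rpois(90, 10) / 0.5
  rt2 <- make_rate_table(matrix(r2, 90, 1), lab, U = matrix(NA_real_, 90, 3))
  res2 <- bootstrap_modal_pd(rt2, 1, n_boot = 1000, seed = 3)
  expect_identical(res2$distribution,
                   bootstrap_modal_pd(rt2, 1, n_boot = 1000, seed = 3)$distribution)
})

test_that("Fano factors behave as Poisson theory demands", {
  set.seed(7)
  expect_lt(abs(fano(rpois(1000, 5)) - 1), 0.1)
  expect_equal(fano(rep(4L, 50)), 0)
  expect_true(is.na(fano(rep(0L, 50))))
  expect_error(fano(3L), "at least two")
})

test_that("mean matching equalizes groups that share a variance law", {
  set.seed(8)
  # two groups, different mean-count distributions, same var/mean law (Poisson)
  mk <- function(lams) {
    d <- t(vapply(lams, function(l) {
      x <- rpois(200, l); c(mean(x), var(x) / mean(x))
    }, numeric(2)))
    data.frame(mean_count = d[, 1], fano = d[, 2])
  }
  groups <- list(low = mk(runif(150, 0.5, 4)), high = mk(runif(150, 2, 8)))
  mm <- mean_matched_fano(groups, seed = 4)
  expect_lt(abs(mm$fano[["low"]] - mm$fano[["high"]]), 0.1)
  raw_gap <- abs(mean(groups$low$fano) - mean(groups$high$fano))
  expect_lt(abs(mm$fano[["low"]] - 1), 0.15)
  expect_identical(mm$fano, mean_matched_fano(groups, seed = 4)$fano)
})

test_that("circular tests calibrate on uniform nulls and detect concentration", {
  set.seed(9)
  # concentrated: tiny p
  expect_lt(rayleigh_test(rnorm(50, 0, 2))$p, 1e-3)
  # uniform null: p exceeds 0.05 in at least 90% of simulations
  ps <- vapply(1:40, function(i) rayleigh_test(runif(200, -180, 180))$p,
               numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
  # k-test flags a concentration difference, passes equal samples
  a1 <- rnorm(60, 10, 5); a2 <- rnorm(60, 10, 25)
  expect_lt(concentration_ktest(a1, a2)$p, 0.01)
  expect_gt(concentration_ktest(a1, rnorm(60, 10, 5))$p, 0.05)
  expect_error(concentration_ktest(rep(1, 10), a1), "degenerate")
  # chi-square on identical discrete distributions is non-significant
  tab <- rbind(c(30, 30, 30), c(30, 30, 30))
  expect_gt(pd_distribution_tests(rnorm(20, 0, 10),
                                  discrete_counts = tab)$chisq_p, 0.99)
})

test_that("tuning contrasts classify gained/lost neurons and detect depth loss", {
  s <- quick_session(n_trials = 60, n_neurons = 20, tuned_fraction = 0.5,
                     baseline_rate = 10, modulation_depth = 10, seed = 61)
  ivb <- balanced_interval_sample(make_intervals(s$kin, 100), seed = 1)
  rt <- interval_firing_rates(s$spikes, ivb)
  tuned <- tune_neurons(rt, n_boot = 300, seed = 2)
  idc <- tuning_contrast(tuned, tuned)
  expect_equal(unname(idc$counts[["gained"]] + idc$counts[["lost"]]), 0L)
  # permuted tuned labels: gained ~ lost by symmetry
  set.seed(3)
  perm <- tuned; perm$tuned <- sample(tuned$tuned)
  sym <- tuning_contrast(tuned, perm)
  expect_equal(unname(sym$counts[["gained"]]), unname(sym$counts[["lost"]]))
  # unmatched sets warn
  expect_warning(tuning_contrast(tuned, tuned[-1, ]), "matched subset")
})
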