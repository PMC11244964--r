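test_that("direction_angle matches the arccos oracle and its symmetries", {
  expect_equal(direction_angle(c(1, 2, 3), c(2, 4, 6)), 0)
  expect_equal(direction_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_true(is.na(direction_angle(c(0, 0, 0), c(1, 1, 1))))
  set.seed(11)
  for (i in 1:1000) {
    v1 <- rnorm(3); v2 <- rnorm(3)
    oracle <- acos(pmin(pmax(sum(v1 * v2) /
      (sqrt(sum(v1^2)) * sqrt(sum(v2^2))), -1), 1)) * 180 / pi
    expect_lt(abs(direction_angle(v1, v2) - oracle), 1e-9)
    # symmetric, scale-invariant
    expect_lt(abs(direction_angle(v2, v1) - oracle), 1e-9)
    expect_lt(abs(direction_angle(2.7 * v1, 0.3 * v2) - oracle), 1e-9)
  }
})

test_that("octant categorization covers all sign combinations distinctly", {
  g <- as.matrix(expand.grid(x = c(1, -1), y = c(1, -1), z = c(1, -1)))
  labs <- octant_label(g)
  expect_equal(length(unique(labs)), 8L)
  expect_false(anyNA(labs))
  expect_equal(as.character(octant_label(c(-1, -1, -1))), "PostInfL")
  # antipodal symmetry: negation swaps every half
  anti <- octant_label(-g)
  expect_true(all(substr(labs, 1, 3) != substr(anti, 1, 3) |
                    substr(labs, 1, 4) != substr(anti, 1, 4)))
  for (i in seq_len(8)) {
    a <- as.character(labs[i]); b <- as.character(anti[i])
    expect_true(xor(grepl("^Ant", a), grepl("^Ant", b)))
    expect_true(xor(grepl("Sup", a), grepl("Sup", b)))
    expect_true(xor(grepl("R$", a), grepl("R$", b)))
  }
  expect_true(is.na(octant_label(c(0, 0, 0))))
})

test_that("left-right binning uses six half-open 10-degree bins over [-30, 30)", {
  expect_equal(leftright_angle_and_bin(c(1, 0, 0))$angle_deg, 0)
  expect_equal(leftright_angle_and_bin(c(1, 0, 0))$bin, 4L)
  ang <- function(a) c(cos(a * pi / 180), sin(a * pi / 180), 0)
  expect_equal(leftright_angle_and_bin(ang(-30))$bin, 1L)
  expect_equal(leftright_angle_and_bin(ang(29.999))$bin, 6L)
  expect_true(is.na(leftright_angle_and_bin(ang(30))$bin))
  expect_true(is.na(leftright_angle_and_bin(ang(-30.001))$bin))
  # exhaustive coverage: a fine sweep of [-30, 30) hits exactly 6 bins
  sweep_bins <- leftright_angle_and_bin(
    t(vapply(seq(-30, 29.99, by = 0.01), ang, numeric(3))))$bin
  expect_equal(sort(unique(sweep_bins)), 1:6)
  expect_true(is.na(leftright_angle_and_bin(c(0, 0, 1))$bin))
})

test_that("yaw/pitch agree with spherical coordinates; yaw equals lr angle", {
  yp <- yaw_pitch(c(0, 0, 1))
  expect_equal(yp$pitch_deg, 90)
  expect_true(is.na(yp$yaw_deg))
  yp2 <- yaw_pitch(c(1, 0, 1))   # anterior-superior diagonal
  expect_equal(yp2$pitch_deg, 45)
  expect_equal(yp2$yaw_deg, 0)
  set.seed(12)
  for (i in 1:1000) {
    d <- rnorm(3)
    yp <- yaw_pitch(d)
    # spherical oracle: azimuth from +x toward +y, elevation above xy-plane
    expect_lt(abs(yp$yaw_deg - atan2(d[2], d[1]) * 180 / pi), 1e-9)
    expect_lt(abs(yp$pitch_deg -
                    asin(d[3] / sqrt(sum(d^2))) * 180 / pi), 1e-9)
    expect_equal(yp$yaw_deg, leftright_angle_and_bin(d)$angle_deg)
  }
})

test_that("Butterworth smoothing passes DC and low frequencies, kills high ones", {
  fr <- 200
  tt <- seq(0, 5, by = 1 / fr)
  const <- marker_trajectory(tt, matrix(7, length(tt), 3))
  sm <- smooth_trajectory(const, 30)
  expect_lt(max(abs(sm$positions - const$positions)), 1e-5)
  probe <- function(freq) {
    pos <- cbind(sin(2 * pi * freq * tt), 0 * tt, 0 * tt)
    out <- smooth_trajectory(marker_trajectory(tt, pos), 30)
    core <- seq(fr, length(tt) - fr)   # avoid edge transients
    max(abs(out$positions[core, 1])) / 1
  }
  expect_gt(probe(5), 0.99)    # < 1% attenuation in the passband
  expect_lt(probe(80), 0.10)   # > 90% attenuation in the stopband
  expect_error(smooth_trajectory(const, 150), "Nyquist")
})

test_that("tiled intervals have the right count, fields and degenerate policy", {
  fr <- 200
  tt <- seq(0, 1, length.out = fr + 1)[-(fr + 1)]
  pos <- cbind(seq(0, 10, length.out = fr), 0, 0)
  pos[101:120, 1] <- pos[100, 1]       # a stationary 100 ms stretch
  traj <- marker_trajectory(tt, pos, behavior = "feeding")
  iv <- make_intervals(traj, span_ms = 100, anchor = "tiled")
  expect_equal(nrow(iv), 10L)
  expect_true(any(iv$degenerate))
  expect_equal(iv$label[1], "AntSupR") # (+,0,0) ties toward Sup and R
  expect_equal(iv$dx[1], pos[20, 1] - pos[1, 1])
  rt_input <- iv[!iv$degenerate, ]
  expect_false(any(rt_input$degenerate))
})

test_that("min-protrusion-centered windows span +/-250 ms and drop edge cycles", {
  s <- quick_session("drinking", n_trials = 12, n_neurons = 2, seed = 7)
  iv <- make_intervals(s$kin, span_ms = 500, anchor = "min_protrusion_centered")
  expect_equal(nrow(iv), 11L)          # the first lick's leading half is clipped
  expect_equal(unique(round(iv$t_end - iv$t_start, 6)), 0.5)
  ctr <- s$kin$times[s$kin$cycles$min_protrusion_idx[-1]]
  expect_equal(iv$t_start, ctr - 0.25, tolerance = 1e-9)
  expect_setequal(unique(iv$label), c("left", "middle", "right"))
})

test_that("balanced sampling applies the min rule deterministically", {
  s <- quick_session(n_trials = 50, n_neurons = 2, seed = 9)
  iv <- make_intervals(s$kin, 100)
  counts <- table(iv$label[!iv$degenerate])
  bal <- balanced_interval_sample(iv, seed = 42)
  expect_true(all(table(bal$label) == min(counts)))
  bal2 <- balanced_interval_sample(iv, seed = 42)
  expect_identical(bal, bal2)
  # already balanced input: a permutation of itself
  rebal <- balanced_interval_sample(bal, seed = 1)
  expect_equal(nrow(rebal), nrow(bal))
  expect_setequal(rownames(rebal), rownames(bal))
})

test_that("kinematic performance flags the 2-SD endpoint rule and detects
           variance inflation", {
  # zero-noise drinking: all variances zero, no failures
  s0 <- quick_session("drinking", n_trials = 30, n_neurons = 2, noise_sd = 0,
                      seed = 3)
  p0 <- kinematic_performance(s0$kin)
  expect_true(all(vapply(p0$per_spout, function(g)
    all(g$var_per_axis < 1e-18), logical(1))))
  expect_equal(p0$failed_proportion, 0)
  # one endpoint displaced far laterally is the only failure among otherwise
  # perfect licks
  s1 <- quick_session("drinking", n_trials = 99, n_neurons = 2, noise_sd = 0,
                      seed = 4)
  kin <- s1$kin
  j <- which(kin$cycles$spout == "middle")[1]
  ep_idx <- kin$cycles$max_protrusion_idx[j]
  kin$positions[ep_idx, 2] <- kin$positions[ep_idx, 2] + 5
  p1 <- kinematic_performance(kin)
  expect_true(p1$failed_cycle[j])
  expect_false(any(p1$failed_cycle[-j]))
  # endpoint_sd_scale = 3 nerve block: F-test rejects equal variance
  ctrl <- quick_session("drinking", n_trials = 100, n_neurons = 2,
                        noise_sd = 1, seed = 5)
  blk <- quick_session("drinking", n_trials = 100, n_neurons = 2,
                       noise_sd = 1, seed = 5, nerve_block = TRUE,
                       nerve_block_effects = list(endpoint_sd_scale = 3))
  cmp <- kinematic_performance_contrast(ctrl$kin, blk$kin)
  expect_lt(cmp$tests$endpoint_dist_f_p, 0.05)
  expect_gt(cmp$block$mean_dist_from_mean, cmp$control$mean_dist_from_mean)
})

test_that("kinematics CSV round-trips through the documented format", {
  s <- quick_session("drinking", n_trials = 8, n_neurons = 2, seed = 15)
  path <- withr::local_tempfile(fileext = ".csv")
  write_kinematics_csv(s$kin, path)
  back <- read_kinematics_csv(path)
  expect_equal(back$positions, s$kin$positions, tolerance = 1e-12)
  expect_equal(back$cycles$spout, as.character(s$kin$cycles$spout))
  expect_equal(back$cycles$min_protrusion_idx, s$kin$cycles$min_protrusion_idx)
})
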