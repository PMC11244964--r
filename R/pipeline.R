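#' Pipeline run configuration
#'
#' One master seed deterministically derives every stage seed. Stage toggles
#' let individual stages be skipped; a stage whose inputs come from a
#' disabled stage refuses to run with a stage-attributed error.
#'
#' @param synth a [synth_config()] (or a list of them, e.g. control and
#'   nerve-block arms).
#' @param out_dir output directory for all artifacts.
#' @param stages character vector of enabled stages, a subset of
#'   c("simulate", "kinematics", "tune", "population", "decode").
#' @param span_ms interval span (defaults per behavior).
#' @param cutoff_hz Butterworth smoothing cutoff (default 30).
#' @param n_boot bootstrap replicates for the tuning stage (default 1000).
#' @param alpha significance level (default 0.05).
#' @param bin_ms,smooth_sd_ms,min_rate population-binning parameters.
#' @param m_grid candidate FA dimensionalities (default 1:5).
#' @param folds CV folds for dimensionality selection (default 3).
#' @param K,subsample_n,iters KNN decoding parameters.
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(synth, out_dir,
                       stages = c("simulate", "kinematics", "tune",
                                  "population", "decode"),
                       span_ms = NULL, cutoff_hz = 30,
                       n_boot = 1000, alpha = 0.05,
                       bin_ms = 10, smooth_sd_ms = 10, min_rate = 1.0,
                       m_grid = 1:5, folds = 3,
                       K = 7, subsample_n = 28, iters = 100,
                       seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(synth = synth, out_dir = out_dir, stages = stages,
                 span_ms = span_ms, cutoff_hz = cutoff_hz, n_boot = n_boot,
                 alpha = alpha, bin_ms = bin_ms, smooth_sd_ms = smooth_sd_ms,
                 min_rate = min_rate, m_grid = m_grid, folds = folds,
                 K = K, subsample_n = subsample_n, iters = iters,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate (synthetic kinematics +
#' spiking), kinematics (smoothing, directional intervals, balanced
#' sampling, performance metrics), tune (bootstrap modulation test, cosine
#' fits, Fano factors), population (binning, CV dimensionality, FA, latent
#' trajectories, distances), decode (KNN) — writing every intermediate
#' artifact as CSV/JSON under `config$out_dir` plus a machine-readable
#' manifest (with MD5 content hashes, seeds, parameters and package version)
#' and a human-readable summary.
#'
#' @param config a [run_config()].
#' @return list of stage results plus the manifest, invisibly; artifacts on
#'   disk under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_on <- function(s) s %in% config$stages
  fail <- function(stage, msg) stopf("[stage %s] %s", stage, msg)
  res <- list()
  files <- character(0)
  log_lines <- c(sprintf("linguadir %s", as.character(utils::packageVersion("linguadir"))),
                 sprintf("master seed: %d", config$seed))

  cfg <- config$synth
  if (!stage_on("simulate"))
    fail(if (stage_on("kinematics")) "kinematics" else "tune",
         "downstream stages require the simulate stage (no external inputs configured)")
  kin <- generate_kinematics(cfg)
  popgen <- generate_population(cfg, kin)
  files["kinematics_csv"] <- file.path(config$out_dir, "kinematics.csv")
  write_kinematics_csv(kin, files[["kinematics_csv"]])
  files["spikes_csv"] <- file.path(config$out_dir, "spikes.csv")
  write_spikes_csv(popgen$spikes, files[["spikes_csv"]])
  files["truth_json"] <- file.path(config$out_dir, "truth.json")
  jsonlite::write_json(list(neurons = popgen$truth$neurons,
                            trial_labels = popgen$truth$trial_labels),
                       files[["truth_json"]], auto_unbox = TRUE, digits = NA)
  res$simulate <- list(kin = kin, spikes = popgen$spikes,
                       truth = popgen$truth)
  log_lines <- c(log_lines, sprintf("simulate: %d trials (%s), %d neurons",
                                    cfg$n_trials, cfg$behavior, cfg$n_neurons))

  iv_bal <- NULL
  if (stage_on("kinematics")) {
    sm <- smooth_trajectory(kin, cutoff_hz = config$cutoff_hz)
    span <- config$span_ms %||% if (cfg$behavior == "drinking") 500 else 100
    iv <- make_intervals(sm, span_ms = span)
    iv_bal <- balanced_interval_sample(iv, seed = derive_seed(config$seed,
                                                              "balance"))
    files["intervals_csv"] <- file.path(config$out_dir, "intervals.csv")
    write_intervals_csv(iv_bal, files[["intervals_csv"]])
    perf <- kinematic_performance(sm)
    res$kinematics <- list(intervals = iv, balanced = iv_bal,
                           performance = perf)
    log_lines <- c(log_lines, sprintf("kinematics: %d intervals, %d balanced",
                                      nrow(iv), nrow(iv_bal)))
  }

  rates <- NULL
  if (stage_on("tune")) {
    if (is.null(iv_bal)) fail("tune", "requires the kinematics stage output")
    rates <- interval_firing_rates(popgen$spikes, iv_bal)
    tuned <- tune_neurons(rates, n_boot = config$n_boot, alpha = config$alpha,
                          seed = derive_seed(config$seed, "tune"))
    files["tuning_csv"] <- file.path(config$out_dir, "tuning.csv")
    utils::write.csv(tuned, files[["tuning_csv"]], row.names = FALSE)
    res$tune <- tuned
    log_lines <- c(log_lines, sprintf("tune: %d/%d neurons tuned",
                                      sum(tuned$tuned, na.rm = TRUE),
                                      nrow(tuned)))
  }

  if (stage_on("population")) {
    if (is.null(iv_bal)) fail("population", "requires the kinematics stage output")
    trials <- data.frame(t_start = iv_bal$t_start, t_end = iv_bal$t_end,
                         label = iv_bal$label)
    pop <- bin_and_smooth(popgen$spikes, trials, bin_ms = config$bin_ms,
                          smooth_sd_ms = config$smooth_sd_ms,
                          min_rate = config$min_rate)
    m_grid <- config$m_grid[config$m_grid < sum(pop$include)]
    sel <- select_dimensionality(pop, m_grid, folds = config$folds,
                                 seed = derive_seed(config$seed, "fa_cv"))
    fit <- fit_fa(pop, sel$m_star)
    set <- latent_trajectories(fit, pop)
    met <- trajectory_metrics(set)
    files["fa_json"] <- file.path(config$out_dir, "fa_model.json")
    jsonlite::write_json(list(m = fit$m, mu = fit$mu, C = fit$C, R = fit$R,
                              cv = sel$cv, cum_expvar = set$cum_expvar),
                         files[["fa_json"]], digits = NA)
    files["distances_csv"] <- file.path(config$out_dir, "distances.csv")
    utils::write.csv(data.frame(pair = rownames(met$per_bin),
                                mean_distance = met$mean_distance),
                     files[["distances_csv"]], row.names = FALSE)
    res$population <- list(pop = pop, selection = sel, model = fit,
                           trajectories = set, metrics = met)
    log_lines <- c(log_lines, sprintf("population: m* = %d, mean dist = %.4g",
                                      sel$m_star, mean(met$mean_distance)))
  }

  if (stage_on("decode")) {
    if (is.null(rates)) fail("decode", "requires the tune stage's rate table")
    dec <- knn_decode(rates, K = config$K, iters = config$iters,
                      subsample_n = config$subsample_n,
                      seed = derive_seed(config$seed, "decode"))
    files["decoding_json"] <- file.path(config$out_dir, "decoding.json")
    jsonlite::write_json(list(protocol = dec$protocol, mean = dec$mean,
                              sd = dec$sd, chance = dec$chance,
                              values = dec$values),
                         files[["decoding_json"]], auto_unbox = TRUE,
                         digits = NA)
    res$decode <- dec
    log_lines <- c(log_lines, sprintf("decode: KNN accuracy %.4f (chance %.4f)",
                                      dec$mean, dec$chance))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("linguadir")),
    seed = config$seed,
    stages = config$stages,
    parameters = config[setdiff(names(config), c("synth", "out_dir"))],
    artifacts = lapply(stats::setNames(nm = names(files)), function(k)
      list(path = basename(files[[k]]),
           md5 = unname(tools::md5sum(files[[k]])))))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(config$out_dir, "summary.txt"))
  res$manifest <- manifest
  invisible(res)
}

#' Built-in recovery and calibration suite
#'
#' Runs the package's core self-checks on freshly generated synthetic data:
#' directional-index scale invariance, preferred-direction recovery for
#' planted cosine neurons, bootstrap-test type-I error, KNN chance-level
#' calibration on an untuned population, and FA loading-subspace recovery.
#' Replicate counts are configurable; tolerances widen automatically for
#' reduced replicate counts (binomial/standard-error based rules noted per
#' check).
#'
#' @param seed master seed.
#' @param n_null_neurons neurons for the type-I check (default 50; the
#'   tolerance band scales with the binomial SE of this count).
#' @param n_pd_neurons neurons for the PD-recovery check (default 30).
#' @param n_boot bootstrap replicates (default 300).
#' @return data.frame: check, value, threshold, pass.
#' @export
recovery_suite <- function(seed = 1L, n_null_neurons = 50, n_pd_neurons = 30,
                           n_boot = 300) {
  checks <- list()
  # DI scale invariance (closed-form check on the fitted tuning curve)
  cfg <- synth_config("feeding", n_trials = 30, n_neurons = 2,
                      tuned_fraction = 1, baseline_rate = 20,
                      modulation_depth = 15, seed = seed)
  kin <- generate_kinematics(cfg)
  pg <- generate_population(cfg, kin)
  iv <- balanced_interval_sample(make_intervals(kin, 100),
                                 seed = derive_seed(seed, "rsbal"))
  rt <- interval_firing_rates(pg$spikes, iv)
  f1 <- cosine_fit(rt, 1)
  rt2 <- rt; rt2$rates <- rt$rates * 3.7
  f2 <- cosine_fit(rt2, 1)
  checks$di_scale_invariance <- list(
    value = abs(f1$directional_index - f2$directional_index),
    threshold = 1e-9, cmp = `<`)
  # PD recovery (median angular error, planted cosine neurons)
  pd_err <- pd_recovery_errors(n_neurons = n_pd_neurons, n_per_octant = 50,
                               seed = derive_seed(seed, "rspd"))
  checks$pd_median_error_deg <- list(value = stats::median(pd_err),
                                     threshold = 10, cmp = `<`)
  # bootstrap type-I (band = alpha +/- 3 binomial SE, floored at [0.5a, 2a])
  t1 <- bootstrap_type1_rate(n_neurons = n_null_neurons, n_boot = n_boot,
                             seed = derive_seed(seed, "rst1"))
  se3 <- 3 * sqrt(0.05 * 0.95 / n_null_neurons)
  checks$bootstrap_type1 <- list(value = t1,
                                 threshold = c(max(0, 0.05 - se3), 0.05 + se3),
                                 cmp = function(v, th) v >= th[1] & v <= th[2])
  # KNN chance calibration
  acc <- knn_chance_accuracy(n_trials = 150, iters = 100,
                             seed = derive_seed(seed, "rsknn"))
  checks$knn_chance_accuracy <- list(
    value = acc, threshold = c(1 / 3 - 0.03, 1 / 3 + 0.03),
    cmp = function(v, th) v >= th[1] & v <= th[2])
  # FA subspace recovery
  ang <- fa_subspace_angle(n_obs = 3000, seed = derive_seed(seed, "rsfa"))
  checks$fa_subspace_angle_deg <- list(value = ang, threshold = 5, cmp = `<`)

  data.frame(check = names(checks),
             value = vapply(checks, function(c) c$value, numeric(1)),
             threshold = vapply(checks, function(c)
               paste(signif(c$threshold, 4), collapse = ".."), character(1)),
             pass = vapply(checks, function(c)
               isTRUE(all(c$cmp(c$value, c$threshold))), logical(1)),
             row.names = NULL)
}

# --- reusable measurement helpers (shared by recovery_suite, tests and the
#     acceptance script) ---------------------------------------------------

#' Angular PD-recovery errors for planted cosine neurons
#'
#' Generates a feeding session with planted cosine-tuned neurons
#' (baseline 20, depth 15 spikes/s), extracts balanced 100-ms intervals
#' (`n_per_octant` per octant), fits the cosine tuning model and returns the
#' angular error (degrees) between each recovered and planted preferred
#' direction.
#'
#' @param n_neurons planted neurons.
#' @param n_per_octant balanced intervals per octant.
#' @param seed integer seed.
#' @return numeric vector of angular errors, degrees.
#' @export
pd_recovery_errors <- function(n_neurons = 100, n_per_octant = 50,
                               seed = 1L) {
  # ~ n_per_octant*8 intervals needed; feeding yields ~5 intervals/cycle with
  # the octant bias leaving the rarest octant ~1/10 of intervals
  n_trials <- ceiling(n_per_octant * 8 * 2.4 / 5)
  cfg <- synth_config("feeding", n_trials = n_trials, n_neurons = n_neurons,
                      tuned_fraction = 1, baseline_rate = 20,
                      modulation_depth = 15, noise_sd = 0.2, seed = seed)
  kin <- generate_kinematics(cfg)
  pg <- generate_population(cfg, kin)
  iv <- make_intervals(kin, 100)
  ivb <- balanced_interval_sample(iv, seed = derive_seed(seed, "pdbal"))
  byd <- split(seq_len(nrow(ivb)), ivb$label)
  if (min(lengths(byd)) > n_per_octant)
    ivb <- ivb[unlist(lapply(byd, function(ix) ix[seq_len(n_per_octant)])), ]
  rt <- interval_firing_rates(pg$spikes, ivb)
  vapply(seq_len(n_neurons), function(j) {
    fit <- cosine_fit(rt, j)
    pd_true <- unlist(pg$truth$neurons[j, c("pd_x", "pd_y", "pd_z")])
    acos(pmin(pmax(sum(fit$pd * pd_true), -1), 1)) * 180 / pi
  }, numeric(1))
}

#' Empirical type-I error of the bootstrap direction test
#'
#' Generates untuned (homogeneous Poisson) neurons on feeding kinematics,
#' runs the bootstrap modulation test on each at alpha = 0.05 over a
#' balanced 8-direction design and returns the fraction flagged tuned.
#'
#' @param n_neurons null neurons (default 200).
#' @param n_per_octant balanced intervals per octant (default 20).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return the empirical type-I rate.
#' @export
bootstrap_type1_rate <- function(n_neurons = 200, n_per_octant = 20,
                                 n_boot = 1000, seed = 1L) {
  n_trials <- ceiling(n_per_octant * 8 * 2.4 / 5)
  cfg <- synth_config("feeding", n_trials = n_trials, n_neurons = n_neurons,
                      tuned_fraction = 0, baseline_rate = 10, seed = seed)
  kin <- generate_kinematics(cfg)
  pg <- generate_population(cfg, kin)
  ivb <- balanced_interval_sample(make_intervals(kin, 100),
                                  seed = derive_seed(seed, "t1bal"))
  rt <- interval_firing_rates(pg$spikes, ivb)
  boot <- bootstrap_direction_test_all(rt, n_boot = n_boot, alpha = 0.05,
                                       seed = derive_seed(seed, "t1boot"))
  mean(boot$tuned, na.rm = TRUE)
}

#' Chance-level KNN accuracy on untuned populations
#'
#' Generates drinking sessions (three spouts, balanced trials) with untuned
#' homogeneous-Poisson populations of 28 neurons, decodes spout identity with
#' KNN (K = 7, 80/20 splits, `iters` iterations) and returns the mean
#' accuracy. The chance level is a property of the decoding protocol, not of
#' one noise draw, and a single 150-trial population carries dataset-level
#' fluctuation of several percentage points; the estimate therefore averages
#' over `n_reps` independent populations.
#'
#' @param n_trials licks per population (default 150, balanced over three
#'   spouts).
#' @param n_neurons population size (default 28).
#' @param iters decoder iterations per population (default 100).
#' @param n_reps independent untuned populations averaged (default 10).
#' @param seed integer seed.
#' @return mean decoding accuracy (proportion).
#' @export
knn_chance_accuracy <- function(n_trials = 150, n_neurons = 28, iters = 100,
                                n_reps = 10, seed = 1L) {
  mean(vapply(seq_len(n_reps), function(rep) {
    cfg <- synth_config("drinking", n_trials = n_trials,
                        n_neurons = n_neurons, tuned_fraction = 0,
                        baseline_rate = 10,
                        seed = derive_seed(seed, paste0("pop", rep)))
    kin <- generate_kinematics(cfg)
    pg <- generate_population(cfg, kin)
    iv <- make_intervals(kin, 500)
    rt <- interval_firing_rates(pg$spikes, iv)
    knn_decode(rt, K = 7, iters = iters, subsample_n = n_neurons,
               seed = derive_seed(seed, paste0("knn", rep)))$mean
  }, numeric(1)))
}

#' Largest principal angle of FA subspace recovery
#'
#' Simulates Gaussian observations from a known 3-factor FA model (20
#' neurons) and returns the largest principal angle (degrees) between the
#' recovered and planted loading subspaces.
#'
#' @param n_obs observations (default 10000).
#' @param n_neurons neurons (default 20).
#' @param m planted dimensionality (default 3).
#' @param seed integer seed.
#' @return largest principal angle, degrees.
#' @export
fa_subspace_angle <- function(n_obs = 10000, n_neurons = 20, m = 3,
                              seed = 1L) {
  tr <- with_rng_seed(seed, list(
    C = matrix(stats::rnorm(m * n_neurons), m, n_neurons),
    R = stats::runif(n_neurons, 0.3, 1),
    mu = stats::runif(n_neurons, 1, 4)))
  Y <- simulate_fa_observations(tr$mu, tr$C, tr$R, n_obs,
                                seed = derive_seed(seed, "faobs"))
  fit <- fit_fa(Y, m)
  max(principal_angles(fit$C, tr$C))
}
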