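#' Configuration for the synthetic kinematics + spiking generator
#'
#' Defines the study-like conditions the generator emulates: feeding gape
#' cycles (meandering 3D tongue-tip trajectories whose 100-ms displacement
#' octants cover all eight directions, with a configurable frequency bias
#' favoring Anterior-Superior then Posterior-Inferior movement) or rhythmic
#' drinking licks toward three juice spouts; cosine-tuned Poisson neurons with
#' planted preferred directions; optional shared low-rank log-rate drive; and
#' an optional simulated sensory nerve block (tuning depth scaled down,
#' endpoint scatter scaled up, preferred directions rotated about the vertical
#' axis).
#'
#' @param behavior "feeding" or "drinking".
#' @param n_trials number of gape cycles (feeding) or licks (drinking).
#' @param frame_rate sampling rate in Hz (default 200).
#' @param n_neurons number of simulated neurons.
#' @param tuned_fraction fraction of neurons with planted cosine tuning;
#'   `tuned_fraction * n_neurons` must round cleanly to an integer.
#' @param baseline_rate baseline firing rate, spikes/s.
#' @param modulation_depth cosine modulation depth, spikes/s.
#' @param planted_pds optional matrix (n_tuned x 3) of unit preferred
#'   directions; sampled uniformly on the sphere if NULL.
#' @param latent_dim dimensionality of the shared low-rank log-rate drive
#'   (0 disables it).
#' @param noise_sd kinematic jitter / endpoint scatter SD, mm.
#' @param spout_targets 3 x 3 matrix of drinking spout positions (rows =
#'   left, middle, right), mm in the cranial frame.
#' @param region region label attached to all neurons ("MIo" or "SIo").
#' @param nerve_block logical; apply the simulated nerve block.
#' @param nerve_block_effects list with `depth_scale` in \[0,1\],
#'   `endpoint_sd_scale` >= 1, `pd_rotation_deg` >= 0.
#' @param octant_bias optional named weights over the eight octants for the
#'   feeding drift direction (default favors AntSup, then PostInf).
#' @param cycle_s duration of one gape cycle / lick, s (defaults 0.5 feeding,
#'   1.0 drinking).
#' @param speed_mm_s mean feeding drift speed, mm/s.
#' @param seed master seed; identical configs with identical seeds produce
#'   bit-identical outputs.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(behavior = c("feeding", "drinking"),
                         n_trials = 100,
                         frame_rate = 200,
                         n_neurons = 50,
                         tuned_fraction = 0.7,
                         baseline_rate = 10,
                         modulation_depth = 10,
                         planted_pds = NULL,
                         latent_dim = 0,
                         noise_sd = 0.5,
                         spout_targets = default_spout_targets(),
                         region = "MIo",
                         nerve_block = FALSE,
                         nerve_block_effects = list(depth_scale = 1,
                                                    endpoint_sd_scale = 1,
                                                    pd_rotation_deg = 0),
                         octant_bias = NULL,
                         cycle_s = NULL,
                         speed_mm_s = 40,
                         seed = 1L) {
  behavior <- match.arg(behavior)
  if (n_trials < 1) stopf("need at least one trial")
  n_tuned <- tuned_fraction * n_neurons
  if (abs(n_tuned - round(n_tuned)) > 1e-8)
    stopf("tuned_fraction * n_neurons must be an integer")
  if (!is.null(planted_pds)) {
    planted_pds <- as.matrix(planted_pds)
    if (any(abs(sqrt(rowSums(planted_pds^2)) - 1) > 1e-9))
      stopf("planted PDs must have unit norm")
  }
  if (behavior == "drinking") {
    spout_targets <- as.matrix(spout_targets)
    if (nrow(spout_targets) != 3L || !all(is.finite(spout_targets)))
      stopf("drinking requires three finite spout targets")
  }
  eff <- utils::modifyList(list(depth_scale = 1, endpoint_sd_scale = 1,
                                pd_rotation_deg = 0), nerve_block_effects)
  if (eff$depth_scale < 0 || eff$depth_scale > 1 || eff$endpoint_sd_scale < 1 ||
      eff$pd_rotation_deg < 0)
    stopf("invalid nerve_block_effects")
  if (is.null(octant_bias)) {
    octant_bias <- c(AntSupL = 2, AntSupR = 2, AntInfL = 1, AntInfR = 1,
                     PostSupL = 1, PostSupR = 1, PostInfL = 1.5, PostInfR = 1.5)
  }
  octant_bias <- octant_bias[OCTANT_LEVELS]
  if (any(is.na(octant_bias)) || any(octant_bias <= 0))
    stopf("octant_bias must give a positive weight to all eight octants")
  structure(list(behavior = behavior, n_trials = as.integer(n_trials),
                 frame_rate = frame_rate, n_neurons = as.integer(n_neurons),
                 tuned_fraction = tuned_fraction,
                 baseline_rate = baseline_rate,
                 modulation_depth = modulation_depth,
                 planted_pds = planted_pds, latent_dim = as.integer(latent_dim),
                 noise_sd = noise_sd, spout_targets = spout_targets,
                 region = region, nerve_block = isTRUE(nerve_block),
                 nerve_block_effects = eff, octant_bias = octant_bias,
                 cycle_s = cycle_s %||% if (behavior == "drinking") 1.0 else 0.5,
                 speed_mm_s = speed_mm_s, seed = as.integer(seed)),
            class = "synth_config")
}

#' Default drinking spout layout (mm, cranial frame): left / middle / right.
#' @export
default_spout_targets <- function() {
  m <- rbind(left   = c(30, -20, 0),
             middle = c(35,   0, 0),
             right  = c(30,  20, 0))
  colnames(m) <- c("x", "y", "z")
  m
}

# Uniform random unit vectors on the sphere, one per row.
runif_sphere <- function(n) normalize_rows(matrix(stats::rnorm(n * 3), ncol = 3))

# Rotate row vectors about the vertical (z, superior) axis by `deg` degrees.
rotate_about_z <- function(m, deg) {
  a <- deg * pi / 180
  rot <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  m %*% t(rot)
}

#' Generate synthetic tongue-tip kinematics
#'
#' Feeding: each gape cycle is a drift-plus-jitter 3D walk; every 100-ms block
#' draws an octant from the configured bias and drifts in a random direction
#' within that octant at the configured speed, so 100-ms displacement octants
#' cover all eight directions with the configured frequencies. Drinking: each
#' lick follows a raised-cosine protrusion from a rest position to an endpoint
#' scattered around the cued spout with per-axis SD
#' `noise_sd * endpoint_sd_scale` (the latter only under nerve block);
#' minimum protrusion is at the cycle start, maximum protrusion at
#' mid-cycle. Spout cues cycle through left/middle/right in a seed-shuffled
#' balanced order.
#'
#' @param config a [synth_config()].
#' @return a [marker_trajectory()] with cycle annotations.
#' @export
generate_kinematics <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_rng_seed(derive_seed(config$seed, "kinematics"), {
    if (config$behavior == "feeding") gen_kin_feeding(config) else
      gen_kin_drinking(config)
  })
}

gen_kin_feeding <- function(cfg) {
  fr <- cfg$frame_rate
  fpc <- round(cfg$cycle_s * fr)           # frames per gape cycle
  blk <- max(1L, round(0.1 * fr))          # one octant-drift block = 100 ms
  center <- c(15, 0, 0)
  signs <- cbind(x = ifelse(grepl("^Ant", OCTANT_LEVELS), 1, -1),
                 y = ifelse(grepl("R$", OCTANT_LEVELS), 1, -1),
                 z = ifelse(grepl("Sup", OCTANT_LEVELS), 1, -1))
  w <- cfg$octant_bias / sum(cfg$octant_bias)
  pos <- matrix(NA_real_, cfg$n_trials * fpc, 3)
  cycles <- data.frame(cycle_id = seq_len(cfg$n_trials),
                       start_idx = (seq_len(cfg$n_trials) - 1L) * fpc + 1L,
                       end_idx = seq_len(cfg$n_trials) * fpc,
                       type = sample(c("manipulation", "transport", "chew"),
                                     cfg$n_trials, replace = TRUE),
                       spout = NA_character_,
                       min_protrusion_idx = NA_integer_,
                       max_protrusion_idx = NA_integer_)
  for (tr in seq_len(cfg$n_trials)) {
    p <- center
    n_blocks <- ceiling(fpc / blk)
    octs <- sample(seq_along(OCTANT_LEVELS), n_blocks, replace = TRUE, prob = w)
    vel <- matrix(NA_real_, fpc, 3)
    for (b in seq_len(n_blocks)) {
      u <- abs(stats::rnorm(3)); u <- u / vec_norm(u)
      dirv <- u * signs[octs[b], ]
      rows <- ((b - 1L) * blk + 1L):min(b * blk, fpc)
      vel[rows, ] <- matrix(dirv * cfg$speed_mm_s / fr, length(rows), 3,
                            byrow = TRUE)
    }
    jit <- matrix(stats::rnorm(fpc * 3, sd = cfg$noise_sd / 10), fpc, 3)
    traj <- sweep(apply(vel + jit, 2, cumsum), 2, p, "+")
    pos[cycles$start_idx[tr]:cycles$end_idx[tr], ] <- traj
    cycles$min_protrusion_idx[tr] <- cycles$start_idx[tr] - 1L +
      which.min(traj[, 1])
    cycles$max_protrusion_idx[tr] <- cycles$start_idx[tr] - 1L +
      which.max(traj[, 1])
  }
  times <- (seq_len(nrow(pos)) - 1) / fr
  marker_trajectory(times, pos, cycles, behavior = "feeding")
}

gen_kin_drinking <- function(cfg) {
  fr <- cfg$frame_rate
  fpc <- round(cfg$cycle_s * fr)
  rest <- c(5, 0, -5)
  spouts <- cfg$spout_targets
  spout_names <- rownames(spouts) %||% c("left", "middle", "right")
  cue <- sample(rep_len(seq_len(3L), cfg$n_trials))
  sd_ep <- cfg$noise_sd *
    if (cfg$nerve_block) cfg$nerve_block_effects$endpoint_sd_scale else 1
  pos <- matrix(NA_real_, cfg$n_trials * fpc, 3)
  phase <- 0.5 * (1 - cos(2 * pi * (seq_len(fpc) - 1) / fpc))  # 0 -> 1 -> 0
  cycles <- data.frame(cycle_id = seq_len(cfg$n_trials),
                       start_idx = (seq_len(cfg$n_trials) - 1L) * fpc + 1L,
                       end_idx = seq_len(cfg$n_trials) * fpc,
                       type = "lick",
                       spout = spout_names[cue],
                       min_protrusion_idx = NA_integer_,
                       max_protrusion_idx = NA_integer_)
  for (tr in seq_len(cfg$n_trials)) {
    endpoint <- spouts[cue[tr], ] + stats::rnorm(3, sd = sd_ep)
    seg <- outer(phase, endpoint - rest) + matrix(rest, fpc, 3, byrow = TRUE)
    pos[cycles$start_idx[tr]:cycles$end_idx[tr], ] <- seg
    cycles$min_protrusion_idx[tr] <- cycles$start_idx[tr]
    cycles$max_protrusion_idx[tr] <- cycles$start_idx[tr] - 1L +
      which.max(phase)
  }
  times <- (seq_len(nrow(pos)) - 1) / fr
  marker_trajectory(times, pos, cycles, behavior = "drinking")
}

#' Generate a synthetic spiking population with planted ground truth
#'
#' Each tuned neuron fires as an inhomogeneous Poisson process with rate
#' `max(0, baseline + depth * cos(angle(u(t), pd)))`, where u(t) is the
#' instantaneous movement direction of the tongue-tip marker; untuned neurons
#' are homogeneous Poisson at baseline. With `latent_dim > 0` a shared
#' Gaussian low-rank drive enters multiplicatively (additively on log-rate)
#' through a stored loading matrix, with per-trial latent states centered on
#' direction-specific targets — giving the population direction-organized
#' shared covariance recoverable by Factor Analysis. Under nerve block the
#' tuning depth is scaled by `depth_scale` and PDs are rotated about the
#' vertical axis by `pd_rotation_deg`.
#'
#' @param config a [synth_config()].
#' @param kin the [marker_trajectory()] from [generate_kinematics()] under the
#'   same config.
#' @return list with `spikes` (a `spike_dataset`) and `truth` (planted
#'   ground truth: per-neuron tuning flag, effective and pre-block PDs,
#'   baseline, depth; the latent loading matrix; per-trial direction labels).
#' @export
generate_population <- function(config, kin) {
  stopifnot(inherits(config, "synth_config"), inherits(kin, "marker_trajectory"))
  with_rng_seed(derive_seed(config$seed, "population"), {
    n <- config$n_neurons
    n_tuned <- as.integer(round(config$tuned_fraction * n))
    pds0 <- if (!is.null(config$planted_pds)) {
      if (nrow(config$planted_pds) != n_tuned)
        stopf("planted_pds must have one row per tuned neuron (%d)", n_tuned)
      config$planted_pds
    } else if (n_tuned > 0) runif_sphere(n_tuned) else matrix(numeric(0), 0, 3)
    depth <- config$modulation_depth
    pds <- pds0
    if (config$nerve_block) {
      depth <- depth * config$nerve_block_effects$depth_scale
      if (n_tuned > 0 && config$nerve_block_effects$pd_rotation_deg > 0)
        pds <- rotate_about_z(pds0, config$nerve_block_effects$pd_rotation_deg)
    }
    is_tuned <- rep(c(TRUE, FALSE), c(n_tuned, n - n_tuned))

    fr <- kin$frame_rate; dt <- 1 / fr
    nframe <- length(kin$times)
    dpos <- rbind(diff(kin$positions), rep(0, 3))
    u <- dpos / pmax(sqrt(rowSums(dpos^2)), .Machine$double.eps)
    u[rowSums(dpos != 0) == 0, ] <- 0   # stationary frames: no modulation

    # rates: nframe x n
    lam <- matrix(config$baseline_rate, nframe, n)
    if (n_tuned > 0) {
      cosang <- u %*% t(pds)            # nframe x n_tuned
      lam[, seq_len(n_tuned)] <- pmax(0, config$baseline_rate + depth * cosang)
    }

    # direction label per trial (octant of whole-cycle displacement for
    # feeding; spout for drinking) drives the latent targets
    cyc <- kin$cycles
    trial_label <- if (kin$behavior == "drinking") as.character(cyc$spout) else {
      as.character(octant_label(kin$positions[cyc$end_idx, , drop = FALSE] -
                                kin$positions[cyc$start_idx, , drop = FALSE]))
    }
    loading <- NULL
    if (config$latent_dim > 0) {
      m <- config$latent_dim
      loading <- matrix(stats::rnorm(n * m, sd = 0.25), n, m)
      labs <- unique(trial_label[!is.na(trial_label)])
      targets <- matrix(stats::rnorm(length(labs) * m), length(labs), m,
                        dimnames = list(labs, NULL))
      drive <- matrix(0, nframe, n)
      for (tr in seq_len(nrow(cyc))) {
        tgt <- if (!is.na(trial_label[tr])) targets[trial_label[tr], ] else
          rep(0, m)
        z <- tgt + stats::rnorm(m, sd = 0.3)
        rows <- cyc$start_idx[tr]:cyc$end_idx[tr]
        drive[rows, ] <- matrix(loading %*% z, length(rows), n, byrow = TRUE)
      }
      lam <- lam * exp(drive)
      attr(loading, "targets") <- targets
    }

    counts <- matrix(stats::rpois(nframe * n, lam * dt), nframe, n)
    nz <- which(counts > 0, arr.ind = TRUE)
    reps <- counts[nz]
    frame_idx <- rep(nz[, 1], reps)
    neuron_idx <- rep(nz[, 2], reps)
    st <- kin$times[frame_idx] + stats::runif(length(frame_idx), 0, dt)
    ord <- order(neuron_idx, st)
    spikes <- data.frame(neuron_id = neuron_idx[ord], region = config$region,
                         spike_time_s = st[ord])
    ds <- spike_dataset(spikes,
                        neurons = data.frame(neuron_id = seq_len(n),
                                             region = config$region,
                                             condition = if (config$nerve_block)
                                               "nerve_block" else "control",
                                             stable = TRUE),
                        t_start = kin$times[1],
                        t_end = kin$times[nframe] + dt)
    truth <- list(
      neurons = data.frame(
        neuron_id = seq_len(n), is_tuned = is_tuned,
        pd_x = c(pds[, 1], rep(NA, n - n_tuned)),
        pd_y = c(pds[, 2], rep(NA, n - n_tuned)),
        pd_z = c(pds[, 3], rep(NA, n - n_tuned)),
        pd_preblock_x = c(pds0[, 1], rep(NA, n - n_tuned)),
        pd_preblock_y = c(pds0[, 2], rep(NA, n - n_tuned)),
        pd_preblock_z = c(pds0[, 3], rep(NA, n - n_tuned)),
        baseline = config$baseline_rate, depth = depth),
      loading = loading,
      trial_labels = trial_label)
    list(spikes = ds, truth = truth)
  })
}

#' Spike dataset container
#'
#' Per-neuron spike timestamps with region/condition metadata.
#'
#' @param spikes data.frame with columns `neuron_id`, `region`,
#'   `spike_time_s`.
#' @param neurons data.frame with one row per neuron: `neuron_id`, `region`,
#'   `condition`, and a `stable` flag (cross-session stability is an input
#'   here, not computed).
#' @param t_start,t_end recording span in seconds.
#' @return object of class `spike_dataset`.
#' @export
spike_dataset <- function(spikes, neurons, t_start, t_end) {
  if (nrow(spikes) &&
      (any(spikes$spike_time_s < t_start) || any(spikes$spike_time_s > t_end)))
    stopf("spike times outside the recording span")
  structure(list(spikes = spikes, neurons = neurons,
                 t_start = t_start, t_end = t_end),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat(sprintf("<spike_dataset> %d neurons, %d spikes, span %.3g-%.3g s\n",
              nrow(x$neurons), nrow(x$spikes), x$t_start, x$t_end))
  invisible(x)
}
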