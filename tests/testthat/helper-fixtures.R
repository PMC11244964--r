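# Shared in-code fixtures. Everything is generated at test time; no files.

# A small synthetic session: config, kinematics, spikes, truth.
quick_session <- function(behavior = "feeding", n_trials = 40, n_neurons = 6,
                          tuned_fraction = 0.5, baseline_rate = 20,
                          modulation_depth = 15, seed = 101, ...) {
  cfg <- synth_config(behavior = behavior, n_trials = n_trials,
                      n_neurons = n_neurons, tuned_fraction = tuned_fraction,
                      baseline_rate = baseline_rate,
                      modulation_depth = modulation_depth, seed = seed, ...)
  kin <- generate_kinematics(cfg)
  pg <- generate_population(cfg, kin)
  list(cfg = cfg, kin = kin, spikes = pg$spikes, truth = pg$truth)
}

# Build a rate_table directly from matrices (for closed-form tests).
make_rate_table <- function(rates, labels, U, window_s = 0.1,
                            region = "MIo") {
  rates <- as.matrix(rates)
  colnames(rates) <- as.character(seq_len(ncol(rates)))
  structure(list(rates = rates, counts = round(rates * window_s),
                 window_s = rep(window_s, nrow(rates)),
                 labels = factor(labels), U = U,
                 neurons = data.frame(neuron_id = seq_len(ncol(rates)),
                                      region = region, condition = "control",
                                      stable = TRUE),
                 balanced = length(unique(table(labels))) == 1L),
            class = "rate_table")
}

# Unit vectors pointing at the eight octant centers.
octant_centers <- function() {
  g <- as.matrix(expand.grid(x = c(1, -1), y = c(1, -1), z = c(1, -1)))
  g / sqrt(3)
}

angular_error_deg <- function(u, v)
  acos(pmin(pmax(sum(u * v), -1), 1)) * 180 / pi
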