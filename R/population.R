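#' Bin and smooth population spiking into trials
#'
#' Bins each neuron's spike times into `bin_ms` bins within each trial
#' window, smooths within trial with a truncated (+/-3 SD), edge-renormalized
#' Gaussian kernel (renormalized so each source bin's count mass is conserved),
#' and masks out neurons whose mean firing rate over the trial set is below
#' `min_rate` spikes/s. No smoothing leaks across trial boundaries.
#'
#' @param spikes a [spike_dataset()].
#' @param trials data.frame with columns `t_start`, `t_end`, `label`; all
#'   trials must have equal duration.
#' @param bin_ms bin width, ms (default 10).
#' @param smooth_sd_ms Gaussian kernel SD, ms (default 10; 0 disables).
#' @param min_rate inclusion threshold, spikes/s (default 1.0).
#' @return object of class `binned_population`: `counts` and `smoothed`
#'   arrays (trial x bin x neuron), `labels`, `include` mask, `bin_s`,
#'   neuron metadata.
#' @export
bin_and_smooth <- function(spikes, trials, bin_ms = 10, smooth_sd_ms = 10,
                           min_rate = 1.0) {
  stopifnot(inherits(spikes, "spike_dataset"))
  if (nrow(trials) == 0L) stopf("empty trial set")
  dur <- trials$t_end - trials$t_start
  if (diff(range(dur)) > 1e-9) stopf("trials must have equal duration")
  bin_s <- bin_ms / 1000
  n_bins <- floor(round(dur[1] / bin_s, 9))
  if (n_bins < 1L) stopf("trial shorter than one bin")
  ids <- spikes$neurons$neuron_id
  n_neu <- length(ids)
  counts <- array(0L, c(nrow(trials), n_bins, n_neu),
                  dimnames = list(NULL, NULL, as.character(ids)))
  sp <- split(spikes$spikes$spike_time_s, spikes$spikes$neuron_id)
  for (nm in names(sp)) {
    st <- sort(sp[[nm]])
    j <- match(nm, as.character(ids))
    for (tr in seq_len(nrow(trials))) {
      edges <- trials$t_start[tr] + bin_s * (0:n_bins)
      counts[tr, , j] <- findInterval(edges[-1], st, left.open = TRUE) -
        findInterval(edges[-(n_bins + 1)], st, left.open = TRUE)
    }
  }
  smoothed <- counts
  if (smooth_sd_ms > 0) {
    sd_bins <- smooth_sd_ms / bin_ms
    half <- ceiling(3 * sd_bins)
    # W[i, j]: weight from source bin j to output bin i, columns sum to 1
    W <- outer(seq_len(n_bins), seq_len(n_bins), function(i, j)
      ifelse(abs(i - j) <= half, stats::dnorm(i - j, sd = sd_bins), 0))
    W <- sweep(W, 2, colSums(W), "/")
    smoothed <- array(0, dim(counts), dimnames = dimnames(counts))
    for (j in seq_len(n_neu))
      smoothed[, , j] <- counts[, , j] %*% t(W)
  }
  total_t <- sum(dur)
  mean_rate <- apply(counts, 3, sum) / total_t
  structure(list(counts = counts, smoothed = smoothed, bin_s = bin_s,
                 labels = as.character(trials$label),
                 include = mean_rate >= min_rate, mean_rate = mean_rate,
                 neurons = spikes$neurons),
            class = "binned_population")
}

#' @export
print.binned_population <- function(x, ...) {
  cat(sprintf("<binned_population> %d trials x %d bins x %d neurons (%d included)\n",
              dim(x$counts)[1], dim(x$counts)[2], dim(x$counts)[3],
              sum(x$include)))
  invisible(x)
}

# Stack a binned population into an observation matrix: (trial*bin) x neuron,
# included neurons only.
pop_matrix <- function(pop) {
  d <- dim(pop$smoothed)
  Y <- matrix(aperm(pop$smoothed, c(2, 1, 3)), d[1] * d[2], d[3])
  colnames(Y) <- dimnames(pop$smoothed)[[3]]
  Y[, pop$include, drop = FALSE]
}

#' Fit a Factor Analysis model by expectation-maximization
#'
#' Fits the linear latent-variable model y ~ N(mu, C'C + R): C (m x n) maps m
#' latent factors to the n neurons' smoothed spike counts and R is the
#' diagonal unique (private) variance. EM runs from a principal-axes
#' initialization until the relative log-likelihood improvement falls below
#' `tol` or `max_iter` iterations; the log-likelihood trace is monotone
#' non-decreasing and returned with the model.
#'
#' @param x a `binned_population` or a numeric observation matrix
#'   (observations x neurons).
#' @param m latent dimensionality (must be < number of neurons).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations (default 500).
#' @param psi_floor lower bound on unique variances (default 1e-6).
#' @return object of class `fa_model`: `mu`, `C` (m x n), `R` (diagonal as a
#'   vector), `m`, `loglik` trace, `converged`.
#' @export
fit_fa <- function(x, m, tol = 1e-6, max_iter = 500, psi_floor = 1e-6) {
  Y <- if (inherits(x, "binned_population")) pop_matrix(x) else as.matrix(x)
  N <- nrow(Y); n <- ncol(Y)
  if (m >= n) stopf("latent dimensionality m must be below the neuron count")
  if (N < 10 * m) stopf("need at least 10*m observations")
  mu <- colMeans(Y)
  S <- stats::cov(Y) * (N - 1) / N      # ML covariance
  S <- S + diag(1e-9, n)                # guard exact singularity
  # principal-axes init
  es <- eigen(S, symmetric = TRUE)
  ev <- pmax(es$values, 0)
  noise0 <- if (n > m) mean(ev[(m + 1):n]) else 0
  L <- es$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(pmax(ev[seq_len(m)] - noise0, psi_floor)), m)
  psi <- pmax(diag(S) - rowSums(L^2), psi_floor)
  ll_of <- function(L, psi) {
    Sig <- tcrossprod(L) + diag(psi, n)
    ch <- chol(Sig)
    logdet <- 2 * sum(log(diag(ch)))
    Sinv_S <- chol2inv(ch) %*% S
    -N / 2 * (n * log(2 * pi) + logdet + sum(diag(Sinv_S)))
  }
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Sig <- tcrossprod(L) + diag(psi, n)
    Sig_inv <- chol2inv(chol(Sig))
    beta <- crossprod(L, Sig_inv)                    # m x n
    Ezz <- diag(m) - beta %*% L + beta %*% S %*% t(beta)
    SB <- S %*% t(beta)                              # n x m
    L <- SB %*% solve(Ezz)
    psi <- pmax(diag(S) - rowSums(L * SB), psi_floor)
    ll <- ll_of(L, psi)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  structure(list(mu = mu, C = t(L), R = psi, m = m, loglik = trace,
                 converged = converged,
                 neuron_ids = colnames(Y) %||% as.character(seq_len(n))),
            class = "fa_model")
}

#' @export
print.fa_model <- function(x, ...) {
  cat(sprintf("<fa_model> m = %d, %d neurons, LL = %.4g (%s)\n",
              x$m, ncol(x$C), utils::tail(x$loglik, 1),
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Log-likelihood of data under a Factor Analysis model
#'
#' @param model an `fa_model`.
#' @param Y observation matrix (observations x neurons, same neuron order as
#'   the fit).
#' @return total log-likelihood of `Y`.
#' @export
fa_loglik <- function(model, Y) {
  Y <- as.matrix(Y)
  n <- ncol(Y)
  Sig <- crossprod(model$C) + diag(model$R, n)
  ch <- chol(Sig)
  logdet <- 2 * sum(log(diag(ch)))
  Xc <- sweep(Y, 2, model$mu)
  q <- rowSums((Xc %*% chol2inv(ch)) * Xc)
  -0.5 * sum(n * log(2 * pi) + logdet + q)
}

#' Posterior-mean latent states
#'
#' Standard FA regression estimator E\[z|y\] = C (C'C + R)^-1 (y - mu).
#'
#' @param model an `fa_model`.
#' @param Y observation matrix (observations x neurons).
#' @return matrix (observations x m) of posterior means.
#' @export
infer_latents <- function(model, Y) {
  Y <- as.matrix(Y)
  n <- ncol(Y)
  Sig <- crossprod(model$C) + diag(model$R, n)
  beta <- model$C %*% chol2inv(chol(Sig))   # m x n
  t(beta %*% t(sweep(Y, 2, model$mu)))
}

#' Cross-validated selection of the latent dimensionality
#'
#' 3-fold (by default) cross-validation over a grid of candidate
#' dimensionalities: folds are seed-deterministic partitions of the
#' observations, the model is fit on the training folds and scored by
#' held-out log-likelihood, and m* maximizes the mean held-out
#' log-likelihood (ties go to the smaller m).
#'
#' @param x a `binned_population` or observation matrix.
#' @param m_grid integer vector of candidate dimensionalities.
#' @param folds number of CV folds (default 3).
#' @param seed integer seed for the fold assignment.
#' @param ... passed to [fit_fa()].
#' @return list: `m_star`, `cv` (data.frame of m and mean held-out LL),
#'   `folds` assignment.
#' @export
select_dimensionality <- function(x, m_grid, folds = 3, seed = NULL, ...) {
  Y <- if (inherits(x, "binned_population")) pop_matrix(x) else as.matrix(x)
  if (!length(m_grid)) stopf("empty dimensionality grid")
  m_grid <- sort(unique(as.integer(m_grid)))
  N <- nrow(Y)
  fold_id <- with_rng_seed(seed, sample(rep_len(seq_len(folds), N)))
  heldout <- matrix(NA_real_, length(m_grid), folds)
  for (i in seq_along(m_grid)) {
    for (f in seq_len(folds)) {
      fit <- fit_fa(Y[fold_id != f, , drop = FALSE], m_grid[i], ...)
      heldout[i, f] <- fa_loglik(fit, Y[fold_id == f, , drop = FALSE]) /
        sum(fold_id == f)
    }
  }
  mean_ll <- rowMeans(heldout)
  list(m_star = m_grid[which.max(mean_ll)],
       cv = data.frame(m = m_grid, heldout_ll = mean_ll),
       folds = fold_id)
}

#' Trial-averaged latent population trajectories
#'
#' Extracts posterior-mean latents for every trial, rotates the latent space
#' so factors are ordered by shared variance explained (SVD of the loading
#' matrix), and averages latents within each direction label, yielding one
#' latent trajectory (time-bin x m) per direction plus the cumulative shared
#' variance explained by the ordered factors.
#'
#' @param model an `fa_model`.
#' @param pop the `binned_population` the model was fit to.
#' @return object of class `latent_trajectory_set`: `trajectories` (named
#'   list of bin x m matrices), `cum_expvar`, `n_trials` per direction,
#'   `single_trial_flagged` directions with one trial.
#' @export
latent_trajectories <- function(model, pop) {
  stopifnot(inherits(model, "fa_model"), inherits(pop, "binned_population"))
  d <- dim(pop$smoothed)
  Y <- pop_matrix(pop)                       # (trial*bin) x n, bin fastest
  Z <- infer_latents(model, Y)               # (trial*bin) x m
  sv <- svd(t(model$C))                      # loadings n x m
  Zrot <- Z %*% sv$v                         # factors ordered by shared var
  shared <- sv$d^2
  labs <- pop$labels
  n_bins <- d[2]
  trial_of <- rep(seq_len(d[1]), each = n_bins)
  trajs <- lapply(split(seq_len(d[1]), labs), function(trs) {
    zz <- array(0, c(n_bins, model$m))
    for (tr in trs) zz <- zz + Zrot[trial_of == tr, , drop = FALSE]
    zz / length(trs)
  })
  n_per <- vapply(split(seq_len(d[1]), labs), length, integer(1))
  structure(list(trajectories = trajs,
                 cum_expvar = cumsum(shared) / sum(shared),
                 n_trials = n_per,
                 single_trial_flagged = names(n_per)[n_per < 2]),
            class = "latent_trajectory_set")
}

#' Inter-trajectory distances and path lengths
#'
#' For every unique pair of direction trajectories, the per-bin Euclidean
#' distance over all m latent factors (8 feeding directions give 28 pairs;
#' 3 drinking spouts give 3 pairs) and its mean over bins; per trajectory,
#' the cumulative Euclidean path length from trial start to end.
#'
#' @param set a `latent_trajectory_set`.
#' @param factors optional subset of factor indices (default all).
#' @return list: `per_bin` (pairs x bins matrix), `mean_distance` per pair,
#'   `path_length` per direction, `pairs`.
#' @export
trajectory_metrics <- function(set, factors = NULL) {
  trajs <- set$trajectories
  D <- length(trajs)
  if (D < 2L) stopf("need at least two directions")
  nb <- vapply(trajs, nrow, integer(1))
  if (length(unique(nb)) != 1L) stopf("mismatched bin counts between trajectories")
  if (!is.null(factors)) trajs <- lapply(trajs, function(z)
    z[, factors, drop = FALSE])
  prs <- utils::combn(names(trajs), 2)
  per_bin <- t(apply(prs, 2, function(p)
    sqrt(rowSums((trajs[[p[1]]] - trajs[[p[2]]])^2))))
  rownames(per_bin) <- paste(prs[1, ], prs[2, ], sep = "-")
  path_len <- vapply(trajs, function(z)
    sum(sqrt(rowSums(diff(z)^2))), numeric(1))
  list(per_bin = per_bin, mean_distance = rowMeans(per_bin),
       path_length = path_len, pairs = t(prs))
}

#' Compare mean inter-trajectory distances between two sets
#'
#' Two-sample t-test on the per-pair mean inter-trajectory distances of two
#' conditions or regions.
#'
#' @param set_a,set_b `latent_trajectory_set` objects (or outputs of
#'   [trajectory_metrics()]).
#' @return list: `mean_a`, `mean_b`, `t_p`.
#' @export
trajectory_contrast <- function(set_a, set_b) {
  ma <- if (inherits(set_a, "latent_trajectory_set"))
    trajectory_metrics(set_a)$mean_distance else set_a$mean_distance
  mb <- if (inherits(set_b, "latent_trajectory_set"))
    trajectory_metrics(set_b)$mean_distance else set_b$mean_distance
  list(mean_a = mean(ma), mean_b = mean(mb),
       t_p = stats::t.test(ma, mb)$p.value)
}

#' Subsampling controls for the FA pipeline
#'
#' `equal_trials`: repeats the FA pipeline on standardized samples of
#' `n_trials` trials per direction (default 80), `repeats` times (default
#' 10), reporting cumulative-explained-variance and mean inter-trajectory
#' distance with across-repeat dispersion. `equal_neurons`: subsamples two
#' populations to their common neuron count and reports the same metrics for
#' each.
#'
#' @param pop a `binned_population`.
#' @param mode "equal_trials" or "equal_neurons".
#' @param m latent dimensionality for the repeated fits.
#' @param pop2 second population (required for `equal_neurons`).
#' @param n_trials trials per direction for `equal_trials` (default 80).
#' @param repeats subsampling repetitions (default 10).
#' @param seed integer seed.
#' @return data.frame with one row per repeat (and per population for
#'   `equal_neurons`): cumulative explained variance of the first
#'   min(3, m) factors and mean inter-trajectory distance.
#' @export
subsample_controls <- function(pop, mode = c("equal_trials", "equal_neurons"),
                               m = 3, pop2 = NULL, n_trials = 80, repeats = 10,
                               seed = NULL) {
  mode <- match.arg(mode)
  k_ev <- min(3, m)
  one_run <- function(p) {
    fit <- fit_fa(p, m)
    set <- latent_trajectories(fit, p)
    c(cum_expvar3 = unname(set$cum_expvar[k_ev]),
      mean_distance = mean(trajectory_metrics(set)$mean_distance))
  }
  if (mode == "equal_trials") {
    byd <- split(seq_along(pop$labels), pop$labels)
    if (any(lengths(byd) < n_trials))
      stopf("insufficient trials: need %d per direction, have %s", n_trials,
            paste(lengths(byd), collapse = "/"))
    rows <- with_rng_seed(seed, lapply(seq_len(repeats), function(rep) {
      keep <- sort(unlist(lapply(byd, sample, n_trials)))
      one_run(subset_trials(pop, keep))
    }))
    out <- as.data.frame(do.call(rbind, rows))
    out$repeat_id <- seq_len(repeats)
    out
  } else {
    if (is.null(pop2)) stopf("equal_neurons requires a second population")
    n_common <- min(sum(pop$include), sum(pop2$include))
    rows <- with_rng_seed(seed, lapply(seq_len(repeats), function(rep) {
      r1 <- one_run(subset_neurons(pop, sample(which(pop$include), n_common)))
      r2 <- one_run(subset_neurons(pop2, sample(which(pop2$include), n_common)))
      rbind(c(r1, population = 1), c(r2, population = 2))
    }))
    out <- as.data.frame(do.call(rbind, rows))
    out$repeat_id <- rep(seq_len(repeats), each = 2)
    out
  }
}

subset_trials <- function(pop, idx) {
  out <- pop
  out$counts <- pop$counts[idx, , , drop = FALSE]
  out$smoothed <- pop$smoothed[idx, , , drop = FALSE]
  out$labels <- pop$labels[idx]
  out
}

subset_neurons <- function(pop, idx) {
  out <- pop
  out$counts <- pop$counts[, , idx, drop = FALSE]
  out$smoothed <- pop$smoothed[, , idx, drop = FALSE]
  out$include <- pop$include[idx]
  out$mean_rate <- pop$mean_rate[idx]
  out$neurons <- pop$neurons[idx, , drop = FALSE]
  out
}

#' Simulate Gaussian observations from a Factor Analysis model
#'
#' Draws y = mu + C'z + e with z ~ N(0, I_m) and e ~ N(0, R): the generative
#' model the EM fitter assumes. Used for subspace-recovery validation.
#'
#' @param mu mean vector (length n).
#' @param C loading matrix (m x n).
#' @param R diagonal unique variances (length n).
#' @param n_obs number of observations.
#' @param seed integer seed.
#' @return matrix (n_obs x n).
#' @export
simulate_fa_observations <- function(mu, C, R, n_obs, seed = NULL) {
  m <- nrow(C); n <- ncol(C)
  with_rng_seed(seed, {
    Z <- matrix(stats::rnorm(n_obs * m), n_obs, m)
    E <- matrix(stats::rnorm(n_obs * n), n_obs, n) *
      matrix(sqrt(R), n_obs, n, byrow = TRUE)
    sweep(Z %*% C + E, 2, mu, "+")
  })
}

#' Principal angles between two loading subspaces
#'
#' @param C1,C2 loading matrices (m x n each; rows span the subspaces in
#'   neuron space after transposition).
#' @return principal angles in degrees, length min(m1, m2).
#' @export
principal_angles <- function(C1, C2) {
  Q1 <- qr.Q(qr(t(C1)))
  Q2 <- qr.Q(qr(t(C2)))
  sv <- svd(crossprod(Q1, Q2))$d
  acos(pmin(pmax(sv, -1), 1)) * 180 / pi
}
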