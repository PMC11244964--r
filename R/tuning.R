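#' Interval firing-rate table
#'
#' Counts spikes of every neuron in every directional interval and converts
#' to rates (count / window length). Counts are retained for Fano-factor
#' analysis, and each interval's unit displacement is kept for cosine fits.
#' Degenerate (zero-displacement) intervals are excluded from tuning inputs
#' by default.
#'
#' @param spikes a [spike_dataset()].
#' @param intervals data.frame from [make_intervals()] (or
#'   [balanced_interval_sample()]).
#' @param include_degenerate keep degenerate intervals (default FALSE).
#' @return object of class `rate_table`: rates and counts matrices
#'   (interval x neuron), per-interval labels and unit displacements,
#'   per-neuron metadata, and a `balanced` flag.
#' @export
interval_firing_rates <- function(spikes, intervals, include_degenerate = FALSE) {
  stopifnot(inherits(spikes, "spike_dataset"))
  iv <- intervals
  if (!include_degenerate) iv <- iv[!iv$degenerate, , drop = FALSE]
  if (any(iv$t_start < spikes$t_start - 1e-9) ||
      any(iv$t_end > spikes$t_end + 1e-9))
    stopf("intervals extend outside the recording span")
  n_iv <- nrow(iv)
  ids <- spikes$neurons$neuron_id
  counts <- matrix(0L, n_iv, length(ids),
                   dimnames = list(NULL, as.character(ids)))
  sp <- split(spikes$spikes$spike_time_s, spikes$spikes$neuron_id)
  for (nm in names(sp)) {
    st <- sort(sp[[nm]])
    # spikes in [t_start, t_end): #(st < t_end) - #(st < t_start)
    counts[, nm] <- findInterval(iv$t_end, st, left.open = TRUE) -
      findInterval(iv$t_start, st, left.open = TRUE)
  }
  w <- iv$t_end - iv$t_start
  d <- as.matrix(iv[, c("dx", "dy", "dz")])
  nrm <- sqrt(rowSums(d^2)); nrm[nrm == 0] <- NA_real_
  labels <- factor(iv$label)
  structure(list(rates = counts / w, counts = counts, window_s = w,
                 labels = labels, U = d / nrm,
                 neurons = spikes$neurons,
                 balanced = length(unique(table(labels))) == 1L),
            class = "rate_table")
}

#' @export
print.rate_table <- function(x, ...) {
  cat(sprintf("<rate_table> %d intervals x %d neurons, %d directions%s\n",
              nrow(x$rates), ncol(x$rates), nlevels(x$labels),
              if (x$balanced) " (balanced)" else ""))
  invisible(x)
}

#' Bootstrap test of directional modulation
#'
#' Tests whether a neuron's mean firing-rate ranks are the same across
#' directions. The statistic is the spread (max - min) of per-direction mean
#' mid-ranks on a balanced design (an equal number of intervals per
#' direction). Its null distribution is built by resampling an equal number
#' of intervals per direction with replacement from the rates pooled across
#' directions (exchangeable under the null); the neuron is called tuned when
#' the observed spread exceeds the (1 - alpha) quantile of that null
#' distribution. The test is calibrated: its type-I error is alpha by
#' construction.
#'
#' @param rates a `rate_table` from [interval_firing_rates()].
#' @param neuron neuron id (column of the rate table).
#' @param n_boot bootstrap replicates (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @param min_per_direction minimum intervals required per direction
#'   (default 5; below it the result is flagged `insufficient_data`).
#' @return list: `tuned` flag, `statistic` (observed mean-rank spread),
#'   `null_q` (null (1-alpha) quantile), `p` (bootstrap p-value),
#'   `mean_ranks` per direction, flags.
#' @export
bootstrap_direction_test <- function(rates, neuron, n_boot = 1000,
                                     alpha = 0.05, seed = NULL,
                                     min_per_direction = 5L) {
  r <- rates$rates[, as.character(neuron)]
  labs <- droplevels(rates$labels)
  D <- nlevels(labs)
  if (D < 2L) stopf("need at least two directions")
  tab <- table(labs)
  if (any(tab < min_per_direction))
    return(list(tuned = NA, statistic = NA_real_, null_q = NA_real_,
                p = NA_real_, mean_ranks = NULL,
                insufficient_data = TRUE, all_zero = FALSE))
  if (all(r == 0))
    return(list(tuned = FALSE, statistic = 0, null_q = NA_real_, p = 1,
                mean_ranks = NULL, insufficient_data = FALSE, all_zero = TRUE))
  n_eq <- min(tab)
  with_rng_seed(seed, {
    # balanced observed design (subsample without replacement if unbalanced)
    idx <- unlist(lapply(levels(labs), function(g) {
      w <- which(labs == g)
      if (length(w) > n_eq) sample(w, n_eq) else w
    }))
    grp <- rep(seq_len(D), each = n_eq)
    obs_ranks <- rowsum(rank(r[idx]), grp)[, 1] / n_eq
    stat <- diff(range(obs_ranks))
    pool <- r[idx]
    bidx <- matrix(sample.int(length(pool), n_eq * D * n_boot, replace = TRUE),
                   n_eq * D, n_boot)
    samp <- matrix(pool[bidx], n_eq * D, n_boot)
    null_mr <- rowsum(apply(samp, 2, rank), grp) / n_eq
    null_stat <- apply(null_mr, 2, function(m) diff(range(m)))
    q <- stats::quantile(null_stat, 1 - alpha, names = FALSE)
    list(tuned = stat > q, statistic = stat, null_q = q,
         p = (1 + sum(null_stat >= stat)) / (n_boot + 1),
         mean_ranks = stats::setNames(obs_ranks, levels(labs)),
         insufficient_data = FALSE, all_zero = FALSE)
  })
}

#' Run the bootstrap direction test on every neuron
#'
#' @inheritParams bootstrap_direction_test
#' @return data.frame with one row per neuron: `neuron_id`, `tuned`, `p`,
#'   `statistic`, `insufficient_data`.
#' @export
bootstrap_direction_test_all <- function(rates, n_boot = 1000, alpha = 0.05,
                                         seed = NULL) {
  ids <- colnames(rates$rates)
  res <- lapply(seq_along(ids), function(i)
    bootstrap_direction_test(rates, ids[i], n_boot = n_boot, alpha = alpha,
                             seed = derive_seed(seed, paste0("boot", i))))
  data.frame(neuron_id = ids,
             tuned = vapply(res, function(x) as.logical(x$tuned), logical(1)),
             p = vapply(res, function(x) x$p, numeric(1)),
             statistic = vapply(res, function(x) x$statistic, numeric(1)),
             insufficient_data = vapply(res, function(x) x$insufficient_data,
                                        logical(1)))
}

#' Cosine tuning fit and 3D preferred direction
#'
#' Ordinary least squares of firing rate on the components of each interval's
#' unit displacement: rate ~ b0 + bx ux + by uy + bz uz. The neuron
#' `fits_cosine` when the regression F-test has p < 0.05; the preferred
#' direction is (bx, by, bz) normalized; the directional index is the
#' depth-of-tuning of the fitted curve over the sphere,
#' DI = (f_max - f_min) / f_max with f_max = b0 + ||b||,
#' f_min = b0 - ||b||, clipped to \[0, 1\].
#'
#' @param rates a `rate_table` (needs >= 8 distinct directions for a
#'   well-posed 3D fit; coplanar direction sets are flagged degenerate).
#' @param neuron neuron id.
#' @return list: `coefficients` (b0, bx, by, bz), `p_F`, `fits_cosine`, `pd`
#'   (unit 3-vector), `directional_index`, `preferred_yaw_deg`,
#'   `preferred_pitch_deg`, `degenerate` flag.
#' @export
cosine_fit <- function(rates, neuron) {
  keep <- !is.na(rates$U[, 1])
  U <- rates$U[keep, , drop = FALSE]
  r <- rates$rates[keep, as.character(neuron)]
  X <- cbind(1, U)
  if (qr(X)$rank < 4L)
    return(list(coefficients = rep(NA_real_, 4), p_F = NA_real_,
                fits_cosine = FALSE, pd = rep(NA_real_, 3),
                directional_index = NA_real_, degenerate = TRUE))
  df <- data.frame(rate = r, ux = U[, 1], uy = U[, 2], uz = U[, 3])
  fit <- stats::lm(rate ~ ux + uy + uz, data = df)
  # full-regression F test, computed directly (robust to perfect fits)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((r - mean(r))^2)
  df1 <- 3; df2 <- length(r) - 4L
  p_F <- if (tss <= 0) 1 else if (rss < 1e-12 * tss) 0 else
    stats::pf(((tss - rss) / df1) / (rss / df2), df1, df2, lower.tail = FALSE)
  b <- stats::coef(fit)
  bn <- vec_norm(b[2:4])
  pd <- if (bn > 0) unname(b[2:4] / bn) else rep(NA_real_, 3)
  f_max <- b[1] + bn; f_min <- b[1] - bn
  di <- if (f_max > 0) min(max((f_max - f_min) / f_max, 0), 1) else NA_real_
  yp <- yaw_pitch(pd)
  list(coefficients = unname(b), p_F = unname(p_F),
       fits_cosine = unname(p_F) < 0.05, pd = pd,
       directional_index = unname(di),
       preferred_yaw_deg = yp$yaw_deg, preferred_pitch_deg = yp$pitch_deg,
       degenerate = FALSE)
}

#' Bootstrap modal preferred direction over discrete directions
#'
#' For tasks with discrete direction labels (three spouts, or six left-right
#' bins), resamples rates within each direction with replacement and records
#' the direction with the maximal mean rate per replicate. Ties within a
#' replicate are broken uniformly at random. Returns the empirical
#' distribution over directions and its mode.
#'
#' @param rates a `rate_table` with discrete labels.
#' @param neuron neuron id.
#' @param n_boot replicates (default 1000).
#' @param seed integer seed.
#' @return list: `distribution` (named shares), `mode`.
#' @export
bootstrap_modal_pd <- function(rates, neuron, n_boot = 1000, seed = NULL) {
  r <- rates$rates[, as.character(neuron)]
  labs <- droplevels(rates$labels)
  D <- nlevels(labs)
  if (D < 2L) stopf("need at least two directions")
  groups <- split(r, labs)
  with_rng_seed(seed, {
    wins <- integer(D)
    means <- matrix(NA_real_, n_boot, D)
    for (d in seq_len(D)) {
      v <- groups[[d]]; n_d <- length(v)
      idx <- matrix(sample.int(n_d, n_d * n_boot, replace = TRUE), n_d, n_boot)
      means[, d] <- colMeans(matrix(v[idx], n_d, n_boot))
    }
    argmax <- apply(means, 1, function(m) {
      w <- which(m == max(m))
      if (length(w) > 1L) sample(w, 1L) else w
    })
    shares <- tabulate(argmax, D) / n_boot
    names(shares) <- levels(labs)
    list(distribution = shares, mode = levels(labs)[which.max(shares)])
  })
}

#' Fano factor
#'
#' Spike-count variance divided by spike-count mean. Cells with zero mean
#' count return NA (excluded with a flag downstream).
#'
#' @param counts integer vector of spike counts from one condition cell.
#' @return the Fano factor (NA for a zero-mean cell).
#' @export
fano <- function(counts) {
  if (length(counts) < 2L) stopf("need at least two counts")
  m <- mean(counts)
  if (m == 0) return(NA_real_)
  stats::var(counts) / m
}

#' Per-neuron Fano factors from a rate table
#'
#' @param rates a `rate_table`.
#' @param by optionally split counts by direction label and average the
#'   per-direction Fano factors ("label"), or pool all intervals ("none").
#' @return data.frame with `neuron_id`, `mean_count`, `fano`.
#' @export
fano_table <- function(rates, by = c("none", "label")) {
  by <- match.arg(by)
  ids <- colnames(rates$counts)
  ff <- vapply(ids, function(nm) {
    x <- rates$counts[, nm]
    if (by == "none") fano(x) else
      mean(vapply(split(x, rates$labels), function(v)
        if (mean(v) == 0) NA_real_ else stats::var(v) / mean(v), numeric(1)),
        na.rm = TRUE)
  }, numeric(1))
  data.frame(neuron_id = ids,
             mean_count = colMeans(rates$counts),
             fano = unname(ff))
}

#' Mean-matched Fano factor across groups
#'
#' Controls for firing-rate differences between groups of neurons: bins the
#' per-neuron mean counts into `n_bins` equal-width bins over the common
#' range, takes the greatest common histogram (per-bin minimum across
#' groups), and repeatedly down-samples every group to that histogram,
#' averaging each group's mean Fano factor over `n_resample` draws.
#'
#' @param groups named list; each element a data.frame with columns
#'   `mean_count` and `fano` (one row per neuron), e.g. from [fano_table()].
#' @param n_bins equal-width mean-count bins (default 20).
#' @param n_resample resampling repetitions (default 50).
#' @param seed integer seed.
#' @return list: `fano` (named per-group mean-matched Fano factors),
#'   `n_matched` (neurons retained per draw), `excluded_zero_mean` counts.
#' @export
mean_matched_fano <- function(groups, n_bins = 20, n_resample = 50,
                              seed = NULL) {
  stopifnot(length(groups) >= 2L, !is.null(names(groups)))
  excluded <- vapply(groups, function(g) sum(is.na(g$fano) | g$mean_count == 0),
                     integer(1))
  groups <- lapply(groups, function(g)
    g[!is.na(g$fano) & g$mean_count > 0, , drop = FALSE])
  rng <- range(unlist(lapply(groups, function(g) g$mean_count)))
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  binned <- lapply(groups, function(g)
    findInterval(g$mean_count, brk, rightmost.closed = TRUE,
                 all.inside = TRUE))
  hist_per <- vapply(binned, function(b) tabulate(b, n_bins), integer(n_bins))
  target <- apply(hist_per, 1, min)
  if (sum(target) == 0) stopf("mean-count distributions share no common bins")
  with_rng_seed(seed, {
    ff <- vapply(names(groups), function(gn) {
      g <- groups[[gn]]; b <- binned[[gn]]
      mean(vapply(seq_len(n_resample), function(rep) {
        keep <- unlist(lapply(which(target > 0), function(k) {
          w <- which(b == k)
          if (length(w) > target[k]) sample(w, target[k]) else w
        }))
        mean(g$fano[keep])
      }, numeric(1)))
    }, numeric(1))
    list(fano = ff, n_matched = sum(target), excluded_zero_mean = excluded)
  })
}

#' Rayleigh test of circular uniformity
#'
#' Tests a sample of angles against uniformity on the circle using the
#' Rayleigh statistic Z = n * Rbar^2 with the standard finite-n corrected
#' p-value (Zar).
#'
#' @param angles_deg angles in degrees.
#' @return list: `p`, `Z`, `rbar`, `n`.
#' @export
rayleigh_test <- function(angles_deg) {
  a <- angles_deg[!is.na(angles_deg)] * pi / 180
  n <- length(a)
  if (n < 2L) stopf("need at least two angles")
  rbar <- vec_norm(c(mean(cos(a)), mean(sin(a))))
  Z <- n * rbar^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  list(p = max(min(p, 1), 0), Z = Z, rbar = rbar, n = n)
}

#' Two-sample circular concentration (k-) test
#'
#' F-ratio test of equal von Mises concentration between two circular
#' samples, in the classical form: f = ((n2 - 1)(n1 - R1)) /
#' ((n1 - 1)(n2 - R2)) with R the resultant lengths; two-sided p from the F
#' distribution. Accurate for concentrated samples (mean resultant length
#' above roughly 0.7).
#'
#' @param a1_deg,a2_deg the two angle samples, degrees.
#' @return list: `p`, `f`, `rbar1`, `rbar2`.
#' @export
concentration_ktest <- function(a1_deg, a2_deg) {
  a1 <- a1_deg[!is.na(a1_deg)] * pi / 180
  a2 <- a2_deg[!is.na(a2_deg)] * pi / 180
  n1 <- length(a1); n2 <- length(a2)
  if (n1 < 3L || n2 < 3L) stopf("need at least three angles per sample")
  R1 <- n1 * vec_norm(c(mean(cos(a1)), mean(sin(a1))))
  R2 <- n2 * vec_norm(c(mean(cos(a2)), mean(sin(a2))))
  if (abs(n1 - R1) < 1e-12 || abs(n2 - R2) < 1e-12)
    stopf("degenerate (all-identical) sample")
  f <- ((n2 - 1) * (n1 - R1)) / ((n1 - 1) * (n2 - R2))
  p <- if (f > 1) 2 * stats::pf(f, n1 - 1, n2 - 1, lower.tail = FALSE) else
    2 * stats::pf(1 / f, n2 - 1, n1 - 1, lower.tail = FALSE)
  list(p = min(p, 1), f = f, rbar1 = R1 / n1, rbar2 = R2 / n2)
}

#' Preferred-direction distribution tests
#'
#' Rayleigh uniformity test on left-right-projected PD angles; optional
#' two-sample concentration (k-) test against a second sample; optional
#' chi-square test on discrete PD category counts.
#'
#' @param pd_angles_deg left-right PD angles of the first sample, degrees.
#' @param pd_angles2_deg optional second sample for the concentration test.
#' @param discrete_counts optional matrix of discrete PD category counts
#'   (samples x categories) for the chi-square test.
#' @return list with `rayleigh_p` and, when inputs allow, `concentration_p`
#'   and `chisq_p`.
#' @export
pd_distribution_tests <- function(pd_angles_deg, pd_angles2_deg = NULL,
                                  discrete_counts = NULL) {
  if (sum(!is.na(pd_angles_deg)) < 10L)
    stopf("need at least 10 PDs per sample")
  out <- list(rayleigh_p = rayleigh_test(pd_angles_deg)$p)
  if (!is.null(pd_angles2_deg))
    out$concentration_p <- concentration_ktest(pd_angles_deg, pd_angles2_deg)$p
  if (!is.null(discrete_counts))
    out$chisq_p <- suppressWarnings(stats::chisq.test(discrete_counts))$p.value
  out
}

#' Tune every neuron in a rate table
#'
#' Runs the bootstrap modulation test on every neuron, then the cosine fit
#' (the fit is only attempted on neurons passing the bootstrap test) and the
#' Fano factor, producing one row per neuron.
#'
#' @inheritParams bootstrap_direction_test
#' @return data.frame of per-neuron results: `neuron_id`, `region`, `tuned`,
#'   `p_boot`, `fits_cosine`, `p_F`, `pd_x/y/z`, `di`, `preferred_yaw_deg`,
#'   `preferred_pitch_deg`, `fano`, `mean_count`.
#' @export
tune_neurons <- function(rates, n_boot = 1000, alpha = 0.05, seed = NULL) {
  boot <- bootstrap_direction_test_all(rates, n_boot = n_boot, alpha = alpha,
                                       seed = seed)
  ft <- fano_table(rates)
  cos_rows <- lapply(seq_len(nrow(boot)), function(i) {
    if (isTRUE(boot$tuned[i])) cosine_fit(rates, boot$neuron_id[i]) else
      list(p_F = NA_real_, fits_cosine = FALSE, pd = rep(NA_real_, 3),
           directional_index = NA_real_, preferred_yaw_deg = NA_real_,
           preferred_pitch_deg = NA_real_)
  })
  data.frame(
    neuron_id = boot$neuron_id,
    region = rates$neurons$region[match(boot$neuron_id,
                                        rates$neurons$neuron_id)],
    tuned = boot$tuned, p_boot = boot$p,
    fits_cosine = vapply(cos_rows, function(x) isTRUE(x$fits_cosine), logical(1)),
    p_F = vapply(cos_rows, function(x) x$p_F %||% NA_real_, numeric(1)),
    pd_x = vapply(cos_rows, function(x) x$pd[1], numeric(1)),
    pd_y = vapply(cos_rows, function(x) x$pd[2], numeric(1)),
    pd_z = vapply(cos_rows, function(x) x$pd[3], numeric(1)),
    di = vapply(cos_rows, function(x) x$directional_index, numeric(1)),
    preferred_yaw_deg = vapply(cos_rows, function(x)
      x$preferred_yaw_deg %||% NA_real_, numeric(1)),
    preferred_pitch_deg = vapply(cos_rows, function(x)
      x$preferred_pitch_deg %||% NA_real_, numeric(1)),
    fano = ft$fano, mean_count = ft$mean_count)
}

#' Control vs nerve-block tuning contrast
#'
#' Matches neurons by id across conditions and classifies each as having
#' gained, lost, or kept (stable-tuned / stable-untuned) directional tuning;
#' compares tuned proportions between conditions with a chi-square test; and
#' compares the preferred-direction distributions (left-right angles of
#' neurons tuned in both conditions) with the circular concentration k-test.
#'
#' @param control,block data.frames from [tune_neurons()] for the two
#'   conditions.
#' @return list: `per_neuron` classification, `counts`, `proportions`
#'   (gained/lost/stable shares), `tuned_prop` per condition,
#'   `chisq_p` (tuned proportions), `pd_shift_p` (k-test; NA when fewer than
#'   three PDs per condition).
#' @export
tuning_contrast <- function(control, block) {
  ids <- intersect(control$neuron_id, block$neuron_id)
  if (length(ids) < length(control$neuron_id) ||
      length(ids) < length(block$neuron_id))
    warning("unmatched neuron sets; contrasting the matched subset",
            call. = FALSE)
  c2 <- control[match(ids, control$neuron_id), ]
  b2 <- block[match(ids, block$neuron_id), ]
  cls <- ifelse(!c2$tuned & b2$tuned, "gained",
         ifelse(c2$tuned & !b2$tuned, "lost",
         ifelse(c2$tuned & b2$tuned, "stable_tuned", "stable_untuned")))
  counts <- table(factor(cls, levels = c("gained", "lost", "stable_tuned",
                                         "stable_untuned")))
  tab <- rbind(control = c(tuned = sum(c2$tuned), untuned = sum(!c2$tuned)),
               block = c(tuned = sum(b2$tuned), untuned = sum(!b2$tuned)))
  chisq_p <- suppressWarnings(stats::chisq.test(tab))$p.value
  both <- c2$tuned & b2$tuned & !is.na(c2$preferred_yaw_deg) &
    !is.na(b2$preferred_yaw_deg)
  pd_shift_p <- if (sum(both) >= 3L)
    concentration_ktest(c2$preferred_yaw_deg[both],
                        b2$preferred_yaw_deg[both])$p else NA_real_
  list(per_neuron = data.frame(neuron_id = ids, class = cls),
       counts = counts, proportions = counts / length(ids),
       tuned_prop = c(control = mean(c2$tuned), block = mean(b2$tuned)),
       chisq_p = chisq_p, pd_shift_p = pd_shift_p)
}
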