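#' Marker trajectory container
#'
#' Bundles a uniformly sampled 3D tongue-tip marker trace in the cranial
#' coordinate frame (origin at the posterior nasal spine) with its cycle
#' annotations. Axis convention throughout the package:
#' x = posterior(-)/anterior(+), y = left(-)/right(+),
#' z = inferior(-)/superior(+), all in mm.
#'
#' @param times numeric vector of timestamps (s), strictly increasing with a
#'   constant sampling interval.
#' @param positions numeric matrix (n x 3) of x, y, z positions in mm.
#' @param cycles data.frame of cycle annotations with columns `cycle_id`,
#'   `start_idx`, `end_idx`, `type`, `spout` (NA for feeding),
#'   `min_protrusion_idx`, `max_protrusion_idx` (indices into `times`).
#' @param behavior "feeding" or "drinking".
#' @return an object of class `marker_trajectory`.
#' @export
marker_trajectory <- function(times, positions, cycles = NULL,
                              behavior = c("feeding", "drinking")) {
  behavior <- match.arg(behavior)
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stopf("positions must be an n x 3 matrix")
  if (length(times) != nrow(positions)) stopf("times/positions length mismatch")
  dt <- diff(times)
  if (length(dt) && (any(dt <= 0) || diff(range(dt)) > 1e-9))
    stopf("times must be strictly increasing with a constant sampling interval")
  if (!all(is.finite(positions))) stopf("positions must be finite")
  if (!is.null(cycles)) {
    idx_cols <- intersect(c("start_idx", "end_idx", "min_protrusion_idx",
                            "max_protrusion_idx"), names(cycles))
    for (cc in idx_cols) {
      v <- cycles[[cc]]
      if (any(!is.na(v) & (v < 1 | v > length(times))))
        stopf("cycle annotation '%s' indexes outside the time axis", cc)
    }
  }
  colnames(positions) <- c("x", "y", "z")
  structure(list(times = times, positions = positions,
                 frame_rate = if (length(dt)) 1 / stats::median(dt) else NA_real_,
                 cycles = cycles, behavior = behavior),
            class = "marker_trajectory")
}

#' @export
print.marker_trajectory <- function(x, ...) {
  cat(sprintf("<marker_trajectory> %s: %d frames @ %.6g Hz, %d cycles\n",
              x$behavior, length(x$times), x$frame_rate,
              if (is.null(x$cycles)) 0L else nrow(x$cycles)))
  invisible(x)
}

#' Zero-phase low-pass smoothing of a marker trajectory
#'
#' Forward-backward 4th-order Butterworth low-pass filter applied to each
#' coordinate, preserving length and timestamps.
#'
#' @param traj a [marker_trajectory()].
#' @param cutoff_hz cutoff frequency in Hz (default 30).
#' @param order filter order (default 4).
#' @return the smoothed `marker_trajectory`.
#' @export
smooth_trajectory <- function(traj, cutoff_hz = 30, order = 4) {
  fr <- traj$frame_rate
  if (!is.finite(fr) || fr <= 2 * cutoff_hz)
    stopf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
          cutoff_hz, fr / 2)
  bf <- signal::butter(order, cutoff_hz / (fr / 2), type = "low")
  # odd-reflection padding suppresses the zero-initial-condition edge
  # transients of the forward-backward pass
  n <- nrow(traj$positions)
  npad <- min(n - 1L, max(3L * (order + 1L), ceiling(10 * fr / cutoff_hz)))
  sm <- apply(traj$positions, 2, function(col) {
    pre <- 2 * col[1] - col[(npad + 1):2]
    post <- 2 * col[n] - col[(n - 1):(n - npad)]
    out <- signal::filtfilt(bf, c(pre, col, post))
    out[(npad + 1):(npad + n)]
  })
  out <- traj
  out$positions <- matrix(sm, ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
  out
}

#' Unsigned 3D angle between two position vectors
#'
#' The instantaneous 3D direction angle between the position vectors at the
#' start and end of an interval: theta = atan2(||v1 x v2||, v1 . v2), in
#' degrees, always in \[0, 180\].
#'
#' @param v1,v2 numeric length-3 vectors (positions from the cranial origin).
#' @return angle in degrees, or NA with a warning-free degenerate signal when
#'   either vector has zero norm.
#' @export
direction_angle <- function(v1, v2) {
  n1 <- vec_norm(v1); n2 <- vec_norm(v2)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  atan2(vec_norm(cr), sum(v1 * v2)) * 180 / pi
}

OCTANT_LEVELS <- c("AntSupL", "AntSupR", "AntInfL", "AntInfR",
                   "PostSupL", "PostSupR", "PostInfL", "PostInfR")

#' Octant category of a displacement
#'
#' Categorizes a 3D displacement into one of eight direction octants from the
#' signs of its anteroposterior (x), lateral (y) and vertical (z) components:
#' Ant/Post, L/R, Sup/Inf. Zero components tie-break toward the positive label
#' (Ant, R, Sup); an all-zero displacement is degenerate and returns NA.
#'
#' @param displacement length-3 vector or n x 3 matrix of displacements (mm).
#' @return factor with the eight octant levels (NA for degenerate rows).
#' @export
octant_label <- function(displacement) {
  m <- if (is.matrix(displacement)) displacement else matrix(displacement, ncol = 3)
  lab <- paste0(ifelse(m[, 1] >= 0, "Ant", "Post"),
                ifelse(m[, 3] >= 0, "Sup", "Inf"),
                ifelse(m[, 2] >= 0, "R", "L"))
  lab[rowSums(m != 0) == 0] <- NA
  factor(lab, levels = OCTANT_LEVELS)
}

#' Signed left-right angle and 10-degree bin
#'
#' Angle of the horizontal-plane projection of a displacement relative to
#' straight-ahead (anterior), rightward positive. Binned into six half-open
#' 10-degree bins covering \[-30, 30): bin k spans
#' \[-30 + 10(k-1), -30 + 10k). Angles outside the range get bin NA.
#'
#' @param displacement length-3 vector or n x 3 matrix (mm).
#' @return list with `angle_deg` and `bin` (integer 1..6 or NA).
#' @export
leftright_angle_and_bin <- function(displacement) {
  m <- if (is.matrix(displacement)) displacement else matrix(displacement, ncol = 3)
  # snap to nanodegrees so bin edges are decided by the intended angle, not
  # by atan2 rounding
  a <- round(atan2(m[, 2], m[, 1]) * 180 / pi, 9)
  a[m[, 1] == 0 & m[, 2] == 0] <- NA_real_
  bin <- ifelse(!is.na(a) & a >= -30 & a < 30, floor((a + 30) / 10) + 1, NA_integer_)
  list(angle_deg = a, bin = as.integer(bin))
}

#' Yaw and pitch of a displacement
#'
#' Yaw is the signed angle of the horizontal-plane projection (rightward
#' positive; identical to the left-right angle). Pitch is the signed elevation
#' above the horizontal plane (superior positive). A purely vertical
#' displacement has pitch +/-90 and undefined (NA) yaw.
#'
#' @param displacement length-3 vector or n x 3 matrix (mm).
#' @return list with `yaw_deg` and `pitch_deg`.
#' @export
yaw_pitch <- function(displacement) {
  m <- if (is.matrix(displacement)) displacement else matrix(displacement, ncol = 3)
  h <- sqrt(m[, 1]^2 + m[, 2]^2)
  yaw <- round(atan2(m[, 2], m[, 1]) * 180 / pi, 9)  # matches lr_angle exactly
  yaw[h == 0] <- NA_real_
  pitch <- atan2(m[, 3], h) * 180 / pi
  pitch[h == 0 & m[, 3] == 0] <- NA_real_
  list(yaw_deg = yaw, pitch_deg = pitch)
}

#' Directional intervals from a marker trajectory
#'
#' Cuts the trajectory into fixed-length intervals and attaches, for each, the
#' displacement vector, the 3D direction angle between the start and end
#' position vectors, the octant, the signed left-right angle and its
#' 10-degree bin, yaw, pitch, and a direction label (octant for feeding,
#' spout for drinking). Two anchoring modes:
#' \describe{
#'   \item{tiled}{non-overlapping spans of `span_ms` tiled within each
#'     annotated cycle (or the whole trace if unannotated); the feeding
#'     default span is 100 ms.}
#'   \item{min_protrusion_centered}{one window of `span_ms` centered on each
#'     annotated minimum-protrusion time (the drinking default span is 500 ms,
#'     i.e. +/-250 ms); windows clipped by the recording edge are dropped.}
#' }
#' Zero-displacement intervals are flagged `degenerate` and are excluded from
#' tuning inputs downstream.
#'
#' @param traj a [marker_trajectory()].
#' @param span_ms interval length in ms.
#' @param anchor "tiled" or "min_protrusion_centered".
#' @return data.frame of directional intervals.
#' @export
make_intervals <- function(traj, span_ms = if (traj$behavior == "drinking") 500 else 100,
                           anchor = NULL) {
  if (is.null(anchor))
    anchor <- if (traj$behavior == "drinking") "min_protrusion_centered" else "tiled"
  anchor <- match.arg(anchor, c("tiled", "min_protrusion_centered"))
  fr <- traj$frame_rate
  nf <- round(span_ms / 1000 * fr)
  if (nf < 1) stopf("span_ms too short for the frame rate")
  n <- length(traj$times)
  # a window covers nf frames [i_start, i_start + nf - 1]; its spike-counting
  # span is [t_start, t_start + span_ms) and its displacement is measured
  # between the first and last frames inside the window
  if (anchor == "tiled") {
    if (!is.null(traj$cycles)) {
      segs <- traj$cycles
    } else {
      segs <- data.frame(cycle_id = 1L, start_idx = 1L, end_idx = n,
                         spout = NA_character_)
    }
    i_start <- integer(0); cyc <- integer(0)
    for (k in seq_len(nrow(segs))) {
      s <- segs$start_idx[k]; e <- segs$end_idx[k]
      if (e - s + 1L < nf) next
      st <- seq(s, e - nf + 1L, by = nf)
      i_start <- c(i_start, st); cyc <- c(cyc, rep(segs$cycle_id[k], length(st)))
    }
    if (!length(i_start)) stopf("span longer than every cycle")
  } else {
    if (is.null(traj$cycles) || !"min_protrusion_idx" %in% names(traj$cycles))
      stopf("min_protrusion_centered anchoring requires minimum-protrusion annotations")
    half <- floor(nf / 2)
    ctr <- traj$cycles$min_protrusion_idx
    keep <- !is.na(ctr) & ctr - half >= 1 & ctr - half + nf - 1L <= n
    i_start <- ctr[keep] - half
    cyc <- traj$cycles$cycle_id[keep]
  }
  i_end <- i_start + nf - 1L
  p1 <- traj$positions[i_start, , drop = FALSE]
  p2 <- traj$positions[i_end, , drop = FALSE]
  d <- p2 - p1
  theta <- vapply(seq_len(nrow(d)), function(i) direction_angle(p1[i, ], p2[i, ]),
                  numeric(1))
  oct <- octant_label(d)
  lr <- leftright_angle_and_bin(d)
  yp <- yaw_pitch(d)
  degen <- rowSums(d != 0) == 0
  spout_of <- if (!is.null(traj$cycles) && "spout" %in% names(traj$cycles)) {
    stats::setNames(as.character(traj$cycles$spout), traj$cycles$cycle_id)
  } else NULL
  label <- if (traj$behavior == "drinking" && !is.null(spout_of)) {
    spout_of[as.character(cyc)]
  } else as.character(oct)
  out <- data.frame(
    t_start = traj$times[i_start],
    t_end = traj$times[i_start] + nf / fr,
    i_start = i_start, i_end = i_end,
    dx = d[, 1], dy = d[, 2], dz = d[, 3],
    theta_deg = theta, octant = oct,
    lr_angle_deg = lr$angle_deg, lr_bin = lr$bin,
    yaw_deg = yp$yaw_deg, pitch_deg = yp$pitch_deg,
    cycle_id = cyc, label = label, degenerate = degen,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Balanced sampling of directional intervals
#'
#' Samples, without replacement, an equal number of intervals from each
#' direction label — the minimum count over labels — so that downstream neural
#' analyses see the same number of intervals per direction. Degenerate
#' intervals are excluded first.
#'
#' @param intervals data.frame from [make_intervals()].
#' @param seed integer seed (deterministic selection).
#' @param by column to balance on (default "label").
#' @return the balanced subset of `intervals` (row order: grouped by label).
#' @export
balanced_interval_sample <- function(intervals, seed = NULL, by = "label") {
  iv <- intervals[!intervals$degenerate & !is.na(intervals[[by]]), , drop = FALSE]
  counts <- table(iv[[by]])
  counts <- counts[counts > 0]
  if (length(counts) < 2L) stopf("need at least two non-empty directions")
  n_min <- min(counts)
  with_rng_seed(seed, {
    picked <- unlist(lapply(names(counts), function(g) {
      idx <- which(iv[[by]] == g)
      if (length(idx) == 1L) idx else sample(idx, n_min)
    }))
    iv[picked, , drop = FALSE]
  })
}

#' Kinematic performance metrics of one condition
#'
#' For drinking: per-spout maximum-protrusion endpoint statistics — per-axis
#' variance, mean distance from the spout's mean endpoint, and failed-cycle
#' flags (an endpoint deviating more than 2 SD from the spout mean on any
#' axis, both tails). For feeding: circular mean and spread of the left-right
#' direction angles. Both: mean and variance of tongue speed.
#'
#' @param traj a [marker_trajectory()] with cycle annotations.
#' @return object of class `kinematic_performance`.
#' @export
kinematic_performance <- function(traj) {
  sp <- speed_profile(traj)
  out <- list(behavior = traj$behavior,
              speed_mean = mean(sp), speed_var = stats::var(sp))
  if (traj$behavior == "drinking") {
    cyc <- traj$cycles
    ep <- traj$positions[cyc$max_protrusion_idx, , drop = FALSE]
    spout <- as.character(cyc$spout)
    per_spout <- lapply(split(seq_len(nrow(ep)), spout), function(idx) {
      e <- ep[idx, , drop = FALSE]
      mu <- colMeans(e)
      sdv <- apply(e, 2, stats::sd)
      dev <- sweep(e, 2, mu)
      dist <- sqrt(rowSums(dev^2))
      # an endpoint fails when it deviates more than 2 SD (either tail) from
      # the spout mean on any axis with nonzero spread
      thr <- 2 * sdv
      thr[sdv == 0] <- Inf
      failed <- rowSums(abs(dev) > rep(thr, each = nrow(e))) > 0
      list(mean_endpoint = mu, var_per_axis = sdv^2,
           mean_dist_from_mean = mean(dist), dist_from_mean = dist,
           failed = failed, idx = idx)
    })
    failed_all <- logical(nrow(cyc))
    dist_all <- numeric(nrow(cyc))
    for (g in per_spout) {
      failed_all[g$idx] <- g$failed
      dist_all[g$idx] <- g$dist_from_mean
    }
    out$per_spout <- lapply(per_spout, function(g)
      g[c("mean_endpoint", "var_per_axis", "mean_dist_from_mean")])
    out$failed_cycle <- failed_all
    out$failed_proportion <- mean(failed_all)
    out$dist_from_mean <- dist_all
    out$mean_dist_from_mean <- mean(dist_all)
  } else {
    iv <- make_intervals(traj, span_ms = 100, anchor = "tiled")
    a <- iv$lr_angle_deg[!is.na(iv$lr_angle_deg)] * pi / 180
    rbar <- vec_norm(c(mean(cos(a)), mean(sin(a))))
    out$direction_mean_deg <- atan2(mean(sin(a)), mean(cos(a))) * 180 / pi
    out$direction_spread_deg <- sqrt(-2 * log(max(rbar, .Machine$double.eps))) * 180 / pi
    out$lr_angles_deg <- a * 180 / pi
  }
  structure(out, class = "kinematic_performance")
}

speed_profile <- function(traj) {
  d <- diff(traj$positions)
  sqrt(rowSums(d^2)) * traj$frame_rate
}

#' Control vs nerve-block kinematic contrasts
#'
#' Two-sample two-tailed t-tests (means) and F-tests (variances) between two
#' conditions on tongue speed and, for drinking, on the distance from the mean
#' endpoint. Returns both per-condition metrics and the contrast p-values.
#'
#' @param control,block [marker_trajectory()] objects of the two conditions.
#' @return list with `control`, `block` ([kinematic_performance()]) and
#'   `tests` (t/F p-values).
#' @export
kinematic_performance_contrast <- function(control, block) {
  pc <- kinematic_performance(control)
  pb <- kinematic_performance(block)
  sp_c <- speed_profile(control); sp_b <- speed_profile(block)
  tests <- list(
    speed_t_p = stats::t.test(sp_c, sp_b)$p.value,
    speed_f_p = stats::var.test(sp_c, sp_b)$p.value)
  if (control$behavior == "drinking" && block$behavior == "drinking") {
    tests$endpoint_dist_t_p <-
      stats::t.test(pc$dist_from_mean, pb$dist_from_mean)$p.value
    tests$endpoint_dist_f_p <-
      stats::var.test(pc$dist_from_mean, pb$dist_from_mean)$p.value
  } else if (control$behavior == "feeding") {
    tests$direction_t_p <- stats::t.test(pc$lr_angles_deg, pb$lr_angles_deg)$p.value
    tests$direction_f_p <- stats::var.test(pc$lr_angles_deg, pb$lr_angles_deg)$p.value
  }
  list(control = pc, block = pb, tests = tests)
}
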