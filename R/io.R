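# Plain-text serialization of the pipeline's data types. All tabular formats
# are CSV with fixed, documented headers; configs and results are JSON/YAML.

#' Write / read marker kinematics as CSV
#'
#' Columns: time_s, x_mm, y_mm, z_mm, cycle_id, cycle_type, spout plus
#' per-cycle annotation columns is_min_protrusion / is_max_protrusion.
#'
#' @param traj a [marker_trajectory()].
#' @param path output file.
#' @return `path`, invisibly (writer); a `marker_trajectory` (reader).
#' @export
write_kinematics_csv <- function(traj, path) {
  n <- length(traj$times)
  cyc_of <- rep(NA_integer_, n); type_of <- rep(NA_character_, n)
  spout_of <- rep(NA_character_, n)
  is_min <- logical(n); is_max <- logical(n)
  if (!is.null(traj$cycles)) {
    for (k in seq_len(nrow(traj$cycles))) {
      rows <- traj$cycles$start_idx[k]:traj$cycles$end_idx[k]
      cyc_of[rows] <- traj$cycles$cycle_id[k]
      type_of[rows] <- as.character(traj$cycles$type[k])
      spout_of[rows] <- as.character(traj$cycles$spout[k])
    }
    is_min[stats::na.omit(traj$cycles$min_protrusion_idx)] <- TRUE
    is_max[stats::na.omit(traj$cycles$max_protrusion_idx)] <- TRUE
  }
  df <- data.frame(time_s = traj$times,
                   x_mm = traj$positions[, 1], y_mm = traj$positions[, 2],
                   z_mm = traj$positions[, 3],
                   cycle_id = cyc_of, cycle_type = type_of, spout = spout_of,
                   is_min_protrusion = is_min, is_max_protrusion = is_max,
                   behavior = traj$behavior)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinematics_csv
#' @export
read_kinematics_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cycles <- NULL
  if (any(!is.na(df$cycle_id))) {
    byc <- split(seq_len(nrow(df)), df$cycle_id)
    cycles <- do.call(rbind, lapply(names(byc), function(cid) {
      rows <- byc[[cid]]
      data.frame(cycle_id = as.integer(cid), start_idx = min(rows),
                 end_idx = max(rows),
                 type = df$cycle_type[rows[1]],
                 spout = df$spout[rows[1]],
                 min_protrusion_idx =
                   if (any(df$is_min_protrusion[rows]))
                     rows[which(df$is_min_protrusion[rows])[1]] else NA_integer_,
                 max_protrusion_idx =
                   if (any(df$is_max_protrusion[rows]))
                     rows[which(df$is_max_protrusion[rows])[1]] else NA_integer_)
    }))
    cycles <- cycles[order(cycles$cycle_id), ]
    rownames(cycles) <- NULL
  }
  marker_trajectory(df$time_s, as.matrix(df[, c("x_mm", "y_mm", "z_mm")]),
                    cycles, behavior = df$behavior[1])
}

#' Write / read a spike dataset as CSV
#'
#' Spike columns: neuron_id, region, spike_time_s; a `#meta` JSON comment on
#' the first line carries the recording span and per-neuron metadata.
#'
#' @param spikes a [spike_dataset()].
#' @param path output file.
#' @return `path`, invisibly (writer); a `spike_dataset` (reader).
#' @export
write_spikes_csv <- function(spikes, path) {
  meta <- jsonlite::toJSON(list(t_start = spikes$t_start,
                                t_end = spikes$t_end,
                                neurons = spikes$neurons),
                           auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#meta ", meta), con)
  utils::write.csv(spikes$spikes, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#meta ")) stopf("missing #meta header in %s", path)
  meta <- jsonlite::fromJSON(sub("^#meta ", "", first))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  spike_dataset(df, neurons = as.data.frame(meta$neurons),
                t_start = meta$t_start, t_end = meta$t_end)
}

#' Write directional intervals as CSV
#' @param intervals data.frame from [make_intervals()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_intervals_csv <- function(intervals, path) {
  utils::write.csv(intervals, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intervals_csv
#' @export
read_intervals_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$octant <- factor(df$octant, levels = OCTANT_LEVELS)
  df
}
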