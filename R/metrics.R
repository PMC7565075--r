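#' Normalized cell counts (growth statistic)
#'
#' Per-frame segmented cell counts divided by the initial count,
#' `N_t / N_0`; the first element is always 1. A 38% population increase
#' reads as 1.38.
#'
#' @param counts_per_frame non-negative per-frame cell counts; the first
#'   must be positive.
#' @return numeric vector of the same length.
#' @export
normalized_counts <- function(counts_per_frame) {
  if (length(counts_per_frame) == 0L) stop2("empty count series")
  if (any(counts_per_frame < 0)) stop2("counts must be >= 0")
  if (counts_per_frame[1] <= 0) stop2("initial cell count must be > 0")
  counts_per_frame / counts_per_frame[1]
}

#' Per-step velocities of one track
#'
#' Centroid differences between consecutive detections, converted to um/h
#' using the stack calibration. Across a closed gap the displacement is
#' divided by the full elapsed time, preserving the physical velocity
#' scale.
#'
#' @param track data.frame with columns `frame, Cx, Cy` (one track,
#'   frames strictly increasing).
#' @param pixel_size um/pix.
#' @param frame_interval min/frame.
#' @return data.frame `frame_from, frame_to, u, v, speed` (um/h).
#' @export
step_velocities <- function(track, pixel_size, frame_interval) {
  if (nrow(track) < 2L) stop2("track must have at least 2 points")
  track <- track[order(track$frame), , drop = FALSE]
  dt_h <- diff(track$frame) * frame_interval / 60
  u <- diff(track$Cx) * pixel_size / dt_h
  v <- diff(track$Cy) * pixel_size / dt_h
  data.frame(frame_from = utils::head(track$frame, -1),
             frame_to = utils::tail(track$frame, -1),
             u = u, v = v, speed = sqrt(u^2 + v^2))
}

#' Euclidean and accumulated travel distance of one track
#'
#' `d_euc` is the straight-line distance from the first to the last
#' centroid; `d_acc` sums the per-step displacement magnitudes
#' `sqrt(u^2 + v^2)`, so `d_euc <= d_acc` always.
#'
#' @param track data.frame with `frame, Cx, Cy` (pix).
#' @param pixel_size um/pix (1 to stay in pixels).
#' @return named vector `(d_euc, d_acc)` in um.
#' @export
distances <- function(track, pixel_size = 1) {
  if (nrow(track) < 2L) stop2("track must have at least 2 points")
  track <- track[order(track$frame), , drop = FALSE]
  dx <- diff(track$Cx) * pixel_size
  dy <- diff(track$Cy) * pixel_size
  c(d_euc = sqrt(sum(dx)^2 + sum(dy)^2), d_acc = sum(sqrt(dx^2 + dy^2)))
}

#' Per-track migration metrics
#'
#' Computes, for every track in a tracks table, the step count, mean
#' speed, Euclidean and accumulated distance, the net end-displacement
#' components, and the per-track directness `d_euc / d_acc`. Tracks with a
#' single detection are dropped (no step exists).
#'
#' @param tracks data.frame with columns `track_id, frame, Cx, Cy`.
#' @param pixel_size um/pix.
#' @param frame_interval min/frame.
#' @return data.frame, one row per track: `track_id, n_frames, n_steps,
#'   mean_speed, d_euc, d_acc, x_end, y_end, directness_i`.
#' @export
track_metrics <- function(tracks, pixel_size, frame_interval) {
  if (nrow(tracks) == 0L) stop2("empty tracks table")
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  id <- tracks$track_id
  same <- c(FALSE, id[-1] == id[-length(id)])   # row continues previous track
  dx <- c(NA, diff(tracks$Cx)) * pixel_size
  dy <- c(NA, diff(tracks$Cy)) * pixel_size
  dt <- c(NA, diff(tracks$frame)) * frame_interval / 60
  dx[!same] <- NA; dy[!same] <- NA; dt[!same] <- NA
  step <- sqrt(dx^2 + dy^2)

  ids <- unique(id)
  g <- match(id, ids)
  n_frames <- tabulate(g)
  sum_by <- function(x) {
    x[is.na(x)] <- 0
    as.numeric(rowsum(x, g, reorder = FALSE))
  }
  n_steps <- sum_by(as.numeric(same))
  x_end <- sum_by(dx); y_end <- sum_by(dy)
  d_acc <- sum_by(step)
  mean_speed <- sum_by(step / dt) / pmax(n_steps, 1)
  res <- data.frame(track_id = ids, n_frames = n_frames, n_steps = n_steps,
                    mean_speed = mean_speed,
                    d_euc = sqrt(x_end^2 + y_end^2), d_acc = d_acc,
                    x_end = x_end, y_end = y_end)
  res$directness_i <- ifelse(res$d_acc > 0, pmin(res$d_euc / res$d_acc, 1), NA)
  res <- res[res$n_steps >= 1, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Forward migration index
#'
#' Mean over tracks of the net end displacement along an axis divided by
#' that track's accumulated distance: chemotactic efficiency in `[-1, 1]`.
#' The x-axis is parallel to the chemotaxis gradient (negative x points
#' toward the chemoattractant, so straight runs toward it give -1); the
#' y-axis is perpendicular. Tracks with zero accumulated distance are
#' excluded with a warning.
#'
#' @param metrics per-track metrics from [track_metrics()].
#' @param axis `"parallel"` (x) or `"perpendicular"` (y).
#' @return scalar FMI.
#' @export
forward_migration_index <- function(metrics, axis = c("parallel", "perpendicular")) {
  axis <- match.arg(axis)
  bad <- metrics$d_acc <= 0
  if (any(bad)) {
    warning(sum(bad), " track(s) with zero accumulated distance excluded from FMI")
    metrics <- metrics[!bad, , drop = FALSE]
  }
  if (nrow(metrics) == 0L) stop2("no tracks with positive accumulated distance")
  comp <- if (axis == "parallel") metrics$x_end else metrics$y_end
  mean(comp / metrics$d_acc)
}

#' Mean directness
#'
#' Mean over tracks of `d_euc / d_acc`, in `[0, 1]`; 1 means every cell
#' migrated along a straight line from start to end.
#'
#' @inheritParams forward_migration_index
#' @return scalar directness.
#' @export
directness <- function(metrics) {
  bad <- metrics$d_acc <= 0
  if (any(bad)) {
    warning(sum(bad), " track(s) with zero accumulated distance excluded from directness")
    metrics <- metrics[!bad, , drop = FALSE]
  }
  if (nrow(metrics) == 0L) stop2("no tracks with positive accumulated distance")
  mean(metrics$d_euc / metrics$d_acc)
}

#' Select the longest tracks of a sample
#'
#' Drops tracks spanning no more than `min_frames` frames (short tracks
#' and debris bias the migration means), ranks the rest by track length in
#' frames (ties: larger accumulated distance, then smaller track id), and
#' keeps the top `k`. Warns when fewer than `k` tracks survive.
#'
#' @param tracks tracks table (`track_id, frame, Cx, Cy, ...`).
#' @param k number of tracks to keep (default 100).
#' @param min_frames minimum track length in frames, exclusive
#'   (default 10).
#' @param pixel_size um/pix used for the tie-breaking distance.
#' @return the selected subset of `tracks`.
#' @export
select_tracks <- function(tracks, k = 100L, min_frames = 10L, pixel_size = 1) {
  if (k <= 0) stop2("k must be > 0")
  if (nrow(tracks) == 0L) {
    warning("no tracks to select")
    return(tracks)
  }
  tm <- track_metrics(tracks, pixel_size = pixel_size, frame_interval = 60)
  tm <- tm[tm$n_frames > min_frames, , drop = FALSE]
  if (nrow(tm) < k)
    warning("only ", nrow(tm), " track(s) longer than ", min_frames,
            " frames; returning all")
  ord <- order(-tm$n_frames, -tm$d_acc, tm$track_id)
  keep <- tm$track_id[ord][seq_len(min(k, nrow(tm)))]
  tracks[tracks$track_id %in% keep, , drop = FALSE]
}

#' Pooled summary of one culture condition
#'
#' Applies the track-selection rule per replicate sample, pools the
#' selected tracks (e.g. 3 replicates x 100 tracks = 300), and computes
#' the condition-level statistics: normalized cell counts over time (from
#' all detections, before selection), the per-frame mean velocity
#' magnitude, forward migration indices, mean directness, mean speed, and
#' a velocity-magnitude histogram.
#'
#' @param samples list of tracks tables, one per replicate.
#' @param pixel_size um/pix.
#' @param frame_interval min/frame.
#' @param k,min_frames track-selection rule (see [select_tracks()]).
#' @param hist_binwidth velocity histogram bin width, um/h.
#' @param velocity_on_all compute the per-frame mean velocity series on
#'   all tracks instead of the selected pool (default `FALSE`).
#' @param smooth_window odd window length of a centered moving average
#'   applied to the mean-velocity series; `0` (default) disables.
#' @return a `condition_summary` list: `n_tracks`, `N_over_N0`,
#'   `mean_velocity_magnitude` (per-frame series), `FMI_par`, `FMI_perp`,
#'   `D`, `mean_speed`, `velocity_histogram` (`mids`, `counts`),
#'   `per_track` (pooled per-track metrics), `selected_tracks`.
#' @export
condition_summary <- function(samples, pixel_size, frame_interval,
                              k = 100L, min_frames = 10L,
                              hist_binwidth = 0.5, velocity_on_all = FALSE,
                              smooth_window = 0L) {
  if (!is.list(samples) || length(samples) == 0L) stop2("samples must be a non-empty list")
  all_tracks <- list(); selected <- list()
  for (s in seq_along(samples)) {
    tr <- samples[[s]]
    if (nrow(tr) == 0L) next
    tr$track_id <- tr$track_id + s * 1e7   # disambiguate ids across samples
    all_tracks[[s]] <- tr
    selected[[s]] <- select_tracks(tr, k = k, min_frames = min_frames,
                                   pixel_size = pixel_size)
  }
  pool_all <- do.call(rbind, all_tracks)
  pool_sel <- do.call(rbind, selected)
  if (is.null(pool_sel) || nrow(pool_sel) == 0L) stop2("no tracks survive selection")

  ## growth: counts per frame over all detections
  frames <- sort(unique(pool_all$frame))
  counts <- vapply(frames, function(f) sum(pool_all$frame == f), numeric(1))
  n_over_n0 <- normalized_counts(counts)

  tm <- track_metrics(pool_sel, pixel_size, frame_interval)
  vel_pool <- if (velocity_on_all) pool_all else pool_sel
  vseries <- per_frame_mean_speed(vel_pool, pixel_size, frame_interval, frames)
  if (smooth_window >= 3L) {
    w <- rep(1 / smooth_window, smooth_window)
    vseries$mean_speed <- as.numeric(stats::filter(vseries$mean_speed, w, sides = 2))
  }

  speeds <- all_step_speeds(vel_pool, pixel_size, frame_interval)
  brks <- seq(0, max(stats::quantile(speeds, 0.99), hist_binwidth) + hist_binwidth,
              by = hist_binwidth)
  h <- graphics::hist(pmin(speeds, max(brks)), breaks = brks, plot = FALSE)

  structure(list(
    n_tracks = length(unique(pool_sel$track_id)),
    N_over_N0 = data.frame(frame = frames, N_over_N0 = n_over_n0),
    mean_velocity_magnitude = vseries,
    FMI_par = forward_migration_index(tm, "parallel"),
    FMI_perp = forward_migration_index(tm, "perpendicular"),
    D = directness(tm),
    mean_speed = mean(tm$mean_speed),
    velocity_histogram = data.frame(mids = h$mids, counts = h$counts),
    per_track = tm,
    selected_tracks = pool_sel
  ), class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf(paste0("condition_summary: %d pooled tracks\n",
                     "  N/N0 final: %.3f | mean speed: %.3g um/h\n",
                     "  FMI par: %+.4f | FMI perp: %+.4f | directness: %.3f\n"),
              x$n_tracks, utils::tail(x$N_over_N0$N_over_N0, 1), x$mean_speed,
              x$FMI_par, x$FMI_perp, x$D))
  invisible(x)
}

## per-frame mean step-speed over the cells present at each frame
per_frame_mean_speed <- function(tracks, pixel_size, frame_interval, frames) {
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  id <- tracks$track_id
  same <- c(FALSE, id[-1] == id[-length(id)])
  dt <- c(NA, diff(tracks$frame)) * frame_interval / 60
  sp <- sqrt(c(NA, diff(tracks$Cx))^2 + c(NA, diff(tracks$Cy))^2) * pixel_size / dt
  sp[!same] <- NA
  fr <- tracks$frame
  ms <- vapply(frames, function(f) {
    v <- sp[fr == f & !is.na(sp)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  data.frame(frame = frames, mean_speed = ms)
}

all_step_speeds <- function(tracks, pixel_size, frame_interval) {
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  id <- tracks$track_id
  same <- c(FALSE, id[-1] == id[-length(id)])
  dt <- c(NA, diff(tracks$frame)) * frame_interval / 60
  sp <- sqrt(c(NA, diff(tracks$Cx))^2 + c(NA, diff(tracks$Cy))^2) * pixel_size / dt
  sp[same & !is.na(sp)]
}
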