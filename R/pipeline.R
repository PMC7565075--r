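#' Pipeline configuration
#'
#' Bundles the segmentation, tracking and selection settings with the
#' physical calibration. The calibration defaults describe wide-field
#' imaging at 4x magnification (1.34 um/pix) with one frame every 30 min.
#'
#' @param segmentation a [segmentation_config()].
#' @param tracking a [tracking_config()].
#' @param select_k,select_min_frames track-selection rule
#'   (see [select_tracks()]).
#' @param pixel_size um/pix.
#' @param frame_interval min/frame.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(segmentation = segmentation_config(),
                            tracking = tracking_config(),
                            select_k = 100L, select_min_frames = 10L,
                            pixel_size = 1.34, frame_interval = 30) {
  if (pixel_size <= 0 || frame_interval <= 0)
    stop2("calibration values must be > 0")
  validate_segmentation_config(segmentation)
  structure(list(segmentation = segmentation, tracking = tracking,
                 select_k = as.integer(select_k),
                 select_min_frames = as.integer(select_min_frames),
                 pixel_size = pixel_size, frame_interval = frame_interval),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on one or more channels
#'
#' For each channel stack independently: segment every frame, build the
#' multi-parametric feature tables, link them into tracks, and compute the
#' per-track metrics and condition summary. All tabular artifacts are
#' written to `out_dir` together with a manifest recording the
#' configuration (and its hash) for exact reruns. The whole pipeline is
#' deterministic given inputs and config.
#'
#' @param stacks named list of [image_stack()] objects, or a named
#'   character vector of TIFF paths (names = channel).
#' @param config a [pipeline_config()]. The calibration is taken from each
#'   stack's metadata.
#' @param out_dir output directory; created if needed. `NULL` disables
#'   writing.
#' @param progress log per-frame cell counts.
#' @return named list per channel, each with `labels`, `tracks`,
#'   `metrics`, `summary`.
#' @export
run_pipeline <- function(stacks, config = pipeline_config(), out_dir = NULL,
                         progress = FALSE) {
  if (is.character(stacks)) {
    if (is.null(names(stacks)) || any(names(stacks) == ""))
      names(stacks) <- paste0("ch", seq_along(stacks) - 1L)
    stacks <- lapply(stacks, read_stack)
  }
  if (!is.list(stacks) || !length(stacks)) stop2("no input stacks")
  if (is.null(names(stacks))) names(stacks) <- paste0("ch", seq_along(stacks) - 1L)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- list()
  for (ch in names(stacks)) {
    stack <- stacks[[ch]]
    if (!inherits(stack, "image_stack")) stop2("input '", ch, "' is not an image_stack")
    core <- track_stack(stack, config$segmentation, config$tracking,
                        progress = progress)
    labs <- core$labels
    tracks <- core$tracks
    tm <- track_metrics(tracks, stack$pixel_size, stack$frame_interval)
    ## a movie shorter than the selection cutoff still yields tracks/metrics
    summ <- tryCatch(
      condition_summary(list(tracks), stack$pixel_size, stack$frame_interval,
                        k = config$select_k,
                        min_frames = config$select_min_frames),
      error = function(e) {
        warning("channel '", ch, "': no condition summary (", conditionMessage(e), ")")
        NULL
      })
    results[[ch]] <- list(labels = labs, tracks = tracks, metrics = tm,
                          summary = summ)
    if (!is.null(out_dir)) {
      write_tracks(tracks, file.path(out_dir, paste0("tracks_", ch, ".csv")))
      utils::write.csv(tm, file.path(out_dir, paste0("metrics_", ch, ".csv")),
                       row.names = FALSE)
      if (!is.null(summ))
        write_summary(summ, file.path(out_dir, paste0("summary_", ch, ".json")))
    }
  }
  if (!is.null(out_dir)) {
    strip_class <- function(x) {
      x <- unclass(x)
      if (is.list(x)) lapply(x, strip_class) else x
    }
    cfg_plain <- strip_class(config)
    manifest <- list(
      package = "mptrack",
      version = as.character(utils::packageVersion("mptrack")),
      channels = names(stacks),
      config = cfg_plain,
      config_hash = config_hash(cfg_plain)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(results)
}

#' Segment, featurize and track one stack
#'
#' Convenience wrapper running the per-channel core of the pipeline:
#' segment every frame, measure the multi-parametric feature vectors on
#' the preprocessed frames, and link them into tracks.
#'
#' @param stack an [image_stack()].
#' @param seg_config a [segmentation_config()].
#' @param track_config a [tracking_config()].
#' @param progress log per-frame cell counts.
#' @return list with `labels` (list of [label_image()]), `features` (list
#'   of per-frame feature tables) and `tracks` (the tracks data.frame).
#' @export
track_stack <- function(stack, seg_config = segmentation_config(),
                        track_config = tracking_config(), progress = FALSE) {
  labs <- segment_stack(stack, seg_config, progress = progress)
  feats <- lapply(seq_along(labs), function(i)
    featurize_frame(labs[[i]], preprocess_frame(stack$frames[[i]], seg_config)))
  list(labels = labs, features = feats,
       tracks = build_tracks(feats, track_config))
}

## the preprocessed frame used for feature measurement (same transform the
## refinement stage sees)
preprocess_frame <- function(frame, seg_config) {
  bg <- subtract_background(frame, seg_config)
  tryCatch(adjust_intensity(bg, seg_config$saturation_fraction),
           error = function(e) bg)
}

config_hash <- function(cfg) {
  ser <- serialize(cfg, NULL)
  f <- tempfile(); on.exit(unlink(f))
  writeBin(ser, f)
  unname(tools::md5sum(f))
}

#' Write / read a tracks table as CSV
#'
#' Column layout `track_id,frame,x_pix,y_pix,imax,r,theta,s,ar`;
#' `read_tracks(write_tracks(x))` reproduces `x`. Malformed rows
#' (non-numeric or missing fields) are reported with their line numbers.
#'
#' @param tracks tracks table from [build_tracks()].
#' @param path CSV path.
#' @return `write_tracks`: `path`, invisibly. `read_tracks`: the tracks
#'   data.frame with the in-memory column names (`track_id, frame, Cx, Cy,
#'   Imax, R, theta, S, AR`).
#' @export
write_tracks <- function(tracks, path) {
  out <- data.frame(track_id = tracks$track_id, frame = tracks$frame,
                    x_pix = tracks$Cx, y_pix = tracks$Cy,
                    imax = tracks$Imax, r = tracks$R, theta = tracks$theta,
                    s = tracks$S, ar = tracks$AR)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop2("tracks file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character")
  need <- c("track_id", "frame", "x_pix", "y_pix", "imax", "r", "theta", "s", "ar")
  if (!all(need %in% names(raw)))
    stop2("tracks CSV is missing columns: ",
          paste(setdiff(need, names(raw)), collapse = ", "))
  num <- suppressWarnings(lapply(raw[need], as.numeric))
  bad <- Reduce(`|`, lapply(num, is.na))
  if (any(bad))
    stop2("malformed rows in ", path, " at line(s): ",
          paste(which(bad) + 1L, collapse = ", "))
  data.frame(track_id = num$track_id, frame = as.integer(num$frame),
             Cx = num$x_pix, Cy = num$y_pix, Imax = num$imax,
             R = num$r, theta = num$theta, S = num$s, AR = num$ar)
}

#' Write a condition summary as JSON
#'
#' @param summary a `condition_summary`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  x <- unclass(summary)
  x$selected_tracks <- NULL   # bulk data lives in the tracks CSV
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Trajectory map of the longest-traveling tracks
#'
#' Draws the `k` tracks with the largest accumulated distance, each
#' re-origined at (0, 0) — the standard wind-rose view of chemotaxis
#' assays. Axes are in um when a pixel size is given.
#'
#' @param tracks tracks table.
#' @param k number of tracks to draw (all if fewer exist).
#' @param pixel_size um/pix scaling applied to the coordinates.
#' @return a ggplot object.
#' @export
render_trajectory_map <- function(tracks, k = 50L, pixel_size = 1) {
  if (nrow(tracks) == 0L) stop2("empty tracks table")
  tm <- track_metrics(tracks, pixel_size = pixel_size, frame_interval = 60)
  ord <- tm$track_id[order(-tm$d_acc)]
  keep <- ord[seq_len(min(k, length(ord)))]
  df <- tracks[tracks$track_id %in% keep, , drop = FALSE]
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  sp <- split(df, df$track_id)
  df <- do.call(rbind, lapply(sp, function(d) {
    d$X <- (d$Cx - d$Cx[1]) * pixel_size
    d$Y <- (d$Cy - d$Cy[1]) * pixel_size
    d
  }))
  unit <- if (pixel_size == 1) "pix" else "um"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$X, y = .data$Y,
                                   group = factor(.data$track_id))) +
    ggplot2::geom_path(alpha = 0.6, linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = sprintf("x (%s)", unit), y = sprintf("y (%s)", unit),
                  title = sprintf("Trajectories of %d longest-traveling tracks",
                                  length(keep))) +
    ggplot2::theme_minimal()
}
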