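#' Image stack container
#'
#' A time-ordered list of 2D intensity frames plus the physical calibration
#' needed to report migration statistics in micrometers and hours. Frames
#' are numeric matrices with rows = y and columns = x; intensities are
#' arbitrary units, finite and non-negative.
#'
#' @param frames list of numeric matrices, all of one shape.
#' @param pixel_size physical pixel size, um/pix.
#' @param frame_interval acquisition interval, min/frame.
#' @param channel_name channel label (e.g. `"EGFP"`, `"dTomato"`).
#' @return An `image_stack` object.
#' @export
image_stack <- function(frames, pixel_size, frame_interval, channel_name = "ch0") {
  if (!is.list(frames) || length(frames) == 0)
    stop2("frames must be a non-empty list of matrices")
  dims <- dim(frames[[1]])
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || !identical(dim(f), dims))
      stop2("frame ", i, " has a different shape than frame 1")
    if (!all(is.finite(f)) || any(f < 0))
      stop2("frame ", i, " contains non-finite or negative intensities")
  }
  if (!is_scalar_num(pixel_size) || pixel_size <= 0) stop2("pixel_size must be > 0")
  if (!is_scalar_num(frame_interval) || frame_interval <= 0)
    stop2("frame_interval must be > 0")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 channel_name = as.character(channel_name)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("image_stack: %d frames of %d x %d [%s], %.3g um/pix, %g min/frame\n",
              length(x$frames), d[1], d[2], x$channel_name,
              x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' Write / read an image stack as multi-page TIFF
#'
#' Frames are stored as 16-bit grayscale TIFF pages. Because TIFF stores
#' values in `[0, 1]`, intensities are divided by a single scale factor
#' (the stack maximum, rounded up) which is recorded — together with the
#' calibration metadata — in a YAML sidecar file `<path>.yaml`, so that
#' `read_stack(write_stack(x))` recovers the stack up to 16-bit
#' quantization.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF file path.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns an
#'   [image_stack()].
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "image_stack")) stop2("stack must be an image_stack")
  mx <- max(vapply(stack$frames, max, numeric(1)))
  scale <- if (mx <= 0) 1 else ceiling(mx)
  pages <- lapply(stack$frames, function(f) f / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  meta <- list(pixel_size = stack$pixel_size,
               frame_interval = stack$frame_interval,
               channel_name = stack$channel_name,
               intensity_scale = scale,
               n_frames = length(stack$frames))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @param path TIFF file path; calibration is taken from the `<path>.yaml`
#'   sidecar when present, else from the explicit arguments.
#' @param pixel_size,frame_interval,channel_name calibration used when no
#'   sidecar file exists.
#' @rdname write_stack
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval = NULL,
                       channel_name = NULL) {
  if (!file.exists(path)) stop2("stack file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".yaml")
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list()
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]   # drop extra channels
    p * scale
  })
  ps <- pixel_size %||% meta$pixel_size
  fi <- frame_interval %||% meta$frame_interval
  ch <- channel_name %||% meta$channel_name %||% "ch0"
  if (is.null(ps) || is.null(fi))
    stop2("no calibration metadata: supply pixel_size and frame_interval or a sidecar yaml")
  image_stack(frames, pixel_size = ps, frame_interval = fi, channel_name = ch)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write simulation outputs to disk
#'
#' Writes the rendered stack as multi-page TIFF (with YAML sidecar), the
#' ground-truth tracks as CSV with header
#' `cell_id,frame,x,y,a,b,theta,imax`, and the configuration as YAML.
#'
#' @param truth a `ground_truth` object.
#' @param stack the matching rendered [image_stack()].
#' @param dir output directory, created if needed.
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation <- function(truth, stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(stack = file.path(dir, "stack.tif"),
             truth = file.path(dir, "truth.csv"),
             config = file.path(dir, "sim_config.yaml"))
  write_stack(stack, paths[["stack"]])
  utils::write.csv(truth$tracks, paths[["truth"]], row.names = FALSE)
  cfg <- truth$config
  cfg$image_size <- as.integer(cfg$image_size)
  yaml::write_yaml(unclass(cfg), paths[["config"]])
  invisible(paths)
}
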