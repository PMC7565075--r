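#' Simulation configuration
#'
#' Parameters of the synthetic fluorescence time-lapse generator. Defaults
#' describe a chemotaxis assay imaged on a 1280 x 1024 camera at 4x
#' magnification (1.34 um/pix), one frame every 30 min for 5 days
#' (240 frames), with ~100 diffuse elliptical cells performing a persistent
#' random walk in the field of view.
#'
#' @param image_size integer `(H, W)` frame size in pixels.
#' @param n_frames number of frames.
#' @param frame_interval minutes between frames.
#' @param pixel_size physical pixel size, um/pix.
#' @param n_cells_init initial cell count.
#' @param cell_radius_range `(min, max)` major semi-axis, um.
#' @param cell_eccentricity_range `(min, max)` ellipse eccentricity in
#'   `[0, 1)`; 0 is a circle.
#' @param intensity_range `(min, max)` peak fluorescence amplitude, a.u.
#' @param motion_speed mean cell speed, um/h.
#' @param persistence directional persistence in `[0, 1]`: the expected
#'   cosine of the per-step turning angle (0 = uncorrelated random walk,
#'   1 = straight-line motion).
#' @param chemotaxis_bias drift along x in `[-1, 1]`, as a fraction of the
#'   mean step length. Negative x points toward the chemoattractant
#'   reservoir, so a bias of -1 yields straight chemotactic runs.
#' @param division_rate,death_rate Poisson event rates, events/cell/h.
#' @param bleach_halflife photobleaching half-life, h (`Inf` disables).
#' @param illumination_gradient fractional drop of the multiplicative
#'   illumination field across the diagonal of the field of view.
#' @param noise_sd additive Gaussian sensor noise, a.u.
#' @param background_level baseline background intensity, a.u.
#' @param min_spacing minimum initial center-to-center distance, um.
#'   Defaults to four times the maximum cell radius so neighboring cells
#'   start well separated, as in a sparsely seeded gel.
#' @param seed integer seed; identical seed and config give bit-identical
#'   truth and rendered stack.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(image_size = c(1024L, 1280L),
                              n_frames = 240L,
                              frame_interval = 30,
                              pixel_size = 1.34,
                              n_cells_init = 100L,
                              cell_radius_range = c(7, 12),
                              cell_eccentricity_range = c(0, 0.7),
                              intensity_range = c(100, 200),
                              motion_speed = 3,
                              persistence = 0.6,
                              chemotaxis_bias = 0,
                              division_rate = 0.005,
                              death_rate = 0.002,
                              bleach_halflife = 48,
                              illumination_gradient = 0.2,
                              noise_sd = 2,
                              background_level = 10,
                              min_spacing = NULL,
                              seed = 1L) {
  cfg <- list(
    image_size = as.integer(image_size), n_frames = as.integer(n_frames),
    frame_interval = frame_interval, pixel_size = pixel_size,
    n_cells_init = as.integer(n_cells_init),
    cell_radius_range = cell_radius_range,
    cell_eccentricity_range = cell_eccentricity_range,
    intensity_range = intensity_range, motion_speed = motion_speed,
    persistence = persistence, chemotaxis_bias = chemotaxis_bias,
    division_rate = division_rate, death_rate = death_rate,
    bleach_halflife = bleach_halflife,
    illumination_gradient = illumination_gradient, noise_sd = noise_sd,
    background_level = background_level,
    min_spacing = if (is.null(min_spacing)) 4 * max(cell_radius_range) else min_spacing,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop2("invalid simulation config: ", msg)
  chk(length(cfg$image_size) == 2 && all(cfg$image_size >= 16), "image_size must be (H, W) >= 16")
  chk(is_scalar_num(cfg$n_frames) && cfg$n_frames >= 1, "n_frames must be >= 1")
  chk(is_scalar_num(cfg$frame_interval) && cfg$frame_interval > 0, "frame_interval must be > 0")
  chk(is_scalar_num(cfg$pixel_size) && cfg$pixel_size > 0, "pixel_size must be > 0")
  chk(is_scalar_num(cfg$n_cells_init) && cfg$n_cells_init >= 0, "n_cells_init must be >= 0")
  rng <- function(r) length(r) == 2 && all(is.finite(r)) && r[1] <= r[2]
  chk(rng(cfg$cell_radius_range) && cfg$cell_radius_range[1] > 0, "cell_radius_range invalid")
  chk(rng(cfg$cell_eccentricity_range) && cfg$cell_eccentricity_range[1] >= 0 &&
        cfg$cell_eccentricity_range[2] < 1, "cell_eccentricity_range must lie in [0, 1)")
  chk(rng(cfg$intensity_range) && cfg$intensity_range[1] > 0, "intensity_range invalid")
  chk(is_scalar_num(cfg$motion_speed) && cfg$motion_speed >= 0, "motion_speed must be >= 0")
  chk(is_scalar_num(cfg$persistence) && cfg$persistence >= 0 && cfg$persistence <= 1,
      "persistence must lie in [0, 1]")
  chk(is_scalar_num(cfg$chemotaxis_bias) && abs(cfg$chemotaxis_bias) <= 1,
      "chemotaxis_bias must lie in [-1, 1]")
  chk(is_scalar_num(cfg$division_rate) && cfg$division_rate >= 0, "division_rate must be >= 0")
  chk(is_scalar_num(cfg$death_rate) && cfg$death_rate >= 0, "death_rate must be >= 0")
  chk(is.numeric(cfg$bleach_halflife) && length(cfg$bleach_halflife) == 1 &&
        cfg$bleach_halflife > 0, "bleach_halflife must be > 0 (Inf allowed)")
  chk(is_scalar_num(cfg$illumination_gradient) && cfg$illumination_gradient >= 0 &&
        cfg$illumination_gradient < 1, "illumination_gradient must lie in [0, 1)")
  chk(is_scalar_num(cfg$noise_sd) && cfg$noise_sd >= 0, "noise_sd must be >= 0")
  chk(is_scalar_num(cfg$background_level) && cfg$background_level >= 0,
      "background_level must be >= 0")
  chk(is_scalar_num(cfg$min_spacing) && cfg$min_spacing >= 0, "min_spacing must be >= 0")
  invisible(cfg)
}

#' Simulate ground-truth cell tracks
#'
#' Draws cell trajectories from a persistent random walk with optional
#' chemotactic drift along x, plus Poisson division and death events.
#' Positions are in pixels, 0-based, `x` = column, `y` = row. Per step the
#' displacement is
#' `(1 - |bias|) * L * (cos phi, sin phi) + bias * L * (1, 0)`,
#' with `L = motion_speed * frame_interval` converted to pixels and `phi`
#' a heading whose turning angles are wrapped-normal with
#' `E[cos(turn)] = persistence`; hence with zero persistence the expected
#' x-displacement per step is exactly `bias * L`. Cells reflect at the
#' image edges. Daughters of a division are placed one major radius away
#' at a random angle and receive a fresh cell id; the lineage is recorded.
#'
#' @param config a [simulation_config()].
#' @return A `ground_truth` list with elements `tracks` (data.frame with
#'   columns `cell_id, frame, x, y, a, b, theta, imax`; `a`, `b` are the
#'   ellipse semi-axes in pixels), `lineage` (`parent`, `child`),
#'   `death_frames` (`cell_id`, `frame`) and the `config`.
#' @export
simulate_truth <- function(config) {
  validate_simulation_config(config)
  withr::with_seed(config$seed, simulate_truth_impl(config))
}

simulate_truth_impl <- function(cfg) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  dt_h <- cfg$frame_interval / 60
  L <- cfg$motion_speed * dt_h / cfg$pixel_size    # mean step length, pix
  p <- cfg$persistence
  turn_sd <- if (p >= 1) 0 else if (p <= 0) Inf else sqrt(-2 * log(p))
  bias <- cfg$chemotaxis_bias
  p_div <- 1 - exp(-cfg$division_rate * dt_h)
  p_die <- 1 - exp(-cfg$death_rate * dt_h)

  r_px <- cfg$cell_radius_range / cfg$pixel_size
  spacing_px <- cfg$min_spacing / cfg$pixel_size

  ## initial placement with minimum spacing (rejection sampling)
  n0 <- cfg$n_cells_init
  xs <- numeric(0); ys <- numeric(0)
  margin <- min(max(r_px[2], 1), min(H, W) / 4)
  tries <- 0L
  while (length(xs) < n0) {
    cx <- runif(1, margin, W - 1 - margin)
    cy <- runif(1, margin, H - 1 - margin)
    if (length(xs) == 0 || all((xs - cx)^2 + (ys - cy)^2 >= spacing_px^2)) {
      xs <- c(xs, cx); ys <- c(ys, cy); tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > 20000L)
        stop2("could not place ", n0, " cells with min_spacing = ",
              cfg$min_spacing, " um; reduce density or spacing")
    }
  }

  new_cell <- function(id, x, y) {
    a <- runif(1, r_px[1], r_px[2])
    ecc <- runif(1, cfg$cell_eccentricity_range[1], cfg$cell_eccentricity_range[2])
    list(id = id, x = x, y = y,
         a = a, b = a * sqrt(1 - ecc^2),
         theta = runif(1, -pi / 2, pi / 2),
         imax = runif(1, cfg$intensity_range[1], cfg$intensity_range[2]),
         heading = runif(1, 0, 2 * pi), alive = TRUE)
  }

  cells <- lapply(seq_len(n0), function(i) new_cell(i, xs[i], ys[i]))
  next_id <- n0 + 1L
  rows <- vector("list", 2048L); nrows <- 0L
  lineage <- list(); deaths <- list()

  push <- function(cell, f) {
    nrows <<- nrows + 1L
    if (nrows > length(rows)) length(rows) <<- 2L * nrows
    rows[[nrows]] <<- c(cell$id, f, cell$x, cell$y, cell$a, cell$b,
                        cell$theta, cell$imax)
  }
  reflect <- function(v, lo, hi) {
    span <- hi - lo
    v <- (v - lo) %% (2 * span)
    lo + ifelse(v > span, 2 * span - v, v)
  }

  for (f in seq_len(cfg$n_frames) - 1L) {
    for (cell in cells) if (cell$alive) push(cell, f)
    if (f == cfg$n_frames - 1L) break

    updated <- list()
    for (cell in cells) {
      if (!cell$alive) next
      ## death / division events for the coming interval
      if (runif(1) < p_die) {
        cell$alive <- FALSE
        deaths[[length(deaths) + 1L]] <- c(cell$id, f + 1L)
        updated[[length(updated) + 1L]] <- cell
        next
      }
      if (runif(1) < p_div) {
        ang <- runif(1, 0, 2 * pi)
        d <- new_cell(next_id, reflect(cell$x + cell$a * cos(ang), 0, W - 1),
                      reflect(cell$y + cell$a * sin(ang), 0, H - 1))
        d$a <- cell$a; d$b <- cell$b; d$imax <- cell$imax
        lineage[[length(lineage) + 1L]] <- c(cell$id, next_id)
        next_id <- next_id + 1L
        updated[[length(updated) + 1L]] <- d
      }
      ## persistent random-walk step with chemotactic drift
      cell$heading <- if (is.infinite(turn_sd)) runif(1, 0, 2 * pi)
                      else cell$heading + rnorm(1, 0, turn_sd)
      step_x <- (1 - abs(bias)) * L * cos(cell$heading) + bias * L
      step_y <- (1 - abs(bias)) * L * sin(cell$heading)
      cell$x <- reflect(cell$x + step_x, 0, W - 1)
      cell$y <- reflect(cell$y + step_y, 0, H - 1)
      updated[[length(updated) + 1L]] <- cell
    }
    cells <- updated
  }

  tr <- do.call(rbind, rows[seq_len(nrows)])
  tracks <- data.frame(cell_id = as.integer(tr[, 1]), frame = as.integer(tr[, 2]),
                       x = tr[, 3], y = tr[, 4], a = tr[, 5], b = tr[, 6],
                       theta = wrap_orientation(tr[, 7]), imax = tr[, 8])
  tracks <- tracks[order(tracks$cell_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  lin <- if (length(lineage)) do.call(rbind, lineage) else matrix(integer(0), 0, 2)
  dth <- if (length(deaths)) do.call(rbind, deaths) else matrix(integer(0), 0, 2)
  structure(list(
    tracks = tracks,
    lineage = data.frame(parent = as.integer(lin[, 1]), child = as.integer(lin[, 2])),
    death_frames = data.frame(cell_id = as.integer(dth[, 1]), frame = as.integer(dth[, 2])),
    config = cfg
  ), class = "ground_truth")
}

#' Render a synthetic fluorescence stack from ground truth
#'
#' Each cell is drawn as an anisotropic Gaussian intensity profile whose
#' quarter-maximum contour coincides with the truth ellipse (so a
#' 25%-of-peak boundary criterion recovers the truth semi-axes). Frame `t`
#' amplitudes are scaled by `2^(-t * frame_interval / bleach_halflife)`
#' (photobleaching); the whole frame is multiplied by a smooth linear
#' illumination field spanning `1 - illumination_gradient` to 1 across the
#' diagonal; Gaussian sensor noise of sd `noise_sd` is added and the result
#' clipped at zero.
#'
#' @param truth a `ground_truth` from [simulate_truth()].
#' @param config the matching [simulation_config()].
#' @return An [image_stack()] carrying the calibration metadata.
#' @export
render_stack <- function(truth, config) {
  validate_simulation_config(config)
  if (!inherits(truth, "ground_truth")) stop2("truth must be a ground_truth object")
  if (nrow(truth$tracks) > 0 && max(truth$tracks$frame) >= config$n_frames)
    stop2("truth contains frames beyond config$n_frames")
  withr::with_seed(config$seed + 1L, render_stack_impl(truth, config))
}

render_stack_impl <- function(truth, cfg) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  dt_h <- cfg$frame_interval / 60
  ## sigma such that the quarter-maximum radius equals the semi-axis
  k <- sqrt(2 * log(4))
  xs <- 0:(W - 1); ys <- 0:(H - 1)
  g <- cfg$illumination_gradient
  illum <- 1 - g * (outer(ys / max(H - 1, 1), xs / max(W - 1, 1), `+`)) / 2
  tr <- truth$tracks

  frames <- vector("list", cfg$n_frames)
  for (f in seq_len(cfg$n_frames) - 1L) {
    img <- matrix(cfg$background_level, H, W)
    sub <- tr[tr$frame == f, , drop = FALSE]
    bleach <- 2^(-f * dt_h / cfg$bleach_halflife)
    for (i in seq_len(nrow(sub))) {
      sa <- sub$a[i] / k; sb <- sub$b[i] / k
      ext <- ceiling(4 * max(sa, sb))
      cx <- sub$x[i]; cy <- sub$y[i]
      c0 <- max(0, floor(cx) - ext); c1 <- min(W - 1, ceiling(cx) + ext)
      r0 <- max(0, floor(cy) - ext); r1 <- min(H - 1, ceiling(cy) + ext)
      if (c1 < c0 || r1 < r0) next
      dx <- outer(rep(1, r1 - r0 + 1), (c0:c1) - cx)
      dy <- outer((r0:r1) - cy, rep(1, c1 - c0 + 1))
      ct <- cos(sub$theta[i]); st <- sin(sub$theta[i])
      u <- dx * ct + dy * st
      v <- -dx * st + dy * ct
      blob <- sub$imax[i] * bleach * exp(-(u^2 / (2 * sa^2) + v^2 / (2 * sb^2)))
      img[(r0:r1) + 1, (c0:c1) + 1] <- img[(r0:r1) + 1, (c0:c1) + 1] + blob
    }
    img <- img * illum
    if (cfg$noise_sd > 0)
      img <- img + matrix(rnorm(H * W, 0, cfg$noise_sd), H, W)
    frames[[f + 1L]] <- pmax(img, 0)
  }
  image_stack(frames, pixel_size = cfg$pixel_size,
              frame_interval = cfg$frame_interval, channel_name = "sim")
}

#' Convert ground-truth tracks to the tracks-table layout
#'
#' Recasts simulator ground truth into the same data.frame layout produced
#' by [build_tracks()], so the migration statistics can be computed directly
#' on noise-free truth trajectories (e.g. for validating the statistics
#' against known motion parameters).
#'
#' @param truth a `ground_truth` object.
#' @return data.frame with columns `track_id, frame, Cx, Cy, Imax, R,
#'   theta, S, AR`.
#' @export
truth_to_tracks <- function(truth) {
  if (!inherits(truth, "ground_truth")) stop2("truth must be a ground_truth object")
  tr <- truth$tracks
  data.frame(track_id = tr$cell_id, frame = tr$frame,
             Cx = tr$x, Cy = tr$y, Imax = tr$imax,
             R = sqrt(tr$a * tr$b), theta = tr$theta,
             S = 1, AR = tr$b / tr$a)
}
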