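# Shared fixtures: analytic images with known geometry, a non-saturating
# segmentation config for closed-form checks, and a truth-vs-tracks matcher.

# anisotropic Gaussian blob, 0-based center (cx, cy), semi-axis sigmas
gauss_blob <- function(H, W, cx, cy, sx, sy = sx, theta = 0, amp = 1) {
  dx <- outer(rep(1, H), (0:(W - 1)) - cx)
  dy <- outer((0:(H - 1)) - cy, rep(1, W))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  amp * exp(-(u^2 / (2 * sx^2) + v^2 / (2 * sy^2)))
}

# filled ellipse mask as a label_image (binary region)
ellipse_label <- function(H, W, cx, cy, a, b = a, theta = 0) {
  dx <- outer(rep(1, H), (0:(W - 1)) - cx)
  dy <- outer((0:(H - 1)) - cy, rep(1, W))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  label_image((u^2 / a^2 + v^2 / b^2 <= 1) * 1L, 0L)
}

# segmentation config for closed-form fixtures: effectively no saturation
# (the 1% default deliberately clips peaks, which rescales "25% of peak")
seg_config_exact <- function(...) {
  segmentation_config(saturation_fraction = 1e-5, ...)
}

# fast small simulation for pipeline tests
small_sim_config <- function(seed, n_frames = 5, n_cells = 8, size = 256, ...) {
  simulation_config(image_size = c(size, size), n_frames = n_frames,
                    n_cells_init = n_cells, division_rate = 0, death_rate = 0,
                    seed = seed, ...)
}

# build per-frame feature tables from a rendered stack
stack_features <- function(stack, sc) {
  labs <- segment_stack(stack, sc)
  lapply(seq_along(labs), function(i)
    featurize_frame(labs[[i]], mptrack:::preprocess_frame(stack$frames[[i]], sc)))
}

# fraction of consecutive-frame links in `tracks` that agree with ground
# truth (detections matched to truth cells by nearest centroid <= tol px)
link_recovery <- function(tracks, truth, tol = 3) {
  tt <- truth$tracks
  mm <- do.call(rbind, lapply(sort(unique(tracks$frame)), function(fr) {
    d <- tracks[tracks$frame == fr, ]
    g <- tt[tt$frame == fr, ]
    if (!nrow(d) || !nrow(g)) return(NULL)
    cell <- vapply(seq_len(nrow(d)), function(i) {
      dist <- sqrt((g$x - d$Cx[i])^2 + (g$y - d$Cy[i])^2)
      j <- which.min(dist)
      if (dist[j] <= tol) g$cell_id[j] else NA_integer_
    }, numeric(1))
    data.frame(track_id = d$track_id, frame = fr, cell = cell)
  }))
  mm <- mm[order(mm$track_id, mm$frame), ]
  n <- nrow(mm)
  same <- mm$track_id[-1] == mm$track_id[-n] & mm$frame[-1] == mm$frame[-n] + 1
  agree <- mm$cell[-1][same] == mm$cell[-n][same]
  mean(agree, na.rm = FALSE)
}

# brute-force maximum-cardinality minimum-cost partial assignment by
# recursive enumeration; oracle for link_frames(optimal)
brute_force_assignment <- function(cost, allowed) {
  n <- nrow(cost); m <- ncol(cost)
  best <- list(card = -1L, cost = Inf)
  recurse <- function(i, used, card, total) {
    if (i > n) {
      if (card > best$card || (card == best$card && total < best$cost - 1e-12))
        best <<- list(card = card, cost = total)
      return(invisible())
    }
    # prune: even matching all remaining rows cannot beat best cardinality
    if (card + (n - i + 1L) < best$card) return(invisible())
    for (j in seq_len(m)) {
      if (allowed[i, j] && !used[j]) {
        used[j] <- TRUE
        recurse(i + 1L, used, card + 1L, total + cost[i, j])
        used[j] <- FALSE
      }
    }
    recurse(i + 1L, used, card, total)
    invisible()
  }
  recurse(1L, logical(m), 0L, 0)
  best
}

# random walk tracks table: n_tracks independent tracks of n_steps unit-free
# steps (step length `len`), optional drift
random_tracks <- function(n_tracks, n_steps, len = 1, drift = c(0, 0)) {
  do.call(rbind, lapply(seq_len(n_tracks), function(id) {
    ang <- runif(n_steps, 0, 2 * pi)
    dx <- len * cos(ang) + drift[1]
    dy <- len * sin(ang) + drift[2]
    data.frame(track_id = id, frame = 0:n_steps,
               Cx = cumsum(c(runif(1, 0, 100), dx)),
               Cy = cumsum(c(runif(1, 0, 100), dy)))
  }))
}
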