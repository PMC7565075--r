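#' Tracking configuration
#'
#' Weights and gates of the multi-parametric frame-to-frame linker. The
#' link cost between two cells is the weighted deviation of their feature
#' vectors: `w_xyz` scales the Euclidean centroid distance (pixels) and
#' `w_m` scales the deviations of the five non-spatial features
#' `(Imax, R, theta, S, AR)`, each normalized by a robust per-feature
#' scale (median absolute deviation over the current frame pair) so the
#' weights are comparable across units.
#'
#' @param w_xyz weight of the spatial (centroid-distance) term.
#' @param w_m named numeric vector of weights for
#'   `c(Imax, R, theta, S, AR)`.
#' @param max_link_distance spatial gate, pixels: pairs further apart are
#'   never linked.
#' @param max_gap_frames number of consecutive missed frames a track may
#'   bridge; the spatial gate is scaled by the elapsed frame gap.
#' @param assignment_mode `"optimal"` (global minimum-cost matching) or
#'   `"greedy"` (ascending-cost acceptance).
#' @return A `tracking_config` list.
#' @export
tracking_config <- function(w_xyz = 1,
                            w_m = c(Imax = 1, R = 1, theta = 1, S = 1, AR = 1),
                            max_link_distance = 20,
                            max_gap_frames = 0L,
                            assignment_mode = c("optimal", "greedy")) {
  assignment_mode <- match.arg(assignment_mode)
  if (length(w_m) != 5L) stop2("w_m must have 5 entries (Imax, R, theta, S, AR)")
  if (is.null(names(w_m)) || !all(names(w_m) == c("Imax", "R", "theta", "S", "AR")))
    names(w_m) <- c("Imax", "R", "theta", "S", "AR")
  if (w_xyz < 0 || any(w_m < 0)) stop2("weights must be >= 0")
  if (w_xyz == 0 && all(w_m == 0)) stop2("at least one weight must be > 0")
  if (max_link_distance <= 0) stop2("max_link_distance must be > 0")
  if (max_gap_frames < 0) stop2("max_gap_frames must be >= 0")
  structure(list(w_xyz = w_xyz, w_m = w_m,
                 max_link_distance = max_link_distance,
                 max_gap_frames = as.integer(max_gap_frames),
                 assignment_mode = assignment_mode),
            class = "tracking_config")
}

FEATURE_COLS <- c("Imax", "R", "theta", "S", "AR")

#' Robust per-feature scales for a frame pair
#'
#' Median absolute deviation (scaled for normal consistency) of each
#' non-spatial feature over the pooled cells of the two frames being
#' linked; features with zero spread get scale 1 so they contribute the
#' raw absolute deviation.
#'
#' @param a,b feature data.frames of the two frames.
#' @return named numeric vector of scales for `(Imax, R, theta, S, AR)`.
#' @export
feature_scales <- function(a, b) {
  vapply(FEATURE_COLS, function(col) {
    s <- stats::mad(c(a[[col]], b[[col]]))
    if (!is.finite(s) || s < 1e-9) 1 else s
  }, numeric(1))
}

#' Weighted feature-deviation cost between two cells
#'
#' `cost = w_xyz * ||(Cx,Cy)_a - (Cx,Cy)_b|| + sum_m w_m * |delta_m| / s_m`
#' where the orientation deviation uses the wrapped angular distance with
#' period pi (so +89 deg and -89 deg differ by 2 deg, not 178 deg) and
#' `s_m` are the per-feature scales. Zero for identical vectors.
#'
#' @param a,b one-row feature data.frames (or named lists) with fields
#'   `Cx, Cy, Imax, R, theta, S, AR`.
#' @param config a [tracking_config()].
#' @param scales per-feature scales, default all 1 (see
#'   [feature_scales()]).
#' @return non-negative scalar cost.
#' @export
pairwise_cost <- function(a, b, config = tracking_config(),
                          scales = stats::setNames(rep(1, 5), FEATURE_COLS)) {
  spatial <- sqrt((a$Cx - b$Cx)^2 + (a$Cy - b$Cy)^2)
  dev <- c(Imax = abs(a$Imax - b$Imax),
           R = abs(a$R - b$R),
           theta = angle_diff_pi(a$theta, b$theta),
           S = abs(a$S - b$S),
           AR = abs(a$AR - b$AR))
  config$w_xyz * spatial + sum(config$w_m * dev / scales[FEATURE_COLS])
}

## Vectorized n x m cost and spatial-distance matrices for two frames.
cost_matrices <- function(a, b, config, scales = NULL) {
  if (is.null(scales)) scales <- feature_scales(a, b)
  dx <- outer(a$Cx, b$Cx, `-`); dy <- outer(a$Cy, b$Cy, `-`)
  dist <- sqrt(dx^2 + dy^2)
  cost <- config$w_xyz * dist
  for (col in FEATURE_COLS) {
    d <- if (col == "theta") outer(a$theta, b$theta, angle_diff_pi)
         else abs(outer(a[[col]], b[[col]], `-`))
    cost <- cost + config$w_m[[col]] * d / scales[[col]]
  }
  list(cost = cost, dist = dist)
}

#' Link the cells of two frames
#'
#' One-to-one partial assignment between the cells of consecutive frames
#' minimizing the total weighted feature deviation. Pairs whose centroid
#' distance exceeds the gate are forbidden. In `"optimal"` mode the
#' maximum number of admissible links is matched at globally minimal total
#' cost (Hungarian algorithm on a matrix padded with unmatched
#' alternatives); `"greedy"` mode accepts admissible pairs in ascending
#' cost order.
#'
#' @param cells_t,cells_t1 feature data.frames of frames t and t+1.
#' @param config a [tracking_config()].
#' @param gate spatial gate; a scalar, or a vector of per-row gates (one
#'   per cell of `cells_t`, used for gap-scaled linking). Defaults to
#'   `config$max_link_distance`.
#' @return list with `matches` (data.frame `i`, `j`, `cost`: row indices
#'   into `cells_t` and `cells_t1`), `unmatched_t`, `unmatched_t1`.
#' @export
link_frames <- function(cells_t, cells_t1, config = tracking_config(),
                        gate = config$max_link_distance) {
  n <- nrow(cells_t); m <- nrow(cells_t1)
  empty <- data.frame(i = integer(0), j = integer(0), cost = numeric(0))
  if (n == 0L || m == 0L)
    return(list(matches = empty, unmatched_t = seq_len(n), unmatched_t1 = seq_len(m)))
  cm <- cost_matrices(cells_t, cells_t1, config)
  allowed <- cm$dist <= gate   # vector gates recycle along rows
  cost <- cm$cost
  if (!any(allowed))
    return(list(matches = empty, unmatched_t = seq_len(n), unmatched_t1 = seq_len(m)))

  if (config$assignment_mode == "optimal") {
    pairs <- solve_assignment(cost, allowed)
  } else {
    idx <- which(allowed)
    ii <- (idx - 1L) %% n + 1L; jj <- (idx - 1L) %/% n + 1L
    ord <- order(cost[idx], ii, jj)   # ties: smaller row (older track) first
    used_i <- logical(n); used_j <- logical(m)
    pi_ <- integer(0); pj <- integer(0)
    for (r in ord) {
      i <- ii[r]; j <- jj[r]
      if (!used_i[i] && !used_j[j]) {
        used_i[i] <- TRUE; used_j[j] <- TRUE
        pi_ <- c(pi_, i); pj <- c(pj, j)
      }
    }
    pairs <- cbind(pi_, pj)
  }
  matches <- data.frame(i = pairs[, 1], j = pairs[, 2],
                        cost = cost[pairs])
  matches <- matches[order(matches$i), , drop = FALSE]
  rownames(matches) <- NULL
  list(matches = matches,
       unmatched_t = setdiff(seq_len(n), matches$i),
       unmatched_t1 = setdiff(seq_len(m), matches$j))
}

## Maximum-cardinality minimum-cost partial assignment via a padded
## Hungarian solve: dummy columns/rows charge a fixed unmatch cost large
## enough that any admissible link is preferred, and forbidden pairs cost
## more than any complete alternative.
solve_assignment <- function(cost, allowed) {
  n <- nrow(cost); m <- ncol(cost)
  finite_max <- max(cost[allowed], 0)
  UNMATCH <- (finite_max + 1) * (n + m + 1)
  BIG <- UNMATCH * (n + m + 1)
  C <- matrix(BIG, n + m, n + m)
  C[seq_len(n), seq_len(m)] <- ifelse(allowed, cost, BIG)
  for (i in seq_len(n)) C[i, m + i] <- UNMATCH
  for (j in seq_len(m)) C[n + j, j] <- UNMATCH
  C[n + seq_len(m), m + seq_len(n)] <- 0
  sol <- clue::solve_LSAP(C)
  i <- seq_len(n)
  j <- as.integer(sol)[i]
  keep <- j <= m
  keep[keep] <- allowed[cbind(i[keep], j[keep])]
  cbind(i[keep], j[keep])
}

#' Build tracks across a stack
#'
#' Sequentially links per-frame feature tables into tracks. A track whose
#' cell goes undetected may bridge up to `max_gap_frames` missed frames:
#' its last detection keeps competing in later frames with the spatial
#' gate scaled by the elapsed gap. Every detection belongs to exactly one
#' track; unmatched detections start new tracks.
#'
#' @param per_frame_cells list of feature data.frames (as from
#'   [featurize_frame()]), ordered by frame; each must carry a consistent
#'   `frame_index`.
#' @param config a [tracking_config()].
#' @return data.frame with one row per detection: `track_id, frame, Cx,
#'   Cy, Imax, R, theta, S, AR` (plus any further feature columns),
#'   ordered by track then frame.
#' @export
build_tracks <- function(per_frame_cells, config = tracking_config()) {
  if (length(per_frame_cells) == 0L) stop2("no frames supplied")
  frames_idx <- vapply(per_frame_cells, function(d)
    if (nrow(d)) d$frame_index[1] else NA_integer_, numeric(1))
  frames_idx[is.na(frames_idx)] <- seq_along(per_frame_cells)[is.na(frames_idx)] - 1
  ## active tracks: last feature row, last frame, id
  active <- list()
  next_id <- 1L
  out <- vector("list", length(per_frame_cells))

  start_tracks <- function(det, f) {
    ids <- integer(nrow(det))
    for (r in seq_len(nrow(det))) {
      ids[r] <- next_id
      active[[length(active) + 1L]] <<- list(id = next_id, last_frame = f,
                                             feat = det[r, , drop = FALSE])
      next_id <<- next_id + 1L
    }
    ids
  }

  for (fi in seq_along(per_frame_cells)) {
    det <- per_frame_cells[[fi]]
    f <- frames_idx[fi]
    track_of <- integer(nrow(det))
    if (length(active)) {
      ## candidates ordered by track id for deterministic tie-breaking
      ord <- order(vapply(active, `[[`, integer(1), "id"))
      active <- active[ord]
      gaps <- vapply(active, function(a) f - a$last_frame, numeric(1))
      ok <- gaps >= 1 & gaps <= config$max_gap_frames + 1
      active <- active[ok]
      if (length(active) && nrow(det)) {
        prev <- do.call(rbind, lapply(active, `[[`, "feat"))
        gaps <- gaps[ok]
        res <- link_frames(prev, det, config,
                           gate = config$max_link_distance * gaps)
        mt <- res$matches
        for (r in seq_len(nrow(mt))) {
          a <- active[[mt$i[r]]]
          track_of[mt$j[r]] <- a$id
          active[[mt$i[r]]]$last_frame <- f
          active[[mt$i[r]]]$feat <- det[mt$j[r], , drop = FALSE]
        }
      }
    }
    new_rows <- which(track_of == 0L)
    if (length(new_rows))
      track_of[new_rows] <- start_tracks(det[new_rows, , drop = FALSE], f)
    if (nrow(det)) {
      det$track_id <- track_of
      det$frame <- f
      out[[fi]] <- det
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) stop2("no detections in any frame")
  keep_cols <- c("track_id", "frame",
                 setdiff(names(res), c("track_id", "frame", "frame_index", "label")))
  res <- res[order(res$track_id, res$frame), keep_cols, drop = FALSE]
  rownames(res) <- NULL
  res
}
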