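#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
NULL

## Shift a matrix by (dr, dc), padding with `fill`. Used by the morphological
## and edge-detection helpers below.
shift_mat <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  r0 <- max(1, 1 + dr); r1 <- min(h, h + dr)
  c0 <- max(1, 1 + dc); c1 <- min(w, w + dc)
  if (r0 > r1 || c0 > c1) return(out)
  rs <- r0:r1; cs <- c0:c1
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

## Grayscale 3x3 maximum filter (8-neighborhood plus center; conn = 4 for
## the von Neumann neighborhood).
maxfilter3 <- function(m, fill = -Inf, conn = 8L) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    if (conn == 4L && dr != 0L && dc != 0L) next
    out <- pmax(out, shift_mat(m, dr, dc, fill = fill))
  }
  out
}

## Connected-component labeling of a logical matrix by iterative label
## propagation (default 8-connectivity; 4-connectivity is used where
## growth must not cross thin 8-connected barrier lines). Returns an
## integer matrix, 0 = background, components numbered 1..K in raster
## (column-major) order of their first pixel.
label_components <- function(mask, conn = 8L) {
  mask <- mask & !is.na(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (!any(mask)) return(lab)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    nb <- maxfilter3(lab, fill = 0L, conn = conn)
    upd <- mask & nb > lab
    if (!any(upd)) break
    lab[upd] <- nb[upd]
  }
  ## relabel consecutively in order of first occurrence (column-major)
  ids <- unique(lab[lab > 0L])
  lab[] <- match(lab, c(0L, ids)) - 1L
  lab
}

## Shoelace area of a polygon given vertex coordinates.
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

## Wrapped angular distance for orientations with period pi.
angle_diff_pi <- function(a, b) {
  d <- abs(a - b) %% pi
  pmin(d, pi - d)
}

## Wrap an orientation angle to [-pi/2, pi/2).
wrap_orientation <- function(theta) {
  th <- (theta + pi / 2) %% pi - pi / 2
  th[th >= pi / 2] <- -pi / 2
  th
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop2 <- function(...) stop(..., call. = FALSE)
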