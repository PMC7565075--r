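#' Canny edge detection
#'
#' Classic Canny chain: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the quantized gradient direction, and hysteresis
#' thresholding. The hysteresis thresholds are specified as quantiles of
#' the non-zero gradient magnitude so the detector adapts to the frame's
#' contrast.
#'
#' @param frame numeric intensity matrix.
#' @param sigma Gaussian smoothing scale, pixels.
#' @param low_quantile,high_quantile hysteresis thresholds as quantiles of
#'   the positive gradient magnitudes; weak edges (above low) are kept only
#'   when 8-connected to a strong edge (above high).
#' @param min_gradient absolute floor (intensity change per pixel) for the
#'   strong threshold; the weak threshold is floored at half of it. Keeps
#'   the sensor-noise gradient floor from flooding the edge map in frames
#'   whose quantiles sit below it.
#' @return logical matrix, `TRUE` on edge pixels, with attribute
#'   `"magnitude"`: the non-maximum-suppressed gradient magnitude
#'   (intensity change per pixel), used downstream to judge how sharp each
#'   edge chain is.
#' @export
canny_edges <- function(frame, sigma = 1, low_quantile = 0.80, high_quantile = 0.95,
                        min_gradient = 0.05) {
  if (sigma <= 0) stop2("sigma must be > 0")
  sm <- gaussian_blur(frame, sigma)
  ## Sobel gradients (x = columns, y = rows)
  gx <- (shift_edge(sm, 0, -1) - shift_edge(sm, 0, 1)) * 2 +
    (shift_edge(sm, -1, -1) - shift_edge(sm, -1, 1)) +
    (shift_edge(sm, 1, -1) - shift_edge(sm, 1, 1))
  gy <- (shift_edge(sm, -1, 0) - shift_edge(sm, 1, 0)) * 2 +
    (shift_edge(sm, -1, -1) - shift_edge(sm, 1, -1)) +
    (shift_edge(sm, -1, 1) - shift_edge(sm, 1, 1))
  mag <- sqrt(gx^2 + gy^2) / 8   # ~ intensity change per pixel
  pos <- mag[mag > 0]
  if (length(pos) == 0) return(matrix(FALSE, nrow(frame), ncol(frame)))
  lo <- max(stats::quantile(pos, low_quantile, names = FALSE), min_gradient / 2)
  hi <- max(stats::quantile(pos, high_quantile, names = FALSE), min_gradient)

  ## non-maximum suppression: direction quantized to 4 sectors
  ang <- atan2(gy, gx) %% pi
  sector <- (floor(ang / (pi / 4) + 0.5)) %% 4   # 0=E/W,1=NE/SW,2=N/S,3=NW/SE
  n1 <- mag; n2 <- mag
  pick <- function(dr, dc) shift_mat(mag, dr, dc, fill = 0)
  cand <- list(list(pick(0, 1), pick(0, -1)),    # horizontal gradient
               list(pick(1, 1), pick(-1, -1)),   # diagonal
               list(pick(1, 0), pick(-1, 0)),    # vertical gradient
               list(pick(1, -1), pick(-1, 1)))   # anti-diagonal
  for (s in 0:3) {
    sel <- sector == s
    n1[sel] <- cand[[s + 1]][[1]][sel]
    n2[sel] <- cand[[s + 1]][[2]][sel]
  }
  nms <- mag >= n1 & mag >= n2 & mag > 0

  strong <- nms & mag >= hi
  weak <- nms & mag >= lo
  if (!any(strong)) {
    out <- matrix(FALSE, nrow(frame), ncol(frame))
    attr(out, "magnitude") <- matrix(0, nrow(frame), ncol(frame))
    return(out)
  }
  ## hysteresis: keep weak components containing a strong pixel
  lab <- label_components(weak)
  keep <- unique(lab[strong & lab > 0L])
  out <- lab > 0L & lab %in% keep
  dim(out) <- dim(frame)
  attr(out, "magnitude") <- ifelse(out, mag, 0)
  out
}
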