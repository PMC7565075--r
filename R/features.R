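#' Extract segmented cells from a label image
#'
#' Collects, for every label, the pixel set (0-based coordinates, x =
#' column, y = row), the pixel area, the convex-hull area, and whether the
#' region touches the image border. The hull is the convex hull of the
#' pixel corner points (each pixel treated as a unit square), so the hull
#' area of a convex pixel region equals its pixel count and solidity is
#' always <= 1.
#'
#' @param labels a [label_image()].
#' @return list of `segmented_cell` objects with fields `frame_index`,
#'   `label`, `pixels` (two-column matrix `x`, `y`), `area`, `hull_area`,
#'   `touches_border`.
#' @export
extract_cells <- function(labels) {
  if (!inherits(labels, "label_image")) stop2("labels must be a label_image")
  lab <- labels$labels
  n <- max(lab)
  H <- nrow(lab); W <- ncol(lab)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    idx <- which(lab == k, arr.ind = TRUE)
    x <- idx[, 2] - 1; y <- idx[, 1] - 1
    out[[k]] <- structure(list(
      frame_index = labels$frame_index, label = k,
      pixels = cbind(x = x, y = y),
      area = nrow(idx),
      hull_area = pixel_hull_area(x, y),
      touches_border = any(idx[, 1] == 1L | idx[, 1] == H |
                             idx[, 2] == 1L | idx[, 2] == W)
    ), class = "segmented_cell")
  }
  out
}

## convex hull area of the union of unit squares' corners
pixel_hull_area <- function(x, y) {
  px <- c(x - 0.5, x + 0.5, x - 0.5, x + 0.5)
  py <- c(y - 0.5, y - 0.5, y + 0.5, y + 0.5)
  h <- grDevices::chull(px, py)
  polygon_area(px[h], py[h])
}

#' Equivalent ellipse of a pixel region
#'
#' The ellipse with the same second central moments as the (unweighted)
#' pixel set: `Ra`/`Rb` are the major/minor semi-axes and `theta` the
#' major-axis orientation with respect to the positive x-direction,
#' wrapped to `[-pi/2, pi/2)`. A single-pixel (or collinear-degenerate)
#' region gets the defined minimum semi-axis of 0.5 pix.
#'
#' @param cell a `segmented_cell` from [extract_cells()].
#' @return named numeric vector `(Ra, Rb, theta)`.
#' @export
equivalent_ellipse <- function(cell) {
  p <- cell$pixels
  if (nrow(p) == 0L) stop2("empty pixel set")
  x <- p[, 1]; y <- p[, 2]
  mu20 <- mean((x - mean(x))^2)
  mu02 <- mean((y - mean(y))^2)
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  disc <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + disc
  l2 <- (mu20 + mu02) / 2 - disc
  Ra <- max(2 * sqrt(max(l1, 0)), 0.5)
  Rb <- max(2 * sqrt(max(l2, 0)), 0.5)
  theta <- if (disc < 1e-12) 0 else wrap_orientation(0.5 * atan2(2 * mu11, mu20 - mu02))
  c(Ra = Ra, Rb = Rb, theta = theta)
}

#' Aspect ratio of the equivalent ellipse
#'
#' `AR = Rb / Ra`, in `(0, 1]`; 1 for a circle.
#'
#' @param Ra,Rb major and minor semi-axes (`Ra >= Rb > 0`).
#' @return aspect ratio.
#' @export
aspect_ratio <- function(Ra, Rb) {
  if (any(Ra <= 0) || any(Rb <= 0)) stop2("semi-axes must be > 0")
  if (any(Rb > Ra + 1e-9)) stop2("Ra must be the major semi-axis (Ra >= Rb)")
  Rb / Ra
}

#' Solidity of a region
#'
#' `S = A_cell / A_CH`: pixel area over convex-hull area, in `(0, 1]`;
#' 1 for convex regions.
#'
#' @param cell a `segmented_cell`.
#' @return solidity.
#' @export
solidity <- function(cell) {
  if (cell$hull_area <= 0) stop2("degenerate hull area")
  min(cell$area / cell$hull_area, 1)
}

#' Equivalent radius
#'
#' Radius of the circle with the region's area: `R = sqrt(A_cell / pi)`.
#'
#' @param area region area, pix^2 (> 0).
#' @return equivalent radius, pix.
#' @export
equivalent_radius <- function(area) {
  if (any(area <= 0)) stop2("area must be > 0")
  sqrt(area / pi)
}

#' Intensity-weighted centroid
#'
#' `C = sum(I * p) / sum(I)` over the region's pixels. If the region's
#' intensities are all zero the geometric centroid is returned with
#' attribute `fallback = TRUE`.
#'
#' @param cell a `segmented_cell`.
#' @param frame full-resolution intensity matrix.
#' @return named numeric vector `(Cx, Cy)` in 0-based pixel coordinates.
#' @export
weighted_centroid <- function(cell, frame) {
  p <- cell$pixels
  I <- frame[cbind(p[, 2] + 1L, p[, 1] + 1L)]
  tot <- sum(I)
  if (tot <= 0) {
    out <- c(Cx = mean(p[, 1]), Cy = mean(p[, 2]))
    attr(out, "fallback") <- TRUE
    return(out)
  }
  c(Cx = sum(I * p[, 1]) / tot, Cy = sum(I * p[, 2]) / tot)
}

#' Assemble the multi-parametric feature vector of a cell
#'
#' The tracking descriptor `(Cx, Cy, Imax, R, theta, S, AR)`: the
#' intensity-weighted centroid, peak intensity inside the region, the
#' equivalent radius, and the equivalent-ellipse orientation, solidity and
#' aspect ratio (plus the ellipse semi-axes `Ra`, `Rb`).
#'
#' @param cell a `segmented_cell`.
#' @param frame intensity matrix the cell was segmented from.
#' @return one-row data.frame with columns `frame_index, label, Cx, Cy,
#'   Imax, R, theta, S, AR, Ra, Rb, touches_border`.
#' @export
featurize <- function(cell, frame) {
  ell <- equivalent_ellipse(cell)
  ctr <- weighted_centroid(cell, frame)
  p <- cell$pixels
  data.frame(frame_index = cell$frame_index, label = cell$label,
             Cx = unname(ctr["Cx"]), Cy = unname(ctr["Cy"]),
             Imax = max(frame[cbind(p[, 2] + 1L, p[, 1] + 1L)]),
             R = equivalent_radius(cell$area),
             theta = unname(ell["theta"]),
             S = solidity(cell),
             AR = aspect_ratio(ell["Ra"], ell["Rb"]),
             Ra = unname(ell["Ra"]), Rb = unname(ell["Rb"]),
             touches_border = cell$touches_border)
}

#' Feature vectors for every cell of a frame
#'
#' @param labels a [label_image()].
#' @param frame the intensity matrix the labels were derived from.
#' @return data.frame with one row per cell (possibly zero rows), the
#'   columns of [featurize()].
#' @export
featurize_frame <- function(labels, frame) {
  cells <- extract_cells(labels)
  if (length(cells) == 0L)
    return(data.frame(frame_index = integer(0), label = integer(0),
                      Cx = numeric(0), Cy = numeric(0), Imax = numeric(0),
                      R = numeric(0), theta = numeric(0), S = numeric(0),
                      AR = numeric(0), Ra = numeric(0), Rb = numeric(0),
                      touches_border = logical(0)))
  do.call(rbind, lapply(cells, featurize, frame = frame))
}
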