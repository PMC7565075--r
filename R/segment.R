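#' Segmentation configuration
#'
#' Parameters of the segmentation chain: background subtraction, saturating
#' linear intensity adjustment, block downsampling, Hessian-eigenmap blob
#' detection, adaptive peak splitting, marker-seeded region growing, and
#' full-resolution boundary refinement.
#'
#' @param saturation_fraction fraction of pixels saturated by the linear
#'   intensity adjustment (split equally between the low and high tail).
#' @param downsample_factor block size of the averaging downsample; 5 means
#'   each coarse pixel is the mean of a 5 x 5 neighborhood.
#' @param hessian_scale Gaussian smoothing scale (pixels, on the
#'   downsampled grid) applied before computing the intensity Hessian.
#' @param refine_stop_fraction boundary refinement stops where intensity
#'   falls below this fraction of the cell's peak intensity (default 0.25).
#' @param canny_low,canny_high hysteresis thresholds of the Canny edge
#'   detector, expressed as quantiles of the non-zero gradient magnitude.
#' @param canny_sigma Gaussian scale of the Canny detector, pixels.
#' @param edge_stop_fraction an edge chain stops a cell's boundary growth
#'   only when its peak gradient reaches this fraction of the cell's peak
#'   intensity (per pixel). Separates genuinely sharp boundaries from the
#'   smooth flanks of diffuse fluorescent blobs, whose per-pixel gradient
#'   is necessarily small relative to their amplitude.
#' @param background_radius radius (pixels) of the disc structuring element
#'   of the morphological-opening background estimate; should exceed the
#'   largest cell radius by a comfortable margin (default ~4x).
#' @param min_cell_area,max_cell_area area limits (pix^2) for accepted
#'   cells on the full-resolution grid.
#' @param h_fraction adaptive prominence threshold of the peak-splitting
#'   step, as a fraction of each candidate component's intensity range:
#'   two touching cells are split only if the saddle between their peaks is
#'   deeper than `h_fraction * (component max - component min)`.
#' @param support_threshold intensity (on the adjusted `[0, 1]` scale)
#'   above which coarse pixels count as above-background during
#'   marker-seeded growing.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(saturation_fraction = 0.01,
                                downsample_factor = 5L,
                                hessian_scale = 1,
                                refine_stop_fraction = 0.25,
                                canny_low = 0.80,
                                canny_high = 0.95,
                                canny_sigma = 1,
                                edge_stop_fraction = 0.2,
                                background_radius = 40L,
                                min_cell_area = 20,
                                max_cell_area = 5000,
                                h_fraction = 0.1,
                                support_threshold = 0.1) {
  cfg <- list(saturation_fraction = saturation_fraction,
              downsample_factor = as.integer(downsample_factor),
              hessian_scale = hessian_scale,
              refine_stop_fraction = refine_stop_fraction,
              canny_low = canny_low, canny_high = canny_high,
              canny_sigma = canny_sigma, edge_stop_fraction = edge_stop_fraction,
              background_radius = as.integer(background_radius),
              min_cell_area = min_cell_area, max_cell_area = max_cell_area,
              h_fraction = h_fraction, support_threshold = support_threshold)
  class(cfg) <- "segmentation_config"
  validate_segmentation_config(cfg)
  cfg
}

validate_segmentation_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop2("invalid segmentation config: ", msg)
  chk(cfg$saturation_fraction > 0 && cfg$saturation_fraction < 1,
      "saturation_fraction must lie in (0, 1)")
  chk(cfg$downsample_factor >= 1L, "downsample_factor must be >= 1")
  chk(cfg$hessian_scale > 0, "hessian_scale must be > 0")
  chk(cfg$refine_stop_fraction > 0 && cfg$refine_stop_fraction < 1,
      "refine_stop_fraction must lie in (0, 1)")
  chk(cfg$canny_low > 0 && cfg$canny_low < 1 && cfg$canny_high > cfg$canny_low &&
        cfg$canny_high < 1, "canny quantiles must satisfy 0 < low < high < 1")
  chk(cfg$edge_stop_fraction > 0, "edge_stop_fraction must be > 0")
  chk(cfg$background_radius > 0L, "background_radius must be > 0")
  chk(cfg$min_cell_area >= 0 && cfg$max_cell_area >= cfg$min_cell_area,
      "cell area limits invalid")
  chk(cfg$h_fraction > 0 && cfg$h_fraction < 1, "h_fraction must lie in (0, 1)")
  invisible(cfg)
}

#' Label image container
#'
#' @param labels integer matrix; 0 = background, k > 0 = pixels of cell k.
#'   Labels are consecutive positive integers starting at 1.
#' @param frame_index 0-based frame index the labels belong to.
#' @return A `label_image` object.
#' @export
label_image <- function(labels, frame_index = 0L) {
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, frame_index = as.integer(frame_index)),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("label_image: frame %d, %d x %d, %d cells\n", x$frame_index,
              nrow(x$labels), ncol(x$labels), max(x$labels)))
  invisible(x)
}

#' Background subtraction
#'
#' Estimates a smooth background by grayscale morphological opening with a
#' disc of radius `background_radius` and subtracts it, clipping at zero.
#' The opening is computed on a lightly smoothed copy of the frame (as in
#' rolling-ball implementations) so the estimate follows the local mean of
#' the sensor noise rather than its lower envelope, and the frame is
#' replicate-padded so borders are not underestimated. Removes uneven
#' illumination and any additive offset: adding a constant to the frame
#' does not change the result.
#'
#' @param frame numeric intensity matrix.
#' @param config a [segmentation_config()].
#' @return background-subtracted frame of the same shape.
#' @export
subtract_background <- function(frame, config = segmentation_config()) {
  if (!all(is.finite(frame)) || any(frame < 0))
    stop2("frame must be finite and non-negative")
  if (config$background_radius <= 0L) stop2("background_radius must be > 0")
  r <- config$background_radius
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  H <- nrow(frame); W <- ncol(frame)
  ri <- c(rep(1L, r), seq_len(H), rep(H, r))
  ci <- c(rep(1L, r), seq_len(W), rep(W, r))
  padded <- gaussian_blur(frame, 2)[ri, ci, drop = FALSE]
  ## EBImage grayscale morphology operates on [0, 1]: rescale around it
  mx <- max(padded)
  if (mx <= 0) return(frame)
  bg <- EBImage::opening(padded / mx, brush)[r + seq_len(H), r + seq_len(W),
                                             drop = FALSE] * mx
  pmax(frame - bg, 0)
}

#' Saturating linear intensity adjustment
#'
#' Linearly maps intensities onto `[0, 1]` such that `saturation_fraction`
#' of the pixels saturate, half at each tail: the low and high quantiles at
#' `saturation_fraction / 2` and `1 - saturation_fraction / 2` map to 0 and
#' 1 and values beyond are clipped. Applied frame-wise, this normalizes
#' away temporal fluorescence decay (photobleaching): the output is
#' invariant to positive affine rescaling of the input.
#'
#' @param frame numeric intensity matrix (non-constant).
#' @param saturation_fraction total fraction of saturated pixels.
#' @return adjusted frame with values in `[0, 1]`.
#' @export
adjust_intensity <- function(frame, saturation_fraction = 0.01) {
  if (saturation_fraction <= 0 || saturation_fraction >= 1)
    stop2("saturation_fraction must lie in (0, 1)")
  q <- stats::quantile(frame, c(saturation_fraction / 2, 1 - saturation_fraction / 2),
                       names = FALSE, type = 7)
  if (q[2] <= q[1]) stop2("cannot adjust a (near-)constant frame")
  pmin(pmax((frame - q[1]) / (q[2] - q[1]), 0), 1)
}

#' Block-average downsampling
#'
#' Replaces each non-overlapping `factor` x `factor` block by its mean
#' intensity; trailing partial blocks are averaged over the available
#' pixels. Averaging before blob detection suppresses intracellular signal
#' heterogeneity that would otherwise cause over-segmentation.
#'
#' @param frame numeric matrix.
#' @param factor integer block size (>= 1).
#' @return downsampled matrix of shape `ceiling(dim(frame) / factor)`.
#' @export
downsample <- function(frame, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop2("factor must be >= 1")
  if (factor > nrow(frame) || factor > ncol(frame))
    stop2("factor exceeds image dimensions")
  if (factor == 1L) return(frame)
  rg <- (seq_len(nrow(frame)) - 1L) %/% factor
  cg <- (seq_len(ncol(frame)) - 1L) %/% factor
  sums <- t(rowsum(t(rowsum(frame, rg)), cg))
  dimnames(sums) <- NULL
  cnt <- outer(tabulate(rg + 1L), tabulate(cg + 1L))
  sums / cnt
}

#' Hessian-eigenmap blob candidates
#'
#' Smooths the frame with a Gaussian of scale `hessian_scale`, computes the
#' per-pixel 2x2 intensity Hessian by central differences, and marks pixels
#' where the dominant eigenvalue (largest in magnitude, the Frangi
#' vesselness ordering `|lambda1| <= |lambda2|`) is negative — i.e. bright
#' blob- or tube-like structures on a darker background.
#'
#' @param frame numeric matrix (typically downsampled and adjusted).
#' @param hessian_scale Gaussian derivative scale, pixels.
#' @return logical matrix, `TRUE` on candidate cell pixels.
#' @export
hessian_candidates <- function(frame, hessian_scale = 1) {
  if (hessian_scale <= 0) stop2("hessian_scale must be > 0")
  sm <- gaussian_blur(frame, hessian_scale)
  ## central second differences; replicate-padded borders
  sxp <- shift_edge(sm, 0, -1); sxm <- shift_edge(sm, 0, 1)
  syp <- shift_edge(sm, -1, 0); sym <- shift_edge(sm, 1, 0)
  fxx <- sxp + sxm - 2 * sm
  fyy <- syp + sym - 2 * sm
  fxy <- (shift_edge(sm, -1, -1) + shift_edge(sm, 1, 1) -
            shift_edge(sm, -1, 1) - shift_edge(sm, 1, -1)) / 4
  tr2 <- (fxx + fyy) / 2
  disc <- sqrt(((fxx - fyy) / 2)^2 + fxy^2)
  e1 <- tr2 + disc
  e2 <- tr2 - disc
  ## lambda2 = eigenvalue of larger magnitude
  lam2 <- ifelse(abs(e1) >= abs(e2), e1, e2)
  lam2 < 0
}

## Gaussian smoothing via separable convolution with replicate padding
## (EBImage::gblur uses circular FFT padding, which wraps bright borders).
gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(x, along_rows) {
    acc <- 0
    for (i in seq_along(k)) {
      d <- i - r - 1L
      acc <- acc + k[i] * (if (along_rows) shift_edge(x, d, 0) else shift_edge(x, 0, d))
    }
    acc
  }
  conv1(conv1(m, TRUE), FALSE)
}

## shift with replicate (edge-clamp) padding
shift_edge <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) - dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) - dc, 1L), w)
  m[ri, ci, drop = FALSE]
}

#' Adaptive peak splitting ("dynamic erosion")
#'
#' Identifies one marker per intensity peak inside each candidate
#' component, splitting touching cells. Within each 8-connected component
#' of `mask` the h-maxima transform suppresses peaks whose prominence over
#' the connecting saddle is below an adaptive threshold
#' `h = h_fraction * (component max - component min)` — equivalent to
#' raising an erosion threshold until sufficiently prominent peaks
#' separate. The regional maxima that survive become markers.
#'
#' @param mask logical candidate mask from [hessian_candidates()].
#' @param frame the intensity image the mask was derived from.
#' @param h_fraction adaptive prominence fraction (see
#'   [segmentation_config()]).
#' @return integer marker matrix; 0 = background, k = marker of peak k.
#' @export
dynamic_erosion <- function(mask, frame, h_fraction = 0.1) {
  if (!identical(dim(mask), dim(frame))) stop2("mask and frame shapes differ")
  markers <- matrix(0L, nrow(frame), ncol(frame))
  comp <- label_components(mask)
  ncomp <- max(comp)
  if (ncomp == 0L) return(markers)
  next_marker <- 1L
  for (ci in seq_len(ncomp)) {
    idx <- which(comp == ci, arr.ind = TRUE)
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    sub <- frame[r0:r1, c0:c1, drop = FALSE]
    msub <- comp[r0:r1, c0:c1, drop = FALSE] == ci
    lo <- min(sub[msub]); hi <- max(sub[msub])
    h <- h_fraction * (hi - lo)
    f <- ifelse(msub, sub, -Inf)
    ## h-maxima: geodesic reconstruction by dilation of (f - h) under f
    rec <- f - h
    repeat {
      nxt <- pmin(maxfilter3(rec, fill = -Inf), f)
      if (all(nxt == rec)) break
      rec <- nxt
    }
    ## regional maxima of the transform = surviving peak plateaus
    peaks <- msub & rec >= maxfilter3(rec, fill = -Inf) - 1e-12
    plab <- label_components(peaks)
    np <- max(plab)
    if (np == 0L) next
    tgt <- markers[r0:r1, c0:c1, drop = FALSE]
    tgt[plab > 0L] <- plab[plab > 0L] + (next_marker - 1L)
    markers[r0:r1, c0:c1] <- tgt
    next_marker <- next_marker + np
  }
  markers
}

#' Marker-seeded region growing to coarse boundaries
#'
#' Expands each marker over the above-background support of the frame by
#' intensity-guided propagation (a marker-controlled watershed on the
#' inverted intensity surface): each supported pixel is assigned to the
#' marker reachable by the path of least intensity descent, so boundaries
#' between touching cells fall at the intensity saddle.
#'
#' @param markers integer marker matrix from [dynamic_erosion()].
#' @param frame intensity image (adjusted, `[0, 1]` scale).
#' @param support_threshold pixels with intensity above this value form
#'   the growth support.
#' @param frame_index 0-based frame index recorded in the result.
#' @return a [label_image()] on the same (coarse) grid.
#' @export
dilate_to_boundaries <- function(markers, frame, support_threshold = 0.1,
                                 frame_index = 0L) {
  if (!identical(dim(markers), dim(frame))) stop2("markers and frame shapes differ")
  if (max(markers) == 0L)
    return(label_image(matrix(0L, nrow(frame), ncol(frame)), frame_index))
  support <- frame > support_threshold | markers > 0L
  lab <- EBImage::propagate(frame, seeds = markers, mask = support, lambda = 1e-4)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(frame), ncol(frame))
  label_image(relabel_consecutive(lab), frame_index)
}

relabel_consecutive <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) return(lab)
  lab[] <- match(lab, c(0L, ids)) - 1L
  lab
}

#' Full-resolution boundary refinement
#'
#' Maps coarse labels back to the original grid (block upscaling by the
#' downsample factor) and refines each cell boundary by geodesic growth on
#' the preprocessed full-resolution frame, starting from the cell's bright
#' core (pixels above 80% of its peak intensity, falling back to the
#' brightest pixel). Growth stops where the
#' pixel intensity falls below `refine_stop_fraction * (that cell's peak
#' intensity)`, or at Canny edge chains that are sharp relative to the
#' cell (peak gradient of the chain at least
#' `edge_stop_fraction * peak intensity` per pixel); the refined region is
#' the connected component of the admissible pixels containing the seed.
#' Cells are processed in label order and may not overlap; regions outside
#' `[min_cell_area, max_cell_area]` are discarded and the survivors
#' relabeled consecutively.
#'
#' @param coarse a [label_image()] on the downsampled grid.
#' @param original_frame preprocessed (background-subtracted, adjusted)
#'   full-resolution frame.
#' @param config a [segmentation_config()].
#' @return a [label_image()] on the original grid.
#' @export
refine_boundaries <- function(coarse, original_frame, config = segmentation_config()) {
  f <- config$downsample_factor
  H <- nrow(original_frame); W <- ncol(original_frame)
  if (ceiling(H / f) != nrow(coarse$labels) || ceiling(W / f) != ncol(coarse$labels))
    stop2("coarse grid x factor does not match original frame shape")
  up <- kronecker(coarse$labels, matrix(1L, f, f))[seq_len(H), seq_len(W), drop = FALSE]
  out <- matrix(0L, H, W)
  n <- max(coarse$labels)
  if (n == 0L) return(label_image(out, coarse$frame_index))
  edges <- canny_edges(original_frame, sigma = config$canny_sigma,
                       low_quantile = config$canny_low,
                       high_quantile = config$canny_high)
  emag <- attr(edges, "magnitude")
  edge_lab <- label_components(edges)
  ## peak gradient of each edge chain: chains are barriers only for cells
  ## relative to whose peak intensity they are sharp
  chain_max <- if (max(edge_lab) > 0L)
    as.numeric(tapply(emag[edge_lab > 0L], edge_lab[edge_lab > 0L], max))
  else numeric(0)
  pad <- 3L * f + 5L
  for (k in seq_len(n)) {
    idx <- which(up == k, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    peak <- max(original_frame[up == k])
    if (peak <= 0) next
    thr <- config$refine_stop_fraction * peak
    r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(H, max(idx[, 1]) + pad)
    c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(W, max(idx[, 2]) + pad)
    win_f <- original_frame[r0:r1, c0:c1, drop = FALSE]
    win_up <- up[r0:r1, c0:c1, drop = FALSE]
    win_el <- edge_lab[r0:r1, c0:c1, drop = FALSE]
    sharp_ids <- which(chain_max >= config$edge_stop_fraction * peak)
    barrier <- win_el > 0L & win_el %in% sharp_ids
    dim(barrier) <- dim(win_f)
    allowed <- win_f >= thr & !barrier & out[r0:r1, c0:c1, drop = FALSE] == 0L
    ## seed from the cell's bright core so enclosing sharp edges stop growth;
    ## a high core fraction keeps seeds on the inner side of barrier lines
    seed <- win_up == k & allowed & win_f >= 0.8 * peak
    if (!any(seed)) {
      inreg <- win_up == k
      wmax <- which(inreg & win_f == max(win_f[inreg]))[1]
      if (is.na(wmax) || !allowed[wmax]) next
      seed <- matrix(FALSE, nrow(win_f), ncol(win_f)); seed[wmax] <- TRUE
    }
    ## 4-connected growth: an 8-connected edge chain then forms a closed
    ## barrier (connectivity duality)
    cc <- label_components(allowed, conn = 4L)
    keep_ids <- unique(cc[seed & cc > 0L])
    if (length(keep_ids) == 0L) next
    region <- cc %in% keep_ids
    dim(region) <- dim(cc)
    tgt <- out[r0:r1, c0:c1, drop = FALSE]
    tgt[region] <- k
    out[r0:r1, c0:c1] <- tgt
  }
  ## area filter + consecutive relabeling
  areas <- tabulate(out[out > 0L], nbins = n)
  drop <- which(areas < config$min_cell_area | areas > config$max_cell_area)
  if (length(drop)) out[out %in% drop] <- 0L
  label_image(relabel_consecutive(out), coarse$frame_index)
}

#' Segment one frame
#'
#' Runs the full segmentation chain: background subtraction, saturating
#' intensity adjustment, block downsampling, Hessian blob detection,
#' adaptive peak splitting, marker-seeded growing, and full-resolution
#' boundary refinement. Deterministic given frame and config. A blank
#' (constant) frame yields zero labels.
#'
#' @param frame numeric intensity matrix.
#' @param config a [segmentation_config()].
#' @param frame_index 0-based index recorded in the result.
#' @return a [label_image()].
#' @export
segment_frame <- function(frame, config = segmentation_config(), frame_index = 0L) {
  validate_segmentation_config(config)
  bg <- subtract_background(frame, config)
  rng <- range(bg)
  if (rng[2] - rng[1] <= .Machine$double.eps * max(1, rng[2]))
    return(label_image(matrix(0L, nrow(frame), ncol(frame)), frame_index))
  adj <- tryCatch(adjust_intensity(bg, config$saturation_fraction),
                  error = function(e) NULL)
  if (is.null(adj))
    return(label_image(matrix(0L, nrow(frame), ncol(frame)), frame_index))
  ds <- downsample(adj, config$downsample_factor)
  mask <- hessian_candidates(ds, config$hessian_scale)
  ## blob candidates must also rise above background: bare noise curvature
  ## otherwise seeds spurious markers
  mask <- mask & ds >= config$support_threshold
  markers <- dynamic_erosion(mask, ds, config$h_fraction)
  coarse <- dilate_to_boundaries(markers, ds, config$support_threshold, frame_index)
  refine_boundaries(coarse, adj, config)
}

#' Segment every frame of a stack
#'
#' @param stack an [image_stack()].
#' @param config a [segmentation_config()].
#' @param progress print per-frame cell counts.
#' @return list of [label_image()], one per frame (0-based frame indices).
#' @export
segment_stack <- function(stack, config = segmentation_config(), progress = FALSE) {
  if (!inherits(stack, "image_stack")) stop2("stack must be an image_stack")
  out <- vector("list", length(stack$frames))
  for (i in seq_along(stack$frames)) {
    out[[i]] <- segment_frame(stack$frames[[i]], config, frame_index = i - 1L)
    if (progress)
      message(sprintf("frame %d: %d cells", i - 1L, max(out[[i]]$labels)))
  }
  out
}
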