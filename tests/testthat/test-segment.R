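test_that("background subtraction removes uniform and offset backgrounds", {
  sc <- segmentation_config(background_radius = 10)
  uni <- matrix(7, 60, 80)
  expect_equal(subtract_background(uni, sc), matrix(0, 60, 80))

  # isolated blob much smaller than the structuring element is preserved
  blob <- gauss_blob(80, 80, 40, 40, 3, amp = 100)
  out <- subtract_background(blob, segmentation_config(background_radius = 30))
  expect_lt(abs(max(out) - 100) / 100, 0.05)

  # offset invariance: frame + c gives the same result as frame
  expect_equal(subtract_background(blob + 13, segmentation_config(background_radius = 30)),
               subtract_background(blob, segmentation_config(background_radius = 30)),
               tolerance = 1e-8)
  expect_error(subtract_background(matrix(-1, 4, 4), sc), "non-negative")
})

test_that("intensity adjustment saturates symmetrically and is affine-invariant", {
  set.seed(1)
  f <- matrix(rnorm(10000, 50, 10), 100, 100)
  f <- pmax(f, 0)
  a <- adjust_intensity(f, 0.01)
  expect_true(all(a >= 0 & a <= 1))
  # about 0.5% clipped at each tail
  expect_equal(mean(a == 1), 0.005, tolerance = 0.3)
  expect_equal(mean(a == 0), 0.005, tolerance = 0.3)
  # scale and offset invariance
  expect_equal(adjust_intensity(3.7 * f, 0.01), a, tolerance = 1e-9)
  expect_equal(adjust_intensity(f + 40, 0.01), a, tolerance = 1e-9)
  expect_error(adjust_intensity(matrix(5, 4, 4)), "constant")

  # constructed outliers: exactly 1% extreme pixels map to 1
  g <- matrix(seq(0, 1, length.out = 10000), 100, 100)
  g[1:100] <- 1000
  ag <- adjust_intensity(g, 0.02)
  expect_true(all(ag[1:100] == 1))
  expect_lt(max(ag[-(1:100)]), 1)
})

test_that("downsampling averages blocks and handles partial blocks", {
  expect_equal(downsample(matrix(3.5, 10, 10), 5), matrix(3.5, 2, 2))
  f <- matrix(runif(48), 6, 8)
  expect_identical(downsample(f, 1), f)
  expect_equal(downsample(matrix(1:25, 5, 5), 5), matrix(13, 1, 1))
  # trailing partial blocks averaged over available pixels
  g <- matrix(1, 7, 7)
  g[6:7, ] <- 4
  d <- downsample(g, 5)
  expect_equal(dim(d), c(2L, 2L))
  expect_equal(d[2, 1], 4)
  expect_error(downsample(matrix(1, 3, 3), 4), "exceeds")
})

test_that("hessian eigenmap marks bright blobs, not dark ones or flat fields", {
  blob <- gauss_blob(41, 41, 20, 20, 4)
  m <- hessian_candidates(blob, 1)
  expect_true(m[21, 21])
  # dark blob on bright background: center not marked
  m2 <- hessian_candidates(1 - blob, 1)
  expect_false(m2[21, 21])
  expect_false(any(hessian_candidates(matrix(1, 30, 30), 1)))
  expect_error(hessian_candidates(blob, 0), "hessian_scale")
})

test_that("dynamic erosion finds one marker per prominent peak", {
  # two well-separated peaks in one mask component
  f <- gauss_blob(40, 80, 20, 20, 5) + gauss_blob(40, 80, 58, 20, 5)
  mask <- f > 0.05
  mk <- dynamic_erosion(mask, f, 0.1)
  expect_equal(max(mk), 2L)
  # single blob: one marker
  mk1 <- dynamic_erosion(gauss_blob(40, 40, 20, 20, 5) > 0.05,
                         gauss_blob(40, 40, 20, 20, 5), 0.1)
  expect_equal(max(mk1), 1L)
  # shallow saddle below the adaptive threshold: one marker
  g <- gauss_blob(40, 80, 36, 20, 6) + gauss_blob(40, 80, 43, 20, 6)
  mkg <- dynamic_erosion(g > 0.05, g, 0.1)
  expect_equal(max(mkg), 1L)
  # empty mask is not an error
  expect_equal(max(dynamic_erosion(matrix(FALSE, 10, 10), matrix(0, 10, 10))), 0L)
})

test_that("marker-seeded growing covers blobs and splits at the saddle", {
  f <- gauss_blob(40, 80, 20, 20, 5) + gauss_blob(40, 80, 58, 20, 5)
  mk <- dynamic_erosion(f > 0.05, f, 0.1)
  lab <- dilate_to_boundaries(mk, f, 0.1)
  expect_s3_class(lab, "label_image")
  expect_equal(max(lab$labels), 2L)
  # each blob center belongs to a different region
  expect_true(lab$labels[21, 21] != lab$labels[21, 59])
  expect_true(all(lab$labels[f > 0.3] > 0))
  # symmetric blobs: boundary at the saddle gives near-equal region sizes
  sizes <- tabulate(lab$labels[lab$labels > 0])
  expect_lt(abs(diff(sizes)) / max(sizes), 0.2)
  # zero markers: all-background labels
  z <- dilate_to_boundaries(matrix(0L, 10, 10), matrix(0.5, 10, 10))
  expect_equal(max(z$labels), 0L)
})

test_that("refinement recovers the quarter-maximum level set of a blob", {
  sigma <- 6
  f <- gauss_blob(200, 200, 100.3, 99.6, sigma) * 150 + 5
  lab <- segment_frame(f, seg_config_exact(background_radius = 40), 0)
  expect_equal(max(lab$labels), 1L)
  r_meas <- sqrt(sum(lab$labels == 1) / pi)
  r_true <- sqrt(2 * log(4)) * sigma
  expect_lt(abs(r_meas - r_true), 1)
  # region contains the truth centroid
  expect_equal(lab$labels[100, 101], 1L)
  # area within 15% of the closed-form level-set area
  expect_lt(abs(sum(lab$labels == 1) - pi * r_true^2) / (pi * r_true^2), 0.15)
})

test_that("a sharp enclosing edge stops refinement where intensity would not", {
  H <- W <- 200
  dx <- outer(rep(1, H), (0:(W - 1)) - 100)
  dy <- outer((0:(H - 1)) - 100, rep(1, W))
  r <- sqrt(dx^2 + dy^2)
  # dome with a sharp rim at r = 25; outside plateau stays above 25% of peak
  f <- ifelse(r < 25, 1 - 0.05 * (r / 25)^2, ifelse(r < 60, 0.28, 0.01)) * 150 + 5
  lab <- segment_frame(f, seg_config_exact(background_radius = 70), 0)
  expect_equal(max(lab$labels), 1L)
  idx <- which(lab$labels == 1, arr.ind = TRUE)
  rr <- sqrt((idx[, 2] - 101)^2 + (idx[, 1] - 101)^2)
  expect_lt(max(rr), 27)    # stopped at the rim, not the plateau edge (r 60)
  expect_gt(max(rr), 20)    # but did reach the rim
})

test_that("empty coarse labels refine to empty labels", {
  co <- label_image(matrix(0L, 10, 10), 0L)
  out <- refine_boundaries(co, matrix(0.5, 50, 50), segmentation_config())
  expect_equal(max(out$labels), 0L)
  expect_error(refine_boundaries(co, matrix(0.5, 80, 80), segmentation_config()),
               "does not match")
})

test_that("segment_frame is deterministic and handles blank frames", {
  f <- gauss_blob(120, 120, 60, 60, 5) * 120 + 8
  sc <- seg_config_exact(background_radius = 30)
  l1 <- segment_frame(f, sc, 0)
  l2 <- segment_frame(f, sc, 0)
  expect_identical(l1, l2)
  expect_equal(max(segment_frame(matrix(5, 100, 100), sc, 0)$labels), 0L)
})

test_that("segmentation count matches truth on well-separated synthetic frames", {
  # independent seeded frames at the stated spacing condition
  n_ok <- 0L; n_frames <- 0L
  for (seed in 1:4) {
    cfg <- simulation_config(image_size = c(320, 320), n_frames = 5,
                             n_cells_init = 10, division_rate = 0, death_rate = 0,
                             seed = 100 + seed)
    st <- render_stack(simulate_truth(cfg), cfg)
    labs <- segment_stack(st, segmentation_config())
    counts <- vapply(labs, function(l) max(l$labels), integer(1))
    n_ok <- n_ok + sum(counts == 10L)
    n_frames <- n_frames + length(counts)
  }
  expect_gte(n_ok / n_frames, 0.99)
})

test_that("label images have consecutive labels and connected regions", {
  cfg <- simulation_config(image_size = c(256, 256), n_frames = 1,
                           n_cells_init = 8, division_rate = 0, death_rate = 0,
                           seed = 55)
  st <- render_stack(simulate_truth(cfg), cfg)
  lab <- segment_frame(st$frames[[1]], segmentation_config(), 0)
  n <- max(lab$labels)
  expect_setequal(unique(as.integer(lab$labels)), 0:n)
  for (k in seq_len(n)) {
    comp <- mptrack:::label_components(lab$labels == k)
    expect_equal(max(comp), 1L)
  }
})
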