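test_that("normalized counts divide by the initial count", {
  expect_equal(normalized_counts(c(100, 138)), c(1, 1.38))
  expect_equal(normalized_counts(c(50, 100, 25)), c(1, 2, 0.5))
  expect_equal(normalized_counts(c(7, 7, 7))[1], 1)
  expect_error(normalized_counts(c(0, 5)), "initial")
  expect_error(normalized_counts(integer(0)), "empty")
})

test_that("step velocities convert to um/h with the stack calibration", {
  # +1 pix/frame in x at 1.34 um/pix and 30 min/frame: u = 2.68 um/h
  tr <- data.frame(frame = 0:5, Cx = 0:5, Cy = 0)
  v <- step_velocities(tr, pixel_size = 1.34, frame_interval = 30)
  expect_equal(v$u, rep(2.68, 5))
  expect_equal(v$v, rep(0, 5))

  # static cell: all zero
  v0 <- step_velocities(data.frame(frame = 0:3, Cx = 1, Cy = 2), 1.34, 30)
  expect_true(all(v0$u == 0 & v0$v == 0))

  # reversing path: velocities sum to zero
  tr2 <- data.frame(frame = 0:4, Cx = c(0, 2, 4, 2, 0), Cy = 0)
  v2 <- step_velocities(tr2, 1, 60)
  expect_equal(sum(v2$u), 0)

  # gap: displacement divided by the full elapsed time
  trg <- data.frame(frame = c(0, 1, 3), Cx = c(0, 1, 5), Cy = 0)
  vg <- step_velocities(trg, 1, 60)
  expect_equal(vg$u, c(1, 2))

  expect_error(step_velocities(data.frame(frame = 0, Cx = 1, Cy = 1), 1, 30),
               "at least 2")
})

test_that("distances satisfy their closed forms", {
  straight <- data.frame(frame = 0:5, Cx = seq(0, 10, by = 2), Cy = 0)
  d <- distances(straight)
  expect_equal(unname(d["d_euc"]), unname(d["d_acc"]))

  lshape <- data.frame(frame = 0:2, Cx = c(0, 1, 1), Cy = c(0, 0, 1))
  dl <- distances(lshape)
  expect_equal(unname(dl["d_acc"]), 2)
  expect_equal(unname(dl["d_euc"]), sqrt(2), tolerance = 1e-9)

  loop <- data.frame(frame = 0:4, Cx = c(0, 1, 1, 0, 0), Cy = c(0, 0, 1, 1, 0))
  dloop <- distances(loop)
  expect_equal(unname(dloop["d_euc"]), 0)
  expect_gt(dloop["d_acc"], 0)

  # calibration scales both distances linearly
  expect_equal(unname(distances(lshape, pixel_size = 1.34)["d_acc"]), 2 * 1.34)
})

test_that("track metrics agree with per-track brute-force recomputation", {
  set.seed(21)
  tracks <- random_tracks(30, 15, len = 2)
  tm <- track_metrics(tracks, pixel_size = 1.34, frame_interval = 30)
  expect_equal(nrow(tm), 30)
  for (id in sample(unique(tracks$track_id), 5)) {
    d <- tracks[tracks$track_id == id, ]
    dd <- distances(d, pixel_size = 1.34)
    r <- tm[tm$track_id == id, ]
    expect_equal(r$d_euc, unname(dd["d_euc"]))
    expect_equal(r$d_acc, unname(dd["d_acc"]))
    v <- step_velocities(d, 1.34, 30)
    expect_equal(r$mean_speed, mean(v$speed))
    expect_equal(r$x_end, (d$Cx[nrow(d)] - d$Cx[1]) * 1.34)
  }
  expect_true(all(tm$d_euc <= tm$d_acc + 1e-9))
  expect_true(all(tm$directness_i >= 0 & tm$directness_i <= 1))
})

test_that("FMI is signed, bounded, and -1 for straight chemotactic runs", {
  # straight runs toward the chemoattractant (negative x)
  straight <- do.call(rbind, lapply(1:10, function(id)
    data.frame(track_id = id, frame = 0:20, Cx = seq(0, -20), Cy = 5 * id)))
  tm <- track_metrics(straight, pixel_size = 1, frame_interval = 60)
  expect_equal(forward_migration_index(tm, "parallel"), -1)
  expect_equal(forward_migration_index(tm, "perpendicular"), 0)

  # mirror symmetry in x cancels
  mirror <- rbind(straight,
                  within(straight, {track_id <- track_id + 100; Cx <- -Cx}))
  tmm <- track_metrics(mirror, 1, 60)
  expect_equal(forward_migration_index(tmm, "parallel"), 0)

  # x-reflection antisymmetry on random tracks
  set.seed(5)
  rt <- random_tracks(50, 12)
  tm1 <- track_metrics(rt, 1, 60)
  rt2 <- rt; rt2$Cx <- -rt2$Cx
  tm2 <- track_metrics(rt2, 1, 60)
  expect_equal(forward_migration_index(tm1, "parallel"),
               -forward_migration_index(tm2, "parallel"), tolerance = 1e-12)
})

test_that("directness is 1 for straight tracks, 0 for out-and-back", {
  straight <- do.call(rbind, lapply(1:10, function(id)
    data.frame(track_id = id, frame = 0:20,
               Cx = cumsum(c(0, rep(cos(id), 20))),
               Cy = cumsum(c(0, rep(sin(id), 20))))))
  expect_equal(directness(track_metrics(straight, 1, 60)), 1, tolerance = 1e-12)

  outback <- do.call(rbind, lapply(1:5, function(id)
    data.frame(track_id = id, frame = 0:10, Cx = c(0:5, 4:0), Cy = 0)))
  expect_equal(directness(track_metrics(outback, 1, 60)), 0)
})

test_that("random-walk directness matches a brute-force oracle", {
  # oracle: plain cumulative-sum simulation of fixed-length uncorrelated
  # walks, independent of the package's track machinery
  set.seed(31)
  n_steps <- 60
  oracle_D <- mean(replicate(4000, {
    ang <- runif(n_steps, 0, 2 * pi)
    x <- sum(cos(ang)); y <- sum(sin(ang))
    sqrt(x^2 + y^2) / n_steps
  }))
  cfg <- simulation_config(image_size = c(4000, 4000), n_frames = n_steps + 1,
                           n_cells_init = 300, persistence = 0, motion_speed = 6,
                           pixel_size = 1, division_rate = 0, death_rate = 0,
                           min_spacing = 0, seed = 13)
  tm <- track_metrics(truth_to_tracks(simulate_truth(cfg)), 1, 30)
  D <- directness(tm)
  # MC error of both estimates ~ 0.004; compare within 4 sigma
  expect_lt(abs(D - oracle_D), 0.02)
})

test_that("track selection drops short tracks and ranks by length", {
  set.seed(41)
  lens <- c(rep(5, 10), sample(12:40, 30, replace = TRUE))
  tracks <- do.call(rbind, lapply(seq_along(lens), function(id)
    data.frame(track_id = id, frame = seq_len(lens[id]) - 1,
               Cx = cumsum(runif(lens[id])), Cy = cumsum(runif(lens[id])))))
  sel <- select_tracks(tracks, k = 20, min_frames = 10)
  ids <- unique(sel$track_id)
  expect_equal(length(ids), 20)
  # no selected track shorter than the cutoff; equals brute-force ranking
  nlen <- table(tracks$track_id)
  expect_true(all(nlen[as.character(ids)] > 10))
  ord <- order(-lens)
  expect_setequal(ids, ord[seq_len(20)])

  expect_warning(sel2 <- select_tracks(tracks, k = 100, min_frames = 10), "returning all")
  expect_equal(length(unique(sel2$track_id)), 30)
  short <- tracks[tracks$track_id <= 10, ]
  expect_warning(sel3 <- select_tracks(short, k = 5, min_frames = 10), "returning all")
  expect_equal(nrow(sel3), 0)
})

test_that("condition summary pools selected tracks across replicates", {
  set.seed(51)
  samples <- lapply(1:3, function(s) random_tracks(120, 15, len = 2))
  cs <- condition_summary(samples, pixel_size = 1.34, frame_interval = 30,
                          k = 100, min_frames = 10)
  expect_s3_class(cs, "condition_summary")
  expect_equal(cs$n_tracks, 300)
  expect_equal(cs$N_over_N0$N_over_N0[1], 1)
  expect_true(abs(cs$FMI_par) <= 1 && abs(cs$FMI_perp) <= 1)
  expect_true(cs$D >= 0 && cs$D <= 1)

  # single sample: pooled equals selected
  cs1 <- condition_summary(samples[1], 1.34, 30, k = 100, min_frames = 10)
  expect_equal(cs1$n_tracks, 100)

  # pooled statistics equal brute-force recomputation from the raw tracks
  pool <- cs$selected_tracks
  tm <- track_metrics(pool, 1.34, 30)
  expect_equal(cs$D, mean(tm$d_euc / tm$d_acc))
  expect_equal(cs$FMI_par, mean(tm$x_end / tm$d_acc))
  expect_equal(cs$mean_speed, mean(tm$mean_speed))
})

test_that("metrics are translation invariant", {
  set.seed(61)
  rt <- random_tracks(40, 12)
  rt2 <- rt; rt2$Cx <- rt2$Cx + 500; rt2$Cy <- rt2$Cy - 300
  tm1 <- track_metrics(rt, 1.34, 30); tm2 <- track_metrics(rt2, 1.34, 30)
  expect_equal(tm1$d_euc, tm2$d_euc, tolerance = 1e-9)
  expect_equal(tm1$d_acc, tm2$d_acc, tolerance = 1e-9)
  expect_equal(directness(tm1), directness(tm2), tolerance = 1e-12)
  expect_equal(forward_migration_index(tm1, "parallel"),
               forward_migration_index(tm2, "parallel"), tolerance = 1e-12)
})

test_that("speed and directness recover the configured motion parameters", {
  Ds <- sapply(c(0.2, 0.6, 0.9), function(p) {
    cfg <- simulation_config(image_size = c(3000, 3000), n_frames = 41,
                             n_cells_init = 300, persistence = p,
                             motion_speed = 3, division_rate = 0, death_rate = 0,
                             min_spacing = 0, seed = 71)
    tm <- track_metrics(truth_to_tracks(simulate_truth(cfg)),
                        pixel_size = 1.34, frame_interval = 30)
    c(D = directness(tm), speed = mean(tm$mean_speed))
  })
  # directness increases monotonically with persistence
  expect_true(all(diff(Ds["D", ]) > 0))
  # mean speed within 10% of the configured motion speed
  expect_true(all(abs(Ds["speed", ] - 3) / 3 < 0.1))
})
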