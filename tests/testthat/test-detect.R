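test_that("point-to-polyline distance is exact", {
  seg <- cbind(c(0, 10), c(0, 0))
  # perpendicular foot inside the segment
  expect_equal(point_to_polyline_distance(c(5, 3), seg), 3.0)
  # beyond an endpoint: nearest endpoint distance
  expect_equal(point_to_polyline_distance(c(-3, 4), seg), 5.0)

  # random points vs a 20-segment polyline, against a dense-sampling oracle
  set.seed(42)
  verts <- cbind(cumsum(stats::runif(21, 5, 20)),
                 cumsum(stats::rnorm(21, 0, 8)))
  for (k in 1:12) {
    p <- c(stats::runif(1, 0, 250), stats::runif(1, -60, 60))
    expect_equal(point_to_polyline_distance(p, verts),
                 brute_polyline_dist(p, verts), tolerance = 1e-3)
  }
})

test_that("feature distance queries equal brute-force minima over segments", {
  set.seed(7)
  feats <- lapply(1:6, function(i) {
    list(ftype = sample(lft_feature_types(), 1),
         vertices = cbind(cumsum(stats::runif(9, 10, 60)) + i * 40,
                          cumsum(stats::rnorm(9, 0, 30))))
  })
  fs <- feature_set(feats)
  pts <- cbind(stats::runif(200, 0, 600), stats::runif(200, -150, 150))
  d <- feature_min_distances(pts, fs)
  for (ft in lft_feature_types()) {
    idx <- which(fs$features$ftype == ft)
    if (!length(idx)) {
      expect_true(all(is.infinite(d[, ft])))
      next
    }
    brute <- apply(pts, 1, function(p)
      min(vapply(idx, function(i)
        point_to_polyline_distance(p, fs$vertices[[i]]), 0)))
    expect_equal(unname(d[, ft]), unname(brute), tolerance = 1e-10)
  }
})

test_that("proximity profile uses a strict buffer and nests across widths", {
  fs <- road_along_x()
  b <- make_burst(x = c(0, 15, 30, 45), y = c(9.9, 10, 14.9, 5.1))
  p10 <- proximity_profile(b, fs, lft_config(buffer_m = 10))
  expect_equal(p10$in_road, c(TRUE, FALSE, FALSE, TRUE))  # strict <
  expect_equal(p10$in_any, p10$in_road)
  expect_true(all(is.infinite(p10$dist_stream)))

  p5 <- proximity_profile(b, fs, lft_config(buffer_m = 5))
  p15 <- proximity_profile(b, fs, lft_config(buffer_m = 15))
  expect_true(all(!p5$in_road | p10$in_road))
  expect_true(all(!p10$in_road | p15$in_road))

  empty <- feature_set(list())
  pe <- proximity_profile(b, empty, lft_config())
  expect_true(all(is.infinite(pe$dist_road)))
  expect_false(any(pe$in_any))
})

test_that("case trajectories are the suffix from first buffer entry", {
  fs <- road_along_x()
  # 20 fixes approaching the road; first in-buffer fix at seq_index 7
  y <- c(seq(80, 11, length.out = 7), rep(2, 13))
  b <- make_burst(x = (0:19) * 10, y = y)
  prof <- proximity_profile(b, fs, lft_config())
  ct <- extract_case_trajectory(b, prof, "road")
  expect_equal(ct$entry_index, 7L)
  expect_equal(nrow(ct$fixes), 13)
  expect_equal(ct$fixes$seq_index[1], 7L)

  # no in-buffer fix -> NULL
  bfar <- make_burst(x = (0:5) * 10, y = rep(100, 6))
  expect_null(extract_case_trajectory(
    bfar, proximity_profile(bfar, fs, lft_config()), "road"))

  # entry at seq 0 -> the whole burst
  bon <- burst_on_road(n = 5)
  ct0 <- extract_case_trajectory(
    bon, proximity_profile(bon, fs, lft_config()), "road")
  expect_equal(ct0$entry_index, 0L)
  expect_equal(nrow(ct0$fixes), 5)
})

test_that("displacement-to-distance ratio matches hand computation", {
  pts <- cbind(c(0, 10, 20, 30), c(0, 0, 0, 0))
  expect_equal(displacement_distance_ratio(pts), 2.0)  # (10+20+30)/3 / 10

  back <- cbind(c(0, 10, 0), c(0, 0, 0))
  expect_equal(displacement_distance_ratio(back), 0.5)  # boundary case

  # isometry invariance
  set.seed(3)
  p <- cbind(cumsum(stats::rnorm(6, 3)), cumsum(stats::rnorm(6, 1)))
  r0 <- displacement_distance_ratio(p)
  th <- 1.1
  pr <- cbind(cos(th) * p[, 1] - sin(th) * p[, 2] + 100,
              sin(th) * p[, 1] + cos(th) * p[, 2] - 40)
  expect_equal(displacement_distance_ratio(pr), r0)

  expect_error(displacement_distance_ratio(cbind(c(0, 0), c(0, 0))),
               "undefined")
})

test_that("event detection applies rules a-d on contiguous in-buffer runs", {
  fs <- road_along_x()
  cfg <- lft_config()

  # 6 in-buffer fixes along the road at 45 m steps: one clear event
  b <- burst_on_road(n = 8, speed = 3)
  b$y[7:8] <- 50  # departure after fix 6
  prof <- proximity_profile(b, fs, cfg)
  ev <- detect_lft_events(b, prof, "road", cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_positions, 6L)
  expect_equal(ev$path_distance_m, 225)
  expect_true(ev$ddr > 1)
  expect_false(ev$censored)
  expect_false(ev$start_known)  # started at seq 0

  # run of 2 in-buffer fixes: too short (rule b)
  b2 <- make_burst(x = c(0, 45, 90, 135), y = c(50, 2, 2, 50))
  ev2 <- detect_lft_events(b2, proximity_profile(b2, fs, cfg), "road", cfg)
  expect_equal(nrow(ev2), 0)

  # 5 in-buffer fixes totalling ~20 m: too little path (rule c)
  b3 <- make_burst(x = c(-60, seq(0, 20, length.out = 5), 200),
                   y = c(50, rep(2, 5), 50))
  ev3 <- detect_lft_events(b3, proximity_profile(b3, fs, cfg), "road", cfg)
  expect_equal(nrow(ev3), 0)

  # localized zig-zag inside the buffer: enough path but ddr <= 0.5 (rule d)
  b4 <- make_burst(x = c(-60, 0, 15, 0, 15, 0, 15, 0, 200),
                   y = c(50, rep(2, 7), 50))
  ev4 <- detect_lft_events(b4, proximity_profile(b4, fs, cfg), "road", cfg)
  expect_equal(nrow(ev4), 0)

  # two disjoint qualifying runs in one burst
  b5 <- make_burst(x = c(-60, 0, 45, 90, 135, 0, 0, 45, 90, 135),
                   y = c(50, 2, 2, 2, 2, 50, 2, 2, 2, 2))
  ev5 <- detect_lft_events(b5, proximity_profile(b5, fs, cfg), "road", cfg)
  expect_equal(nrow(ev5), 2)
  expect_true(ev5$censored[2])
  expect_true(all(ev5$start_known))
  # events are disjoint in fix indices
  expect_true(ev5$start_index[2] > ev5$end_index[1])
})

test_that("detection is invariant under rigid motion of fixes and features", {
  cfg <- lft_config()
  b <- make_burst(x = c(-60, 0, 45, 90, 135, 200), y = c(50, 2, 2, 2, 2, 60))
  fs <- road_along_x()
  ev <- detect_lft_events(b, proximity_profile(b, fs, cfg), "road", cfg)
  th <- 0.73; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- function(m) sweep(m %*% t(R), 2, c(-310, 95), "+")
  vb <- rot(cbind(b$x, b$y))
  b2 <- make_burst(x = vb[, 1], y = vb[, 2])
  fs2 <- feature_set(list(list(ftype = "road",
                               vertices = rot(fs$vertices[[1]]))))
  ev2 <- detect_lft_events(b2, proximity_profile(b2, fs2, cfg), "road", cfg)
  expect_equal(nrow(ev2), nrow(ev))
  expect_equal(ev2$path_distance_m, ev$path_distance_m, tolerance = 1e-9)
  expect_equal(ev2$ddr, ev$ddr, tolerance = 1e-9)
  expect_equal(ev2$duration_s, ev$duration_s)
})

test_that("survival records follow the departure/censoring time rules", {
  fs <- road_along_x()
  cfg <- lft_config()
  # 3 in-buffer fixes at t = 15,30,45 then out at 60: time 45, event 1
  b <- make_burst(x = c(0, 45, 90, 135, 180), y = c(50, 2, 2, 2, 60))
  ev <- detect_lft_events(b, proximity_profile(b, fs, cfg), "road", cfg)
  rec <- events_to_survival_records(ev)
  expect_equal(rec$time_s, 45)
  expect_equal(rec$event, 1L)

  # run to burst end: censored, time to last fix
  b2 <- make_burst(x = c(0, 45, 90, 135, 180), y = c(50, 2, 2, 2, 2))
  ev2 <- detect_lft_events(b2, proximity_profile(b2, fs, cfg), "road", cfg)
  rec2 <- events_to_survival_records(ev2)
  expect_equal(rec2$time_s, 45)
  expect_equal(rec2$event, 0L)

  # start-unknown events (entry at seq 0) are excluded from records
  b3 <- burst_on_road(n = 6)
  ev3 <- detect_lft_events(b3, proximity_profile(b3, fs, cfg), "road", cfg)
  expect_equal(nrow(ev3), 1)
  expect_equal(nrow(events_to_survival_records(ev3)), 0)
})

test_that("event mean speed agrees with burst kinematics on the sub-series", {
  fs <- road_along_x()
  cfg <- lft_config()
  b <- make_burst(x = c(0, 45, 90, 135, 180, 300), y = c(50, 2, 2, 2, 2, 60))
  ev <- detect_lft_events(b, proximity_profile(b, fs, cfg), "road", cfg)
  expect_equal(ev$mean_speed_mps, 3.0)
  expect_equal(event_mean_speed(ev[1, ], b), 3.0)

  # steps 30 m and 60 m at 15 s -> 3 m/s
  b2 <- make_burst(x = c(0, 30, 90, 200), y = c(2, 2, 2, 60))
  # force a known-start run by prepending a far fix
  b2 <- rbind(make_burst(x = -60, y = 50), b2)
  b2$seq_index <- 0:4; b2$t <- (0:4) * 15
  ev2 <- detect_lft_events(b2, proximity_profile(b2, fs, cfg), "road", cfg)
  expect_equal(ev2$mean_speed_mps, 3.0)
})

test_that("events found at 5 m nest inside in-buffer runs at 15 m", {
  set.seed(11)
  cfg5 <- lft_config(buffer_m = 5); cfg15 <- lft_config(buffer_m = 15)
  fs <- road_along_x()
  for (k in 1:10) {
    b <- make_burst(x = cumsum(stats::runif(12, 10, 50)),
                    y = stats::rnorm(12, 0, 8))
    p5 <- proximity_profile(b, fs, cfg5)
    p15 <- proximity_profile(b, fs, cfg15)
    ev5 <- detect_lft_events(b, p5, "road", cfg5)
    for (i in seq_len(nrow(ev5))) {
      idx <- (ev5$start_index[i]:ev5$end_index[i]) + 1L
      expect_true(all(p15$in_road[idx]))
    }
  }
})
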