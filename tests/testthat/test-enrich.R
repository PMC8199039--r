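make_static_stream <- function(roll_deg, duration = 5, fs = 54, side = "left") {
  t <- seq(0, duration, by = 1 / fs)
  th <- roll_deg * pi / 180
  sensor_stream(t, cbind(sin(th), cos(th), 0)[rep(1, length(t)), ],
                matrix(0, length(t), 3), side)
}

test_that("complementary filter converges to the gravity-referenced roll", {
  s <- make_static_stream(30)
  ea <- estimate_edge_angle(s)
  after2s <- ea$angle_deg[ea$time_s >= 2]
  expect_lt(max(abs(after2s - 30)), 0.5)

  level <- estimate_edge_angle(make_static_stream(0))
  expect_lt(max(level$angle_deg), 1e-9)
})

test_that("edge angle tracks a known rotation within 2 degrees RMSE", {
  fs <- 54; T_ <- 10
  t <- seq(0, 20, by = 1 / fs)
  theta <- 40 * sin(pi * t / T_)
  gyro_roll <- 40 * (pi / T_) * cos(pi * t / T_)   # deg/s, exact derivative
  th <- theta * pi / 180
  s <- sensor_stream(t, cbind(sin(th), cos(th), 0),
                     cbind(0, 0, gyro_roll), "left")
  ea <- estimate_edge_angle(s)
  rmse <- sqrt(mean((ea$angle_deg - abs(theta))^2))
  expect_lt(rmse, 2)

  # segment slicing and range errors
  seg <- data.frame(start_time = 5, end_time = 8)
  sl <- estimate_edge_angle(s, segment = seg)
  expect_true(all(sl$time_s >= 5 & sl$time_s <= 8))
  expect_error(estimate_edge_angle(s, segment = data.frame(start_time = -1,
                                                           end_time = 3)),
               "outside")
})

test_that("symmetry is the signed pointwise profile difference", {
  expect_equal(estimate_symmetry(rep(10, 101), rep(10, 101)), rep(0, 101))
  expect_equal(estimate_symmetry(rep(10, 101), rep(8, 101)), rep(2, 101))
  off <- sin(seq(0, pi, length.out = 101))
  a <- runif(101) * 20
  expect_equal(estimate_symmetry(a + off, a), off, tolerance = 1e-12)
  expect_error(estimate_symmetry(rep(1, 100), rep(1, 101)))
})

test_that("radial force follows v|omega|/g with sign-flip invariance", {
  expect_equal(estimate_radial_force(10, 0.5), 10 * 0.5 / 9.80665)
  expect_equal(round(estimate_radial_force(10, 0.5), 4), 0.5099)
  expect_equal(estimate_radial_force(rep(12, 50), rep(0, 50)), rep(0, 50))

  withr::local_seed(3)
  v <- runif(101, 0, 20); w <- rnorm(101)
  expect_lt(max(abs(estimate_radial_force(v, w) - v * abs(w) / 9.80665)), 1e-12)
  expect_equal(estimate_radial_force(v, -w), estimate_radial_force(v, w))
  expect_error(estimate_radial_force(-1, 0.5), "non-negative")
})

test_that("GNSS speed interpolation is linear with clamped edges", {
  g <- gnss_track(0:10, rep(10, 11))
  expect_equal(interpolate_speed(g, seq(0, 10, 0.1)), rep(10, 101))

  g2 <- gnss_track(c(0, 1), c(0, 2))
  expect_equal(interpolate_speed(g2, 0.5), 1)
  expect_equal(interpolate_speed(g2, c(-5, 7)), c(0, 2))  # clamped

  withr::local_seed(8)
  tt <- sort(runif(40, 0, 10))
  g3 <- gnss_track(0:10, runif(11, 2, 15))
  oracle <- approx(g3$time_s, g3$speed_mps, xout = tt)$y
  expect_lt(max(abs(interpolate_speed(g3, tt) - oracle)), 1e-12)
})

test_that("run enrichment produces consistent 101-point turns", {
  p <- synthetic_params(gyro_noise_dps = 0, accel_noise_g = 0,
                        speed_drift_mps = 0, seed = 31)
  run <- generate_raw_run(p, size = "medium")
  kept <- filter_turns(segment_run(run))
  turns <- enrich_run(run, kept)
  expect_length(turns, nrow(kept))
  for (tr in turns) {
    expect_length(tr$edge_angle, 101)
    expect_true(all(tr$speed >= 0))
    expect_true(all(tr$edge_angle >= 0))   # edging magnitude
    expect_false(tr$symmetry_missing)
  }
  # peak edge near the generator's peak roll angle
  expect_equal(max(turns[[2]]$edge_angle), p$peak_roll_deg, tolerance = 0.15)
  # radial force roughly v^2/(r*g) at the plateau
  expect_equal(max(turns[[2]]$radial_force), 10^2 / (9 * 9.80665),
               tolerance = 0.25)
  # enrichment has no hidden state
  turns2 <- enrich_run(run, kept)
  expect_identical(turns, turns2)
})

test_that("a turn with no opposite-direction neighbour gets flagged zero symmetry", {
  p <- synthetic_params(gyro_noise_dps = 0, accel_noise_g = 0,
                        speed_drift_mps = 0, seed = 32)
  run <- generate_raw_run(p)
  kept <- filter_turns(segment_run(run))
  solo <- kept[1, , drop = FALSE]
  turns <- enrich_run(run, solo)
  expect_true(turns[[1]]$symmetry_missing)
  expect_equal(turns[[1]]$symmetry, rep(0, 101))
})

test_that("a straight glide yields near-zero radial force", {
  # constant-speed run, yaw gyro forced to zero
  p <- synthetic_params(gyro_noise_dps = 0, accel_noise_g = 0,
                        speed_drift_mps = 0, seed = 33)
  run <- generate_raw_run(p)
  for (b in c("left", "right")) run[[b]]$gyro[, "gy_dps"] <- 0
  kept <- filter_turns(segment_run(run))
  turns <- enrich_run(run, kept)
  expect_lt(max(turns[[1]]$radial_force), 1e-9)
})
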