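test_that("sensor streams enforce their invariants", {
  t <- seq(0, 1, by = 1 / 54)
  n <- length(t)
  a <- matrix(0, n, 3); a[, 2] <- 1
  g <- matrix(0, n, 3)
  s <- sensor_stream(t, a, g, "left")
  expect_equal(sample_rate(s), 54, tolerance = 1e-6)

  t_bad <- t; t_bad[10] <- t_bad[12]
  expect_error(sensor_stream(t_bad, a, g, "left"), "row 11")

  g_bad <- g; g_bad[5, 3] <- 1500
  expect_error(sensor_stream(t, a, g_bad, "left"), "full scale")
  expect_error(sensor_stream(t, a[-1, ], g, "left"), "n x 3")
})

test_that("gnss tracks and runs validate ranges and overlap", {
  expect_error(gnss_track(0:5, c(1, 2, -1, 3, 4, 5)), "non-negative")
  expect_error(gnss_track(c(0, 1, 1, 2), rep(1, 4)), "row 3")

  t <- seq(0, 5, by = 1 / 54)
  mk <- function(side) sensor_stream(t, cbind(0, rep(1, length(t)), 0),
                                     matrix(0, length(t), 3), side)
  g_far <- gnss_track(100:105, rep(5, 6))
  expect_error(raw_run(mk("left"), mk("right"), g_far), "overlap")
  run <- raw_run(mk("left"), mk("right"), gnss_track(0:5, rep(5, 6)))
  expect_s3_class(run, "raw_run")
  expect_error(raw_run(mk("left"), mk("left"), gnss_track(0:5, rep(5, 6))),
               "side")
})

test_that("run CSV reader and writer are inverse and reject bad files", {
  p <- synthetic_params(seed = 21)
  run <- generate_raw_run(p)
  dir <- withr::local_tempdir()
  paths <- write_run(run, dir, prefix = "r1")
  run2 <- read_run(paths[1], paths[2], paths[3], skier_id = "synthetic")
  expect_equal(run2$left$time_s, run$left$time_s)
  expect_equal(run2$right$gyro, run$right$gyro, tolerance = 1e-12)
  expect_equal(run2$gnss$speed_mps, run$gnss$speed_mps)

  # writer(reader(writer(x))) reproduces the CSV bytes
  paths2 <- write_run(run2, dir, prefix = "r2")
  for (i in 1:3) {
    expect_identical(readLines(paths2[i])[-1], readLines(paths[i])[-1])
  }

  # missing column named in the error
  df <- read.csv(paths[1]); df$gz_dps <- NULL
  bad <- file.path(dir, "bad_left.csv")
  write.csv(df, bad, row.names = FALSE)
  expect_error(read_run(bad, paths[2], paths[3]), "gz_dps")

  # empty file
  writeLines("time_s,ax_g,ay_g,az_g,gx_dps,gy_dps,gz_dps", bad)
  expect_error(read_run(bad, paths[2], paths[3]), "no data rows")

  # non-monotone timestamp cites the row
  df <- read.csv(paths[1]); df$time_s[40] <- df$time_s[38]
  write.csv(df, bad, row.names = FALSE)
  expect_error(read_run(bad, paths[2], paths[3]), "row 40")
})

test_that("out-of-range gyro samples are clipped with a warning per config", {
  p <- synthetic_params(seed = 22)
  run <- generate_raw_run(p)
  dir <- withr::local_tempdir()
  paths <- write_run(run, dir, prefix = "r")
  df <- read.csv(paths[1])
  df$gy_dps[100] <- 1500
  write.csv(df, paths[1], row.names = FALSE)
  expect_warning(run2 <- read_run(paths[1], paths[2], paths[3]), "clipped")
  expect_equal(unname(run2$left$gyro[100, "gy_dps"]),
               ski_config()$limits$gyro_dps)
})

test_that("model persistence round-trips within 1e-12 over random models", {
  withr::local_seed(99)
  dir <- withr::local_tempdir()
  for (i in 1:50) {
    m <- random_reference_model()
    f <- file.path(dir, sprintf("m%d.json", i))
    save_model(m, f)
    m2 <- load_model(f)
    for (key in names(m$cells)) {
      for (v in names(m$cells[[key]])) {
        a <- m$cells[[key]][[v]]; b <- m2$cells[[key]][[v]]
        expect_lt(max(abs(a$mean_curve - b$mean_curve)), 1e-12)
        expect_lt(max(abs(a$loadings - b$loadings)), 1e-12)
        expect_lt(max(abs(a$varfrac - b$varfrac)), 1e-12)
        expect_lt(max(abs(a$score_sd - b$score_sd)), 1e-12)
        expect_identical(a$n_ref, b$n_ref)
      }
    }
  }
})

test_that("model files with bad schema, incomplete cells or broken loadings are rejected", {
  withr::local_seed(7)
  dir <- withr::local_tempdir()
  m <- random_reference_model(cells = "carving.small")
  f <- file.path(dir, "m.json")
  save_model(m, f)

  obj <- jsonlite::read_json(f, simplifyVector = TRUE, simplifyMatrix = FALSE)
  obj$schema_version <- "2"
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(f), "schema_version")

  obj$schema_version <- "1"
  obj$cells$carving.small$speed <- NULL
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(f), "speed")

  # perturb a loading row: no longer orthonormal
  save_model(m, f)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE, simplifyMatrix = FALSE)
  obj$cells$carving.small$edge_angle$loadings[[1]] <-
    unlist(obj$cells$carving.small$edge_angle$loadings[[1]]) * 1.01
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(f), "orthonormal")
})

test_that("enriched turns and segment tables enforce their invariants", {
  v <- rep(1, 101)
  expect_error(enriched_turn(v[-1], v, v, v, "carving", "small"), "101")
  expect_error(enriched_turn(v, v, v, -v, "carving", "small"), "non-negative")
  expect_error(turn_segments(c(0, 2), c(2, 4), c("left", "left")), "alternate")
  expect_error(
    variable_model(rep(0, 101), matrix(rnorm(303), 3), c(0.5, 0.3, 0.1),
                   rep(1, 3), 20L),
    "orthonormal"
  )
  expect_error(
    variable_model(rep(0, 101), random_orthonormal_rows(3, 101),
                   c(0.3, 0.5, 0.1), rep(1, 3), 20L),
    "non-increasing"
  )
})
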