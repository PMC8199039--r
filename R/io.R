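#' Read a raw run from CSV sensor logs
#'
#' Reads one run from three CSV files: one IMU log per boot with columns
#' `time_s, ax_g, ay_g, az_g, gx_dps, gy_dps, gz_dps` and a GNSS log with
#' columns `time_s, speed_mps`. Samples beyond the sensor full scale are
#' clipped to the configured limits with a warning; rows with non-monotone
#' timestamps are a format error naming the offending row. Gaps longer than
#' three nominal sample intervals are flagged (attribute `gap_times`), never
#' interpolated.
#'
#' @param imu_left_path,imu_right_path,gnss_path file paths.
#' @param skier_id,intended_style,body_mass run metadata, see [raw_run()].
#' @param config a [ski_config()] list (sensor limits are taken from it).
#' @return A [raw_run()]; boot streams carry a `gap_times` attribute listing
#'   the start times of flagged transmission gaps.
#' @export
read_run <- function(imu_left_path, imu_right_path, gnss_path,
                     skier_id = "skier", intended_style = NULL,
                     body_mass = 75, config = ski_config()) {
  left <- read_imu_csv(imu_left_path, "left", config$limits)
  right <- read_imu_csv(imu_right_path, "right", config$limits)
  g <- read_gnss_csv(gnss_path)
  raw_run(left, right, g, skier_id = skier_id,
          intended_style = intended_style, body_mass = body_mass)
}

read_imu_csv <- function(path, side, limits) {
  df <- read_checked_csv(path,
                         c("time_s", "ax_g", "ay_g", "az_g",
                           "gx_dps", "gy_dps", "gz_dps"))
  accel <- as.matrix(df[, c("ax_g", "ay_g", "az_g")])
  gyro <- as.matrix(df[, c("gx_dps", "gy_dps", "gz_dps")])
  if (max(abs(accel)) > limits$accel_g) {
    warning(sprintf("%s: accelerometer samples beyond +/-%g g clipped",
                    basename(path), limits$accel_g), call. = FALSE)
    accel <- pmin(pmax(accel, -limits$accel_g), limits$accel_g)
  }
  if (max(abs(gyro)) > limits$gyro_dps) {
    warning(sprintf("%s: gyroscope samples beyond +/-%g dps clipped",
                    basename(path), limits$gyro_dps), call. = FALSE)
    gyro <- pmin(pmax(gyro, -limits$gyro_dps), limits$gyro_dps)
  }
  stream <- sensor_stream(df$time_s, accel, gyro, side, limits = limits)
  dt <- diff(stream$time_s)
  nominal <- median(dt)
  gaps <- which(dt > 3 * nominal)
  attr(stream, "gap_times") <- stream$time_s[gaps]
  stream
}

read_gnss_csv <- function(path) {
  df <- read_checked_csv(path, c("time_s", "speed_mps"))
  gnss_track(df$time_s, df$speed_mps)
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.csv(path)
  if (nrow(df) == 0L) {
    stop(sprintf("%s: file contains no data rows", basename(path)),
         call. = FALSE)
  }
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad)) {
    stop(sprintf("%s: timestamp not increasing at row %d", basename(path),
                 bad[1] + 1L), call. = FALSE)
  }
  df
}

#' Write a raw run to the three-file CSV layout read by [read_run()]
#'
#' @param run a [raw_run()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; files are `<prefix>_left.csv`,
#'   `<prefix>_right.csv`, `<prefix>_gnss.csv`.
#' @return Invisibly, the three file paths.
#' @export
write_run <- function(run, dir, prefix = run$skier_id) {
  stopifnot(inherits(run, "raw_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_left.csv", "_right.csv", "_gnss.csv")))
  for (i in 1:2) {
    s <- run[[c("left", "right")[i]]]
    df <- data.frame(time_s = s$time_s, s$accel, s$gyro)
    write.csv(df, paths[i], row.names = FALSE, quote = FALSE)
  }
  write.csv(data.frame(time_s = run$gnss$time_s, speed_mps = run$gnss$speed_mps),
            paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Persist a fitted reference model to JSON
#'
#' The model file is human-inspectable JSON with an explicit
#' `schema_version`; [load_model()] validates the schema and the model
#' invariants on read. Round-tripping preserves all numbers to full double
#' precision.
#'
#' @param model a [reference_model()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "reference_model"))
  cells <- lapply(model$cells, function(cell) {
    lapply(cell, function(vm) {
      list(mean_curve = vm$mean_curve,
           loadings = apply(vm$loadings, 1, identity, simplify = FALSE),
           varfrac = vm$varfrac, score_sd = vm$score_sd,
           n_ref = vm$n_ref, n_components = vm$n_components)
    })
  })
  obj <- list(schema_version = model$schema_version,
              fit_config = model$fit_config, cells = cells)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a reference model from JSON
#'
#' @param path file written by [save_model()].
#' @return A validated [reference_model()].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path), call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (is.null(obj$schema_version) || !identical(as.character(obj$schema_version), "1")) {
    stop(sprintf("unsupported model schema_version '%s' (expected \"1\")",
                 obj$schema_version), call. = FALSE)
  }
  cells <- lapply(obj$cells, function(cell) {
    lapply(cell, function(vm) {
      variable_model(
        mean_curve = vm$mean_curve,
        loadings = do.call(rbind, vm$loadings),
        varfrac = vm$varfrac,
        score_sd = vm$score_sd,
        n_ref = vm$n_ref,
        n_components = vm$n_components
      )
    })
  })
  reference_model(cells, fit_config = obj$fit_config, schema_version = "1")
}

#' Write turn scores to CSV
#'
#' One row per scored turn: `run_id, turn_index, style, size, percentage,
#' final_score` plus one absolute-Z column per (variable, PC), e.g.
#' `edge_angle_z1`. Unscorable turns carry `NA` in the numeric columns.
#'
#' @param scores a list of `turn_score` objects as returned by [score_run()].
#' @param path output file path.
#' @param run_id run identifier to repeat in every row.
#' @return Invisibly, the data frame written.
#' @export
write_scores <- function(scores, path, run_id = "run") {
  df <- scores_to_df(scores, run_id)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Convert a list of turn scores to a flat data frame
#' @inheritParams write_scores
#' @return A data frame, one row per turn.
#' @export
scores_to_df <- function(scores, run_id = "run") {
  zcols <- paste0(rep(SKI_VARIABLES, each = 3), "_z", rep(1:3, 4))
  if (length(scores) == 0L) {
    out <- data.frame(run_id = character(0), turn_index = integer(0),
                      style = character(0), size = character(0),
                      percentage = numeric(0), final_score = numeric(0))
    out[zcols] <- lapply(zcols, function(...) numeric(0))
    return(out)
  }
  rows <- lapply(seq_along(scores), function(i) {
    s <- scores[[i]]
    z <- rep(NA_real_, 12)
    if (!is.null(s$variables)) {
      z <- unlist(lapply(SKI_VARIABLES, function(v) s$variables[[v]]$z))
    }
    out <- data.frame(run_id = run_id, turn_index = i, style = s$style,
                      size = s$size %||% NA_character_,
                      percentage = s$percentage, final_score = s$final_score)
    out[zcols] <- as.list(z)
    out
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
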