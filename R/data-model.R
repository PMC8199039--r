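#' Construct a validated boot sensor stream
#'
#' One boot's IMU record: timestamps, 3-axis specific force in g (full scale
#' +/- 16 g) and 3-axis angular rate in deg/s (full scale +/- 1000 dps). Axis
#' convention follows the boot mounting: Y vertical (superior), X lateral
#' (right), Z posterior, so the Z gyro channel carries boot roll rate and the
#' Y gyro channel carries yaw rate.
#'
#' @param time_s numeric vector of timestamps in seconds, strictly increasing.
#' @param accel numeric matrix, n x 3, columns `ax_g`, `ay_g`, `az_g` in g.
#' @param gyro numeric matrix, n x 3, columns `gx_dps`, `gy_dps`, `gz_dps`.
#' @param side `"left"` or `"right"`.
#' @param limits list with `accel_g` and `gyro_dps` full-scale values.
#'
#' @return An object of class `sensor_stream`.
#' @export
sensor_stream <- function(time_s, accel, gyro, side,
                          limits = ski_config()$limits) {
  side <- match.arg(side, c("left", "right"))
  accel <- as.matrix(accel)
  gyro <- as.matrix(gyro)
  n <- length(time_s)
  if (n == 0L) stop("empty sensor stream", call. = FALSE)
  if (nrow(accel) != n || nrow(gyro) != n ||
      ncol(accel) != 3L || ncol(gyro) != 3L) {
    stop("accel and gyro must be n x 3 with n matching time_s", call. = FALSE)
  }
  bad <- which(diff(time_s) <= 0)
  if (length(bad)) {
    stop(sprintf("timestamps not strictly increasing at row %d", bad[1] + 1L),
         call. = FALSE)
  }
  if (anyNA(time_s) || anyNA(accel) || anyNA(gyro)) {
    stop("sensor stream contains missing values", call. = FALSE)
  }
  if (max(abs(accel)) > limits$accel_g + 1e-9) {
    stop(sprintf("accelerometer sample exceeds full scale +/-%g g",
                 limits$accel_g), call. = FALSE)
  }
  if (max(abs(gyro)) > limits$gyro_dps + 1e-9) {
    stop(sprintf("gyroscope sample exceeds full scale +/-%g dps",
                 limits$gyro_dps), call. = FALSE)
  }
  colnames(accel) <- c("ax_g", "ay_g", "az_g")
  colnames(gyro) <- c("gx_dps", "gy_dps", "gz_dps")
  structure(
    list(time_s = as.numeric(time_s), accel = accel, gyro = gyro, side = side),
    class = "sensor_stream"
  )
}

#' Nominal sampling rate of a sensor stream
#'
#' Recovered as the reciprocal of the median inter-sample interval.
#'
#' @param stream a [sensor_stream()].
#' @return Sampling rate in Hz.
#' @export
sample_rate <- function(stream) {
  stopifnot(inherits(stream, "sensor_stream"))
  1 / median(diff(stream$time_s))
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %s boot, %d samples @ %.1f Hz, %.1f-%.1f s\n",
              x$side, length(x$time_s), sample_rate(x),
              x$time_s[1], x$time_s[length(x$time_s)]))
  invisible(x)
}

#' Construct a validated GNSS speed track
#'
#' @param time_s timestamps in seconds at nominally 1 Hz, strictly increasing.
#' @param speed_mps non-negative speeds in m/s.
#' @return An object of class `gnss_track`.
#' @export
gnss_track <- function(time_s, speed_mps) {
  if (length(time_s) == 0L) stop("empty GNSS track", call. = FALSE)
  if (length(time_s) != length(speed_mps)) {
    stop("GNSS timestamps and speeds must have equal length", call. = FALSE)
  }
  bad <- which(diff(time_s) <= 0)
  if (length(bad)) {
    stop(sprintf("GNSS timestamps not strictly increasing at row %d",
                 bad[1] + 1L), call. = FALSE)
  }
  if (anyNA(speed_mps) || any(speed_mps < 0)) {
    stop("GNSS speeds must be non-negative and non-missing", call. = FALSE)
  }
  structure(list(time_s = as.numeric(time_s), speed_mps = as.numeric(speed_mps)),
            class = "gnss_track")
}

#' Construct a raw skiing run
#'
#' Bundles the two boot streams, the GNSS track and run metadata. The three
#' streams must overlap in time.
#'
#' @param left,right [sensor_stream()] objects for the two boots.
#' @param gnss a [gnss_track()].
#' @param skier_id character identifier.
#' @param intended_style optional run-level protocol label, one of
#'   `CL, CM, CS, DL, DM, DS, Max` (carving/drifting x long/medium/short,
#'   or a maximum-performance run).
#' @param body_mass body mass in kg. Radial force is reported in multiples of
#'   body weight so the mass cancels; the default 75 kg is kept only so an
#'   optional newton-scale output remains well defined.
#' @return An object of class `raw_run`.
#' @export
raw_run <- function(left, right, gnss, skier_id = "skier",
                    intended_style = NULL, body_mass = 75) {
  stopifnot(inherits(left, "sensor_stream"), inherits(right, "sensor_stream"),
            inherits(gnss, "gnss_track"))
  if (left$side != "left" || right$side != "right") {
    stop("left/right streams have mismatched side labels", call. = FALSE)
  }
  if (!is.null(intended_style)) {
    intended_style <- match.arg(intended_style,
                                c("CL", "CM", "CS", "DL", "DM", "DS", "Max"))
  }
  spans <- rbind(range(left$time_s), range(right$time_s), range(gnss$time_s))
  if (max(spans[, 1]) >= min(spans[, 2])) {
    stop("sensor and GNSS streams do not overlap in time", call. = FALSE)
  }
  if (!is.numeric(body_mass) || body_mass <= 0) {
    stop("body_mass must be positive", call. = FALSE)
  }
  structure(
    list(left = left, right = right, gnss = gnss, skier_id = skier_id,
         intended_style = intended_style, body_mass = body_mass),
    class = "raw_run"
  )
}

#' @export
print.raw_run <- function(x, ...) {
  cat(sprintf("<raw_run> skier %s%s\n", x$skier_id,
              if (is.null(x$intended_style)) "" else
                paste0(" (intended ", x$intended_style, ")")))
  print(x$left); print(x$right)
  cat(sprintf("  GNSS: %d fixes, speed %.1f-%.1f m/s\n",
              length(x$gnss$time_s), min(x$gnss$speed_mps),
              max(x$gnss$speed_mps)))
  invisible(x)
}

#' Construct a turn-segment table
#'
#' @param start_time,end_time segment boundaries in seconds.
#' @param direction `"left"`/`"right"`, alternating along a run.
#' @param mean_speed optional mean speed per segment in m/s.
#' @return A `data.frame` of class `turn_segments` with one row per turn.
#' @export
turn_segments <- function(start_time, end_time, direction,
                          mean_speed = NA_real_) {
  if (length(start_time) == 0L) {
    out <- data.frame(start_time = numeric(0), end_time = numeric(0),
                      direction = character(0), mean_speed = numeric(0))
    class(out) <- c("turn_segments", "data.frame")
    return(out)
  }
  stopifnot(all(end_time > start_time),
            all(direction %in% c("left", "right")))
  if (length(direction) > 1L &&
      any(direction[-1] == direction[-length(direction)])) {
    stop("consecutive turn directions must alternate", call. = FALSE)
  }
  out <- data.frame(start_time = start_time, end_time = end_time,
                    direction = direction,
                    mean_speed = rep_len(mean_speed, length(start_time)))
  class(out) <- c("turn_segments", "data.frame")
  out
}

#' Construct an enriched turn
#'
#' Holds the four time-normalized variable vectors of one turn (101 points
#' on 0-100 % turn duration) plus its labels: edge angle (deg), edge-angle
#' symmetry (deg, signed difference to the neighbouring opposite-direction
#' turn), radial force (multiples of body weight) and speed (m/s).
#'
#' @param edge_angle,symmetry,radial_force,speed numeric vectors of length 101.
#' @param style one of carving, drifting, non_parallel, snowplow,
#'   snowplow_steering.
#' @param size one of small, medium, large.
#' @param direction `"left"` or `"right"`.
#' @param mean_speed mean turn speed in m/s.
#' @param symmetry_missing `TRUE` when no opposite-direction neighbour
#'   existed and the symmetry vector was zero-filled.
#' @return An object of class `enriched_turn`.
#' @export
enriched_turn <- function(edge_angle, symmetry, radial_force, speed,
                          style, size, direction = "left",
                          mean_speed = NA_real_, symmetry_missing = FALSE) {
  vars <- list(edge_angle = edge_angle, symmetry = symmetry,
               radial_force = radial_force, speed = speed)
  for (nm in names(vars)) {
    v <- vars[[nm]]
    if (length(v) != N_NORM || anyNA(v)) {
      stop(sprintf("%s must be a complete vector of %d values", nm, N_NORM),
           call. = FALSE)
    }
  }
  if (any(speed < 0)) stop("speed entries must be non-negative", call. = FALSE)
  style <- match.arg(style, SKI_STYLES)
  size <- match.arg(size, SKI_SIZES)
  direction <- match.arg(direction, c("left", "right"))
  structure(
    c(lapply(vars, as.numeric),
      list(style = style, size = size, direction = direction,
           mean_speed = mean_speed, symmetry_missing = isTRUE(symmetry_missing))),
    class = "enriched_turn"
  )
}

#' @export
print.enriched_turn <- function(x, ...) {
  cat(sprintf(
    "<enriched_turn> %s/%s, %s turn, mean speed %.1f m/s, peak edge %.1f deg\n",
    x$style, x$size, x$direction, x$mean_speed, max(x$edge_angle)))
  invisible(x)
}

#' Construct a per-variable PCA reference cell
#'
#' The fitted principal-component description of one variable in one
#' (style, size) cell of the reference cohort: the mean curve, up to three
#' orthonormal loading vectors, the fraction of total variance each explains
#' and the standard deviation of the reference PC scores that defines the
#' scoring Z-scale.
#'
#' @param mean_curve numeric vector of length 101.
#' @param loadings 3 x 101 matrix; rows with `varfrac > 0` are mutually
#'   orthonormal; rank-deficient trailing rows are zero and flagged.
#' @param varfrac 3 non-increasing fractions of total variance, sum <= 1.
#' @param score_sd 3 reference PC-score standard deviations (n-1 denominator),
#'   positive wherever `varfrac > 0`.
#' @param n_ref number of reference turns behind the fit.
#' @param n_components effective number of fitted components (rank), <= 3.
#' @return An object of class `variable_model`.
#' @export
variable_model <- function(mean_curve, loadings, varfrac, score_sd, n_ref,
                           n_components = sum(varfrac > 0)) {
  loadings <- as.matrix(loadings)
  if (length(mean_curve) != N_NORM) {
    stop(sprintf("mean_curve must have %d entries", N_NORM), call. = FALSE)
  }
  if (!all(dim(loadings) == c(3L, N_NORM))) {
    stop(sprintf("loadings must be 3 x %d", N_NORM), call. = FALSE)
  }
  stopifnot(length(varfrac) == 3L, length(score_sd) == 3L)
  if (any(diff(varfrac) > 1e-12)) {
    stop("variance fractions must be non-increasing", call. = FALSE)
  }
  if (any(varfrac < -1e-12) || sum(varfrac) > 1 + 1e-8) {
    stop("variance fractions must lie in [0, 1] and sum to at most 1",
         call. = FALSE)
  }
  active <- seq_len(n_components)
  if (n_components > 0L) {
    gram <- loadings[active, , drop = FALSE] %*% t(loadings[active, , drop = FALSE])
    if (max(abs(gram - diag(n_components))) > 1e-8) {
      stop("active loading rows are not orthonormal (tolerance 1e-8)",
           call. = FALSE)
    }
    if (any(score_sd[active] <= 0)) {
      stop("score_sd must be positive for fitted components", call. = FALSE)
    }
  }
  structure(
    list(mean_curve = as.numeric(mean_curve), loadings = loadings,
         varfrac = as.numeric(varfrac), score_sd = as.numeric(score_sd),
         n_ref = as.integer(n_ref), n_components = as.integer(n_components)),
    class = "variable_model"
  )
}

#' Cell key used to index a reference model
#' @param style,size turn labels.
#' @return A character scalar like `"carving.small"`.
#' @export
cell_key <- function(style, size) paste(style, size, sep = ".")

#' Construct a reference scoring model
#'
#' The persisted "gold standard": a [variable_model()] for each of the four
#' variables in every fitted (style, size) cell, where style is carving or
#' drifting.
#'
#' @param cells named list; element `"<style>.<size>"` is itself a named list
#'   with all four entries `edge_angle`, `symmetry`, `radial_force`, `speed`.
#' @param fit_config the configuration list used for the fit (echoed).
#' @param schema_version persistence schema version, currently `"1"`.
#' @return An object of class `reference_model`.
#' @export
reference_model <- function(cells, fit_config = ski_config(),
                            schema_version = "1") {
  if (length(cells) == 0L) {
    stop("reference model has no fitted cells", call. = FALSE)
  }
  for (key in names(cells)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !parts[1] %in% c("carving", "drifting") ||
        !parts[2] %in% SKI_SIZES) {
      stop(sprintf("invalid cell key '%s'", key), call. = FALSE)
    }
    missing_vars <- setdiff(SKI_VARIABLES, names(cells[[key]]))
    if (length(missing_vars)) {
      stop(sprintf("cell '%s' is incomplete: missing %s", key,
                   paste(missing_vars, collapse = ", ")), call. = FALSE)
    }
    for (v in SKI_VARIABLES) {
      if (!inherits(cells[[key]][[v]], "variable_model")) {
        stop(sprintf("cell '%s' variable '%s' is not a variable_model",
                     key, v), call. = FALSE)
      }
    }
  }
  structure(list(cells = cells, fit_config = fit_config,
                 schema_version = schema_version),
            class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("<reference_model> schema %s, %d cell(s)\n",
              x$schema_version, length(x$cells)))
  for (key in names(x$cells)) {
    n <- x$cells[[key]]$edge_angle$n_ref
    cum3 <- vapply(x$cells[[key]], function(vm) sum(vm$varfrac), numeric(1))
    cat(sprintf("  %-18s n=%d, cum. varfrac PC1-3: %s\n", key, n,
                paste(sprintf("%s %.2f", names(cum3), cum3), collapse = ", ")))
  }
  invisible(x)
}

#' @export
print.turn_score <- function(x, ...) {
  if (!is.na(x$final_score) && is.na(x$percentage)) {
    cat(sprintf("<turn_score> %s: constant score %.0f\n", x$style, x$final_score))
  } else if (is.na(x$final_score)) {
    cat(sprintf("<turn_score> unscorable (%s)\n", x$reason))
  } else {
    cat(sprintf("<turn_score> %s/%s: %.1f%% -> final %.2f\n",
                x$style, x$size, x$percentage, x$final_score))
  }
  invisible(x)
}
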