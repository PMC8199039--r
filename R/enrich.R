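#' Estimate boot roll (edge) angle with a complementary filter
#'
#' Edge angle is approximated by the boot roll angle relative to gravity.
#' The gravity-referenced roll from the accelerometer,
#' `theta_acc = atan2(ax, ay)` (lateral over vertical specific force), is
#' fused with the integrated roll-rate gyro (boot Z channel):
#' `theta_t = alpha * (theta_{t-1} + gz * dt) + (1 - alpha) * theta_acc_t`.
#' The filter runs over the whole stream, with the state initialised at the
#' first accelerometer roll so a static posture is tracked immediately, and
#' the edging magnitude `|theta|` is returned.
#'
#' @param stream a [sensor_stream()].
#' @param alpha complementary-filter weight on the gyro path, in (0, 1).
#' @param segment optional one-row piece of a [turn_segments()] frame; when
#'   given, only samples within the segment are returned.
#' @return A list with `time_s` and `angle_deg` (non-negative).
#' @export
estimate_edge_angle <- function(stream, alpha = 0.98, segment = NULL) {
  stopifnot(inherits(stream, "sensor_stream"), alpha > 0, alpha < 1)
  t <- stream$time_s
  theta_acc <- atan2(stream$accel[, "ax_g"], stream$accel[, "ay_g"]) * 180 / pi
  gz <- stream$gyro[, "gz_dps"]
  n <- length(t)
  theta <- numeric(n)
  theta[1] <- theta_acc[1]
  for (i in 2:n) {
    dt <- t[i] - t[i - 1]
    theta[i] <- alpha * (theta[i - 1] + gz[i] * dt) + (1 - alpha) * theta_acc[i]
  }
  out <- list(time_s = t, angle_deg = abs(theta))
  if (!is.null(segment)) {
    if (segment$start_time < t[1] || segment$end_time > t[n]) {
      stop("segment lies outside the sensor stream", call. = FALSE)
    }
    sel <- t >= segment$start_time & t <= segment$end_time
    out <- list(time_s = t[sel], angle_deg = out$angle_deg[sel])
  }
  out
}

#' Edge-angle symmetry between consecutive opposite-direction turns
#'
#' Pointwise signed difference, on the normalized time base, between the
#' current turn's edge-angle profile and that of the neighbouring turn of
#' opposite direction (left-right turn difference).
#'
#' @param current,previous_opposite numeric vectors of length 101.
#' @return A numeric vector of length 101.
#' @export
estimate_symmetry <- function(current, previous_opposite) {
  stopifnot(length(current) == N_NORM, length(previous_opposite) == N_NORM)
  current - previous_opposite
}

#' Radial force in multiples of body weight
#'
#' Centripetal load approximated pointwise from speed and yaw rate:
#' `F/BW = v * |omega_yaw| / g` with `g = 9.80665` m/s^2. Body mass cancels.
#'
#' @param speed_mps speeds in m/s, non-negative.
#' @param yaw_rate_rads yaw rate in rad/s (sign is ignored).
#' @return A numeric vector of the same length.
#' @export
estimate_radial_force <- function(speed_mps, yaw_rate_rads) {
  stopifnot(length(speed_mps) == length(yaw_rate_rads))
  if (any(speed_mps < 0)) stop("speeds must be non-negative", call. = FALSE)
  speed_mps * abs(yaw_rate_rads) / G_ACCEL
}

#' Interpolate the 1 Hz GNSS speed onto IMU sample times
#'
#' Piecewise-linear interpolation; targets outside the GNSS span are clamped
#' to the first/last fix.
#'
#' @param gnss a [gnss_track()].
#' @param target_times times (s) at which speed is wanted.
#' @return Speeds in m/s at `target_times`.
#' @export
interpolate_speed <- function(gnss, target_times) {
  stopifnot(inherits(gnss, "gnss_track"))
  if (length(gnss$time_s) == 1L) {
    return(rep(gnss$speed_mps, length(target_times)))
  }
  approx(gnss$time_s, gnss$speed_mps, xout = target_times, rule = 2)$y
}

#' Enrich every retained turn of a run
#'
#' Computes the four scoring variables for each segment and time-normalizes
#' them to 101 points. Edge angle comes from the outside boot of each turn
#' (left turn -> right boot) or the per-boot mean, per config. Yaw rate is the
#' outside boot's vertical (Y) gyro channel. Symmetry compares each turn's
#' edge-angle profile to the previous opposite-direction turn (the following
#' one for the first turn); with no opposite-direction neighbour at all the
#' symmetry vector is zero-filled and flagged.
#'
#' Style comes from `labels` when provided (pass-through, as when an external
#' classifier supplies them) and otherwise from the naive built-in rule in
#' [classify_style()]; size from per-turn radius thresholds ([assign_size()]).
#'
#' @param run a [raw_run()].
#' @param segments retained [turn_segments()] (see [filter_turns()]).
#' @param labels optional character vector of style labels, one per segment.
#' @param config a [ski_config()] list.
#' @return A list of [enriched_turn()] objects.
#' @export
enrich_run <- function(run, segments, labels = NULL, config = ski_config()) {
  stopifnot(inherits(run, "raw_run"))
  n <- nrow(segments)
  if (n == 0L) return(list())
  if (!is.null(labels) && length(labels) != n) {
    stop("labels must have one entry per segment", call. = FALSE)
  }
  alpha <- config$enrich$alpha
  edge_full <- list(left = estimate_edge_angle(run$left, alpha),
                    right = estimate_edge_angle(run$right, alpha))

  per_turn <- vector("list", n)
  for (i in seq_len(n)) {
    seg <- segments[i, , drop = FALSE]
    outside <- if (seg$direction == "left") "right" else "left"
    boots <- if (config$enrich$edge_boot == "mean") c("left", "right") else outside

    edge101 <- rowMeans(vapply(boots, function(b) {
      s <- run[[b]]
      sel <- s$time_s >= seg$start_time & s$time_s <= seg$end_time
      if (sum(sel) < 2L) stop("segment contains too few samples", call. = FALSE)
      time_normalize(edge_full[[b]]$angle_deg[sel], edge_full[[b]]$time_s[sel])
    }, numeric(N_NORM)))

    ob <- run[[outside]]
    sel <- ob$time_s >= seg$start_time & ob$time_s <= seg$end_time
    tt <- ob$time_s[sel]
    v <- interpolate_speed(run$gnss, tt)
    yaw <- ob$gyro[sel, "gy_dps"] * pi / 180
    force101 <- time_normalize(estimate_radial_force(v, yaw), tt)
    speed101 <- pmax(time_normalize(v, tt), 0)

    mean_speed <- if (is.na(seg$mean_speed)) mean(v) else seg$mean_speed
    size <- assign_size(mean_speed, mean(abs(yaw)))
    per_turn[[i]] <- list(edge = edge101, force = force101, speed = speed101,
                          size = size, mean_speed = mean_speed,
                          mean_yaw = mean(abs(yaw)))
  }

  turns <- vector("list", n)
  for (i in seq_len(n)) {
    opp <- which(segments$direction != segments$direction[i])
    nb <- NA_integer_
    if (any(opp < i)) nb <- max(opp[opp < i]) else if (length(opp)) nb <- min(opp)
    if (is.na(nb)) {
      sym101 <- rep(0, N_NORM)
      sym_missing <- TRUE
    } else {
      sym101 <- estimate_symmetry(per_turn[[i]]$edge, per_turn[[nb]]$edge)
      sym_missing <- FALSE
    }
    turn <- enriched_turn(
      edge_angle = per_turn[[i]]$edge, symmetry = sym101,
      radial_force = per_turn[[i]]$force, speed = per_turn[[i]]$speed,
      style = "drifting", size = per_turn[[i]]$size,
      direction = segments$direction[i],
      mean_speed = per_turn[[i]]$mean_speed, symmetry_missing = sym_missing
    )
    turn$style <- classify_style(
      turn, label = if (is.null(labels)) NULL else labels[i],
      carve_angle_min = config$classify$carve_angle_min
    )
    turns[[i]] <- turn
  }
  turns
}
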