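#' Detect turn boundaries from the roll-axis gyroscope signal
#'
#' Under the pendulum model of skiing the legs roll from one edge set to the
#' other once per turn, so the roll-rate signal shows one dominant extremum
#' of alternating sign at every edge change. The signal is low-pass filtered
#' (zero-phase 2nd-order Butterworth), all local extrema whose absolute
#' filtered roll rate reaches `min_prominence_dps` are collected, and
#' consecutive extrema are forced to alternate in sign and to be at least
#' `min_period_s` apart (the larger-magnitude extremum wins a conflict). A
#' turn spans one extremum to the next.
#'
#' @param time_s sample timestamps in seconds.
#' @param roll_dps roll-axis angular rate in deg/s (boot Z gyro channel).
#' @param lowpass_hz Butterworth cutoff in Hz.
#' @param min_prominence_dps minimum absolute filtered roll rate at a
#'   boundary extremum, deg/s. Measured from the zero baseline: the filtered
#'   roll rate of cyclic skiing oscillates about zero, so peak height above
#'   zero is the natural prominence scale.
#' @param min_period_s minimum boundary separation (= minimum turn duration).
#' @return A [turn_segments()] data frame (possibly empty) with a
#'   `boundary_times` attribute giving the extremum times. Direction
#'   convention: a positive roll-rate extremum starts a `"left"` turn.
#' @export
detect_turn_boundaries <- function(time_s, roll_dps,
                                   lowpass_hz = 2,
                                   min_prominence_dps = 15,
                                   min_period_s = 0.6) {
  stopifnot(length(time_s) == length(roll_dps),
            lowpass_hz > 0, min_prominence_dps > 0, min_period_s > 0)
  fs <- 1 / median(diff(time_s))
  # filtfilt needs ~3x the filter order of padding; require a modest warm-up
  if (length(roll_dps) < 24L ||
      (time_s[length(time_s)] - time_s[1]) < 2 * min_period_s) {
    stop("series too short for boundary detection (filter warm-up)",
         call. = FALSE)
  }
  bf <- signal::butter(2, W = min(lowpass_hz / (fs / 2), 0.99))
  xf <- signal::filtfilt(bf, roll_dps)

  d <- diff(xf)
  idx <- which(d[-length(d)] * d[-1] < 0 | (d[-length(d)] != 0 & d[-1] == 0)) + 1L
  idx <- idx[abs(xf[idx]) >= min_prominence_dps]
  if (length(idx) == 0L) {
    return(structure(turn_segments(numeric(0), numeric(0), character(0)),
                     boundary_times = numeric(0)))
  }

  kept <- idx[1]
  for (i in idx[-1]) {
    last <- kept[length(kept)]
    if (sign(xf[i]) == sign(xf[last]) ||
        (time_s[i] - time_s[last]) < min_period_s) {
      if (abs(xf[i]) > abs(xf[last])) kept[length(kept)] <- i
    } else {
      kept <- c(kept, i)
    }
  }
  bt <- time_s[kept]
  if (length(kept) < 2L) {
    return(structure(turn_segments(numeric(0), numeric(0), character(0)),
                     boundary_times = bt))
  }
  dir <- ifelse(xf[kept[-length(kept)]] > 0, "left", "right")
  segs <- turn_segments(start_time = bt[-length(bt)], end_time = bt[-1],
                        direction = dir)
  structure(segs, boundary_times = bt)
}

#' Segment a run into turns and attach mean speeds
#'
#' Runs [detect_turn_boundaries()] on the configured boot's roll gyro channel
#' and fills each segment's mean speed from the linearly interpolated GNSS
#' track.
#'
#' @param run a [raw_run()].
#' @param config a [ski_config()] list.
#' @return A [turn_segments()] data frame with `mean_speed` filled in.
#' @export
segment_run <- function(run, config = ski_config()) {
  stopifnot(inherits(run, "raw_run"))
  boot <- run[[match.arg(config$segmentation$boot, c("left", "right"))]]
  segs <- detect_turn_boundaries(
    boot$time_s, boot$gyro[, "gz_dps"],
    lowpass_hz = config$segmentation$lowpass_hz,
    min_prominence_dps = config$segmentation$min_prominence_dps,
    min_period_s = config$segmentation$min_period_s
  )
  if (nrow(segs) == 0L) return(segs)
  segs$mean_speed <- vapply(seq_len(nrow(segs)), function(i) {
    sel <- boot$time_s >= segs$start_time[i] & boot$time_s <= segs$end_time[i]
    mean(interpolate_speed(run$gnss, boot$time_s[sel]))
  }, numeric(1))
  segs
}

#' Apply the turn-exclusion rules
#'
#' The first and last detected turn of a run are always dropped (the skier is
#' accelerating or braking there). Among the remaining interior turns, a turn
#' is additionally dropped iff its mean speed is more than one raw median
#' absolute deviation below the interior median speed:
#' `mean_speed < median(s) - median(|s - median(s)|)` (strict inequality, no
#' consistency constant). Order is preserved.
#'
#' @param segments a [turn_segments()] data frame with `mean_speed` filled.
#' @param mad_rule apply the slow-turn rule (default `TRUE`).
#' @return The retained subset of `segments`.
#' @export
filter_turns <- function(segments, mad_rule = TRUE) {
  if (nrow(segments) < 3L) {
    warning("fewer than 3 segments: nothing retained", call. = FALSE)
    return(segments[0, , drop = FALSE])
  }
  interior <- segments[-c(1L, nrow(segments)), , drop = FALSE]
  if (isTRUE(mad_rule)) {
    s <- interior$mean_speed
    if (anyNA(s)) stop("mean_speed required for the exclusion rule", call. = FALSE)
    med <- median(s)
    mad_raw <- median(abs(s - med))
    interior <- interior[!(s < med - mad_raw), , drop = FALSE]
  }
  interior
}

#' Time-normalize a turn signal to 101 points
#'
#' Linear interpolation of the sampled signal onto 101 equally spaced points
#' spanning 0-100 % of turn duration. Endpoints are preserved exactly.
#'
#' @param x sampled values over one turn.
#' @param time_s optional sample times; equal spacing is assumed when absent.
#' @return A numeric vector of length 101.
#' @export
time_normalize <- function(x, time_s = NULL) {
  if (length(x) < 2L) {
    stop("time_normalize needs at least 2 samples", call. = FALSE)
  }
  if (is.null(time_s)) time_s <- seq_along(x)
  stopifnot(length(time_s) == length(x))
  approx(time_s, x, xout = seq(time_s[1], time_s[length(time_s)],
                               length.out = N_NORM))$y
}
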