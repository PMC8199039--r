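#' Parameters of the synthetic skiing-data generators
#'
#' Bundles everything the seeded generators need. Mode SDs are the standard
#' deviations of the per-turn coefficients on the three variability modes
#' (magnitude, timing, single-vs-double peak); the modes themselves are
#' scaled to unit peak amplitude, so mode SDs and the per-sample white-noise
#' SD are both in the natural units of each variable (degrees, multiples of
#' body weight, m/s).
#'
#' @param n_turns number of turns in a generated raw run.
#' @param turn_period turn duration in seconds.
#' @param mode_sds named list, per variable, of 3 decreasing mode SDs.
#' @param noise_sd named list, per variable, of the additive white-noise SD.
#' @param skill_offset shift of the mode-coefficient draws, in units of each
#'   mode SD: coefficients are drawn from `N(skill_offset * sd_k, sd_k^2)`.
#'   0 reproduces the reference ("gold standard") population.
#' @param peak_roll_deg peak boot roll angle per turn in a raw run, degrees.
#' @param gyro_noise_dps,accel_noise_g sensor noise SDs for raw runs.
#' @param speed_drift_mps amplitude of the slow sinusoidal speed drift over a
#'   raw run, m/s; 0 gives a perfectly steady run.
#' @param seed integer seed; every generator draw is reproducible from it.
#' @return A list of class `synthetic_params`.
#' @export
synthetic_params <- function(n_turns = 10,
                             turn_period = 2,
                             mode_sds = list(
                               edge_angle = c(8, 3, 1.5),
                               symmetry = c(3, 1.5, 0.8),
                               radial_force = c(0.30, 0.12, 0.06),
                               speed = c(1.5, 0.5, 0.25)
                             ),
                             noise_sd = list(
                               edge_angle = 0.8, symmetry = 0.3,
                               radial_force = 0.03, speed = 0.15
                             ),
                             skill_offset = 0,
                             peak_roll_deg = 40,
                             gyro_noise_dps = 2,
                             accel_noise_g = 0.02,
                             speed_drift_mps = 0.5,
                             seed = 1L) {
  stopifnot(n_turns >= 1, turn_period > 0, peak_roll_deg > 0)
  for (v in SKI_VARIABLES) {
    s <- mode_sds[[v]]
    if (length(s) != 3L || any(s <= 0) || any(diff(s) > 0)) {
      stop(sprintf("mode_sds$%s must be 3 positive non-increasing values", v),
           call. = FALSE)
    }
    if (length(noise_sd[[v]]) != 1L || noise_sd[[v]] < 0) {
      stop(sprintf("noise_sd$%s must be a non-negative scalar", v),
           call. = FALSE)
    }
  }
  structure(list(n_turns = n_turns, turn_period = turn_period,
                 mode_sds = mode_sds, noise_sd = noise_sd,
                 skill_offset = skill_offset, peak_roll_deg = peak_roll_deg,
                 gyro_noise_dps = gyro_noise_dps,
                 accel_noise_g = accel_noise_g,
                 speed_drift_mps = speed_drift_mps, seed = as.integer(seed)),
            class = "synthetic_params")
}

#' The three ground-truth variability modes on the 101-point base
#'
#' Built from a Gaussian bump (magnitude mode), its first derivative (timing
#' mode) and a Mexican-hat second-derivative shape (width / single-vs-double
#' peak mode), Gram-Schmidt orthogonalized and rescaled to unit peak
#' amplitude. Deterministic: no randomness.
#'
#' @return A 3 x 101 matrix of mutually orthogonal rows with `max(|row|) = 1`.
#' @export
turn_modes <- function() {
  t <- seq(0, 1, length.out = N_NORM)
  u <- (t - 0.5)
  raw <- rbind(
    exp(-0.5 * (u / 0.16)^2),
    -u / 0.16^2 * exp(-0.5 * (u / 0.16)^2),
    (1 - (u / 0.12)^2) * exp(-0.5 * (u / 0.12)^2)
  )
  for (j in 2:3) {
    for (i in seq_len(j - 1)) {
      raw[j, ] <- raw[j, ] -
        sum(raw[j, ] * raw[i, ]) / sum(raw[i, ]^2) * raw[i, ]
    }
  }
  sweep(raw, 1, apply(abs(raw), 1, max), "/")
}

# Mean curves by style and size: bell-shaped edge angle and radial force,
# mid-turn slowdown in speed, zero symmetry. Speeds and radii follow the
# size classes (small ~7 m/s on ~6 m, medium ~10 on ~10, large ~13 on ~14).
synthetic_mean_curves <- function(style, size) {
  t <- seq(0, 1, length.out = N_NORM)
  bump <- exp(-0.5 * ((t - 0.5) / 0.25)^2)
  v0 <- c(small = 7, medium = 10, large = 13)[[size]]
  r0 <- c(small = 5.5, medium = 9, large = 15)[[size]]
  edge_peak <- if (style == "carving") 55 else 25
  list(
    edge_angle = 3 + edge_peak * bump,
    symmetry = rep(0, N_NORM),
    radial_force = 0.05 + v0^2 / (r0 * G_ACCEL) * bump,
    speed = v0 - 0.8 * bump
  )
}

#' Generate one enriched turn with known mode coefficients
#'
#' Each variable is built as `x = mu + a1*phi1 + a2*phi2 + a3*phi3 + eps`
#' where the `phi_k` are the orthogonal modes of [turn_modes()], the
#' coefficients are drawn from `N(skill_offset * sd_k, sd_k^2)` and `eps` is
#' white noise. Coefficients are returned as ground truth for parameter-
#' recovery tests.
#'
#' @param params a [synthetic_params()].
#' @param style,size labels of the generated turn.
#' @param direction turn direction label.
#' @param seed optional seed; when `NULL` the current RNG state is used (as
#'   when called from [generate_cohort()]).
#' @return An [enriched_turn()] with attribute `truth`, a 4 x 3 matrix of
#'   mode coefficients (rows = variables).
#' @export
generate_turn_curves <- function(params, style = "carving", size = "medium",
                                 direction = "left", seed = NULL) {
  stopifnot(inherits(params, "synthetic_params"))
  if (!is.null(seed)) set.seed(seed)
  phi <- turn_modes()
  mu <- synthetic_mean_curves(style, size)
  truth <- matrix(NA_real_, 4, 3,
                  dimnames = list(SKI_VARIABLES, paste0("a", 1:3)))
  vals <- list()
  for (v in SKI_VARIABLES) {
    sds <- params$mode_sds[[v]]
    a <- rnorm(3, mean = params$skill_offset * sds, sd = sds)
    truth[v, ] <- a
    x <- mu[[v]] + drop(a %*% phi) +
      rnorm(N_NORM, sd = params$noise_sd[[v]])
    if (v == "speed") x <- pmax(x, 0)
    vals[[v]] <- x
  }
  turn <- enriched_turn(vals$edge_angle, vals$symmetry, vals$radial_force,
                        vals$speed, style = style, size = size,
                        direction = direction,
                        mean_speed = mean(vals$speed))
  attr(turn, "truth") <- truth
  turn
}

#' Generate a labelled cohort of enriched turns
#'
#' Independent draws of [generate_turn_curves()] for each requested
#' (style, size) cell, reproducible from the seed.
#'
#' @param params a [synthetic_params()].
#' @param n_per_cell turns per cell.
#' @param cells list of `c(style, size)` pairs.
#' @param seed integer seed (defaults to `params$seed`).
#' @return A list of [enriched_turn()] objects with attribute `truth`: a data
#'   frame with columns `cell`, `index`, `variable`, `a1`, `a2`, `a3`.
#' @export
generate_cohort <- function(params, n_per_cell = 200,
                            cells = list(c("carving", "small"),
                                         c("drifting", "large")),
                            seed = params$seed) {
  stopifnot(inherits(params, "synthetic_params"), n_per_cell >= 1)
  set.seed(seed)
  turns <- list()
  truth <- list()
  for (cell in cells) {
    style <- cell[1]; size <- cell[2]
    key <- cell_key(style, size)
    for (i in seq_len(n_per_cell)) {
      turn <- generate_turn_curves(params, style = style, size = size,
                                   direction = c("left", "right")[1 + i %% 2])
      co <- attr(turn, "truth")
      truth[[length(truth) + 1L]] <- data.frame(
        cell = key, index = i, variable = rownames(co),
        a1 = co[, 1], a2 = co[, 2], a3 = co[, 3], row.names = NULL)
      turns[[length(turns) + 1L]] <- turn
    }
  }
  attr(turns, "truth") <- do.call(rbind, truth)
  turns
}

#' Generate a raw two-boot IMU + GNSS run with known turn boundaries
#'
#' The boot roll angle follows the pendulum model: within turn i,
#' `theta(t) = s_i * Theta_i * sin(pi (t - t_i) / P)` with alternating sign
#' `s_i`, so the roll-rate signal has one extremum of alternating sign at
#' every turn boundary `t_i` and the accelerometer channels
#' (`ax = sin theta`, `ay = cos theta` in g) are consistent with the gyro.
#' Yaw rate alternates with the turn direction at the magnitude implied by
#' the size's speed and radius (with short ramps); GNSS speed is sampled at
#' 1 Hz from a slowly drifting profile. Sensor noise is additive white noise.
#'
#' @param params a [synthetic_params()].
#' @param size turn-size class controlling speed and radius.
#' @param slow_turn optional index of one turn whose speed is halved, to
#'   exercise the slow-turn exclusion rule.
#' @param seed integer seed (defaults to `params$seed`).
#' @param fs IMU sampling rate in Hz.
#' @return A [raw_run()] with attribute `truth`: `boundary_times`,
#'   `directions` and `mean_speeds` per turn.
#' @export
generate_raw_run <- function(params, size = "medium", slow_turn = NA,
                             seed = params$seed, fs = 54) {
  stopifnot(inherits(params, "synthetic_params"), params$n_turns >= 3)
  P <- params$turn_period
  if (P * fs < 4) stop("turn_period too short for the sampling rate", call. = FALSE)
  set.seed(seed)
  n_turns <- params$n_turns
  lead <- 2
  t_end <- lead + n_turns * P + lead
  tt <- seq(0, t_end, by = 1 / fs)
  bounds <- lead + (0:n_turns) * P
  sgn <- rep_len(c(1, -1), n_turns)

  v0 <- c(small = 7, medium = 10, large = 13)[[size]]
  r0 <- c(small = 5.5, medium = 9, large = 15)[[size]]
  speed_t <- v0 + params$speed_drift_mps * sin(2 * pi * tt / t_end)
  if (!is.na(slow_turn)) {
    stopifnot(slow_turn >= 1, slow_turn <= n_turns)
    in_turn <- tt >= bounds[slow_turn] & tt < bounds[slow_turn + 1]
    speed_t[in_turn] <- speed_t[in_turn] * 0.5
  }

  theta <- numeric(length(tt))
  roll_rate <- numeric(length(tt))
  yaw_rate <- numeric(length(tt))
  amp <- params$peak_roll_deg + rnorm(n_turns, sd = 1.5)
  for (i in seq_len(n_turns)) {
    sel <- tt >= bounds[i] & tt < bounds[i + 1]
    u <- (tt[sel] - bounds[i]) / P
    theta[sel] <- sgn[i] * amp[i] * sin(pi * u)
    roll_rate[sel] <- sgn[i] * amp[i] * (pi / P) * cos(pi * u)
    ramp <- pmin(1, pmin(u, 1 - u) / 0.15)
    yaw_rate[sel] <- sgn[i] * (speed_t[sel] / r0) * ramp * 180 / pi
  }

  make_stream <- function(side) {
    th_rad <- theta * pi / 180
    accel <- cbind(sin(th_rad), cos(th_rad), 0) +
      matrix(rnorm(3 * length(tt), sd = params$accel_noise_g), ncol = 3)
    gyro <- cbind(0, yaw_rate, roll_rate) +
      matrix(rnorm(3 * length(tt), sd = params$gyro_noise_dps), ncol = 3)
    sensor_stream(tt, accel, gyro, side)
  }
  left <- make_stream("left")
  right <- make_stream("right")
  gnss_t <- seq(0, floor(t_end), by = 1)
  gnss <- gnss_track(gnss_t, pmax(approx(tt, speed_t, xout = gnss_t)$y, 0))

  mean_speeds <- vapply(seq_len(n_turns), function(i) {
    sel <- tt >= bounds[i] & tt < bounds[i + 1]
    mean(speed_t[sel])
  }, numeric(1))

  run <- raw_run(left, right, gnss, skier_id = "synthetic")
  attr(run, "truth") <- list(
    boundary_times = bounds,
    directions = ifelse(sgn > 0, "left", "right"),
    mean_speeds = mean_speeds
  )
  run
}
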