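#' Assign a turn-size class from mean speed and yaw rate
#'
#' The turn radius is estimated as `r = mean_speed / mean_yaw` and mapped to
#' the snow-cat-width size classes: large for r > 12 m, medium for
#' 8 m <= r <= 12 m, small for r < 8 m. The medium band is closed on both
#' ends so every radius maps to exactly one class.
#'
#' @param mean_speed mean turn speed, m/s.
#' @param mean_yaw mean absolute yaw rate, rad/s.
#' @return `"small"`, `"medium"` or `"large"`; a zero yaw rate (straight
#'   glide) yields `"large"` with attribute `straight_glide = TRUE`.
#' @export
assign_size <- function(mean_speed, mean_yaw) {
  stopifnot(mean_speed >= 0, mean_yaw >= 0)
  if (mean_yaw == 0) {
    return(structure("large", straight_glide = TRUE))
  }
  r <- mean_speed / mean_yaw
  if (r > 12) "large" else if (r >= 8) "medium" else "small"
}

#' Assign a turn style
#'
#' When `label` is provided (e.g. from an external classification algorithm)
#' it is validated and returned verbatim. Otherwise a deliberately naive
#' demonstration rule is applied: a turn is called carving when its mean edge
#' angle reaches `carve_angle_min` degrees and its radial-force waveform is
#' single-peaked, and drifting otherwise. The built-in rule never returns
#' non_parallel or the snowplow classes; those require external labels.
#'
#' @param enriched an [enriched_turn()].
#' @param label optional externally supplied style label.
#' @param carve_angle_min mean edge angle threshold for carving, degrees.
#' @return A style string.
#' @export
classify_style <- function(enriched, label = NULL, carve_angle_min = 30) {
  if (!is.null(label)) {
    if (!label %in% SKI_STYLES) {
      stop(sprintf("unknown style label '%s'", label), call. = FALSE)
    }
    return(label)
  }
  if (mean(enriched$edge_angle) >= carve_angle_min &&
      is_single_peaked(enriched$radial_force)) "carving" else "drifting"
}

# Single-peak test on a 101-point waveform: lightly smooth, then count local
# maxima whose topographic prominence exceeds 25 % of the waveform range.
# Prominence (height above the deeper of the two flanking valleys up to the
# nearest higher ground) ignores the small noise wiggles riding on a broad
# peak that a plain height criterion would count.
is_single_peaked <- function(x) {
  k <- rep(1 / 9, 9)
  xs <- stats::filter(x, k, sides = 2)
  xs[is.na(xs)] <- x[is.na(xs)]
  xs <- as.numeric(xs)
  rng <- max(xs) - min(xs)
  if (rng == 0) return(TRUE)
  d <- diff(xs)
  peaks <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  prom <- vapply(peaks, function(i) {
    h <- xs[i]
    left <- xs[seq_len(i - 1L)]
    right <- xs[seq.int(i + 1L, length(xs))]
    higher_l <- which(left > h)
    key_l <- if (length(higher_l)) min(left[seq.int(max(higher_l), i - 1L)]) else min(left)
    higher_r <- which(right > h)
    key_r <- if (length(higher_r)) min(right[seq_len(min(higher_r))]) else min(right)
    h - max(key_l, key_r)
  }, numeric(1))
  sum(prom > 0.25 * rng) <= 1L
}
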