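#' Default configuration for the skiing processing chain
#'
#' Returns the nested list of tunable parameters used throughout the
#' pipeline. Any element can be overridden by name, e.g.
#' `ski_config(segmentation = list(min_prominence_dps = 20))`; unnamed
#' elements keep their defaults.
#'
#' @param ... named overrides, merged recursively into the defaults.
#'
#' @return A nested list with components:
#' \describe{
#'   \item{segmentation}{`lowpass_hz` (zero-phase Butterworth cutoff, Hz;
#'     default 2), `min_prominence_dps` (minimum absolute roll-rate at a
#'     boundary extremum, deg/s; default 15), `min_period_s` (minimum turn
#'     duration / boundary separation, s; default 0.6), `boot` (which boot's
#'     roll gyro drives segmentation; default `"left"`).}
#'   \item{filter}{`mad_rule` (apply the slow-turn exclusion rule; default
#'     `TRUE`).}
#'   \item{enrich}{`alpha` (complementary-filter weight on the gyro path;
#'     default 0.98), `edge_boot` (`"outside"` or `"mean"`; default
#'     `"outside"`).}
#'   \item{classify}{`carve_angle_min` (mean edge angle, degrees, above which
#'     the naive style rule calls a turn carving; default 30), `size_by`
#'     (`"turn"` for per-turn radius thresholds or `"run"` to honour the
#'     run's intended size label; default `"turn"`).}
#'   \item{model}{`n_pcs` (retained principal components; default 3),
#'     `min_ref_turns` (minimum reference turns per style/size cell;
#'     default 10).}
#'   \item{limits}{`accel_g`, `gyro_dps` (sensor full-scale values used to
#'     clip out-of-range samples on read; defaults 16 and 1000).}
#' }
#' @export
#' @examples
#' cfg <- ski_config(segmentation = list(lowpass_hz = 3))
#' cfg$segmentation$lowpass_hz
ski_config <- function(...) {
  defaults <- list(
    segmentation = list(
      lowpass_hz = 2,
      min_prominence_dps = 15,
      min_period_s = 0.6,
      boot = "left"
    ),
    filter = list(mad_rule = TRUE),
    enrich = list(alpha = 0.98, edge_boot = "outside"),
    classify = list(carve_angle_min = 30, size_by = "turn"),
    model = list(n_pcs = 3L, min_ref_turns = 10L),
    limits = list(accel_g = 16, gyro_dps = 1000)
  )
  overrides <- list(...)
  if (length(overrides) == 0L) {
    return(defaults)
  }
  if (is.null(names(overrides)) || any(names(overrides) == "")) {
    stop("ski_config() overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  modifyList(defaults, overrides)
}
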