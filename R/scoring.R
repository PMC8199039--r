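#' Project a turn vector into the reference PC space
#'
#' Scores are the inner products of the mean-centered turn vector with the
#' loading rows: `score_k = <x - mean_curve, loading_k>`.
#'
#' @param turn_vector numeric vector of length 101.
#' @param vm a [variable_model()].
#' @return Three PC scores.
#' @export
project_turn <- function(turn_vector, vm) {
  stopifnot(inherits(vm, "variable_model"))
  if (length(turn_vector) != length(vm$mean_curve)) {
    stop("turn vector length does not match the model", call. = FALSE)
  }
  drop(vm$loadings %*% (turn_vector - vm$mean_curve))
}

#' Absolute Z-scores of PC scores against the reference distribution
#'
#' Reference PC scores have mean zero by centering, so
#' `Z_k = |score_k| / score_sd_k`. Components the model did not fit
#' (`varfrac = 0`) get Z = 0, i.e. they neither reward nor penalise.
#'
#' @param scores three PC scores from [project_turn()].
#' @param vm a [variable_model()].
#' @return Three non-negative Z values.
#' @export
zscore_turn <- function(scores, vm) {
  stopifnot(length(scores) == 3L, inherits(vm, "variable_model"))
  z <- numeric(3)
  active <- vm$varfrac > 0
  if (any(active & vm$score_sd <= 0)) {
    stop("degenerate model: zero score SD on a fitted component", call. = FALSE)
  }
  z[active] <- abs(scores[active]) / vm$score_sd[active]
  z
}

#' Discrete scoring bin for an absolute Z-score
#'
#' `[0, 0.75) -> 4`, `[0.75, 1.5) -> 3`, `[1.5, 3) -> 2`, `[3, Inf) -> 1`.
#' Values exactly on a boundary take the lower (worse) bin.
#'
#' @param z absolute Z-score(s), non-negative; vectorized.
#' @return Integer bin(s) in 1..4.
#' @export
bin_z <- function(z) {
  if (any(z < 0)) stop("absolute Z-scores must be non-negative", call. = FALSE)
  4L - findInterval(z, c(0.75, 1.5, 3))
}

#' Variance-weighted sub-score of one variable
#'
#' `subscore = sum_k bin_k * varfrac_k`, so the PC that explains the most
#' reference variance carries the most weight; the attainable maximum is
#' `4 * sum(varfrac)`.
#'
#' @param bins three integers in 1..4.
#' @param varfrac three explained-variance fractions.
#' @return The weighted sub-score (scalar).
#' @export
variable_subscore <- function(bins, varfrac) {
  stopifnot(length(bins) == 3L, length(varfrac) == 3L,
            all(bins %in% 1:4))
  sum(bins * varfrac)
}

#' Turn percentage of the maximum attainable score
#'
#' `pct = 100 * sum_v subscore_v / sum_v 4 * sum_k varfrac_vk`. Because the
#' lowest bin is 1 (not 0), the result lies in [25, 100].
#'
#' @param subscores named numeric vector, one sub-score per variable (all
#'   four variables required).
#' @param varfracs named list of the matching varfrac vectors.
#' @return Percentage in [25, 100].
#' @export
turn_percentage <- function(subscores, varfracs) {
  missing <- setdiff(SKI_VARIABLES, names(subscores))
  if (length(missing)) {
    stop(sprintf("missing variable sub-score(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tot_max <- sum(vapply(SKI_VARIABLES,
                        function(v) 4 * sum(varfracs[[v]]), numeric(1)))
  100 * sum(subscores[SKI_VARIABLES]) / tot_max
}

#' Map a turn percentage onto the 1-10 style-scaled score
#'
#' Carving turns span 7-10 and drifting turns 3-6 (linear in the
#' percentage); snowplow and snowplow-steering turns are assigned the
#' constants 1 and 2 and are not otherwise scored. Non-parallel turns have no
#' band of their own and are scored in the drifting band with a flag.
#'
#' @param pct percentage in [0, 100].
#' @param style a turn style.
#' @return Final score on the 1-10 scale; attribute `off_band = TRUE` marks
#'   non-parallel turns scored in the drifting band.
#' @export
scale_score <- function(pct, style) {
  style <- match.arg(style, SKI_STYLES)
  if (style %in% c("snowplow", "snowplow_steering")) {
    return(if (style == "snowplow") 1 else 2)
  }
  stopifnot(pct >= 0, pct <= 100)
  switch(style,
    carving = 7 + 3 * pct / 100,
    drifting = 3 + 3 * pct / 100,
    non_parallel = structure(3 + 3 * pct / 100, off_band = TRUE)
  )
}

#' Score one enriched turn against a reference model
#'
#' Composes projection, Z-scoring, binning, variance weighting, the turn
#' percentage and the style band, retaining all intermediates. Snowplow
#' classes receive their constant score without consulting the model.
#' Non-parallel turns are scored against the drifting cell of their size.
#' A missing (style, size) cell yields an unscorable result carrying the
#' reason, not an error, so batch scoring can proceed.
#'
#' @param enriched an [enriched_turn()].
#' @param model a [reference_model()].
#' @return A `turn_score` object: per variable `z`, `bins`, `subscore`;
#'   turn-level `percentage`, `final_score`, `style`, `size`.
#' @export
score_turn <- function(enriched, model) {
  stopifnot(inherits(enriched, "enriched_turn"),
            inherits(model, "reference_model"))
  style <- enriched$style
  if (style %in% c("snowplow", "snowplow_steering")) {
    return(structure(list(style = style, size = enriched$size,
                          variables = NULL, percentage = NA_real_,
                          final_score = scale_score(0, style), reason = NULL),
                     class = "turn_score"))
  }
  model_style <- if (style == "non_parallel") "drifting" else style
  key <- cell_key(model_style, enriched$size)
  cell <- model$cells[[key]]
  if (is.null(cell)) {
    return(structure(list(style = style, size = enriched$size,
                          variables = NULL, percentage = NA_real_,
                          final_score = NA_real_,
                          reason = sprintf("no reference cell '%s'", key)),
                     class = "turn_score"))
  }
  vars <- lapply(setNames(SKI_VARIABLES, SKI_VARIABLES), function(v) {
    vm <- cell[[v]]
    scores <- project_turn(enriched[[v]], vm)
    z <- zscore_turn(scores, vm)
    bins <- bin_z(z)
    list(scores = scores, z = z, bins = bins,
         subscore = variable_subscore(bins, vm$varfrac),
         varfrac = vm$varfrac)
  })
  pct <- turn_percentage(
    vapply(vars, `[[`, numeric(1), "subscore"),
    lapply(vars, `[[`, "varfrac")
  )
  structure(list(style = style, size = enriched$size, variables = vars,
                 percentage = pct,
                 final_score = as.numeric(scale_score(pct, style)),
                 off_band = style == "non_parallel", reason = NULL),
            class = "turn_score")
}

#' Score all turns of a run and summarise
#'
#' @param turns list of [enriched_turn()] objects.
#' @param model a [reference_model()].
#' @return A list with `scores` (list of `turn_score`), and `summary`:
#'   `n_scored`, `n_unscorable`, `mean_score`, `median_score` (both over the
#'   final scaled scores of scorable turns; both are reported because run
#'   summaries are used with either central tendency), and `reasons` for any
#'   unscorable turns.
#' @export
score_run <- function(turns, model) {
  scores <- lapply(turns, score_turn, model = model)
  finals <- vapply(scores, `[[`, numeric(1), "final_score")
  ok <- !is.na(finals)
  summary <- list(
    n_scored = sum(ok), n_unscorable = sum(!ok),
    mean_score = if (any(ok)) mean(finals[ok]) else NA_real_,
    median_score = if (any(ok)) median(finals[ok]) else NA_real_,
    reasons = unlist(lapply(scores[!ok], `[[`, "reason"))
  )
  list(scores = scores, summary = summary)
}
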