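#' Full pre-processing of one raw run
#'
#' Segmentation, turn exclusion and enrichment in one step.
#'
#' @param run a [raw_run()].
#' @param labels optional style labels for the *retained* turns.
#' @param config a [ski_config()] list.
#' @return A list of [enriched_turn()] objects (possibly empty).
#' @export
preprocess_run <- function(run, labels = NULL, config = ski_config()) {
  segs <- segment_run(run, config)
  kept <- filter_turns(segs, mad_rule = config$filter$mad_rule)
  enrich_run(run, kept, labels = labels, config = config)
}

#' Fit a reference model from raw runs
#'
#' Runs the full chain (segment, exclude, enrich, classify) on every run of
#' a gold-standard cohort and fits the per-variable PCA reference model.
#'
#' @param runs list of [raw_run()] objects.
#' @param labels optional list of per-run style-label vectors.
#' @param config a [ski_config()] list.
#' @return A [reference_model()].
#' @export
fit_pipeline <- function(runs, labels = NULL, config = ski_config()) {
  if (length(runs) == 0L) stop("no runs found", call. = FALSE)
  turns <- list()
  for (i in seq_along(runs)) {
    turns <- c(turns, preprocess_run(runs[[i]],
                                     labels = if (is.null(labels)) NULL else labels[[i]],
                                     config = config))
  }
  fit_reference(turns, config = config)
}

#' Score raw runs against a fitted reference model
#'
#' @param model a [reference_model()].
#' @param runs list of [raw_run()] objects.
#' @param labels optional list of per-run style-label vectors.
#' @param config a [ski_config()] list.
#' @return A data frame of per-turn scores (see [scores_to_df()]) with an
#'   attribute `summaries`: per-run mean and median final scores.
#' @export
score_pipeline <- function(model, runs, labels = NULL, config = ski_config()) {
  stopifnot(inherits(model, "reference_model"))
  dfs <- list()
  summaries <- list()
  for (i in seq_along(runs)) {
    run <- runs[[i]]
    turns <- preprocess_run(run,
                            labels = if (is.null(labels)) NULL else labels[[i]],
                            config = config)
    res <- score_run(turns, model)
    id <- run$skier_id %||% paste0("run", i)
    dfs[[i]] <- scores_to_df(res$scores, run_id = id)
    summaries[[id]] <- res$summary
  }
  out <- do.call(rbind, dfs)
  attr(out, "summaries") <- summaries
  out
}
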