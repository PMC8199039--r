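#' Fit the centered PCA reference cell for one variable
#'
#' Given the n x 101 matrix of one variable's time-normalized reference
#' turns, computes the column-mean curve and the singular value
#' decomposition of the centered matrix. The first three right singular
#' vectors become the loading rows; explained-variance fractions are taken
#' against the *total* variance (all components); the reference Z-scale is
#' the standard deviation (n-1 denominator) of the n reference PC scores on
#' each component. Each loading's largest-magnitude element is made positive
#' so the sign convention is reproducible.
#'
#' Rank-deficient inputs are fitted with the available components; trailing
#' components get zero loadings, zero variance fraction and zero score SD and
#' `n_components` records the effective rank.
#'
#' @param x numeric matrix, n turns x 101 features.
#' @param min_ref_turns minimum n required.
#' @param cell optional "style.size" label used in error messages.
#' @return A [variable_model()].
#' @export
fit_variable_pca <- function(x, min_ref_turns = 10, cell = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < min_ref_turns) {
    stop(sprintf("insufficient reference turns%s: %d < %d",
                 if (is.null(cell)) "" else paste0(" in cell ", cell),
                 n, min_ref_turns), call. = FALSE)
  }
  p <- ncol(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc)
  lambda <- sv$d^2 / (n - 1)
  total <- sum(lambda)
  tol <- max(sv$d) * 1e-10
  rank <- if (total <= 0) 0L else sum(sv$d > tol)
  k <- min(3L, rank)

  loadings <- matrix(0, 3L, p)
  varfrac <- numeric(3)
  score_sd <- numeric(3)
  if (k > 0L) {
    for (j in seq_len(k)) {
      v <- sv$v[, j]
      if (v[which.max(abs(v))] < 0) v <- -v
      loadings[j, ] <- v
    }
    varfrac[seq_len(k)] <- lambda[seq_len(k)] / total
    score_sd[seq_len(k)] <- sv$d[seq_len(k)] / sqrt(n - 1)
  }
  vm <- variable_model(
    mean_curve = if (p == N_NORM) mu else c(mu, rep(0, N_NORM - p)),
    loadings = if (p == N_NORM) loadings else
      cbind(loadings, matrix(0, 3L, N_NORM - p)),
    varfrac = varfrac, score_sd = score_sd, n_ref = n, n_components = k
  )
  if (k < 3L) attr(vm, "rank_deficient") <- TRUE
  attr(vm, "eigenvalues") <- lambda
  vm
}

#' Fit the full reference model from a gold-standard cohort
#'
#' Turns are grouped by (style, size); within each group with at least
#' `min_ref_turns` members, all four variables are fitted with
#' [fit_variable_pca()]. Only carving and drifting turns enter the model (the
#' snowplow classes are scored by constant assignment and never modelled);
#' undersized groups are skipped with a warning.
#'
#' @param cohort list of [enriched_turn()] objects.
#' @param config a [ski_config()] list; `config$model$min_ref_turns` applies.
#' @return A [reference_model()].
#' @export
fit_reference <- function(cohort, config = ski_config()) {
  if (length(cohort) == 0L) stop("empty reference cohort", call. = FALSE)
  min_n <- config$model$min_ref_turns
  styles <- vapply(cohort, `[[`, character(1), "style")
  sizes <- vapply(cohort, `[[`, character(1), "size")
  usable <- styles %in% c("carving", "drifting")
  keys <- cell_key(styles, sizes)

  cells <- list()
  for (key in unique(keys[usable])) {
    members <- cohort[usable & keys == key]
    if (length(members) < min_n) {
      warning(sprintf("cell %s skipped: %d < %d reference turns",
                      key, length(members), min_n), call. = FALSE)
      next
    }
    cells[[key]] <- lapply(setNames(SKI_VARIABLES, SKI_VARIABLES), function(v) {
      m <- do.call(rbind, lapply(members, `[[`, v))
      fit_variable_pca(m, min_ref_turns = min_n, cell = key)
    })
  }
  if (length(cells) == 0L) {
    stop(sprintf("no (style, size) cell reaches %d reference turns", min_n),
         call. = FALSE)
  }
  reference_model(cells, fit_config = config)
}

#' Stack one variable of a cohort into a turns x 101 matrix
#'
#' @param cohort list of [enriched_turn()] objects.
#' @param variable one of `edge_angle`, `symmetry`, `radial_force`, `speed`.
#' @return A numeric matrix, one row per turn.
#' @export
cohort_matrix <- function(cohort, variable = SKI_VARIABLES) {
  variable <- match.arg(variable)
  do.call(rbind, lapply(cohort, `[[`, variable))
}
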