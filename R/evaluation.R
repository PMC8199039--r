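#' Pearson correlation with effect-size band
#'
#' Standard Pearson correlation with a two-sided p-value, labelled with the
#' conventional effect-size band: |r| < 0.3 small, 0.3 <= |r| < 0.6 medium,
#' |r| >= 0.6 large.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return A list with `r`, `p` and `band`.
#' @export
pearson_with_band <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined: zero variance in an input", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  band <- if (abs(r) < 0.3) "small" else if (abs(r) < 0.6) "medium" else "large"
  list(r = r, p = ct$p.value, band = band)
}

#' Kruskal-Wallis comparison of score distributions
#'
#' Rank-based H statistic with tie correction and a chi-square p-value on
#' k - 1 degrees of freedom, used to ask whether the algorithm assigns
#' different scores to different skiers. When every pooled value is
#' identical the test is degenerate and H = 0, p = 1 is returned.
#'
#' @param groups a list of >= 2 numeric vectors (scores per skier).
#' @return A list with `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(lengths(groups) >= 1), sum(lengths(groups)) >= 3)
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1L) {
    return(list(H = 0, p = 1))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- kruskal.test(pooled, g)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Sample skewness (adjusted Fisher-Pearson)
#'
#' The adjusted Fisher-Pearson standardized third moment
#' `G1 = g1 * sqrt(n (n - 1)) / (n - 2)` with
#' `g1 = m3 / m2^(3/2)` on central moments with denominator n. Negative
#' values indicate a distribution skewed toward higher scores.
#'
#' @param x numeric vector, n >= 3, non-constant.
#' @return The skewness estimate.
#' @export
score_skewness <- function(x) {
  n <- length(x)
  stopifnot(n >= 3)
  if (sd(x) == 0) stop("skewness undefined for a constant sample", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
}

#' Evaluation report over a scores table
#'
#' Convenience wrapper used by the command-line `evaluate` step: computes
#' per-group medians, the Kruskal-Wallis comparison across groups and the
#' skewness of each group's score distribution; optionally the Pearson
#' correlation against external ratings.
#'
#' @param scores data frame with a `final_score` column.
#' @param group factor-like vector grouping the rows (e.g. skier id).
#' @param ratings optional numeric vector of external ratings, one per row
#'   of `scores`, correlated against `final_score`.
#' @return A list with `group_medians`, `kruskal`, `skewness` (per group,
#'   NA for degenerate groups) and optionally `pearson`.
#' @export
evaluate_scores <- function(scores, group, ratings = NULL) {
  stopifnot("final_score" %in% names(scores))
  keep <- !is.na(scores$final_score)
  x <- scores$final_score[keep]
  g <- factor(group[keep])
  split_scores <- split(x, g)
  out <- list(
    group_medians = vapply(split_scores, median, numeric(1)),
    kruskal = if (nlevels(g) >= 2) kruskal_wallis(split_scores) else NULL,
    skewness = vapply(split_scores, function(v) {
      if (length(v) >= 3 && sd(v) > 0) score_skewness(v) else NA_real_
    }, numeric(1))
  )
  if (!is.null(ratings)) {
    out$pearson <- pearson_with_band(x, ratings[keep])
  }
  out
}
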