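# Shared fixture builders. Everything is generated in code; no stored data.

`%||%` <- function(a, b) if (is.null(a)) b else a

# k mutually orthonormal rows of length p
random_orthonormal_rows <- function(k, p) {
  q <- qr.Q(qr(matrix(rnorm(p * k), p, k)))
  t(q)
}

random_variable_model <- function() {
  l <- random_orthonormal_rows(3, 101)
  vf <- sort(runif(3), decreasing = TRUE)
  vf <- vf / sum(vf) * runif(1, 0.85, 0.999)
  variable_model(mean_curve = rnorm(101), loadings = l, varfrac = vf,
                 score_sd = runif(3, 0.5, 3), n_ref = 25L, n_components = 3L)
}

random_reference_model <- function(cells = c("carving.small", "drifting.large")) {
  vars <- c("edge_angle", "symmetry", "radial_force", "speed")
  cl <- lapply(setNames(cells, cells), function(k) {
    lapply(setNames(vars, vars), function(v) random_variable_model())
  })
  reference_model(cl)
}

# an enriched turn whose four vectors equal a model cell's mean curves
turn_from_cell_means <- function(model, key = names(model$cells)[1],
                                 style = strsplit(key, ".", fixed = TRUE)[[1]][1],
                                 size = strsplit(key, ".", fixed = TRUE)[[1]][2]) {
  cell <- model$cells[[key]]
  enriched_turn(
    edge_angle = cell$edge_angle$mean_curve,
    symmetry = cell$symmetry$mean_curve,
    radial_force = cell$radial_force$mean_curve,
    speed = pmax(cell$speed$mean_curve, 0),
    style = style, size = size
  )
}

# a fitted single-cell model from a seeded synthetic cohort
fitted_test_model <- function(seed = 42, n = 40,
                              cells = list(c("carving", "small"))) {
  p <- synthetic_params(seed = seed)
  coh <- generate_cohort(p, n_per_cell = n, cells = cells)
  fit_reference(coh)
}

expect_cosine_close <- function(a, b, min_abs_cos = 0.95) {
  cs <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  expect_gte(cs, min_abs_cos)
}
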