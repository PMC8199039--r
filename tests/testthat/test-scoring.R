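test_that("projection is the inner product with the centered turn", {
  withr::local_seed(11)
  vm <- random_variable_model()
  expect_equal(project_turn(vm$mean_curve, vm), rep(0, 3), tolerance = 1e-12)
  expect_equal(project_turn(vm$mean_curve + 2 * vm$loadings[1, ], vm),
               c(2, 0, 0), tolerance = 1e-12)
  x <- rnorm(101)
  oracle <- vapply(1:3, function(k) sum((x - vm$mean_curve) * vm$loadings[k, ]),
                   numeric(1))
  expect_lt(max(abs(project_turn(x, vm) - oracle)), 1e-12)
  expect_error(project_turn(rnorm(100), vm), "length")
})

test_that("absolute Z-scores scale by the reference score SD", {
  withr::local_seed(12)
  vm <- random_variable_model()
  expect_equal(zscore_turn(c(0, 0, 0), vm), c(0, 0, 0))
  vm$score_sd <- c(1, 2, 4)
  expect_equal(zscore_turn(c(1.5, -3, 2), vm), c(1.5, 1.5, 0.5))
  # unfitted components neither reward nor penalise
  vm$varfrac <- c(0.9, 0.05, 0)
  expect_equal(zscore_turn(c(1, 1, 99), vm)[3], 0)
  # degenerate fitted component
  vm$score_sd <- c(0, 2, 4)
  expect_error(zscore_turn(c(1, 1, 1), vm), "degenerate")
})

test_that("Z-binning follows the published rule with lower-bin boundaries", {
  expect_equal(bin_z(0.5), 4L)
  expect_equal(bin_z(1.0), 3L)
  expect_equal(bin_z(3.5), 1L)
  expect_equal(bin_z(c(0, 0.7499, 0.75, 1.4999, 1.5, 2.9999, 3, 100)),
               c(4L, 4L, 3L, 3L, 2L, 2L, 1L, 1L))
  expect_error(bin_z(-0.1), "non-negative")
})

test_that("variance weighting gives heavier PCs more influence", {
  # a perfect bin of 4 on a PC explaining 22 % contributes 0.88
  expect_equal(4 * 0.22, 0.88)
  expect_equal(variable_subscore(c(4L, 4L, 4L), c(0.70, 0.22, 0.05)),
               2.80 + 0.88 + 0.20)
  expect_equal(variable_subscore(c(4L, 4L, 4L), c(0.6, 0.3, 0.1)), 4)
  expect_equal(variable_subscore(c(1L, 1L, 1L), c(0.5, 0.3, 0.2)), 1.0)
  expect_error(variable_subscore(c(5L, 1L, 1L), c(0.5, 0.3, 0.2)))
})

test_that("turn percentage spans 25-100 over the bin range", {
  vf <- list(edge_angle = c(0.7, 0.2, 0.05), symmetry = c(0.6, 0.3, 0.05),
             radial_force = c(0.75, 0.15, 0.05), speed = c(0.99, 0.005, 0.001))
  sub4 <- vapply(vf, function(f) variable_subscore(c(4L, 4L, 4L), f), numeric(1))
  sub1 <- vapply(vf, function(f) variable_subscore(c(1L, 1L, 1L), f), numeric(1))
  expect_equal(turn_percentage(sub4, vf), 100)
  expect_equal(turn_percentage(sub1, vf), 25)

  # mixed case against a hand computation
  bins <- list(edge_angle = c(4L, 3L, 2L), symmetry = c(3L, 3L, 4L),
               radial_force = c(2L, 1L, 4L), speed = c(4L, 4L, 4L))
  subs <- vapply(names(vf), function(v) variable_subscore(bins[[v]], vf[[v]]),
                 numeric(1))
  hand <- 100 * sum(mapply(function(b, f) sum(b * f), bins, vf)) /
    sum(vapply(vf, function(f) 4 * sum(f), numeric(1)))
  expect_equal(turn_percentage(subs, vf), hand, tolerance = 1e-12)

  expect_error(turn_percentage(sub4[-1], vf), "edge_angle")
})

test_that("the style bands map percentages onto the 1-10 scale", {
  expect_equal(scale_score(100, "carving"), 10)
  expect_equal(scale_score(0, "carving"), 7)
  expect_equal(scale_score(0, "drifting"), 3)
  expect_equal(scale_score(100, "drifting"), 6)
  expect_equal(scale_score(50, "snowplow"), 1)
  expect_equal(scale_score(50, "snowplow_steering"), 2)
  np <- scale_score(50, "non_parallel")
  expect_equal(as.numeric(np), 4.5)
  expect_true(attr(np, "off_band"))
  expect_error(scale_score(50, "parallel"))
})

test_that("scoring composes the chain and retains intermediates", {
  m <- fitted_test_model(seed = 61, n = 40)
  cell <- m$cells$carving.small

  perfect <- turn_from_cell_means(m)
  sc <- score_turn(perfect, m)
  expect_equal(sc$final_score, 10)
  expect_equal(sc$percentage, 100)

  drift <- perfect; drift$style <- "drifting"
  m2 <- m
  m2$cells$drifting.small <- cell
  expect_equal(score_turn(drift, m2)$final_score, 6)

  # hand-composed oracle for a turn offset along known loadings
  vm <- cell$edge_angle
  delta <- 2 * vm$score_sd[2]                    # |Z2| = 2 -> bin 2
  off <- perfect
  off$edge_angle <- vm$mean_curve + delta * vm$loadings[2, ]
  sc <- score_turn(off, m)
  expect_equal(sc$variables$edge_angle$z, c(0, 2, 0), tolerance = 1e-9)
  expect_equal(sc$variables$edge_angle$bins, c(4L, 2L, 4L))
  hand_sub <- sum(c(4, 2, 4) * vm$varfrac)
  expect_equal(sc$variables$edge_angle$subscore, hand_sub, tolerance = 1e-12)
  tot_max <- sum(vapply(cell, function(v) 4 * sum(v$varfrac), numeric(1)))
  hand_pct <- 100 * (hand_sub +
    sum(vapply(cell[-1], function(v) 4 * sum(v$varfrac), numeric(1)))) / tot_max
  expect_equal(sc$percentage, hand_pct, tolerance = 1e-9)
  expect_equal(sc$final_score, 7 + 3 * hand_pct / 100, tolerance = 1e-9)

  # symmetric deviations score identically
  neg <- perfect
  neg$edge_angle <- vm$mean_curve - delta * vm$loadings[2, ]
  expect_equal(score_turn(neg, m)$final_score, sc$final_score)
})

test_that("increasing a single |Z| never increases the final score", {
  m <- fitted_test_model(seed = 62, n = 40)
  vm <- m$cells$carving.small$radial_force
  perfect <- turn_from_cell_means(m)
  finals <- vapply(seq(0, 4, by = 0.25), function(z) {
    tr <- perfect
    tr$radial_force <- vm$mean_curve + z * vm$score_sd[1] * vm$loadings[1, ]
    score_turn(tr, m)$final_score
  }, numeric(1))
  expect_true(all(diff(finals) <= 1e-12))
})

test_that("snowplow classes are constant and missing cells are unscorable", {
  m <- fitted_test_model(seed = 63, n = 40)
  plow <- turn_from_cell_means(m); plow$style <- "snowplow"
  steer <- turn_from_cell_means(m); steer$style <- "snowplow_steering"
  expect_equal(score_turn(plow, m)$final_score, 1)
  expect_equal(score_turn(steer, m)$final_score, 2)

  lost <- turn_from_cell_means(m); lost$size <- "large"
  sc <- score_turn(lost, m)
  expect_true(is.na(sc$final_score))
  expect_match(sc$reason, "carving.large")

  # non-parallel turns are scored in the drifting band, flagged
  m$cells$drifting.small <- m$cells$carving.small
  np <- turn_from_cell_means(m); np$style <- "non_parallel"
  sc <- score_turn(np, m)
  expect_equal(sc$final_score, 6)
  expect_true(sc$off_band)
})

test_that("run scoring summarises with both mean and median", {
  m <- fitted_test_model(seed = 64, n = 40)
  p <- synthetic_params(seed = 65)
  turns <- generate_cohort(p, n_per_cell = 9, cells = list(c("carving", "small")))
  res <- score_run(turns, m)
  finals <- vapply(res$scores, `[[`, numeric(1), "final_score")
  expect_equal(res$summary$n_scored, 9)
  expect_equal(res$summary$mean_score, mean(finals))
  expect_equal(res$summary$median_score, median(finals))
  expect_true(all(finals >= 7 & finals <= 10))  # carving band containment

  perfect <- turn_from_cell_means(m)
  res2 <- score_run(list(perfect, perfect, perfect), m)
  expect_equal(res2$summary$mean_score, 10)
  expect_equal(res2$summary$median_score, 10)
})

test_that("self-scoring a reference cohort skews toward the top of the band", {
  p <- synthetic_params(seed = 66)
  coh <- generate_cohort(p, n_per_cell = 200, cells = list(c("carving", "small")))
  m <- fit_reference(coh)
  finals <- vapply(score_run(coh, m)$scores, `[[`, numeric(1), "final_score")
  expect_lt(score_skewness(finals), 0)
  expect_gt(mean(finals), 7 + 3 * 0.8)  # mean percentage above 80
})
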