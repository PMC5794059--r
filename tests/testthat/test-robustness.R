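# Bootstrap machinery and the paired model comparison.

test_that("aggregate ratio and degenerate bootstrap cases", {
  expect_equal(aggregate_ratio(c(1, 1, 1)), 1)
  expect_equal(aggregate_ratio(c(1, 0, 1, 0)), 0.5)
  expect_equal(aggregate_ratio(c(rep(1, 434), rep(0, 86))), 434 / 520,
               tolerance = 1e-12)
  expect_error(aggregate_ratio(numeric(0)), "empty")

  ones <- bootstrap_ratio(rep(1, 50), B = 200, seed = 1)
  expect_equal(ones$observed, 1)
  expect_equal(c(ones$ci_low, ones$ci_high), c(1, 1))

  single <- bootstrap_ratio(c(1, 0, 0, 1), B = 1, seed = 3)
  expect_equal(single$ci_low, single$ci_high)
  expect_length(single$samples, 1)
})

test_that("bootstrap of an indicator mean matches binomial theory", {
  ind <- c(rep(1, 83), rep(0, 17))
  bs <- bootstrap_ratio(ind, B = 4000, seed = 9)
  p <- 0.83
  expect_equal(mean(bs$samples), p, tolerance = 0.01)
  expect_equal(stats::sd(bs$samples), sqrt(p * (1 - p) / 100),
               tolerance = 0.1)
  expect_true(bs$ci_low <= bs$observed && bs$observed <= bs$ci_high)
  # reproducible under the same seed
  expect_identical(bs$samples, bootstrap_ratio(ind, B = 4000, seed = 9)$samples)
})

test_that("random reference has Bernoulli(1/2) mean and spread", {
  ref <- random_reference(520, B = 2000, seed = 5)
  expect_equal(mean(ref), 0.5, tolerance = 3 * 0.5 / sqrt(520 * 2000) + 5e-3)
  expect_equal(stats::sd(ref), sqrt(0.25 / 520), tolerance = 0.1)
  expect_true(all(random_reference(1, B = 50, seed = 2) %in% c(0, 1)))
})

test_that("Cohen's d with equal-weight pooling and its categories", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  x <- stats::rnorm(2000, 1, 1)
  y <- stats::rnorm(2000, 0, 1)
  expect_equal(cohens_d(x, y), 1, tolerance = 0.15)
  expect_identical(cohens_d(c(2, 2), c(1, 1)), Inf)
  expect_identical(cohens_d(c(1, 1), c(1, 1)), 0)

  expect_equal(effect_category(c(0.1, 0.2, 0.6, 3, -0.9)),
               c("negligible", "small", "medium", "large", "large"))
  expect_equal(effect_category(0.499), "small")
  expect_equal(effect_category(Inf), "large")
})

test_that("per-point bootstrap effect flags separation and identity", {
  same <- per_point_effect(1:6, 1:6, B = 400, seed = 1)
  expect_equal(same$d, 0, tolerance = 0.3)
  expect_true(same$contains_zero)

  apart <- per_point_effect(c(10, 11, 12, 13, 11, 12),
                            c(1, 2, 1.5, 2.2, 1.1, 0.9), B = 400, seed = 1)
  expect_false(apart$contains_zero)
  expect_gt(abs(apart$d), 2)

  # underpowered near-equal sets usually keep zero inside the interval
  set.seed(42)
  hits <- vapply(1:40, function(i) {
    a <- stats::rnorm(6, 10, 1)
    b <- stats::rnorm(6, 10.1, 1)
    per_point_effect(a, b, B = 200, seed = i)$contains_zero
  }, logical(1))
  expect_gt(mean(hits), 0.6)

  expect_error(per_point_effect(1:3, 1:4), "equal length")
})

test_that("paired evaluation: dark gating makes the models identical", {
  base <- fast_colony(n_cells = 4, t_final = 300, seed = 13L)
  base$schedule <- light_schedule(0, "dark")
  ev <- evaluate_point(list(), base = base, seed = 13L)
  expect_equal(ev$iase_danino, ev$iase_hotfm, tolerance = 1e-10)
  expect_equal(ev$r_danino, ev$r_hotfm, tolerance = 1e-8)
})

test_that("zero initial noise gives zero IASE and flagged rates", {
  base <- fast_colony(n_cells = 4, t_final = 300, noise_width = 0)
  ev <- evaluate_point(list(), base = base, seed = 2L)
  expect_equal(ev$iase_danino, 0)
  expect_equal(ev$iase_hotfm, 0)

  # the shared-seed paired design really shares the noise
  base2 <- fast_colony(n_cells = 4, t_final = 200)
  ev2 <- evaluate_point(list(), base = base2, seed = 5L)
  expect_tibble(ev2)
  expect_equal(nrow(ev2$pairs_danino[[1]]), 4)
})

test_that("robustness report has the aggregate and per-point structure", {
  ax <- param_axis("gamma_I", 20, 30, n_points = 2)
  ay <- param_axis("gamma_A", 18, 28, n_points = 2)
  base <- colony_config(n_cells = 4, t_final = 300, seed = 3L,
                        schedule = light_schedule(0, "green"))
  grid <- robustness_grid(ax, ay, base = base, seed = 3L,
                          t_final_bulk = 600)
  expect_s3_class(grid, "robustness_grid")
  expect_equal(nrow(grid), 4)
  rep_ <- robustness_report(grid, B = 200, seed = 3L)
  expect_named(rep_$aggregate,
               c("metric", "n", "n_ties", "hotfm_wins", "fraction",
                 "ci_low", "ci_high", "cohens_d", "category"))
  expect_setequal(rep_$aggregate$metric, c("iase", "r"))
  expect_true(all(rep_$per_point$metric %in% c("iase", "r")))
  expect_true(all(rep_$per_point$category %in%
                  c("negligible", "small", "medium", "large", NA)))
})
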