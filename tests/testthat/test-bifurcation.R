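# Sweeps and Hopf-boundary bisection, validated on the scalar linear delay
# equation whose boundary is known analytically.

linear_dde_classifier <- function(a, tau) {
  traj <- integrate_dde(function(t, y, z) -a * z, tau = tau, history = 1,
                        t_final = 600, step = tau / 20, save_every = 5L)
  classify_behavior(traj$state[, 1], times = traj$time, t_transient = 300,
                    rel_tol = 0.05)
}

test_that("bisection recovers the a*tau = pi/2 boundary of y' = -a y(t-tau)", {
  ax <- param_axis("tau", 0.8, 1.1, n_points = 3)
  # reuse the axis values as the delay; classifier ignores model machinery
  bd <- hopf_boundary(function(x, y) linear_dde_classifier(a = y, tau = x),
                      axis_x = ax, y_bracket = c(1.15, 2.2), tol = 0.01)
  expect_equal(bd$y_boundary * bd$x, rep(pi / 2, 3), tolerance = 0.05)
})

test_that("bisection demands a straddling bracket and respects widening", {
  classify <- function(x, y) if (y > 2 * x) "oscillatory" else "steady_state"
  ax <- param_axis("K", 1, 2, n_points = 2)
  bd1 <- hopf_boundary(classify, ax, y_bracket = c(0, 10), tol = 1e-4)
  bd2 <- hopf_boundary(classify, ax, y_bracket = c(1, 20), tol = 1e-4)
  expect_equal(bd1$y_boundary, 2 * bd1$x, tolerance = 1e-3)
  expect_equal(bd1$y_boundary, bd2$y_boundary, tolerance = 1e-3)
  expect_error(hopf_boundary(classify, ax, y_bracket = c(5, 10)),
               "identically")
})

test_that("repressor degradation sweep shows the tunability structure", {
  sw <- degradation_sweep()
  expect_tibble(sw)
  osc <- dplyr::filter(sw, label == "oscillatory")
  expect_gte(nrow(osc), 8)
  expect_true(all(diff(osc$period) > 0))
  expect_true(all(diff(osc$amplitude) > 0))
  expect_gt(stats::cor(osc$period, osc$amplitude), 0.9)

  # below the boundary the repressed cell sits at a steady state
  low <- degradation_sweep(gamma_R_values = c(0.005, 0.015))
  expect_true(all(low$label == "steady_state"))

  # fast repressor turnover recovers the unrepressed reference
  ref <- attr(sw, "reference")
  hi <- degradation_sweep(gamma_R_values = 50)
  expect_equal(hi$period, ref$period, tolerance = 0.05)
  expect_equal(hi$amplitude, ref$amplitude, tolerance = 0.05)
})

test_that("two-parameter sweep labels a coarse grid sensibly", {
  ax <- param_axis("K", 20, 2000, n_points = 3, scale = "log")
  ay <- param_axis("gamma_R", 0.01, 0.1, n_points = 3)
  map <- sweep_two_params("hotfm", ax, ay, t_final = 1000)
  expect_s3_class(map, "bifurcation_map")
  expect_equal(nrow(map), 9)
  expect_true(all(map$label %in% c("oscillatory", "steady_state")))
  # weak repression (large K) is oscillatory for every gamma_R in range
  weak <- dplyr::filter(map, x == max(x))
  expect_true(all(weak$label == "oscillatory"))
  # oscillatory points carry period and amplitude, steady ones do not
  expect_true(all(!is.na(map$period[map$label == "oscillatory"])))
  expect_true(all(is.na(map$period[map$label == "steady_state"])))
})

test_that("gated trajectories approach the plain model as K grows", {
  p <- study_params(D1 = 0)
  run_k <- function(K) {
    cfg <- colony_config(n_cells = 1, model_per_cell = "hotfm", params = p,
                         green = channel_params(K = K),
                         schedule = light_schedule(0, "green"),
                         t_final = 500, noise_width = 0, seed = 1L)
    species_series(simulate_colony(cfg), "A")[, 1]
  }
  ref <- run_k(1e9)
  dev <- vapply(c(1e3, 1e5, 1e7), function(K) max(abs(run_k(K) - ref)),
                numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 1e-2)
})
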