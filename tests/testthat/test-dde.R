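# Method-of-steps integrator: analytic oracles, convergence order, dense
# output, determinism, and an independent cross-check against deSolve.

test_that("piecewise-polynomial oracle: y' = -y(t-1) with unit history", {
  # exact solution: 1 - t on [0,1]; t^2/2 - 2t + 3/2 on [1,2]
  traj <- integrate_dde(function(t, y, z) -z, tau = 1, history = 1,
                        t_final = 2, step = 0.01)
  v <- dense_eval(traj, c(1, 2))
  expect_equal(v[1], 0, tolerance = 1e-10)
  expect_equal(v[2], -0.5, tolerance = 1e-10)
  # dense evaluation matches the analytic solution between grid points
  ts <- c(0.25, 0.77, 1.33, 1.9)
  exact <- ifelse(ts <= 1, 1 - ts, ts^2 / 2 - 2 * ts + 1.5)
  expect_equal(unname(dense_eval(traj, ts)), exact, tolerance = 1e-9)
})

test_that("delay-free exponential decay is integrated to high accuracy", {
  traj <- integrate_dde(function(t, y, z) -y, tau = 1, history = 1,
                        t_final = 1, step = 0.01)
  expect_equal(dense_eval(traj, 1), exp(-1), tolerance = 1e-8)
})

test_that("step halving shows at least third-order convergence", {
  err_at <- function(h) {
    traj <- integrate_dde(function(t, y, z) -z, tau = 1, history = 1,
                          t_final = 5, step = h)
    ref <- integrate_dde(function(t, y, z) -z, tau = 1, history = 1,
                         t_final = 5, step = h / 8)
    abs(dense_eval(traj, 5) - dense_eval(ref, 5))
  }
  e1 <- err_at(0.1)
  e2 <- err_at(0.05)
  expect_gte(e1 / e2, 8)
})

test_that("dense evaluation is exact at grid points and for cubics", {
  rhs <- function(t, y, z) 3 * t^2         # y = t^3
  traj <- integrate_dde(rhs, tau = 1, history = 0, t_final = 2, step = 0.1)
  expect_equal(dense_eval(traj, traj$time[11]), traj$state[11, 1])
  mid <- 0.55
  expect_equal(dense_eval(traj, mid), mid^3, tolerance = 1e-10)
  expect_error(dense_eval(traj, 3), "outside")
})

test_that("nonconstant history functions are honoured", {
  # y'(t) = y(t-1) with history t on [-1,0]: y(t) = t^2/2 - t on [0,1]
  traj <- integrate_dde(function(t, y, z) z, tau = 1,
                        history = function(s) s, t_final = 1, step = 0.02)
  expect_equal(dense_eval(traj, 1), -0.5, tolerance = 1e-6)
  expect_equal(dense_eval(traj, -0.5), -0.5)
})

test_that("identical inputs give bitwise-identical trajectories", {
  run <- function() simulate_colony(fast_colony(seed = 11L))
  t1 <- run()
  t2 <- run()
  expect_identical(t1$state, t2$state)
})

test_that("step larger than the delay is rejected", {
  expect_error(integrate_dde(function(t, y, z) -z, tau = 0.5, history = 1,
                             t_final = 1, step = 0.6), "delay")
})

test_that("divergent systems raise rather than return non-finite states", {
  expect_error(integrate_dde(function(t, y, z) y^2, tau = 1, history = 2,
                             t_final = 5, step = 0.05), "non-finite")
})

test_that("colony integrator agrees with deSolve on the single-cell model", {
  skip_if_not_installed("deSolve")
  p <- study_params(D1 = 0)
  traj <- simulate_colony(colony_config(
    n_cells = 1, model_per_cell = "danino", params = p,
    t_final = 200, noise_width = 0, seed = 1L))
  rhs <- function(t, y, parms) {
    lag <- if (t < p$tau) 0 else deSolve::lagvalue(t - p$tau, 3)
    s <- stats::setNames(c(y, 0, 0), quorosc:::species_names())
    list(unname(danino_derivatives(s, lag, p))[1:4])
  }
  out <- deSolve::dede(c(A = 0, I = 100, Hi = 0, He = 0),
                       seq(0, 200, by = 5), rhs, NULL,
                       control = list(mxhist = 1e5))
  mine <- dense_eval(traj, seq(0, 200, by = 5))
  expect_equal(unname(mine[, "A_1"]), unname(out[, "A"]), tolerance = 2e-2)
  expect_equal(unname(mine[, "I_1"]), unname(out[, "I"]), tolerance = 2e-2)
})
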