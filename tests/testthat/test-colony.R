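# Colony assembly: noisy initial conditions, diffusion stencil, symmetry,
# and conservation properties.

test_that("noisy initial history draws LuxI in [baseline, baseline+width]", {
  y0 <- noisy_initial_history(6, seed = 3L)
  expect_equal(dim(y0), c(6, 6))
  expect_true(all(y0[, "I"] >= 100 & y0[, "I"] <= 500))
  expect_true(all(y0[, colnames(y0) != "I"] == 0))
  # determinism and zero-width degenerate case
  expect_identical(y0, noisy_initial_history(6, seed = 3L))
  expect_false(identical(y0, noisy_initial_history(6, seed = 4L)))
  flat <- noisy_initial_history(6, seed = 3L, noise_width = 0)
  expect_true(all(flat[, "I"] == 100))
})

test_that("periodic Laplacian stencil is correct for a 3-cell ring", {
  p <- study_params()
  y <- matrix(0, 3, 6)
  y[, 4] <- c(1, 0, 0)  # He
  dy <- quorosc:::.colony_rhs_cpp(
    0, as.vector(t(y)), as.vector(t(y)),
    integer(3), quorosc:::flatten_osc(p),
    quorosc:::flatten_chan(channel_params()),
    quorosc:::flatten_chan(uv_channel()),
    0, 0L, dx = 1)
  d1c <- p$D1 * 60
  he_rates <- dy[c(4, 10, 16)]
  # subtract the non-diffusive part (exchange + decay) cell by cell
  base <- vapply(1:3, function(i) {
    s <- stats::setNames(y[i, ], quorosc:::species_names())
    danino_derivatives(s, y[i, 3], p, He_laplacian = 0)[["He"]]
  }, numeric(1))
  expect_equal(he_rates - base, d1c * c(-2, 1, 1))
})

test_that("identical initial states stay identical (symmetry preserved)", {
  cfg <- fast_colony(n_cells = 6, t_final = 300, noise_width = 0)
  traj <- simulate_colony(cfg)
  A <- species_series(traj, "A")
  expect_lt(max(abs(A - A[, 1])), 1e-9)
  expect_equal(iase(ase_series(traj)), 0)
})

test_that("rotating the initial conditions rotates the solution", {
  y0 <- noisy_initial_history(5, seed = 8L)
  rot <- function(m, k) m[((seq_len(nrow(m)) - 1 + k) %% nrow(m)) + 1, ]
  cfg <- fast_colony(n_cells = 5, t_final = 150)
  t1 <- simulate_colony(cfg, y0 = y0)
  t2 <- simulate_colony(cfg, y0 = rot(y0, 2))
  A1 <- species_series(t1, "A")
  A2 <- species_series(t2, "A")
  expect_equal(unname(A2[, 1]), unname(A1[, 3]), tolerance = 1e-10)
  expect_equal(unname(A2[, 4]), unname(A1[, 1]), tolerance = 1e-10)
})

test_that("with D1 = 0 cells evolve independently", {
  p <- study_params(D1 = 0)
  y0 <- noisy_initial_history(3, seed = 21L)
  cfg3 <- fast_colony(n_cells = 3, t_final = 150, params = p)
  traj3 <- simulate_colony(cfg3, y0 = y0)
  # same cell simulated alone reproduces its column exactly
  cfg1 <- colony_config(n_cells = 1, model_per_cell = "danino", params = p,
                        schedule = light_schedule(0, "green"),
                        t_final = 150, seed = 1L,
                        step = cfg3$step, save_every = cfg3$save_every)
  traj1 <- simulate_colony(cfg1, y0 = y0[2, , drop = FALSE])
  expect_equal(unname(species_series(traj3, "A")[, 2]),
               unname(species_series(traj1, "A")[, 1]), tolerance = 1e-12)
})

test_that("membrane exchange conserves the density-weighted AHL total", {
  # with mu = 0, D1 = 0, b = 0, gamma_H = 0 the only Hi/He dynamics is the
  # exchange pair, which conserves d*Hi + (1-d)*He
  p <- oscillator_params(b = 0, gamma_H = 0, mu = 0, D1 = 0, delta = 0)
  y0 <- matrix(0, 1, 6)
  y0[1, 3] <- 4   # Hi
  y0[1, 4] <- 1   # He
  cfg <- colony_config(n_cells = 1, model_per_cell = "danino", params = p,
                       t_final = 100, noise_width = 0, seed = 1L)
  traj <- simulate_colony(cfg, y0 = y0)
  tot <- p$d * species_series(traj, "Hi")[, 1] +
    (1 - p$d) * species_series(traj, "He")[, 1]
  expect_lt(max(abs(tot - tot[1])), 1e-8)
})

test_that("explicit-diffusion stability bound is enforced", {
  expect_error(
    colony_config(n_cells = 4, step = 0.05, cell_spacing = 10,
                  params = study_params(D1 = 100)),
    "stability")
})

test_that("concentrations stay nonnegative over the study horizon", {
  traj <- simulate_colony(fast_colony(n_cells = 6, t_final = 500,
                                      model = "hotfm", seed = 2L))
  expect_true(all(traj$state >= 0))
})

test_that("trajectory tibble view is long and complete", {
  traj <- simulate_colony(fast_colony(n_cells = 3, t_final = 50))
  tb <- tibble::as_tibble(traj)
  expect_tibble(tb)
  expect_setequal(unique(tb$species), quorosc:::species_names())
  expect_equal(nrow(tb), length(traj$time) * 3 * 6)
  one <- dplyr::filter(tb, cell == 2, species == "A")
  expect_equal(one$value, unname(species_series(traj, "A")[, 2]))
})
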