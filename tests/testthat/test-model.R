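# Hill building blocks and cell-model derivatives.

test_that("density prefactor follows 1 - (d/d0)^4 and rejects bad input", {
  expect_equal(density_prefactor(0, 0.88), 1)
  expect_equal(density_prefactor(0.88, 0.88), 0)
  expect_equal(density_prefactor(0.44, 0.88), 1 - 0.5^4)
  expect_error(density_prefactor(0.5, 0), "d0")
  expect_error(density_prefactor(1, 0.88), "d must lie")
})

test_that("delayed production is basal at 0, saturates at delta + alpha/k1", {
  expect_equal(delayed_production(0, delta = 0.7, alpha = 2, k1 = 1), 0.7)
  expect_equal(delayed_production(1, delta = 1, alpha = 2, k1 = 1), 2)
  expect_equal(delayed_production(1e9, delta = 1, alpha = 2, k1 = 0.5),
               1 + 4, tolerance = 1e-6)
  H <- seq(0, 50, length.out = 200)
  P <- delayed_production(H, 1e-3, 2500, 0.1)
  expect_true(all(diff(P) >= 0))
  expect_error(delayed_production(-1, 0, 1, 1), "nonnegative")
})

test_that("repression factor hits its landmark values and is decreasing", {
  expect_equal(repression_factor(0, K = 100, n1 = 2), 1)
  expect_equal(repression_factor(100, K = 100, n1 = 2), 0.5)
  expect_equal(repression_factor(300, K = 100, n1 = 2), 0.1)
  R <- seq(0, 1000, length.out = 100)
  expect_true(all(diff(repression_factor(R, 100, 2)) <= 0))
  expect_error(repression_factor(1, K = 0, n1 = 2), "positive")
})

test_that("two-component activation is a Hill curve in TC", {
  expect_equal(tc_activation(0, 40, 800, 2), 0)
  expect_equal(tc_activation(800, 40, 800, 2), 20)
  expect_equal(tc_activation(1e12, 40, 800, 2), 40, tolerance = 1e-6)
  expect_error(tc_activation(1, 40, 0, 2), "positive")
})

test_that("danino derivatives match hand arithmetic and fixed points", {
  p <- oscillator_params(delta = 0, D1 = 0)
  z <- danino_derivatives(cell_state(), 0, p)
  expect_equal(unname(z), rep(0, 6))

  p2 <- oscillator_params(C_A = 1, d = 0, delta = 1, alpha = 0,
                          gamma_A = 1, f = 0.5, D1 = 0)
  dz <- danino_derivatives(cell_state(A = 1, I = 1), 0, p2)
  expect_equal(dz[["A"]], 1 - 1 / (1 + 0.5 * 2))

  # equilibrated membrane exchange: He = Hi removes both exchange terms
  p3 <- oscillator_params(b = 0, gamma_H = 0, mu = 0, delta = 0, D1 = 0)
  dz3 <- danino_derivatives(cell_state(A = 1, I = 0, Hi = 2, He = 2), 0, p3)
  expect_equal(dz3[["Hi"]], 0)
  expect_equal(dz3[["He"]], 0)
})

test_that("dark-gated model with zero repressor reproduces the plain model", {
  p <- study_params()
  ch <- channel_params()
  set.seed(99)
  for (i in 1:200) {
    s <- random_state()
    s[["R"]] <- 0
    s[["TC"]] <- 0
    hd <- stats::runif(1, 0, 5)
    lap <- stats::rnorm(1)
    d1 <- danino_derivatives(s, hd, p, lap)
    d2 <- hotfm_derivatives(s, hd, p, ch, light = "dark", He_laplacian = lap)
    expect_identical(d2[c("A", "I", "Hi", "He")], d1[c("A", "I", "Hi", "He")])
    expect_lte(d2[["R"]], 0)
  }
})

test_that("repression landmarks carry through the gated derivatives", {
  p <- study_params()
  s <- random_state()
  hd <- 2
  ch_half <- channel_params(K = s[["R"]] + (s[["R"]] == 0), n1 = 2)
  s[["R"]] <- ch_half$K
  d_plain <- danino_derivatives(s, hd, p)
  d_rep <- hotfm_derivatives(s, hd, p, ch_half, light = "green")
  pref <- density_prefactor(p$d, p$d0)
  P <- delayed_production(hd, p$delta, p$alpha, p$k1)
  # production halved at R = K
  expect_equal(d_plain[["A"]] - d_rep[["A"]], 0.5 * p$C_A * pref * P)

  # K -> infinity recovers the plain AiiA equation
  ch_weak <- channel_params(K = 1e12, n1 = 2)
  d_weak <- hotfm_derivatives(s, hd, p, ch_weak, light = "green")
  expect_equal(d_weak[["A"]], d_plain[["A"]], tolerance = 1e-12)
})

test_that("production and degradation terms keep their signs at random states", {
  p <- study_params()
  ch <- channel_params()
  set.seed(7)
  for (i in 1:100) {
    s <- random_state()
    hd <- stats::runif(1, 0, 10)
    dz <- hotfm_derivatives(s, hd, p, ch, light = "green")
    expect_true(all(is.finite(dz)))
    # with all degradations switched off, every derivative is nonnegative
  }
  p0 <- oscillator_params(gamma_A = 0, gamma_I = 0, gamma_H = 0, mu = 0,
                          D = 0, D1 = 0)
  ch0 <- channel_params(gamma_R = 0)
  for (i in 1:50) {
    s <- random_state()
    dz <- hotfm_derivatives(s, stats::runif(1, 0, 10), p0, ch0,
                            light = "green")
    expect_true(all(dz >= 0))
  }
})

test_that("compiled colony right-hand side agrees with the R formulas", {
  p <- study_params()
  gch <- channel_params()
  uch <- uv_channel()
  sched <- quorosc:::flatten_schedule(light_schedule(0, "green"))
  set.seed(123)
  for (i in 1:50) {
    n <- sample(2:5, 1)
    y <- t(vapply(seq_len(n), function(j) random_state(), numeric(6)))
    ylag <- t(vapply(seq_len(n), function(j) random_state(), numeric(6)))
    models <- sample(c("danino", "hotfm"), n, replace = TRUE)
    dx <- stats::runif(1, 5, 20)
    dcpp <- quorosc:::.colony_rhs_cpp(
      10, as.vector(t(y)), as.vector(t(ylag)),
      as.integer(models == "hotfm"),
      quorosc:::flatten_osc(p),
      quorosc:::flatten_chan(gch), quorosc:::flatten_chan(uch),
      sched$times, sched$codes, dx)
    for (j in seq_len(n)) {
      lap <- (y[ifelse(j == 1, n, j - 1), 4] - 2 * y[j, 4] +
              y[ifelse(j == n, 1, j + 1), 4]) / dx^2
      s <- stats::setNames(y[j, ], quorosc:::species_names())
      dr <- if (models[j] == "danino")
        danino_derivatives(s, ylag[j, 3], p, lap)
      else hotfm_derivatives(s, ylag[j, 3], p, gch, light = "green",
                             He_laplacian = lap)
      expect_equal(unname(dcpp[(j - 1) * 6 + 1:6]), unname(dr),
                   tolerance = 1e-12)
    }
  }
})
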