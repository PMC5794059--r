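# Right-hand sides of the cell models, in plain R.  These are the reference
# formulas; the compiled colony integrator reimplements them for speed and is
# cross-checked against these functions in the test suite.

#' Density-dependent production prefactor
#'
#' Protein production is attenuated by nutrient limitation and waste
#' accumulation as the colony densifies: the prefactor is
#' \eqn{1 - (d/d_0)^4}, equal to 1 in a dilute culture and 0 at saturation.
#'
#' @param d Cell density (dimensionless), `0 <= d <= d0`.
#' @param d0 Density saturation scale, > 0.
#' @return A number in \[0, 1\].
#' @export
density_prefactor <- function(d, d0) {
  if (any(d0 <= 0)) stop("d0 must be positive", call. = FALSE)
  if (any(d < 0) || any(d > d0)) stop("d must lie in [0, d0]", call. = FALSE)
  1 - (d / d0)^4
}

#' Delayed Hill production term
#'
#' The AHL-activated promoter drive
#' \eqn{P = \delta + \alpha H_\tau^2 / (1 + k_1 H_\tau^2)}, where
#' `H_tau` is the internal AHL concentration a delay tau ago.  Monotone
#' nondecreasing in `H_tau`, saturating at `delta + alpha/k1`.
#'
#' @param H_tau Delayed internal AHL concentration (a.u., >= 0).
#' @param delta Basal rate.
#' @param alpha,k1 Hill coefficients.
#' @return Production rate (>= 0).
#' @export
delayed_production <- function(H_tau, delta, alpha, k1) {
  if (any(H_tau < 0)) stop("H_tau must be nonnegative", call. = FALSE)
  delta + alpha * H_tau^2 / (1 + k1 * H_tau^2)
}

#' Hill repression factor
#'
#' \eqn{K^{n_1} / (R^{n_1} + K^{n_1})}: 1 with no repressor, 1/2 at
#' `R = K`, monotone decreasing in `R`.
#'
#' @param R Repressor concentration (a.u., >= 0).
#' @param K Repression coefficient (> 0).
#' @param n1 Cooperativity.
#' @return A number in (0, 1\].
#' @export
repression_factor <- function(R, K, n1) {
  if (any(K <= 0)) stop("K must be positive", call. = FALSE)
  if (any(R < 0)) stop("R must be nonnegative", call. = FALSE)
  K^n1 / (R^n1 + K^n1)
}

#' Two-component sensor activation
#'
#' Hill activation of repressor production by the phosphorylated response
#' regulator: \eqn{\alpha_{TC} TC^{n} / (TC^{n} + K_{TC}^{n})}.
#'
#' @param TC Two-component regulator concentration (a.u., >= 0).
#' @param alpha_TC Maximal rate.
#' @param K_TC Half-activation (> 0).
#' @param n_TC Cooperativity.
#' @return Activation rate in \[0, `alpha_TC`\].
#' @export
tc_activation <- function(TC, alpha_TC, K_TC, n_TC) {
  if (any(K_TC <= 0)) stop("K_TC must be positive", call. = FALSE)
  if (any(TC < 0)) stop("TC must be nonnegative", call. = FALSE)
  ifelse(TC > 0, alpha_TC * TC^n_TC / (TC^n_TC + K_TC^n_TC), 0)
}

#' Cell state constructor
#'
#' @param A,I,Hi,He AiiA, LuxI, internal and external AHL concentrations.
#' @param R,TC Repressor and two-component regulator concentrations (used by
#'   the light-gated model; remain 0 in the plain Danino model).
#' @return A named numeric vector of length 6 (species order `A`, `I`,
#'   `Hi`, `He`, `R`, `TC`).
#' @export
cell_state <- function(A = 0, I = 0, Hi = 0, He = 0, R = 0, TC = 0) {
  s <- c(A = A, I = I, Hi = Hi, He = He, R = R, TC = TC)
  if (any(s < 0)) stop("concentrations must be nonnegative", call. = FALSE)
  s
}

species_names <- function() c("A", "I", "Hi", "He", "R", "TC")

#' Time derivatives of the Danino oscillator cell
#'
#' The four coupled rates of the delayed quorum-sensing oscillator: AiiA and
#' LuxI driven by the common delayed Hill term, internal AHL synthesised by
#' LuxI and degraded by AiiA, and the external pool exchanging across the
#' membrane, decaying at rate `mu`, and (in a colony) receiving the
#' discrete diffusion term `D1 * He_laplacian`.
#'
#' @param state Named state vector from [cell_state()].
#' @param Hi_delayed Internal AHL concentration a delay `tau` ago.
#' @param params [oscillator_params()].
#' @param He_laplacian Discrete spatial Laplacian of external AHL at this
#'   cell (1/um^2 scale; 0 for an isolated "bulk" cell).
#' @return Named vector of time derivatives (the `R` and `TC` components
#'   are 0: the plain model carries no repressor).
#' @export
danino_derivatives <- function(state, Hi_delayed, params, He_laplacian = 0) {
  p <- params
  Hi_delayed <- unname(Hi_delayed)
  He_laplacian <- unname(He_laplacian)
  if (p$d >= 1) stop("d must be below 1", call. = FALSE)
  A <- state[["A"]]; I <- state[["I"]]
  Hi <- state[["Hi"]]; He <- state[["He"]]
  pref <- density_prefactor(p$d, p$d0)
  P <- delayed_production(Hi_delayed, p$delta, p$alpha, p$k1)
  dA <- p$C_A * pref * P - p$gamma_A * A / (1 + p$f * (A + I))
  dI <- p$C_I * pref * P - p$gamma_I * I / (1 + p$f * (A + I))
  dHi <- p$b * I / (1 + p$k * I) - p$gamma_H * A * Hi / (1 + p$g * A) +
    p$D * (He - Hi)
  dHe <- -(p$d / (1 - p$d)) * p$D * (He - Hi) - p$mu * He +
    (p$D1 * 60) * He_laplacian
  c(A = dA, I = dI, Hi = dHi, He = dHe, R = 0, TC = 0)
}

#' Time derivatives of the light-gated oscillator cell
#'
#' Extends the Danino cell with a repressor `R` and a two-component light
#' sensor `TC`: AiiA and `TC` production are both scaled by the Hill
#' repression factor of `R`, and `R` is produced through the sensor only
#' while the ambient light matches the channel's activating condition.  In
#' the dark (gate closed) with `R = TC = 0` the derivatives of
#' `(A, I, Hi, He)` coincide exactly with [danino_derivatives()].
#'
#' @inheritParams danino_derivatives
#' @param channel [channel_params()] of the active channel.
#' @param light Current light condition, one of [light_conditions()].
#' @return Named vector of time derivatives.
#' @export
hotfm_derivatives <- function(state, Hi_delayed, params, channel,
                              light = "dark", He_laplacian = 0) {
  p <- params
  Hi_delayed <- unname(Hi_delayed)
  light <- match.arg(light, light_conditions())
  base <- danino_derivatives(state, Hi_delayed, params, He_laplacian)
  A <- state[["A"]]; I <- state[["I"]]
  R <- state[["R"]]; TC <- state[["TC"]]
  pref <- density_prefactor(p$d, p$d0)
  P <- delayed_production(Hi_delayed, p$delta, p$alpha, p$k1)
  repf <- repression_factor(R, channel$K, channel$n1)
  gate <- as.numeric(identical(light, channel$activating_light))
  dA <- p$C_A * pref * P * repf - p$gamma_A * A / (1 + p$f * (A + I))
  dTC <- p$C_A * pref * P * repf - p$gamma_TC * TC / (1 + p$f * (TC + I))
  dR <- gate * pref *
    tc_activation(TC, channel$alpha_TC, channel$K_TC, channel$n_TC) -
    channel$gamma_R * R / (1 + p$f * R)
  c(A = dA, I = base[["I"]], Hi = base[["Hi"]], He = base[["He"]],
    R = dR, TC = dTC)
}
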