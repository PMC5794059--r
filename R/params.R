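# Parameter containers for the oscillator cell models.
#
# Time is in minutes and concentrations in arbitrary units (a.u.) throughout.
# The extracellular diffusion constant D1 is supplied in um^2/s, the unit in
# which it is usually quoted, and converted to um^2/min internally.

# canonical flattening order shared with the compiled core (src/dde.cpp)
osc_par_order <- c("C_A", "C_I", "delta", "alpha", "k1", "tau",
                   "gamma_A", "gamma_I", "gamma_H", "f", "g", "k", "b",
                   "d", "d0", "D", "mu", "D1", "gamma_TC")
chan_par_order <- c("alpha_TC", "K_TC", "n_TC", "K", "n1", "gamma_R",
                    "activating_light")

#' Light conditions understood by the gated repressor channels
#'
#' The repressor channel of a light-gated cell is switched on only while the
#' ambient light matches its activating condition; `"dark"` gates every
#' channel off, so a light-gated cell in the dark behaves exactly like the
#' plain Danino oscillator.
#'
#' @return Character vector of the three recognised conditions.
#' @export
light_conditions <- function() c("dark", "green", "uv_violet")

light_code <- function(condition) {
  match(match.arg(condition, light_conditions()), light_conditions()) - 1L
}

#' Oscillator cell parameters
#'
#' Rate constants and Hill coefficients of the delayed quorum-sensing
#' oscillator: AiiA (`A`) and LuxI (`I`) are produced from a common
#' AHL-activated promoter with delayed Hill kinetics
#' \eqn{P = \delta + \alpha H_\tau^2 / (1 + k_1 H_\tau^2)} and degraded
#' enzymatically with shared Michaelis--Menten saturation; internal AHL
#' (`Hi`) is synthesised by LuxI, degraded by AiiA, and exchanged with the
#' external pool (`He`), which in a colony also diffuses between cells.
#'
#' Defaults are the package's baseline parameterisation of the published
#' Danino-type model (see the methods vignette for provenance and the
#' rationale behind `mu` and `d`).
#'
#' @param C_A,C_I Production scales of AiiA and LuxI (a.u./min).
#' @param delta Basal production rate inside the delayed Hill term.
#' @param alpha,k1 Hill coefficients of the delayed production term.
#' @param tau Transcriptional delay (min).
#' @param gamma_A,gamma_I,gamma_H Enzymatic degradation rates of AiiA, LuxI
#'   and internal AHL (1/min).
#' @param f,g,k Michaelis--Menten denominator coefficients (1/a.u.).
#' @param b AHL synthesis rate per LuxI (1/min).
#' @param d,d0 Cell density and its saturation scale; production carries the
#'   prefactor \eqn{1 - (d/d_0)^4} and the membrane-exchange term in the
#'   external pool the factor \eqn{d/(1-d)}, so `d < 1` and `d <= d0` are
#'   required.
#' @param D Membrane diffusion rate of AHL (1/min).
#' @param mu External AHL decay/flow rate (1/min).
#' @param D1 Extracellular AHL diffusion constant (um^2/s); converted to
#'   um^2/min internally.  Set to zero for "bulk" single-cell simulations.
#' @param gamma_TC Optional degradation rate for the two-component regulator;
#'   defaults to `gamma_A`, matching the model equations in which the
#'   regulator shares the AiiA degradation machinery.
#'
#' @return An object of class `oscillator_params` (a named list).
#' @examples
#' p <- oscillator_params()                 # baseline
#' p <- oscillator_params(gamma_A = 23, gamma_H = 0.023)  # study overrides
#' @export
oscillator_params <- function(C_A = 1, C_I = 4, delta = 1e-3, alpha = 2500,
                              k1 = 0.1, tau = 10, gamma_A = 15, gamma_I = 24,
                              gamma_H = 0.01, f = 0.3, g = 0.01, k = 1,
                              b = 0.06, d = 0.5, d0 = 0.88, D = 2.5,
                              mu = 0.1, D1 = 100, gamma_TC = NULL) {
  p <- list(C_A = C_A, C_I = C_I, delta = delta, alpha = alpha, k1 = k1,
            tau = tau, gamma_A = gamma_A, gamma_I = gamma_I,
            gamma_H = gamma_H, f = f, g = g, k = k, b = b, d = d, d0 = d0,
            D = D, mu = mu, D1 = D1,
            gamma_TC = if (is.null(gamma_TC)) gamma_A else gamma_TC)
  validate_oscillator_params(p)
  structure(p, class = "oscillator_params")
}

validate_oscillator_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && !is.na(x),
                logical(1))
  if (!all(num)) {
    stop("oscillator parameter(s) not a single number: ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  neg <- unlist(p) < 0
  if (any(neg)) {
    stop("oscillator parameter(s) must be nonnegative: ",
         paste(names(p)[neg], collapse = ", "), call. = FALSE)
  }
  if (p$tau <= 0) stop("tau must be positive", call. = FALSE)
  if (p$d0 <= 0) stop("d0 must be positive", call. = FALSE)
  if (p$d > p$d0) stop("d must not exceed d0", call. = FALSE)
  if (p$d >= 1) stop("d must be below 1 (the d/(1-d) factor diverges)",
                     call. = FALSE)
  invisible(p)
}

#' Study parameterisation used by the synchronization experiments
#'
#' The baseline oscillator parameters with the degradation overrides used
#' throughout the colony-level experiments: `gamma_A = 23`,
#' `gamma_H = 0.023`, and extracellular diffusion `D1 = 100` um^2/s.
#'
#' @param gamma_A,gamma_H,D1 Study values (overridable).
#' @param ... Further overrides passed to [oscillator_params()].
#' @return An `oscillator_params` object.
#' @export
study_params <- function(gamma_A = 23, gamma_H = 0.023, D1 = 100, ...) {
  oscillator_params(gamma_A = gamma_A, gamma_H = gamma_H, D1 = D1, ...)
}

#' Light-gated repressor channel parameters
#'
#' A channel couples a two-component light sensor (Hill activation of the
#' repressor with maximum rate `alpha_TC`, half-activation `K_TC` and
#' cooperativity `n_TC`) to Hill repression of AiiA production (repression
#' coefficient `K`, cooperativity `n1`), with repressor degradation
#' `gamma_R`.  The channel is active only while the ambient light equals
#' `activating_light`.
#'
#' Defaults describe the green-light channel with a TetR-class repressor
#' (`K = 100`, `gamma_R = 1.5`); [uv_channel()] returns the UV-violet
#' channel whose slow repressor turnover places the cell below the Hopf
#' boundary, extinguishing oscillations (the kill switch).
#'
#' @param alpha_TC Maximal repressor production rate (a.u./min).
#' @param K_TC Half-activation level of the sensor Hill term (a.u.).
#' @param n_TC Sensor cooperativity (>= 1).
#' @param K Repression coefficient of the repressor (a.u.), > 0.
#' @param n1 Repressor cooperativity (>= 1).
#' @param gamma_R Repressor degradation rate (1/min).
#' @param activating_light One of [light_conditions()].
#' @return An object of class `channel_params`.
#' @export
channel_params <- function(alpha_TC = 40, K_TC = 800, n_TC = 2, K = 100,
                           n1 = 2, gamma_R = 1.5,
                           activating_light = "green") {
  activating_light <- match.arg(activating_light, light_conditions())
  p <- list(alpha_TC = alpha_TC, K_TC = K_TC, n_TC = n_TC, K = K, n1 = n1,
            gamma_R = gamma_R, activating_light = activating_light)
  nums <- p[setdiff(names(p), "activating_light")]
  bad <- !vapply(nums, function(x)
    is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0, logical(1))
  if (any(bad)) {
    stop("channel parameter(s) invalid: ",
         paste(names(nums)[bad], collapse = ", "), call. = FALSE)
  }
  if (p$K <= 0) stop("K must be positive", call. = FALSE)
  if (p$n_TC < 1 || p$n1 < 1) stop("cooperativities must be >= 1",
                                   call. = FALSE)
  structure(p, class = "channel_params")
}

#' @rdname channel_params
#' @export
uv_channel <- function() {
  channel_params(gamma_R = 0.01, activating_light = "uv_violet")
}

#' Piecewise-constant light schedule
#'
#' @param times Breakpoint times (min), strictly increasing, starting at 0.
#' @param conditions One of [light_conditions()] per breakpoint; each holds
#'   from its time until the next breakpoint.
#' @return An object of class `light_schedule`.
#' @examples
#' light_schedule(0, "green")                       # constant green light
#' light_schedule(c(0, 200), c("dark", "uv_violet"))  # kill switch at 200 min
#' @export
light_schedule <- function(times = 0, conditions = "dark") {
  if (length(times) != length(conditions))
    stop("times and conditions must have equal length", call. = FALSE)
  if (length(times) < 1 || times[1] != 0)
    stop("the first breakpoint must be at time 0", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("breakpoint times must be strictly increasing", call. = FALSE)
  conditions <- vapply(conditions, function(x)
    match.arg(x, light_conditions()), character(1), USE.NAMES = FALSE)
  structure(list(times = as.numeric(times), conditions = conditions),
            class = "light_schedule")
}

#' @export
print.light_schedule <- function(x, ...) {
  cat("<light_schedule>\n")
  for (i in seq_along(x$times))
    cat(sprintf("  from %g min: %s\n", x$times[i], x$conditions[i]))
  invisible(x)
}

schedule_at <- function(schedule, t) {
  idx <- findInterval(t, schedule$times)
  schedule$conditions[pmax(idx, 1L)]
}

# flatteners used at the R/C++ boundary -------------------------------------

flatten_osc <- function(p) {
  v <- vapply(osc_par_order, function(nm) p[[nm]], numeric(1))
  v[["D1"]] <- p$D1 * 60  # um^2/s -> um^2/min
  unname(v)
}

flatten_chan <- function(ch) {
  c(ch$alpha_TC, ch$K_TC, ch$n_TC, ch$K, ch$n1, ch$gamma_R,
    light_code(ch$activating_light))
}

flatten_schedule <- function(s) {
  list(times = s$times,
       codes = vapply(s$conditions, light_code, integer(1), USE.NAMES = FALSE))
}

#' @export
print.oscillator_params <- function(x, ...) {
  cat("<oscillator_params>\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' @export
print.channel_params <- function(x, ...) {
  cat("<channel_params> activating light:", x$activating_light, "\n")
  print(unlist(x[setdiff(names(x), "activating_light")]))
  invisible(x)
}
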