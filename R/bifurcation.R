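# Two-parameter behaviour maps and simulation-based Hopf-boundary location.
#
# Oscillatory/steady labels come from deterministic single-cell ("bulk")
# simulations with zero initial noise; the Hopf boundary between them is
# localised by bisection.  This replaces continuation-based branch tracking
# and is validated against the analytic boundary of the scalar linear delay
# equation in the test suite.

#' Parameter axis for sweeps
#'
#' @param name Parameter name; a field of [oscillator_params()] or
#'   [channel_params()].
#' @param min,max Axis range (min < max).
#' @param n_points Number of grid points (>= 2).
#' @param scale `"linear"` or `"log"` spacing.
#' @return A `param_axis` list.
#' @export
param_axis <- function(name, min, max, n_points = 20, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  known <- c(osc_par_order, chan_par_order)
  if (!name %in% known)
    stop("unknown parameter name: ", name, call. = FALSE)
  if (!(min < max)) stop("min must be below max", call. = FALSE)
  if (n_points < 2) stop("n_points must be at least 2", call. = FALSE)
  if (scale == "log" && min <= 0) stop("log axis requires min > 0",
                                       call. = FALSE)
  values <- if (scale == "linear") seq(min, max, length.out = n_points)
            else exp(seq(log(min), log(max), length.out = n_points))
  structure(list(name = name, min = min, max = max,
                 n_points = as.integer(n_points), scale = scale,
                 values = values), class = "param_axis")
}

apply_point <- function(params, green, uv, named_values) {
  p <- unclass(params)
  g <- unclass(green)
  u <- unclass(uv)
  # a gamma_TC equal to the base gamma_A is treated as "tracking" and is
  # re-derived after any gamma_A override
  if (isTRUE(all.equal(p$gamma_TC, p$gamma_A))) p$gamma_TC <- NULL
  for (nm in names(named_values)) {
    v <- named_values[[nm]]
    if (nm %in% osc_par_order) p[[nm]] <- v else g[[nm]] <- v
  }
  list(params = do.call(oscillator_params, p),
       green = do.call(channel_params, g), uv = do.call(channel_params, u))
}

classify_point <- function(model, params, green, uv, light, t_final,
                           t_transient, rel_tol) {
  series <- bulk_series(model, params, green, uv, light, t_final)
  period_and_amplitude(series, t_transient = t_transient, rel_tol = rel_tol)
}

#' Two-parameter behaviour sweep
#'
#' Simulates the single-cell bulk model (diffusion dropped, zero initial
#' noise) at every grid point of two parameter axes, classifies each point
#' as oscillatory or steady, and records period and amplitude where
#' oscillatory.
#'
#' @param model `"danino"` or `"hotfm"`.
#' @param axis_x,axis_y [param_axis()] objects naming distinct parameters.
#' @param params Base [oscillator_params()].
#' @param green,uv Channel parameters for gated cells.
#' @param light Light condition held during the sweep (default `"green"`).
#' @param t_final Simulation horizon per point (min).
#' @param t_transient Transient cut; defaults to half the horizon.
#' @param rel_tol Classifier tolerance.
#' @return A `bifurcation_map`: tibble with columns `x`, `y`, `label`,
#'   `period`, `amplitude` plus axis metadata in attributes.
#' @export
sweep_two_params <- function(model = c("danino", "hotfm"), axis_x, axis_y,
                             params = study_params(),
                             green = channel_params(), uv = uv_channel(),
                             light = "green", t_final = 1500,
                             t_transient = NULL, rel_tol = 1e-3) {
  model <- match.arg(model)
  if (axis_x$name == axis_y$name)
    stop("axes must name distinct parameters", call. = FALSE)
  if (is.null(t_transient)) t_transient <- 0.5 * t_final
  grid <- tidyr::expand_grid(x = axis_x$values, y = axis_y$values)
  res <- purrr::pmap_dfr(grid, function(x, y) {
    pt <- stats::setNames(list(x, y), c(axis_x$name, axis_y$name))
    ap <- apply_point(params, green, uv, pt)
    out <- tryCatch(
      classify_point(model, ap$params, ap$green, ap$uv, light, t_final,
                     t_transient, rel_tol),
      error = function(e) tibble::tibble(label = "failed", period = NA_real_,
                                         amplitude = NA_real_,
                                         n_peaks_used = 0L))
    tibble::tibble(x = x, y = y, label = out$label, period = out$period,
                   amplitude = out$amplitude)
  })
  structure(res, class = c("bifurcation_map", class(res)),
            axis_x = axis_x, axis_y = axis_y, model = model)
}

#' Locate the Hopf boundary by bisection
#'
#' For each value on `axis_x`, bisects the second parameter between a
#' steady and an oscillatory bracket endpoint until the bracket is narrower
#' than `tol`, and returns the midpoint as the boundary estimate.
#'
#' @param model `"danino"` or `"hotfm"`, or a classifier function
#'   `f(x, y)` returning `"oscillatory"`/`"steady_state"` (useful for
#'   testing against analytic oracles).
#' @param axis_x [param_axis()] for the swept abscissa.
#' @param y_name Name of the bisected parameter (ignored when `model` is a
#'   function).
#' @param y_bracket Length-2 numeric; the two endpoints must classify
#'   differently at every `x`.
#' @param tol Absolute tolerance on the boundary location.
#' @inheritParams sweep_two_params
#' @return A tibble with columns `x`, `y_boundary`.
#' @export
hopf_boundary <- function(model, axis_x, y_name = NULL,
                          y_bracket, tol = NULL,
                          params = study_params(),
                          green = channel_params(), uv = uv_channel(),
                          light = "green", t_final = 1500,
                          t_transient = NULL, rel_tol = 1e-3) {
  if (is.null(tol)) tol <- diff(range(y_bracket)) / 100
  if (is.function(model)) {
    classify <- model
  } else {
    model <- match.arg(model, c("danino", "hotfm"))
    if (is.null(t_transient)) t_transient <- 0.5 * t_final
    classify <- function(x, y) {
      pt <- stats::setNames(list(x, y), c(axis_x$name, y_name))
      ap <- apply_point(params, green, uv, pt)
      classify_point(model, ap$params, ap$green, ap$uv, light, t_final,
                     t_transient, rel_tol)$label
    }
  }
  purrr::map_dfr(axis_x$values, function(x) {
    c1 <- classify(x, y_bracket[1])
    c2 <- classify(x, y_bracket[2])
    if (identical(c1, c2))
      stop(sprintf("bracket endpoints classify identically at x = %g", x),
           call. = FALSE)
    lo <- y_bracket[1]; hi <- y_bracket[2]
    cl_lo <- c1
    while (abs(hi - lo) > tol) {
      mid <- (lo + hi) / 2
      if (identical(classify(x, mid), cl_lo)) lo <- mid else hi <- mid
    }
    tibble::tibble(x = x, y_boundary = (lo + hi) / 2)
  })
}

#' Repressor degradation sweep at fixed repression coefficient
#'
#' Sweeps `gamma_R` of the green channel at fixed `K`, classifying the bulk
#' gated model at each value and recording period and amplitude of the AiiA
#' oscillation; the unrepressed (Danino) reference is computed once and
#' attached.  Above the Hopf boundary both period and amplitude grow with
#' `gamma_R`, approaching the reference as the repressor is degraded too
#' fast to act.
#'
#' @param gamma_R_values Swept degradation rates (1/min); the default spans
#'   the supercritical window above the boundary of the default channel.
#' @param K Repression coefficient (default 100).
#' @inheritParams sweep_two_params
#' @return A tibble (`gamma_R`, `label`, `period`, `amplitude`) with the
#'   Danino reference row in attribute `"reference"`.
#' @export
degradation_sweep <- function(gamma_R_values = seq(0.04, 0.14, by = 0.01),
                              K = 100, params = study_params(),
                              green = channel_params(), uv = uv_channel(),
                              t_final = 3000, t_transient = NULL,
                              rel_tol = 1e-3) {
  if (K <= 0) stop("K must be positive", call. = FALSE)
  if (is.null(t_transient)) t_transient <- 0.5 * t_final
  res <- purrr::map_dfr(gamma_R_values, function(gr) {
    ap <- apply_point(params, green, uv, list(K = K, gamma_R = gr))
    out <- classify_point("hotfm", ap$params, ap$green, ap$uv, "green",
                          t_final, t_transient, rel_tol)
    tibble::tibble(gamma_R = gr, label = out$label, period = out$period,
                   amplitude = out$amplitude)
  })
  ref <- classify_point("danino", params, green, uv, "green", t_final,
                        t_transient, rel_tol)
  attr(res, "reference") <- ref
  res
}
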