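# Post-transient behaviour classification and cycle measurement.

# local maxima; runs of equal values (plateaus) count as a single peak
find_peaks <- function(y, min_prominence = 0) {
  if (length(y) < 3) return(integer(0))
  dy <- diff(y)
  nz <- which(dy != 0)
  if (length(nz) < 2) return(integer(0))
  s <- sign(dy[nz])
  chg <- which(s[-length(s)] > 0 & s[-1] < 0)
  idx <- nz[chg] + 1L
  if (min_prominence > 0 && length(idx))
    idx <- idx[y[idx] - min(y) >= min_prominence]
  idx
}

#' Classify a time series as steady or oscillatory
#'
#' A series is called oscillatory when, on the window after `t_transient`,
#' its range exceeds `rel_tol * max(1, mean)` and it carries at least three
#' local maxima with consistent spacing (coefficient of variation of the
#' inter-peak intervals below 0.2).  Damped or irregular signals fall back
#' to `"steady_state"`.
#'
#' @param data A data frame with columns `time` and `value` (or a numeric
#'   vector with `times` supplied).
#' @param t_transient Length of the initial transient to discard (min);
#'   defaults to 40% of the horizon.
#' @param rel_tol Relative amplitude tolerance (default `1e-3`).
#' @param times Time grid when `data` is a bare numeric vector.
#' @return `"oscillatory"` or `"steady_state"`.
#' @export
classify_behavior <- function(data, t_transient = NULL, rel_tol = 1e-3,
                              times = NULL) {
  xy <- as_series(data, times)
  horizon <- xy$time[length(xy$time)]
  if (is.null(t_transient)) t_transient <- 0.4 * horizon
  if (horizon < 2 * t_transient)
    stop("series must cover at least twice the transient window",
         call. = FALSE)
  y <- xy$value[xy$time >= t_transient]
  tt <- xy$time[xy$time >= t_transient]
  rng <- max(y) - min(y)
  if (!(rng > rel_tol * max(1, mean(y)))) return("steady_state")
  pk <- find_peaks(y, min_prominence = rel_tol * rng)
  if (length(pk) < 3) return("steady_state")
  iv <- diff(tt[pk])
  if (stats::sd(iv) / mean(iv) >= 0.2) return("steady_state")
  "oscillatory"
}

as_series <- function(data, times = NULL) {
  if (is.data.frame(data)) {
    stopifnot(all(c("time", "value") %in% names(data)))
    list(time = data$time, value = data$value)
  } else {
    if (is.null(times)) times <- seq_along(data) - 1
    list(time = times, value = as.numeric(data))
  }
}

#' Measure period and amplitude of an oscillatory series
#'
#' Period is the mean inter-peak interval over the post-transient window;
#' amplitude is half the peak-to-trough range over the last three full
#' cycles (robust to slow drifts).
#'
#' @inheritParams classify_behavior
#' @return A one-row tibble (`label`, `period`, `amplitude`,
#'   `n_peaks_used`); `period`/`amplitude` are `NA` for a steady series.
#' @export
period_and_amplitude <- function(data, t_transient = NULL, rel_tol = 1e-3,
                                 times = NULL) {
  xy <- as_series(data, times)
  horizon <- xy$time[length(xy$time)]
  if (is.null(t_transient)) t_transient <- 0.4 * horizon
  label <- classify_behavior(data, t_transient, rel_tol, times)
  if (label == "steady_state") {
    return(tibble::tibble(label = label, period = NA_real_,
                          amplitude = NA_real_, n_peaks_used = 0L))
  }
  y <- xy$value[xy$time >= t_transient]
  tt <- xy$time[xy$time >= t_transient]
  rng <- max(y) - min(y)
  pk <- find_peaks(y, min_prominence = rel_tol * rng)
  if (length(pk) < 3) stop("fewer than 3 peaks after transient",
                           call. = FALSE)
  period <- mean(diff(tt[pk]))
  first <- pk[max(1L, length(pk) - 3L)]
  seg <- y[first:length(y)]
  tibble::tibble(label = label, period = period,
                 amplitude = (max(seg) - min(seg)) / 2,
                 n_peaks_used = length(pk))
}

# convenience: single-cell ("bulk") simulation of either model under a
# constant light condition, returning the AiiA series
bulk_series <- function(model = c("danino", "hotfm"),
                        params = study_params(),
                        green = channel_params(), uv = uv_channel(),
                        light = "green", t_final = 2000,
                        species = "A", y0 = NULL) {
  model <- match.arg(model)
  cfg <- colony_config(
    n_cells = 1, model_per_cell = model,
    params = do.call(oscillator_params,
                     utils::modifyList(unclass(params), list(D1 = 0))),
    green = green, uv = uv,
    schedule = light_schedule(0, light),
    t_final = t_final, noise_width = 0, seed = 1L)
  traj <- simulate_colony(cfg, y0 = y0)
  tibble::tibble(time = traj$time,
                 value = species_series(traj, species)[, 1])
}
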