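# Synchronization metrics: absolute synchronization error (ASE) over a
# periodic cell array, its time integral (IASE), and the synchronization
# rate r from an exponential envelope fitted to the ASE maxima.

#' Absolute synchronization error at one instant
#'
#' Mean absolute nearest-neighbour difference around the periodic array:
#' \eqn{(\sum_{i=1}^{n-1} |A_i - A_{i+1}| + |A_n - A_1|) / n}.
#'
#' @param values Concentrations of one species across the cells (n >= 2).
#' @return A nonnegative number; 0 iff all cells agree.
#' @export
ase_at <- function(values) {
  n <- length(values)
  if (n < 2) stop("ASE needs at least 2 cells", call. = FALSE)
  sum(abs(diff(c(values, values[1])))) / n
}

#' ASE time series of a colony trajectory
#'
#' @param traj A `colony_trajectory` with at least 2 cells.
#' @param species Species on which to measure synchronization (default
#'   AiiA, the reported species).
#' @param normalize Divide by the post-transient oscillation amplitude of
#'   the colony-mean signal (off by default; the plain definition carries
#'   no amplitude factor).
#' @return An `ase_series` tibble with columns `time`, `ase`.
#' @export
ase_series <- function(traj, species = "A", normalize = FALSE) {
  if (traj$n_cells < 2) stop("ASE needs at least 2 cells", call. = FALSE)
  mat <- species_series(traj, species)
  n <- ncol(mat)
  wrapped <- cbind(mat, mat[, 1])
  ase <- rowSums(abs(wrapped[, -1, drop = FALSE] -
                     wrapped[, -(n + 1), drop = FALSE])) / n
  if (normalize) {
    mean_sig <- rowMeans(mat)
    pa <- period_and_amplitude(tibble::tibble(time = traj$time,
                                              value = mean_sig))
    if (!is.na(pa$amplitude) && pa$amplitude > 0) ase <- ase / pa$amplitude
  }
  out <- tibble::tibble(time = traj$time, ase = ase)
  class(out) <- c("ase_series", class(out))
  out
}

#' Integrated absolute synchronization error
#'
#' Trapezoidal integral of ASE(t) over the simulated horizon.
#'
#' @param series An `ase_series` (or any data frame with `time` and `ase`
#'   columns).
#' @return A nonnegative number (a.u. x min).
#' @export
iase <- function(series) {
  t <- series$time
  y <- series$ase
  if (length(t) < 2) stop("need at least two time points", call. = FALSE)
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Synchronization rate from an exponential envelope
#'
#' Extracts the local maxima of ASE(t) and fits
#' \eqn{E(t) = a e^{-r t}} by least squares on the log of the maxima.
#' Positive `r` means the colony is synchronizing; `r` near 0 means the
#' desynchronization neither grows nor decays.
#'
#' @param series An `ase_series`.
#' @param min_prominence Peak prominence threshold as a fraction of the ASE
#'   range (default 0.01).
#' @return A `sync_fit` object with elements `a`, `r`, `n_maxima_used`,
#'   `fit` (the underlying `lm`), supporting [generics::tidy()] and
#'   [generics::glance()].
#' @export
sync_rate <- function(series, min_prominence = 0.01) {
  t <- series$time
  y <- series$ase
  if (all(y == 0))
    return(new_sync_fit(a = 0, r = Inf, n = 0L, fit = NULL,
                        perfect_synchrony = TRUE))
  pk <- find_peaks(y, min_prominence = min_prominence * (max(y) - min(y)))
  if (length(pk) < 3)
    stop("need at least 3 ASE maxima to fit an envelope", call. = FALSE)
  if (any(y[pk] <= 0))
    stop("zero ASE maximum: envelope undefined (perfect synchrony?)",
         call. = FALSE)
  fit <- stats::lm(log(y[pk]) ~ t[pk])
  co <- stats::coef(fit)
  new_sync_fit(a = exp(co[[1]]), r = -co[[2]], n = length(pk), fit = fit)
}

new_sync_fit <- function(a, r, n, fit, perfect_synchrony = FALSE) {
  structure(list(a = a, r = r, n_maxima_used = n, fit = fit,
                 perfect_synchrony = perfect_synchrony),
            class = "sync_fit")
}

#' @export
print.sync_fit <- function(x, ...) {
  if (x$perfect_synchrony) {
    cat("<sync_fit> perfect synchrony (ASE identically 0)\n")
  } else {
    cat(sprintf("<sync_fit> a = %.4g, r = %.4g /min (%d maxima)\n",
                x$a, x$r, x$n_maxima_used))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.sync_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "r"), estimate = c(x$a, x$r))
}

#' @export
glance.sync_fit <- function(x, ...) {
  r2 <- if (is.null(x$fit)) NA_real_ else summary(x$fit)$r.squared
  tibble::tibble(a = x$a, r = x$r, n_maxima_used = x$n_maxima_used,
                 r.squared = r2,
                 perfect_synchrony = x$perfect_synchrony)
}
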