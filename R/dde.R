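# R-facing surface of the method-of-steps integrator.

#' Constant-history function
#'
#' @param state State vector to hold over the whole initial interval
#'   \[-tau, 0\].
#' @return A history function `h(t)` returning `state` for every `t`.
#' @export
constant_history <- function(state) {
  force(state)
  structure(function(t) state, constant = TRUE, class = "dde_history")
}

sample_history <- function(history, dim, tau, h) {
  m <- as.integer(ceiling(tau / h - 1e-9))
  ts <- (-m:0) * h
  if (isTRUE(attr(history, "constant"))) {
    y0 <- history(0)
    hist_y <- matrix(rep(as.numeric(y0), each = m + 1), m + 1, dim)
    hist_f <- matrix(0, m + 1, dim)
  } else {
    hist_y <- matrix(vapply(ts, function(s) as.numeric(history(s)),
                            numeric(dim)),
                     nrow = m + 1, ncol = dim, byrow = TRUE)
    # centred finite-difference derivative of the sampled history, used by
    # the Hermite lookups that reach back before t = 0
    hist_f <- matrix(0, m + 1, dim)
    if (m >= 1) {
      for (j in seq_len(dim)) {
        yj <- hist_y[, j]
        hist_f[, j] <- c(yj[2] - yj[1],
                         if (m >= 2) (yj[-(1:2)] - yj[seq_len(m - 1)]) / 2
                         else numeric(0),
                         yj[m + 1] - yj[m]) / h
      }
    }
  }
  list(y = hist_y, f = hist_f)
}

#' Integrate a delay differential equation with one constant delay
#'
#' Method of steps with a classical fourth-order Runge--Kutta step and cubic
#' Hermite interpolation for the delayed state; fixed step size.  Identical
#' inputs give bitwise-identical trajectories.
#'
#' @param rhs Function `rhs(t, y, y_delayed)` returning the derivative
#'   vector; `y_delayed` is the state at `t - tau`.
#' @param tau Delay (min), > 0.
#' @param history Either a function of `t` defined on \[-tau, 0\] or a
#'   numeric vector taken as a constant history.
#' @param t_final End of integration (min), > 0.
#' @param step Step size (min); must satisfy `step <= tau` and is nudged so
#'   that `t_final` is an exact multiple.  Defaults to `min(tau/20, 0.05)`.
#' @param save_every Thin the returned grid to every `save_every`-th step
#'   (the integrator always steps at `step` internally).
#' @return A `dde_trajectory`: list with `time`, `state` (matrix, one row
#'   per saved time), `deriv`, `tau`, `step`, and the history, supporting
#'   [dense_eval()] and [tibble::as_tibble()].
#' @examples
#' # y'(t) = -y(t - 1), unit history: y(1) = 0, y(2) = -0.5 exactly
#' traj <- integrate_dde(function(t, y, z) -z, tau = 1,
#'                       history = 1, t_final = 2, step = 0.05)
#' dense_eval(traj, c(1, 2))
#' @export
integrate_dde <- function(rhs, tau, history, t_final,
                          step = min(tau / 20, 0.05), save_every = 1L) {
  stopifnot(tau > 0, t_final > 0, step > 0)
  if (step > tau)
    stop("step must not exceed the delay tau", call. = FALSE)
  if (is.numeric(history)) history <- constant_history(history)
  dim <- length(history(0))
  n_steps <- max(1L, as.integer(round(t_final / step)))
  step <- t_final / n_steps
  hs <- sample_history(history, dim, tau, step)
  res <- .dde_integrate_r(function(t, y, z) as.numeric(rhs(t, y, z)),
                          hs$y, hs$f, tau, step, t_final,
                          as.integer(save_every))
  new_dde_trajectory(res, tau = tau, step = step, history = history)
}

new_dde_trajectory <- function(res, tau, step, history,
                               state_names = NULL, metadata = list()) {
  state <- res$state
  if (!is.null(state_names)) colnames(state) <- state_names
  structure(list(time = as.numeric(res$time), state = state,
                 deriv = res$deriv, tau = tau, step = step,
                 history = history,
                 n_clamped = res$n_clamped %||% 0,
                 metadata = metadata),
            class = "dde_trajectory")
}

#' Evaluate a trajectory between grid points
#'
#' Cubic Hermite interpolation on the stored grid (exact at grid points);
#' for `t < 0`, the initial history is returned.
#'
#' @param traj A `dde_trajectory`.
#' @param t Times in \[-tau, t_final\].
#' @return A matrix with one row per requested time (or a vector for a
#'   single time in a one-dimensional system).
#' @export
dense_eval <- function(traj, t) {
  tr <- traj
  t_end <- tr$time[length(tr$time)]
  if (any(t < -tr$tau - 1e-9) || any(t > t_end + 1e-9))
    stop("t outside [-tau, t_final]", call. = FALSE)
  dim <- ncol(tr$state)
  out <- matrix(NA_real_, length(t), dim)
  colnames(out) <- colnames(tr$state)
  for (i in seq_along(t)) {
    s <- t[i]
    if (s < 0) {
      out[i, ] <- as.numeric(tr$history(s))
      next
    }
    j <- findInterval(s, tr$time, rightmost.closed = TRUE)
    j <- min(max(j, 1L), length(tr$time) - 1L)
    h <- tr$time[j + 1] - tr$time[j]
    th <- (s - tr$time[j]) / h
    h00 <- 2 * th^3 - 3 * th^2 + 1
    h10 <- th^3 - 2 * th^2 + th
    h01 <- -2 * th^3 + 3 * th^2
    h11 <- th^3 - th^2
    out[i, ] <- h00 * tr$state[j, ] + h * h10 * tr$deriv[j, ] +
      h01 * tr$state[j + 1, ] + h * h11 * tr$deriv[j + 1, ]
  }
  if (dim == 1L) drop(out) else out
}

#' @export
print.dde_trajectory <- function(x, ...) {
  cat(sprintf("<dde_trajectory> %d states, %d saved points on [0, %g] min (step %g, tau %g)\n",
              ncol(x$state), length(x$time), x$time[length(x$time)],
              x$step, x$tau))
  invisible(x)
}

#' Tidy a trajectory into a long tibble
#'
#' @param x A `dde_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `variable`, `value`.
#' @export
as_tibble.dde_trajectory <- function(x, ...) {
  nm <- colnames(x$state)
  if (is.null(nm)) nm <- paste0("state_", seq_len(ncol(x$state)) - 1L)
  tibble::tibble(
    time = rep(x$time, times = ncol(x$state)),
    variable = rep(nm, each = length(x$time)),
    value = as.vector(x$state)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
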