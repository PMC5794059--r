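# Colonies: N cells on a 1-D periodic array coupled only through diffusion
# of external AHL; each cell runs either the plain Danino circuit or the
# light-gated circuit.

#' Colony configuration
#'
#' @param n_cells Number of cells (>= 1; >= 2 for synchronization metrics).
#' @param model_per_cell Character vector (`"danino"`/`"hotfm"`), length 1
#'   (recycled) or `n_cells`.
#' @param params [oscillator_params()] shared by all cells.
#' @param green,uv [channel_params()] for the two light channels of the
#'   gated cells.
#' @param schedule [light_schedule()] applied to the whole colony.
#' @param cell_spacing Distance between neighbouring cells (um).
#' @param t_final Integration horizon (min).
#' @param step Integrator step (min); the default obeys both the delay bound
#'   (`tau/20`) and the explicit-diffusion stability bound
#'   `D1c * step / dx^2 <= 0.45` (with `D1c` in um^2/min).
#' @param save_every Output thinning; defaults so that roughly `0.25`-min
#'   output resolution is kept.
#' @param noise_width Width of the uniform noise added to the initial LuxI
#'   level (a.u.); see [noisy_initial_history()].
#' @param seed Integer seed for the initial-condition noise.
#' @return A `colony_config` list.
#' @export
colony_config <- function(n_cells = 6, model_per_cell = "danino",
                          params = study_params(),
                          green = channel_params(), uv = uv_channel(),
                          schedule = light_schedule(),
                          cell_spacing = 10, t_final = 500,
                          step = NULL, save_every = NULL,
                          noise_width = 400, seed = 1L) {
  if (n_cells < 1) stop("n_cells must be at least 1", call. = FALSE)
  model_per_cell <- rep_len(model_per_cell, n_cells)
  if (!all(model_per_cell %in% c("danino", "hotfm")))
    stop("model_per_cell entries must be 'danino' or 'hotfm'", call. = FALSE)
  if (cell_spacing <= 0) stop("cell_spacing must be positive", call. = FALSE)
  d1c <- params$D1 * 60
  if (is.null(step)) {
    step <- min(params$tau / 20, 0.05)
    if (n_cells > 1 && d1c > 0)
      step <- min(step, 0.45 * cell_spacing^2 / d1c)
  }
  if (n_cells > 1 && d1c * step / cell_spacing^2 > 0.5)
    stop("explicit-diffusion stability bound violated: ",
         "D1c * step / dx^2 > 0.5; reduce step or increase cell_spacing",
         call. = FALSE)
  if (is.null(save_every))
    save_every <- max(1L, as.integer(floor(0.25 / step)))
  structure(list(n_cells = as.integer(n_cells),
                 model_per_cell = model_per_cell, params = params,
                 green = green, uv = uv, schedule = schedule,
                 cell_spacing = cell_spacing, t_final = t_final,
                 step = step, save_every = as.integer(save_every),
                 noise_width = noise_width, seed = as.integer(seed)),
            class = "colony_config")
}

#' Noisy initial conditions for a colony
#'
#' Each cell starts from rest except LuxI, which is set to a baseline of
#' 100 a.u. plus independent uniform noise on \[0, `noise_width`\]; all
#' other species start at exactly zero.  Draws are seeded and reproducible.
#'
#' @param n_cells Number of cells.
#' @param seed Integer seed.
#' @param noise_width Upper end of the uniform noise interval (default 400).
#' @param baseline Baseline LuxI level (default 100 a.u.).
#' @return A matrix (`n_cells` x 6 species) of initial states, used as
#'   constant history on \[-tau, 0\].
#' @export
noisy_initial_history <- function(n_cells, seed, noise_width = 400,
                                  baseline = 100) {
  draws <- withr::with_seed(as.integer(seed),
                            stats::runif(n_cells, 0, noise_width))
  y0 <- matrix(0, n_cells, 6,
               dimnames = list(NULL, species_names()))
  y0[, "I"] <- baseline + draws
  y0
}

colony_state_names <- function(n_cells) {
  as.vector(t(outer(seq_len(n_cells), species_names(),
                    function(i, s) paste0(s, "_", i))))
}

#' Simulate a colony of coupled oscillator cells
#'
#' Stacks the per-cell delay differential equations, couples the cells
#' through the discrete periodic Laplacian of external AHL
#' (`(He[i-1] - 2 He[i] + He[i+1]) / dx^2`), and integrates with the
#' method-of-steps engine.  Initial conditions are the seeded noisy history
#' of [noisy_initial_history()] (constant on \[-tau, 0\]) unless an explicit
#' state matrix is supplied.
#'
#' Concentrations are clamped to zero after each accepted step; undershoots
#' beyond `1e-8` times the running species maximum are counted and reported
#' with a warning.
#'
#' @param config [colony_config()].
#' @param y0 Optional initial-state matrix (`n_cells` x 6) overriding the
#'   noisy default.
#' @return A `colony_trajectory` (also a `dde_trajectory`); use
#'   [species_series()] or [tibble::as_tibble()] to extract series.
#' @export
simulate_colony <- function(config, y0 = NULL) {
  cfg <- config
  if (is.null(y0))
    y0 <- noisy_initial_history(cfg$n_cells, cfg$seed, cfg$noise_width)
  stopifnot(nrow(y0) == cfg$n_cells, ncol(y0) == 6)
  d1c <- cfg$params$D1 * 60
  if (cfg$n_cells > 1 && d1c * cfg$step / cfg$cell_spacing^2 > 0.5)
    stop("explicit-diffusion stability bound violated", call. = FALSE)
  n_steps <- max(1L, as.integer(round(cfg$t_final / cfg$step)))
  step <- cfg$t_final / n_steps
  sched <- flatten_schedule(cfg$schedule)
  res <- .colony_integrate_cpp(
    unname(y0),
    as.integer(cfg$model_per_cell == "hotfm"),
    flatten_osc(cfg$params),
    flatten_chan(cfg$green), flatten_chan(cfg$uv),
    sched$times, sched$codes,
    step, cfg$t_final, cfg$cell_spacing,
    cfg$save_every, 1e-8)
  if (res$n_clamped > 0)
    warning(sprintf(
      "%d integration steps clamped a concentration below -1e-8 x running max (worst undershoot %.3g)",
      res$n_clamped, res$worst_undershoot), call. = FALSE)
  traj <- new_dde_trajectory(
    res, tau = cfg$params$tau, step = step,
    history = constant_history(as.vector(t(y0))),
    state_names = colony_state_names(cfg$n_cells),
    metadata = list(seed = cfg$seed, config_hash = config_hash(cfg),
                    model_per_cell = cfg$model_per_cell))
  traj$n_cells <- cfg$n_cells
  traj$config <- cfg
  class(traj) <- c("colony_trajectory", class(traj))
  traj
}

config_hash <- function(cfg) {
  # stable content hash without external dependencies
  s <- paste(utils::capture.output(utils::str(cfg, digits.d = 12)),
             collapse = "\n")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251 + 1)) %% 1e9
}

#' Extract one species' time series from a colony trajectory
#'
#' @param traj A `colony_trajectory`.
#' @param species One of `"A"`, `"I"`, `"Hi"`, `"He"`, `"R"`, `"TC"`.
#' @param cells Cell indices (default all).
#' @return A matrix, one column per requested cell.
#' @export
species_series <- function(traj, species = "A", cells = NULL) {
  species <- match.arg(species, species_names())
  if (is.null(cells)) cells <- seq_len(traj$n_cells)
  cols <- paste0(species, "_", cells)
  traj$state[, cols, drop = FALSE]
}

#' @export
as_tibble.colony_trajectory <- function(x, ...) {
  nc <- x$n_cells
  tibble::tibble(
    time = rep(x$time, times = 6 * nc),
    cell = rep(rep(seq_len(nc), each = length(x$time) * 6) , times = 1),
    species = rep(rep(species_names(), each = length(x$time)), times = nc),
    value = as.vector(x$state)
  )
}

#' @export
print.colony_trajectory <- function(x, ...) {
  cat(sprintf("<colony_trajectory> %d cells (%s), %d saved points on [0, %g] min\n",
              x$n_cells,
              paste(unique(x$config$model_per_cell), collapse = "+"),
              length(x$time), x$time[length(x$time)]))
  invisible(x)
}

#' Interface signals of a mixed two-population colony
#'
#' For a colony whose cell labels form two contiguous blocks (e.g. plain
#' oscillators followed by light-gated ones), returns the AiiA and external
#' AHL series at the two cells flanking the interface together with their
#' aggregate (mean by default, sum optionally).  When the two blocks run at
#' different frequencies the aggregate shows beats: amplitude modulation at
#' the difference frequency.
#'
#' @param traj A `colony_trajectory` of a mixed colony.
#' @param aggregate `"mean"` (default) or `"sum"`.
#' @return A tibble with columns `time`, `A_left`, `A_right`, `He_left`,
#'   `He_right`, `interface_A`, `interface_He`; the aggregation rule and
#'   interface position are attached as attributes.
#' @export
interface_beat_signals <- function(traj, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  labels <- traj$config$model_per_cell
  flips <- which(labels[-1] != labels[-length(labels)])
  if (length(flips) != 1)
    stop("colony must contain exactly one contiguous model interface",
         call. = FALSE)
  left <- flips
  right <- flips + 1L
  agg <- if (aggregate == "mean") function(a, b) (a + b) / 2 else `+`
  A <- species_series(traj, "A", c(left, right))
  He <- species_series(traj, "He", c(left, right))
  out <- tibble::tibble(
    time = traj$time,
    A_left = A[, 1], A_right = A[, 2],
    He_left = He[, 1], He_right = He[, 2],
    interface_A = agg(A[, 1], A[, 2]),
    interface_He = agg(He[, 1], He[, 2])
  )
  attr(out, "aggregate") <- aggregate
  attr(out, "interface") <- c(left = left, right = right)
  out
}
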