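# Experiment configuration: YAML round-trip and orchestration of the
# standard experiment kinds.  The thin command-line wrapper in
# inst/exec/quorosc forwards to run_experiment().

experiment_kinds <- function() {
  c("simulate", "sweep", "sync", "robustness", "beats", "killswitch")
}

#' Load and validate an experiment configuration
#'
#' The file is YAML with an `experiment` kind, optional `oscillator`,
#' `channel_green`, `channel_uv`, `light_schedule`, `colony`, `axes`,
#' `bootstrap` sections, and a `seed`.  Unknown keys are rejected;
#' parameter invariants are enforced by the corresponding constructors.
#'
#' @param path Path to a YAML file.
#' @return An `experiment_config` list with constructed parameter objects.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build_config(raw)
}

build_config <- function(raw) {
  allowed <- c("experiment", "oscillator", "channel_green", "channel_uv",
               "light_schedule", "colony", "axes", "bootstrap", "seed",
               "t_final", "out_dir")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  kind <- raw$experiment %||% stop("missing 'experiment' kind",
                                   call. = FALSE)
  kind <- match.arg(kind, experiment_kinds())
  check_keys <- function(section, fn_defaults, label) {
    bad <- setdiff(names(section), names(fn_defaults))
    if (length(bad))
      stop(sprintf("unknown key(s) in %s: %s", label,
                   paste(bad, collapse = ", ")), call. = FALSE)
    section
  }
  # experiments default to the study parameterisation (gamma_A = 23,
  # gamma_H = 0.023, D1 = 100); any key can be overridden per file
  osc <- do.call(study_params,
                 check_keys(raw$oscillator %||% list(),
                            formals(oscillator_params), "oscillator"))
  green <- do.call(channel_params,
                   check_keys(raw$channel_green %||% list(),
                              formals(channel_params), "channel_green"))
  uvdef <- utils::modifyList(unclass(uv_channel()),
                             raw$channel_uv %||% list())
  uv <- do.call(channel_params,
                check_keys(uvdef, formals(channel_params), "channel_uv"))
  sched <- if (is.null(raw$light_schedule)) light_schedule()
           else light_schedule(vapply(raw$light_schedule, `[[`,
                                      numeric(1), "time"),
                               vapply(raw$light_schedule, `[[`,
                                      character(1), "condition"))
  colony_raw <- raw$colony %||% list()
  colony_allowed <- c("n_cells", "model_per_cell", "cell_spacing",
                      "t_final", "step", "save_every", "noise_width")
  bad <- setdiff(names(colony_raw), colony_allowed)
  if (length(bad))
    stop("unknown key(s) in colony: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(
    experiment = kind,
    params = osc, green = green, uv = uv, schedule = sched,
    colony = colony_raw,
    axes = raw$axes %||% list(),
    bootstrap = raw$bootstrap %||% list(B = 1000),
    seed = as.integer(raw$seed %||% 1L),
    out_dir = raw$out_dir %||% "."
  ), class = "experiment_config")
}

config_to_colony <- function(cfg, model = "danino", schedule = NULL) {
  args <- cfg$colony
  args$model_per_cell <- args$model_per_cell %||% model
  args$params <- cfg$params
  args$green <- cfg$green
  args$uv <- cfg$uv
  args$schedule <- schedule %||% cfg$schedule
  args$seed <- cfg$seed
  do.call(colony_config, args)
}

#' Run a configured experiment
#'
#' Executes the configured experiment kind and writes its artifacts (CSV
#' trajectories and grids, JSON summaries) under the configured output
#' directory.  Every output embeds the configuration hash and seed; the
#' same configuration and seed reproduce identical files.
#'
#' @param cfg An `experiment_config` from [load_config()], or a path to a
#'   YAML file.
#' @param out_dir Override the configured output directory.
#' @return Invisibly, a list of the produced objects and file paths.
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  out_dir <- out_dir %||% cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  res <- switch(cfg$experiment,
    simulate = exp_simulate(cfg, out_dir),
    killswitch = exp_killswitch(cfg, out_dir),
    beats = exp_beats(cfg, out_dir),
    sync = exp_sync(cfg, out_dir),
    sweep = exp_sweep(cfg, out_dir),
    robustness = exp_robustness(cfg, out_dir))
  message(sprintf("experiment %s done in %.1f s (seed %d)",
                  cfg$experiment,
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  cfg$seed))
  invisible(res)
}

write_traj_csv <- function(traj, path) {
  df <- as_tibble(traj)
  hash <- traj$metadata$config_hash %||% NA
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%s", hash,
                     traj$metadata$seed %||% NA), con)
  utils::write.csv(df, con, row.names = FALSE)
  path
}

exp_simulate <- function(cfg, out_dir) {
  traj <- simulate_colony(config_to_colony(cfg))
  path <- file.path(out_dir, "trajectory.csv")
  write_traj_csv(traj, path)
  list(trajectory = traj, files = path)
}

exp_killswitch <- function(cfg, out_dir) {
  sched <- if (length(cfg$schedule$times) > 1) cfg$schedule
           else light_schedule(c(0, 200), c("dark", "uv_violet"))
  traj <- simulate_colony(config_to_colony(cfg, model = "hotfm",
                                           schedule = sched))
  path <- file.path(out_dir, "killswitch.csv")
  write_traj_csv(traj, path)
  list(trajectory = traj, files = path)
}

exp_beats <- function(cfg, out_dir) {
  n <- cfg$colony$n_cells %||% 200L
  cfg$colony$n_cells <- n
  cfg$colony$model_per_cell <- rep(c("danino", "hotfm"), each = n / 2)
  # beats are deterministic interference of the two blocks; a noise-free
  # start keeps the homogeneous control strictly periodic
  cfg$colony$noise_width <- cfg$colony$noise_width %||% 0
  traj <- simulate_colony(config_to_colony(
    cfg, schedule = light_schedule(0, "green")))
  sig <- interface_beat_signals(traj)
  path <- file.path(out_dir, "beats.csv")
  utils::write.csv(sig, path, row.names = FALSE)
  list(signals = sig, files = path)
}

exp_sync <- function(cfg, out_dir) {
  traj <- simulate_colony(config_to_colony(cfg))
  ser <- ase_series(traj)
  fit <- sync_rate(ser)
  out <- list(iase = iase(ser), a = fit$a, r = fit$r,
              n_maxima_used = fit$n_maxima_used,
              seed = cfg$seed)
  jpath <- file.path(out_dir, "sync.json")
  jsonlite::write_json(out, jpath, auto_unbox = TRUE, digits = NA)
  cpath <- file.path(out_dir, "ase.csv")
  utils::write.csv(ser, cpath, row.names = FALSE)
  list(fit = fit, files = c(jpath, cpath))
}

axis_from_cfg <- function(a) {
  param_axis(a$name, a$min, a$max, a$n_points %||% 20,
             a$scale %||% "linear")
}

exp_sweep <- function(cfg, out_dir) {
  if (length(cfg$axes) < 2) stop("sweep needs two axes", call. = FALSE)
  ax <- axis_from_cfg(cfg$axes[[1]])
  ay <- axis_from_cfg(cfg$axes[[2]])
  map <- sweep_two_params("hotfm", ax, ay, params = cfg$params,
                          green = cfg$green, uv = cfg$uv)
  path <- file.path(out_dir, "sweep.csv")
  utils::write.csv(map, path, row.names = FALSE)
  list(map = map, files = path)
}

exp_robustness <- function(cfg, out_dir) {
  if (length(cfg$axes) < 2) stop("robustness needs two axes", call. = FALSE)
  ax <- axis_from_cfg(cfg$axes[[1]])
  ay <- axis_from_cfg(cfg$axes[[2]])
  grid <- robustness_grid(ax, ay, base = config_to_colony(cfg),
                          seed = cfg$seed)
  rep_ <- robustness_report(grid, B = cfg$bootstrap$B %||% 1000,
                            seed = cfg$seed)
  gpath <- file.path(out_dir, "robustness_grid.csv")
  utils::write.csv(
    dplyr::select(grid, -dplyr::any_of(c("pairs_danino", "pairs_hotfm"))),
    gpath, row.names = FALSE)
  jpath <- file.path(out_dir, "robustness.json")
  jsonlite::write_json(list(aggregate = rep_$aggregate,
                            seed = cfg$seed),
                       jpath, auto_unbox = TRUE, digits = NA)
  list(grid = grid, report = rep_, files = c(gpath, jpath))
}
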