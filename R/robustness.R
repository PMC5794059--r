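# Paired robustness comparison of the plain and light-gated oscillators:
# colony simulations with shared noisy initial conditions, IASE and
# synchronization-rate differences over parameter grids, and bootstrap
# summary statistics (percentile confidence intervals, Cohen's d, effect
# categories).

#' Fraction of indicator successes
#'
#' @param indicators A 0/1 (or logical) vector.
#' @return The fraction of ones.
#' @export
aggregate_ratio <- function(indicators) {
  if (!length(indicators)) stop("empty indicator vector", call. = FALSE)
  mean(as.numeric(indicators))
}

#' Bootstrap distribution of an indicator fraction
#'
#' Resamples the indicator vector with replacement `B` times; the statistic
#' of each resample is its mean.  The 95% interval is the percentile
#' interval of the resampled means.
#'
#' @param indicators A 0/1 (or logical) vector.
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return A `bootstrap_summary` with `observed`, `B`, `samples`,
#'   `ci_low`, `ci_high`, `seed`.
#' @export
bootstrap_ratio <- function(indicators, B = 1000, seed = 1L) {
  x <- as.numeric(indicators)
  if (!length(x)) stop("empty indicator vector", call. = FALSE)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  samples <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(B), function(i) mean(sample(x, replace = TRUE)),
           numeric(1))
  })
  ci <- unname(stats::quantile(samples, c(0.025, 0.975), type = 7))
  structure(list(observed = mean(x), B = as.integer(B), samples = samples,
                 ci_low = ci[1], ci_high = ci[2], seed = as.integer(seed)),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("<bootstrap_summary> observed %.4f, 95%% CI (%.4f, %.4f), B = %d\n",
              x$observed, x$ci_low, x$ci_high, x$B))
  invisible(x)
}

#' @export
tidy.bootstrap_summary <- function(x, ...) {
  tibble::tibble(observed = x$observed, ci_low = x$ci_low,
                 ci_high = x$ci_high, B = x$B)
}

#' Reference distribution under random robustness assignment
#'
#' `B` means of `n` independent Bernoulli(1/2) indicators: the null
#' distribution of the robust fraction when neither circuit is favoured.
#'
#' @param n Number of grid points.
#' @param B Number of draws (default 1000).
#' @param seed Integer seed.
#' @return Numeric vector of `B` simulated fractions.
#' @export
random_reference <- function(n, B = 1000, seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  withr::with_seed(as.integer(seed),
                   stats::rbinom(B, size = n, prob = 0.5) / n)
}

#' Cohen's d between two samples
#'
#' Standardised mean difference with equal-weight pooled standard deviation
#' \eqn{\sqrt{(s_1^2 + s_2^2)/2}}.
#'
#' @param dist1,dist2 Numeric vectors (each of length >= 2).
#' @return A number; `Inf` (signed) if both samples are degenerate but
#'   their means differ, 0 if identical and degenerate.
#' @export
cohens_d <- function(dist1, dist2) {
  if (length(dist1) < 2 || length(dist2) < 2)
    stop("need at least 2 values per sample", call. = FALSE)
  m <- mean(dist1) - mean(dist2)
  pooled <- sqrt((stats::var(dist1) + stats::var(dist2)) / 2)
  if (pooled == 0) {
    if (m == 0) return(0)
    return(sign(m) * Inf)
  }
  m / pooled
}

#' Effect-size category of a Cohen's d
#'
#' Thresholds on `|d|`: negligible below 0.2, small in \[0.2, 0.5), medium
#' in \[0.5, 0.8), large at 0.8 and above.
#'
#' @param d Cohen's d (may be `Inf`).
#' @return One of `"negligible"`, `"small"`, `"medium"`, `"large"`.
#' @export
effect_category <- function(d) {
  a <- abs(d)
  dplyr::case_when(a < 0.2 ~ "negligible",
                   a < 0.5 ~ "small",
                   a < 0.8 ~ "medium",
                   TRUE ~ "large")
}

#' Per-point bootstrap effect of a paired metric comparison
#'
#' Bootstraps the per-pair metric values of each model independently
#' (resample with replacement, aggregate by mean, `B` times), computes
#' Cohen's d between the two bootstrap distributions, and the 95%
#' percentile interval of the difference distribution.
#'
#' @param values_model1,values_model2 Per-pair metric values (equal length,
#'   one per neighbouring cell pair).
#' @param B Number of resamples.
#' @param seed Integer seed.
#' @param paired Resample pair indices jointly for both models instead of
#'   independently (off by default).
#' @return A one-row tibble: `d`, `ci_low`, `ci_high`, `contains_zero`.
#' @export
per_point_effect <- function(values_model1, values_model2, B = 1000,
                             seed = 1L, paired = FALSE) {
  x <- as.numeric(values_model1)
  y <- as.numeric(values_model2)
  if (length(x) != length(y))
    stop("per-pair value sets must have equal length", call. = FALSE)
  n <- length(x)
  withr::with_seed(as.integer(seed), {
    if (paired) {
      idx <- matrix(sample.int(n, n * B, replace = TRUE), B, n)
      bx <- rowMeans(matrix(x[idx], B, n))
      by <- rowMeans(matrix(y[idx], B, n))
    } else {
      bx <- vapply(seq_len(B), function(i)
        mean(sample(x, replace = TRUE)), numeric(1))
      by <- vapply(seq_len(B), function(i)
        mean(sample(y, replace = TRUE)), numeric(1))
    }
    diffs <- bx - by
    d <- cohens_d(bx, by)
    ci <- unname(stats::quantile(diffs, c(0.025, 0.975), type = 7))
    tibble::tibble(d = d, ci_low = ci[1], ci_high = ci[2],
                   contains_zero = ci[1] <= 0 && 0 <= ci[2])
  })
}

#' Evaluate both models at one parameter point
#'
#' Simulates a colony of each model with the SAME noisy initial history
#' (paired design, shared seed) at the given parameter overrides, and
#' returns IASE, synchronization rate, and the per-pair components of both.
#'
#' @param point Named list/vector of parameter overrides (fields of
#'   [oscillator_params()] or the green [channel_params()]).
#' @param base [colony_config()] providing everything else, including the
#'   light schedule (green light for an active repression channel); its
#'   `model_per_cell` is ignored.
#' @param seed Seed for the shared initial noise.
#' @return A one-row tibble with `iase_danino`, `iase_hotfm`, `r_danino`,
#'   `r_hotfm`, labels of both models, and list-columns `pairs_danino`,
#'   `pairs_hotfm` holding per-pair `(iase_i, r_i)` tibbles.
#' @export
evaluate_point <- function(point,
                           base = colony_config(
                             schedule = light_schedule(0, "green")),
                           seed = 1L) {
  ap <- apply_point(base$params, base$green, base$uv, as.list(point))
  y0 <- noisy_initial_history(base$n_cells, seed, base$noise_width)
  run <- function(model) {
    cfg <- base
    cfg$model_per_cell <- rep(model, base$n_cells)
    cfg$params <- ap$params
    cfg$green <- ap$green
    cfg$uv <- ap$uv
    cfg$seed <- as.integer(seed)
    simulate_colony(cfg, y0 = y0)
  }
  td <- run("danino")
  th <- run("hotfm")
  summarize_colony <- function(traj) {
    A <- species_series(traj, "A")
    n <- ncol(A)
    nxt <- c(2:n, 1)
    pair_series <- abs(A - A[, nxt, drop = FALSE])
    pair_iase <- apply(pair_series, 2, function(y)
      sum(diff(traj$time) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
    pair_r <- vapply(seq_len(n), function(i) {
      s <- tibble::tibble(time = traj$time, ase = pair_series[, i])
      out <- tryCatch(sync_rate(s)$r, error = function(e) NA_real_)
      out
    }, numeric(1))
    ser <- ase_series(traj)
    fit <- tryCatch(sync_rate(ser), error = function(e) NULL)
    mean_sig <- tibble::tibble(time = traj$time,
                               value = rowMeans(A))
    lab <- classify_behavior(mean_sig)
    list(iase = iase(ser),
         r = if (is.null(fit)) NA_real_ else fit$r,
         label = lab,
         pairs = tibble::tibble(pair = seq_len(n), iase_i = pair_iase,
                                r_i = pair_r))
  }
  sd_ <- summarize_colony(td)
  sh <- summarize_colony(th)
  tibble::tibble(
    iase_danino = sd_$iase, iase_hotfm = sh$iase,
    r_danino = sd_$r, r_hotfm = sh$r,
    label_danino = sd_$label, label_hotfm = sh$label,
    pairs_danino = list(sd_$pairs), pairs_hotfm = list(sh$pairs),
    seed = as.integer(seed)
  )
}

#' Paired robustness study over a two-parameter grid
#'
#' Classifies the bulk model of each circuit at every grid point, keeps the
#' common oscillatory region, and runs [evaluate_point()] (shared-seed
#' paired colonies) at each common point.
#'
#' @param axis_x,axis_y [param_axis()] objects.
#' @param base [colony_config()] carrying colony settings and base
#'   parameters.
#' @param seed Shared noise seed.
#' @param t_final_bulk Horizon of the bulk classification runs (min).
#' @param progress Print progress to stderr.
#' @return A `robustness_grid` tibble: one row per grid point with bulk
#'   labels, and the [evaluate_point()] columns for common-region points.
#' @export
robustness_grid <- function(axis_x, axis_y,
                            base = colony_config(
                              schedule = light_schedule(0, "green")),
                            seed = 1L, t_final_bulk = 1000,
                            progress = FALSE) {
  grid <- tidyr::expand_grid(x = axis_x$values, y = axis_y$values)
  res <- purrr::pmap_dfr(grid, function(x, y) {
    pt <- stats::setNames(list(x, y), c(axis_x$name, axis_y$name))
    ap <- apply_point(base$params, base$green, base$uv, pt)
    labd <- tryCatch(classify_point("danino", ap$params, ap$green, ap$uv,
                                    "green", t_final_bulk,
                                    0.5 * t_final_bulk, 1e-3)$label,
                     error = function(e) "failed")
    labh <- tryCatch(classify_point("hotfm", ap$params, ap$green, ap$uv,
                                    "green", t_final_bulk,
                                    0.5 * t_final_bulk, 1e-3)$label,
                     error = function(e) "failed")
    common <- labd == "oscillatory" && labh == "oscillatory"
    if (progress)
      message(sprintf("point (%g, %g): danino %s, hotfm %s", x, y,
                      labd, labh))
    row <- tibble::tibble(x = x, y = y, bulk_danino = labd,
                          bulk_hotfm = labh, common = common)
    if (common) {
      ev <- tryCatch(evaluate_point(pt, base, seed),
                     error = function(e) NULL)
      if (!is.null(ev)) row <- dplyr::bind_cols(row, ev)
    }
    row
  })
  structure(res, class = c("robustness_grid", class(res)),
            axis_x = axis_x, axis_y = axis_y)
}

#' Aggregate robustness report
#'
#' Summarises a [robustness_grid()]: per metric (IASE and synchronization
#' rate), the fraction of common-region points where the light-gated
#' circuit is more robust (IASE lower; r higher), the aggregate percentile
#' bootstrap CI, Cohen's d against the random-assignment reference, and the
#' per-point bootstrap effect categories and zero-in-CI counts.  Exact ties
#' are excluded from both sides and reported.
#'
#' @param grid A `robustness_grid`.
#' @param B Bootstrap resamples.
#' @param seed Bootstrap seed.
#' @return A `robustness_report` list with elements `aggregate` (tibble,
#'   one row per metric) and `per_point` (tibble with d/CI/category per
#'   common point and metric).
#' @export
robustness_report <- function(grid, B = 1000, seed = 1L) {
  pts <- dplyr::filter(grid, .data$common,
                       !is.na(.data$iase_danino), !is.na(.data$iase_hotfm))
  if (!nrow(pts)) stop("no evaluated common-region points", call. = FALSE)

  metric_summary <- function(diffs, metric) {
    ties <- diffs == 0
    ind <- (diffs[!ties] > 0) * 1
    boot <- bootstrap_ratio(ind, B = B, seed = seed)
    ref <- random_reference(length(ind), B = B, seed = seed + 1L)
    d <- cohens_d(boot$samples, ref)
    tibble::tibble(metric = metric, n = length(ind), n_ties = sum(ties),
                   hotfm_wins = sum(ind), fraction = mean(ind),
                   ci_low = boot$ci_low, ci_high = boot$ci_high,
                   cohens_d = d, category = effect_category(d))
  }
  has_r <- !is.na(pts$r_danino) & !is.na(pts$r_hotfm)
  aggregate <- dplyr::bind_rows(
    metric_summary(pts$iase_danino - pts$iase_hotfm, "iase"),
    metric_summary(pts$r_hotfm[has_r] - pts$r_danino[has_r], "r"))

  per_point <- purrr::pmap_dfr(
    list(pts$x, pts$y, pts$pairs_danino, pts$pairs_hotfm,
         seq_len(nrow(pts))),
    function(x, y, pd, ph, i) {
      out_i <- per_point_effect(pd$iase_i, ph$iase_i, B = B,
                                seed = seed + i)
      ok <- !is.na(pd$r_i) & !is.na(ph$r_i)
      out_r <- if (sum(ok) >= 2)
        per_point_effect(ph$r_i[ok], pd$r_i[ok], B = B, seed = seed + i)
      else tibble::tibble(d = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, contains_zero = NA)
      dplyr::bind_rows(
        dplyr::mutate(out_i, x = x, y = y, metric = "iase",
                      .before = 1),
        dplyr::mutate(out_r, x = x, y = y, metric = "r", .before = 1))
    })
  per_point$category <- effect_category(per_point$d)

  structure(list(aggregate = aggregate, per_point = per_point,
                 B = B, seed = seed),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("<robustness_report>\n")
  print(x$aggregate)
  invisible(x)
}

#' @export
glance.robustness_report <- function(x, ...) x$aggregate
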