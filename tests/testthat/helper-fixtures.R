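# Shared fixtures: small, fast configurations used across the test files.

fast_colony <- function(model = "danino", n_cells = 4, t_final = 200,
                        seed = 42L, ...) {
  colony_config(n_cells = n_cells, model_per_cell = model,
                schedule = light_schedule(0, "green"),
                t_final = t_final, seed = seed, ...)
}

random_state <- function() {
  cell_state(A = stats::runif(1, 0, 500), I = stats::runif(1, 0, 2000),
             Hi = stats::runif(1, 0, 5), He = stats::runif(1, 0, 5),
             R = stats::runif(1, 0, 300), TC = stats::runif(1, 0, 500))
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
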