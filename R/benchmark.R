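#' Run the scenario benchmark
#'
#' Simulates every scenario in the grid `repeats` times (repeat `r` of
#' scenario `i` uses seed `seed + 1000 * i + r`, so the whole benchmark is
#' reproducible from the single master seed), runs the full test on each
#' dataset, and scores it against ground truth. Per-scenario means and
#' standard deviations of the discovery counts and true FDRs, plus the mean
#' efficiency, summarise the grid; with a single repeat the SD columns are
#' `NA`.
#'
#' @param grid A list of [scenario_config]s, e.g. from [scenario_grid];
#'   scenario ids are taken from the configs' `scenario_id` attribute when
#'   present.
#' @param repeats Repeats per scenario (default 3).
#' @param seed Master seed.
#' @param omega Shrinkage threshold for [mbeta_test] (a number or an
#'   `mbeta_omega`); default 1.
#' @param alpha FDR cutoff.
#' @param ... Further arguments to [mbeta_test].
#' @return A list of class `mbeta_benchmark` with `runs` (one evaluation row
#'   per scenario x repeat) and `summary` (one row per scenario).
#' @export
run_benchmark <- function(grid, repeats = 3L, seed = 1L, omega = 1,
                          alpha = 0.05, ...) {
  if (!length(grid)) stop("empty scenario grid", call. = FALSE)
  runs <- purrr::imap_dfr(grid, function(cfg, i) {
    id <- attr(cfg, "scenario_id")
    if (is.null(id)) id <- sprintf("scenario_%02d", i)
    purrr::map_dfr(seq_len(repeats), function(r) {
      cfg$seed <- as.integer(seed + 1000L * i + r)
      sc <- simulate_scenario(cfg)
      res <- mbeta_test(sc$counts, omega = omega, alpha = alpha, ...)
      ev <- evaluate_calls(res, sc$truth, alpha = alpha)
      dplyr::mutate(ev, scenario = id, rep = r, seed = cfg$seed,
                    .before = 1)
    })
  })
  summary <- runs |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      mean_discoveries = mean(.data$n_discoveries),
      sd_discoveries = stats::sd(.data$n_discoveries),
      mean_true_fdr = mean(.data$true_fdr),
      sd_true_fdr = stats::sd(.data$true_fdr),
      mean_power = mean(.data$power),
      mean_efficiency = mean(.data$efficiency),
      .groups = "drop")
  structure(list(runs = runs, summary = summary,
                 params = list(repeats = repeats, seed = seed,
                               omega = if (inherits(omega, "mbeta_omega")) omega$omega_bar else omega,
                               alpha = alpha)),
            class = "mbeta_benchmark")
}

#' @export
print.mbeta_benchmark <- function(x, ...) {
  cat(sprintf("<mbeta_benchmark> %d scenario(s) x %d repeat(s)\n",
              nrow(x$summary), x$params$repeats))
  print(x$summary, n = Inf)
  invisible(x)
}
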