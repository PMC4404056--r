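#' Simulate a null dataset matched to a template
#'
#' Generates negative-binomial counts for two conditions with no condition
#' effect, for calibrating the shrinkage threshold. The template is either
#' an existing [mbeta_counts] object — per-feature means are pooled across
#' all libraries and NB dispersions estimated by method of moments
#' (`size = mu^2 / (s^2 - mu)`; features with fewer than two nonzero counts
#' or underdispersed moments fall back to the global median size) — or a
#' list with vectors `mu` and `size` giving the NB parameters directly.
#'
#' @param template An [mbeta_counts] object or a list with `mu`, `size`,
#'   and optionally `R` (replicates per condition, default 3).
#' @param seed Integer seed.
#' @param R Replicates per condition; defaults to the template's design
#'   (or 3 for a parameter-list template).
#' @param min_mean Low-count filter forwarded to the simulator; default 0
#'   so the calibration sees exactly the template's features.
#' @return An `mbeta_scenario` whose truth labels are all `FALSE`.
#' @export
simulate_null <- function(template, seed = 1L, R = NULL, min_mean = 0) {
  if (inherits(template, "mbeta_counts")) {
    mat <- count_matrix(template)
    mu <- rowMeans(mat)
    s2 <- apply(mat, 1, stats::var)
    size <- ifelse(s2 > mu, mu^2 / (s2 - mu), NA_real_)
    few <- rowSums(mat > 0) < 2
    size[few] <- NA_real_
    med <- stats::median(size, na.rm = TRUE)
    if (is.na(med)) med <- 10
    size[is.na(size)] <- med
    if (is.null(R)) R <- min(table(template$design$condition))
  } else {
    mu <- template$mu
    size <- template$size
    if (is.null(R)) R <- if (!is.null(template$R)) template$R else 3L
  }
  if (length(mu) == 0L) {
    cfg <- scenario_config(n_features = 1L, A = 0, P = 0, Q = 0, R = R,
                           min_mean = min_mean, seed = seed)
    empty <- structure(list(
      counts = NULL,
      truth = tibble::tibble(feature = character(), de = logical(),
                             noise = logical(), tau = numeric(),
                             up_condition = character()),
      config = cfg), class = "mbeta_scenario")
    return(empty)
  }
  if (any(mu <= 0)) stop("template means must be positive", call. = FALSE)
  cfg <- scenario_config(n_features = length(mu), A = 0, P = 0, Q = 0,
                         R = R, baseline = list(mu = mu, size = size),
                         min_mean = min_mean, seed = seed)
  simulate_scenario(cfg)
}

#' Pick the shrinkage threshold from null-run gap factors
#'
#' Sorts the gap factors of the false discoveries found on a null dataset in
#' ascending order, assigns quantiles `q_j = j / k`, and returns the value
#' at the smallest `j` with `q_j >= q_target`. With the default
#' `q_target = 0.85`, 85 percent of the null false discoveries have a gap
#' factor at or below the returned threshold and are therefore shrunken out
#' when it is applied.
#'
#' @param rho_false Gap factors of the false discoveries on a null run.
#' @param q_target Quantile level in `(0, 1)`; default 0.85.
#' @return The selected threshold; 1 (with a warning) when no false
#'   discoveries were observed.
#' @export
select_omega <- function(rho_false, q_target = 0.85) {
  if (q_target <= 0 || q_target >= 1) stop("`q_target` must be in (0, 1)", call. = FALSE)
  k <- length(rho_false)
  if (k == 0L) {
    warning("no false discoveries on the null run; falling back to omega = 1")
    return(1)
  }
  sort(rho_false)[ceiling(q_target * k)]
}

#' Calibrate the shrinkage threshold on simulated null data
#'
#' For each of `S` seeded null datasets drawn from the template, runs the
#' weighted beta-binomial test without shrinkage (equivalent to a gap factor
#' and threshold of 1), collects the false discoveries at the FDR cutoff,
#' and applies the quantile rule of [select_omega] to their gap factors. The
#' final threshold is the mean over the `S` datasets. Per-dataset seeds are
#' `seed + s` for `s = 1, ..., S`, so a calibration is reproducible end to
#' end from the master seed.
#'
#' @param template Passed to [simulate_null].
#' @param S Number of null datasets (default 5).
#' @param q_target Quantile level for [select_omega].
#' @param fdr_cutoff FDR cutoff defining false discoveries (default 0.05,
#'   the same cutoff used for testing).
#' @param seed Master seed.
#' @param R Replicates per condition forwarded to [simulate_null].
#' @param ... Further arguments to [mbeta_test] (e.g. `fdr_method`).
#' @return A list of class `mbeta_omega`: `omega_bar` (mean threshold),
#'   `omegas`, `k` (false discoveries per dataset), `rho_false`
#'   (list of per-dataset gap factors), `S`, `q_target`, `fdr_cutoff`,
#'   `seed`.
#' @export
calibrate_omega <- function(template, S = 5L, q_target = 0.85,
                            fdr_cutoff = 0.05, seed = 1L, R = NULL, ...) {
  if (S < 1L) stop("S must be at least 1", call. = FALSE)
  omegas <- numeric(S)
  ks <- integer(S)
  rho_list <- vector("list", S)
  for (s in seq_len(S)) {
    nd <- simulate_null(template, seed = seed + s, R = R)
    res <- mbeta_test(nd$counts, shrink = FALSE, normalize = "scale",
                      alpha = fdr_cutoff, ...)
    rho_fd <- res$rho[res$decision]
    ks[s] <- length(rho_fd)
    rho_list[[s]] <- rho_fd
    omegas[s] <- select_omega(rho_fd, q_target)
  }
  structure(list(omega_bar = mean(omegas), omegas = omegas, k = ks,
                 rho_false = rho_list, S = S, q_target = q_target,
                 fdr_cutoff = fdr_cutoff, seed = seed),
            class = "mbeta_omega")
}

#' @export
print.mbeta_omega <- function(x, ...) {
  cat(sprintf("<mbeta_omega> omega_bar = %.4f over S = %d null datasets (q >= %.2f)\n",
              x$omega_bar, x$S, x$q_target))
  cat("  per-dataset omega:", paste(sprintf("%.3f", x$omegas), collapse = ", "), "\n")
  cat("  false discoveries per dataset:", paste(x$k, collapse = ", "), "\n")
  invisible(x)
}
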