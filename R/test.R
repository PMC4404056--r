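#' Welch-style t-statistic for two weighted beta-binomial fits
#'
#' `t = (p_hat_A - p_hat_B) / sqrt(V_A + V_B)` with degrees of freedom
#' `df = (V_A + V_B)^2 / (V_A^2 / (N_A - 1) + V_B^2 / (N_B - 1))`, where
#' `N_A` and `N_B` are the summed library sizes per condition. In the
#' symmetric case (equal variances and sizes) the df reduce to `2 (N - 1)`.
#'
#' @param p_hat_A,p_hat_B Condition proportion estimates.
#' @param v_A,v_B Floored condition variances (both positive).
#' @param N_A,N_B Total library size per condition (sum over libraries).
#' @return A tibble with columns `t` and `df` (vectorised over features).
#' @export
t_statistic <- function(p_hat_A, p_hat_B, v_A, v_B, N_A, N_B) {
  if (any(v_A + v_B <= 0)) {
    stop("zero total variance: the variance floor guarantees positivity", call. = FALSE)
  }
  tt <- (p_hat_A - p_hat_B) / sqrt(v_A + v_B)
  df <- (v_A + v_B)^2 / (v_A^2 / (N_A - 1) + v_B^2 / (N_B - 1))
  tibble::tibble(t = tt, df = df)
}

#' Shrink or inflate a t-statistic by the gap factor
#'
#' `t_star = (rho / omega) * t`: statistics from well-separated, low-noise
#' count sets (`rho > omega`) are inflated, those from overlapping or noisy
#' sets (`rho < omega`) are shrunken toward zero. The sign of `t` is
#' preserved.
#'
#' @param t Plain t-statistic.
#' @param rho Gap factor, non-negative.
#' @param omega Positive threshold (default 1, the uncalibrated neutral
#'   setting).
#' @return The adjusted statistic.
#' @export
t_shrink <- function(t, rho, omega = 1) {
  if (any(omega <= 0)) stop("`omega` must be positive", call. = FALSE)
  if (any(rho < 0)) stop("`rho` must be non-negative", call. = FALSE)
  (rho / omega) * t
}

#' Two-sided p-value from the t-distribution
#'
#' @param t_star Test statistic.
#' @param df Positive degrees of freedom.
#' @return `2 * P(T >= |t_star|)` under Student-t with `df` degrees of
#'   freedom.
#' @export
p_value_t <- function(t_star, df) {
  if (any(df <= 0)) stop("`df` must be positive", call. = FALSE)
  2 * stats::pt(-abs(t_star), df)
}

#' Bootstrap p-value for one feature
#'
#' Pools the libraries of both conditions and resamples `(X, N)` pairs with
#' replacement into two pseudo-conditions of the original sizes, recomputing
#' the gap-adjusted statistic each time. The p-value is
#' `(1 + #\{|t*_b| >= |t*_obs|\}) / (B + 1)`.
#'
#' @param counts_A,counts_B Observed counts per condition.
#' @param N_A,N_B Library sizes per condition.
#' @param B Number of bootstrap draws, at least 100.
#' @param seed Integer seed; the result is reproducible given the seed.
#' @param omega Shrinkage threshold passed to [t_shrink].
#' @return A single p-value in `(0, 1]`.
#' @export
p_value_bootstrap <- function(counts_A, counts_B, N_A, N_B, B = 1000L,
                              seed = 1L, omega = 1) {
  if (B < 100L) stop("B must be at least 100 for a stable tail estimate", call. = FALSE)
  m_A <- length(counts_A); m_B <- length(counts_B)
  obs <- mbeta_stat_one(counts_A, counts_B, N_A, N_B, omega)
  X <- c(counts_A, counts_B)
  N <- c(N_A, N_B)
  m <- m_A + m_B
  withr::with_seed(seed, {
    idx_A <- matrix(sample.int(m, B * m_A, replace = TRUE), B, m_A)
    idx_B <- matrix(sample.int(m, B * m_B, replace = TRUE), B, m_B)
  })
  XA <- matrix(X[idx_A], B, m_A); NA_ <- matrix(N[idx_A], B, m_A)
  XB <- matrix(X[idx_B], B, m_B); NB_ <- matrix(N[idx_B], B, m_B)
  tb <- t_star_rows(XA, XB, NA_, NB_, omega)
  (1 + sum(abs(tb) >= abs(obs))) / (B + 1)
}

# t* for a single feature from raw counts and sizes (no FDR step).
mbeta_stat_one <- function(counts_A, counts_B, N_A, N_B, omega = 1) {
  t_star_rows(matrix(counts_A, 1), matrix(counts_B, 1), N_A, N_B, omega)
}

# Vectorised t*: each row of XA/XB (with per-row sizes NA_m/NB_m) is one
# two-condition dataset for a single feature.
t_star_rows <- function(XA, XB, NA_m, NB_m, omega = 1) {
  fit_A <- fit_beta_matrix(XA, NA_m)
  fit_B <- fit_beta_matrix(XB, NB_m)
  tt <- t_statistic(fit_A$p_hat, fit_B$p_hat, fit_A$v_final, fit_B$v_final,
                    fit_A$N_total, fit_B$N_total)
  gs <- gap_stats_rows(XA, XB, NA_m, NB_m)
  t_shrink(tt$t, gap_factor(gs$psi, gs$zeta), omega)
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up (default) or Storey q-values with lambda = 0.5
#' (`pi0 = min(1, mean(p > 0.5) / 0.5)` multiplying the BH adjustment).
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @param method `"BH"` or `"storey"`.
#' @return Adjusted values, monotone non-decreasing in p-value rank.
#' @export
fdr_adjust <- function(p_values, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- stats::p.adjust(p_values, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(p_values > 0.5) / 0.5)
    q <- pmin(1, pi0 * q)
  }
  q
}

#' Run the full weighted beta-binomial differential expression test
#'
#' Pipeline: library-size normalization, low-count filtering, per-condition
#' weighted beta-binomial fits, Welch-style t-statistic, gap statistics
#' (polar ratio, log odds ratio, their geometric mean `rho`), shrinkage of t
#' by `rho / omega`, two-sided t-distribution (or bootstrap) p-values, and
#' FDR adjustment.
#'
#' @param cm An [mbeta_counts] object.
#' @param omega Shrinkage threshold. A number (default 1), or the result of
#'   [calibrate_omega()] to use its averaged threshold.
#' @param shrink If `FALSE`, `t_star = t` (the plain weighted beta-binomial
#'   t-test); gap statistics are still reported.
#' @param normalize Normalization method passed to [normalize_libraries],
#'   or `"none"` to skip.
#' @param min_mean Low-count filter threshold (mean count across libraries);
#'   applied after normalization.
#' @param p_method `"t"` for t-distribution p-values (default) or
#'   `"bootstrap"`.
#' @param B,seed Bootstrap draws and seed (used when
#'   `p_method = "bootstrap"`).
#' @param fdr_method `"BH"` or `"storey"`.
#' @param alpha FDR cutoff used for the `decision` column (default 0.05).
#' @param max_iter,tol Iteration controls for the per-condition fits.
#' @return A tibble of class `mbeta_result` with one row per retained
#'   feature and columns `feature`, `p_hat_A`, `p_hat_B`, `log_fc`, `t`,
#'   `df`, `psi`, `zeta`, `rho`, `t_star`, `p_value`, `q_value`,
#'   `decision`. The log fold change is `log2((p_hat_B + e)/(p_hat_A + e))`
#'   with `e` half the smallest nonzero proportion. Run parameters are kept
#'   in the `params` attribute.
#' @examples
#' sc <- simulate_scenario(scenario_config(n_features = 200, seed = 7))
#' res <- mbeta_test(sc$counts)
#' dplyr::filter(res, decision)
#' @export
mbeta_test <- function(cm, omega = 1, shrink = TRUE,
                       normalize = c("scale", "median-ratios", "none"),
                       min_mean = 5,
                       p_method = c("t", "bootstrap"), B = 1000L, seed = 1L,
                       fdr_method = c("BH", "storey"), alpha = 0.05,
                       max_iter = 100L, tol = 1e-8) {
  normalize <- match.arg(normalize)
  p_method <- match.arg(p_method)
  fdr_method <- match.arg(fdr_method)
  if (inherits(omega, "mbeta_omega")) omega <- omega$omega_bar
  if (normalize != "none") cm <- normalize_libraries(cm, normalize)
  cm <- filter_low_count(cm, min_mean)
  mat <- count_matrix(cm)
  if (nrow(mat) == 0L) stop("no features pass the low-count filter", call. = FALSE)
  conds <- sort(unique(cm$design$condition))
  ia <- cm$design$condition == conds[1]
  ib <- cm$design$condition == conds[2]
  X_A <- mat[, ia, drop = FALSE]; N_A <- cm$design$size[ia]
  X_B <- mat[, ib, drop = FALSE]; N_B <- cm$design$size[ib]
  fit_A <- fit_beta_matrix(X_A, N_A, max_iter = max_iter, tol = tol)
  fit_B <- fit_beta_matrix(X_B, N_B, max_iter = max_iter, tol = tol)
  tt <- t_statistic(fit_A$p_hat, fit_B$p_hat, fit_A$v_final, fit_B$v_final,
                    sum(N_A), sum(N_B))
  G <- nrow(mat)
  gs <- gap_stats_rows(X_A, X_B, N_A, N_B)
  psi <- gs$psi; zeta <- gs$zeta
  rho <- gap_factor(psi, zeta)
  t_star <- if (shrink) t_shrink(tt$t, rho, omega) else tt$t
  if (p_method == "t") {
    p <- p_value_t(t_star, tt$df)
  } else {
    p <- vapply(seq_len(G), function(g) {
      p_value_bootstrap(X_A[g, ], X_B[g, ], N_A, N_B, B = B,
                        seed = seed + g, omega = omega)
    }, numeric(1))
  }
  q <- fdr_adjust(p, fdr_method)
  nz <- c(fit_A$p_hat, fit_B$p_hat)
  eps <- if (any(nz > 0)) min(nz[nz > 0]) / 2 else .Machine$double.eps
  out <- tibble::tibble(
    feature = rownames(mat),
    p_hat_A = fit_A$p_hat, p_hat_B = fit_B$p_hat,
    log_fc = log2((fit_B$p_hat + eps) / (fit_A$p_hat + eps)),
    t = tt$t, df = tt$df,
    psi = psi, zeta = zeta, rho = rho,
    t_star = t_star,
    p_value = p, q_value = q,
    decision = q <= alpha
  )
  attr(out, "params") <- list(
    omega = omega, shrink = shrink, normalize = normalize,
    min_mean = min_mean, p_method = p_method, fdr_method = fdr_method,
    alpha = alpha, condition_A = conds[1], condition_B = conds[2],
    m_A = sum(ia), m_B = sum(ib)
  )
  class(out) <- c("mbeta_result", class(out))
  out
}

#' Write an `mbeta_result` table to TSV
#'
#' Column order is fixed: feature, p_hat_A, p_hat_B, log_fc, t, t_star, psi,
#' zeta, rho, df, p_value, q_value, decision.
#'
#' @param res An `mbeta_result` tibble from [mbeta_test].
#' @param path Output path.
#' @return `res`, invisibly.
#' @export
write_results <- function(res, path) {
  cols <- c("feature", "p_hat_A", "p_hat_B", "log_fc", "t", "t_star",
            "psi", "zeta", "rho", "df", "p_value", "q_value", "decision")
  readr::write_tsv(res[, cols], path)
  invisible(res)
}
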