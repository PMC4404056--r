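#' Optimal library weights under the beta-binomial model
#'
#' Each library's proportion estimate `X_i / N_i` has variance proportional
#' to `1/(alpha + beta) + 1/N_i` under a Beta(alpha, beta) prior on the true
#' per-library proportion. Minimising the variance of the weighted proportion
#' subject to the weights summing to one (Lagrange multipliers) gives weights
#' inversely proportional to that term. Two limits bracket the behaviour:
#' as `alpha + beta` grows the prior degenerates and weights become
#' proportional to library size; as it shrinks, between-library variation
#' dominates and the weights become uniform.
#'
#' @param N Positive library sizes.
#' @param alpha_plus_beta Positive scale of the beta prior; `Inf` is accepted
#'   as the degenerate limit.
#' @return Weights summing to 1, one per library.
#' @examples
#' beta_weights(c(100, 300), Inf)   # size-proportional: 0.25, 0.75
#' beta_weights(c(100, 200), 50)
#' @export
beta_weights <- function(N, alpha_plus_beta) {
  if (any(N <= 0)) stop("library sizes must be positive", call. = FALSE)
  if (length(alpha_plus_beta) != 1L || is.na(alpha_plus_beta) || alpha_plus_beta <= 0) {
    stop("`alpha_plus_beta` must be a single positive number", call. = FALSE)
  }
  u <- 1 / (1 / alpha_plus_beta + 1 / N)
  u / sum(u)
}

#' Weighted proportion estimate
#'
#' @param p_hat_i Per-library proportion estimates in `[0, 1]`.
#' @param w Non-negative weights summing to 1 (tolerance 1e-9).
#' @return The weighted proportion, which lies within the range of the
#'   inputs.
#' @export
weighted_proportion <- function(p_hat_i, w) {
  if (length(p_hat_i) != length(w)) stop("length mismatch", call. = FALSE)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  sum(w * p_hat_i)
}

#' Weighted unbiased variance of the proportion estimate
#'
#' Evaluates the weighted moment estimator
#' `(sum((w_i p_i)^2) - sum(w_i^2) * p_hat^2) / (1 - sum(w_i^2))` and clamps
#' the result at zero: on adversarial inputs the printed form can go
#' marginally negative, and the variance floor ([variance_floor]) is designed
#' to take over exactly when this estimate collapses. With equal weights the
#' estimator reduces to the sample variance of the proportions divided by the
#' number of libraries (the variance of the mean).
#'
#' @param p_hat_i Per-library proportions.
#' @param w Weights summing to 1; at least two libraries.
#' @return Non-negative variance estimate.
#' @export
var_unbiased <- function(p_hat_i, w) {
  if (length(p_hat_i) < 2L) {
    stop("need >= 2 libraries; for a single library use the alternative variance floor",
         call. = FALSE)
  }
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1", call. = FALSE)
  sw2 <- sum(w^2)
  p_hat <- sum(w * p_hat_i)
  v <- (sum((w * p_hat_i)^2) - sw2 * p_hat^2) / (1 - sw2)
  max(v, 0)
}

#' Alternative (floor) variance from pooled counts
#'
#' The `"original"` form pools counts and sizes across the condition:
#' `p = sum(X)/sum(N)`, `V = p (1 - p) / sum(N)`. Because the pooled size
#' appears squared, this can become extremely small; the `"modified"` form
#' replaces the pooled size with the mean library size and adds a pseudocount
#' to the pooled counts: `p = (1 + sum(X)) / mean(N)`,
#' `V = p (1 - p) / mean(N)`, which is strictly larger and never zero for
#' `p < 1`. If the modified proportion exceeds 1 (only possible for counts
#' comparable to the library size) it is clamped to 1 with a warning.
#'
#' @param X Non-negative counts per library.
#' @param N Positive sizes per library.
#' @param variant `"modified"` (default) or `"original"`.
#' @return Non-negative variance.
#' @export
var_floor_alt <- function(X, N, variant = c("modified", "original")) {
  variant <- match.arg(variant)
  if (any(X < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(N) <= 0) stop("sizes must be positive", call. = FALSE)
  if (variant == "original") {
    p <- sum(X) / sum(N)
    p * (1 - p) / sum(N)
  } else {
    nbar <- mean(N)
    p <- (1 + sum(X)) / nbar
    if (p > 1) {
      warning("modified floor proportion exceeds 1; clamped (variance 0)")
      p <- 1
    }
    p * (1 - p) / nbar
  }
}

#' Floored variance
#'
#' The working variance is the elementwise maximum of the weighted unbiased
#' estimate and the alternative floor, so features whose replicate
#' proportions happen to coincide never get a zero (or near-zero)
#' denominator in the t-statistic.
#'
#' @param v_star Variance from [var_unbiased].
#' @param v_hash Variance from [var_floor_alt].
#' @return `pmax(v_star, v_hash)`.
#' @export
variance_floor <- function(v_star, v_hash) {
  if (any(v_star < 0) || any(v_hash < 0)) stop("variances must be non-negative", call. = FALSE)
  pmax(v_star, v_hash)
}

# Matrix core of the iterative weighted fit: X is G x m counts for ONE
# condition; N is a length-m size vector shared by all rows, or a G x m
# matrix of per-row sizes (used by the bootstrap, where resampled libraries
# carry their own sizes). Iterates weights -> weighted proportion ->
# unbiased variance -> method-of-moments alpha+beta -> weights until the
# largest weight change drops below tol. alpha+beta is clamped to
# [ab_min, ab_max]; at the upper clamp weights are size-proportional.
fit_beta_matrix <- function(X, N, max_iter = 100L, tol = 1e-8,
                            ab_min = 1e-6, ab_max = 1e8) {
  G <- nrow(X); m <- ncol(X)
  if (m < 2L) stop("need >= 2 replicate libraries per condition", call. = FALSE)
  Nm <- if (is.matrix(N)) N else matrix(N, G, m, byrow = TRUE)
  inv_N <- 1 / Nm
  P <- X * inv_N
  w <- matrix(1 / m, G, m)
  ab <- rep(NA_real_, G)
  n_iter <- rep(0L, G)
  active <- rep(TRUE, G)
  for (iter in seq_len(max_iter)) {
    if (!any(active)) break
    wa <- w[active, , drop = FALSE]
    pa <- P[active, , drop = FALSE]
    p_hat <- rowSums(wa * pa)
    sw2 <- rowSums(wa^2)
    v_star <- (rowSums((wa * pa)^2) - sw2 * p_hat^2) / (1 - sw2)
    v_star <- pmax(v_star, 0)
    ab_new <- ifelse(v_star > 0 & p_hat > 0 & p_hat < 1,
                     p_hat * (1 - p_hat) / v_star - 1,
                     ab_max)
    ab_new <- pmin(pmax(ab_new, ab_min), ab_max)
    u <- 1 / (1 / ab_new + inv_N[active, , drop = FALSE])
    w_new <- u / rowSums(u)
    delta <- rowMaxs(abs(w_new - wa))
    ab[active] <- ab_new
    w[active, ] <- w_new
    n_iter[active] <- iter
    idx <- which(active)
    active[idx[delta < tol]] <- FALSE
  }
  p_hat <- rowSums(w * P)
  sw2 <- rowSums(w^2)
  v_star <- pmax((rowSums((w * P)^2) - sw2 * p_hat^2) / (1 - sw2), 0)
  nbar <- rowMeans(Nm)
  p_pool <- pmin((1 + rowSums(X)) / nbar, 1)
  v_hash <- p_pool * (1 - p_pool) / nbar
  list(p_hat = p_hat, w = w, alpha_plus_beta = ab,
       v_star = v_star, v_hash = v_hash,
       v_final = pmax(v_star, v_hash),
       n_iter = n_iter, converged = !active,
       N_total = rowSums(Nm))
}

rowMaxs <- function(M) do.call(pmax, as.data.frame(M))
rowMins <- function(M) do.call(pmin, as.data.frame(M))

#' Fit the weighted beta-binomial model for one condition
#'
#' Iterates the estimation loop per feature: starting from uniform weights,
#' it alternates (1) the weighted proportion, (2) the unbiased variance,
#' (3) a method-of-moments update of the beta scale
#' `alpha + beta = p (1 - p) / V - 1` (clamped to `[1e-6, 1e8]`), and (4) the
#' optimal weights, until the largest weight change is below `tol` or
#' `max_iter` is reached. Non-convergent features keep their last iterate
#' with `converged = FALSE` and a warning. Features with zero variance or an
#' all-zero count vector fall through to the modified alternative-variance
#' floor, so the final variance is always positive for realistic library
#' sizes.
#'
#' @param X Counts: a numeric matrix (features x libraries) or a single
#'   feature's count vector.
#' @param N Library sizes, one per library.
#' @param max_iter,tol Iteration controls (defaults 100, 1e-8).
#' @return A tibble with one row per feature: `p_hat`, `alpha_plus_beta`,
#'   `v_star`, `v_hash`, `v_final`, `n_iter`, `converged`, and a list-column
#'   `w` of library weights (each summing to 1). `alpha` and `beta` are
#'   recoverable as `p_hat * alpha_plus_beta` and
#'   `(1 - p_hat) * alpha_plus_beta`.
#' @export
fit_beta_condition <- function(X, N, max_iter = 100L, tol = 1e-8) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != length(N)) stop("`N` must have one size per library", call. = FALSE)
  if (any(N <= 0)) stop("library sizes must be positive", call. = FALSE)
  fit <- fit_beta_matrix(X, N, max_iter = max_iter, tol = tol)
  if (!all(fit$converged)) {
    warning(sum(!fit$converged), " feature(s) did not converge in ", max_iter,
            " iterations; last iterate returned")
  }
  tibble::tibble(
    p_hat = fit$p_hat,
    alpha_plus_beta = fit$alpha_plus_beta,
    v_star = fit$v_star,
    v_hash = fit$v_hash,
    v_final = fit$v_final,
    n_iter = fit$n_iter,
    converged = fit$converged,
    w = lapply(seq_len(nrow(X)), function(i) fit$w[i, ])
  )
}
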