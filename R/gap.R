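#' Descriptive gap statistics for two count sets
#'
#' Summarises how separated two within-condition count sets are: `noise` is
#' the within-condition range (max minus min) averaged over the two
#' conditions, `noise_variance` the mean of the two sample variances
#' (denominator m - 1), and `conditional_effect` the absolute difference of
#' the condition means. A clean differential feature has noise well below
#' the conditional effect; a chance gap between noisy sets shows up as a
#' noise variance dwarfing the effect.
#'
#' @param counts_A,counts_B Count vectors, at least two values each.
#' @return A tibble with columns `noise`, `noise_variance`,
#'   `conditional_effect`.
#' @examples
#' gap_descriptives(c(112, 122, 108, 127), c(302, 314, 322, 328))
#' @export
gap_descriptives <- function(counts_A, counts_B) {
  if (length(counts_A) < 2L || length(counts_B) < 2L) {
    stop("each condition needs at least 2 replicates", call. = FALSE)
  }
  tibble::tibble(
    noise = mean(c(diff(range(counts_A)), diff(range(counts_B)))),
    noise_variance = mean(c(stats::var(counts_A), stats::var(counts_B))),
    conditional_effect = abs(mean(counts_B) - mean(counts_A))
  )
}

#' Polar ratio: separation of two count ranges
#'
#' Orders the two sets by mean and returns the continuity-corrected ratio of
#' the higher set's minimum to the lower set's maximum,
#' `(min_hi + 0.5) / (max_lo + 0.5)`. The ratio exceeds 1 exactly when the
#' two ranges are disjoint, equals at most 1 when they overlap, and grows
#' with the relative size of the gap. The half-count correction keeps the
#' statistic finite when the lower set contains zeros.
#'
#' @param counts_A,counts_B Non-empty count vectors.
#' @return The polar ratio (non-negative scalar).
#' @examples
#' polar_ratio(c(511, 230, 754, 335), c(771, 842, 1014, 798)) # ~1.02
#' @export
polar_ratio <- function(counts_A, counts_B) {
  if (!length(counts_A) || !length(counts_B)) stop("empty condition", call. = FALSE)
  if (mean(counts_B) >= mean(counts_A)) {
    lo <- counts_A; hi <- counts_B
  } else {
    lo <- counts_B; hi <- counts_A
  }
  (min(hi) + 0.5) / (max(lo) + 0.5)
}

#' Noise-moderated log odds ratio
#'
#' Measures the between-condition effect on the log-odds scale, discounted
#' by within-condition noise. Per-library log odds are
#' `log((X_i + 0.5) / (N_i - X_i + 0.5))`; the statistic is the absolute
#' difference of the condition means of these log odds divided by
#' `1 + s`, where `s` is the pooled within-condition standard deviation of
#' the log odds. Large within-group noise therefore drives the statistic
#' toward zero, while a clean shift of well-replicated proportions leaves it
#' close to the raw log odds ratio.
#'
#' @param counts_A,counts_B Non-empty count vectors.
#' @param N_A,N_B Library sizes per condition. Defaults treat counts as
#'   proportions of a common large library, which is appropriate for
#'   size-normalized counts.
#' @return Non-negative scalar; 0 when the two conditions have identical
#'   mean log odds.
#' @export
log_odds_ratio <- function(counts_A, counts_B,
                           N_A = rep(1e6, length(counts_A)),
                           N_B = rep(1e6, length(counts_B))) {
  if (!length(counts_A) || !length(counts_B)) stop("empty condition", call. = FALSE)
  lo <- function(x, n) log((x + 0.5) / (n - x + 0.5))
  la <- lo(counts_A, N_A)
  lb <- lo(counts_B, N_B)
  delta <- abs(mean(lb) - mean(la))
  pooled_var <- 0
  if (length(la) > 1L) pooled_var <- pooled_var + stats::var(la)
  if (length(lb) > 1L) pooled_var <- pooled_var + stats::var(lb)
  k <- (length(la) > 1L) + (length(lb) > 1L)
  s <- if (k > 0) sqrt(pooled_var / k) else 0
  delta / (1 + s)
}

# Row-wise gap statistics: XA, XB are G x mA / G x mB count matrices, NA_m /
# NB_m size matrices (or vectors, recycled per row). Same definitions as
# polar_ratio() / log_odds_ratio(), vectorised over features.
gap_stats_rows <- function(XA, XB, NA_m, NB_m) {
  G <- nrow(XA)
  if (!is.matrix(NA_m)) NA_m <- matrix(NA_m, G, ncol(XA), byrow = TRUE)
  if (!is.matrix(NB_m)) NB_m <- matrix(NB_m, G, ncol(XB), byrow = TRUE)
  mean_A <- rowMeans(XA); mean_B <- rowMeans(XB)
  b_high <- mean_B >= mean_A
  min_hi <- ifelse(b_high, rowMins(XB), rowMins(XA))
  max_lo <- ifelse(b_high, rowMaxs(XA), rowMaxs(XB))
  psi <- (min_hi + 0.5) / (max_lo + 0.5)
  LA <- log((XA + 0.5) / (NA_m - XA + 0.5))
  LB <- log((XB + 0.5) / (NB_m - XB + 0.5))
  la_bar <- rowMeans(LA); lb_bar <- rowMeans(LB)
  row_var <- function(L, mu) rowSums((L - mu)^2) / (ncol(L) - 1)
  k <- (ncol(LA) > 1L) + (ncol(LB) > 1L)
  pooled <- (if (ncol(LA) > 1L) row_var(LA, la_bar) else 0) +
    (if (ncol(LB) > 1L) row_var(LB, lb_bar) else 0)
  s <- if (k > 0) sqrt(pooled / k) else rep(0, G)
  zeta <- abs(lb_bar - la_bar) / (1 + s)
  list(psi = psi, zeta = zeta)
}

#' Gap factor: geometric mean of the polar ratio and log odds ratio
#'
#' @param psi Polar ratio (non-negative).
#' @param zeta Log odds ratio (non-negative).
#' @return `sqrt(psi * zeta)`; equals `psi` whenever `psi == zeta`.
#' @examples
#' gap_factor(2.34, 1.71) # 2.0
#' gap_factor(1.02, 0.38) # 0.623
#' @export
gap_factor <- function(psi, zeta) {
  if (any(psi * zeta < 0)) {
    stop("psi * zeta must be non-negative; negative gap statistics indicate a bug",
         call. = FALSE)
  }
  sqrt(psi * zeta)
}
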