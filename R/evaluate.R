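#' Score a test run against ground truth
#'
#' Computes the true false discovery rate (false discoveries divided by
#' discoveries, 0 when nothing is discovered), power
#' `phi = N_f / N_P` (truly differential discoveries over truly differential
#' features), the conservativeness index (1 if the true FDR is below the
#' cutoff, else 0), and efficiency, the product of power and the index — so
#' a method whose true FDR exceeds its nominal cutoff scores zero
#' efficiency no matter how many features it finds.
#'
#' @param results An `mbeta_result` tibble (or any tibble with `feature`,
#'   `q_value` and `decision` columns).
#' @param truth A tibble with columns `feature` and `de` (logical), e.g.
#'   the `truth` element of an `mbeta_scenario`.
#' @param alpha FDR cutoff (default 0.05).
#' @return A one-row tibble of class `mbeta_eval`: `n_discoveries`,
#'   `n_found`, `n_de`, `true_fdr`, `power`, `index`, `efficiency`,
#'   `alpha`.
#' @export
evaluate_calls <- function(results, truth, alpha = 0.05) {
  orphans <- setdiff(results$feature, truth$feature)
  if (length(orphans)) {
    stop("result features missing from truth: ",
         paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
  }
  # truth features absent from the results (e.g. dropped by the pipeline's
  # low-count filter) count as not discovered
  de <- truth$de[match(results$feature, truth$feature)]
  disc <- results$q_value <= alpha
  n_disc <- sum(disc)
  n_found <- sum(disc & de)
  n_de <- sum(truth$de)
  true_fdr <- (n_disc - n_found) / max(1, n_disc)
  power <- if (n_de > 0) n_found / n_de else 0
  index <- as.numeric(true_fdr < alpha)
  tibble::new_tibble(
    tibble::tibble(n_discoveries = n_disc, n_found = n_found, n_de = n_de,
                   true_fdr = true_fdr, power = power, index = index,
                   efficiency = power * index, alpha = alpha),
    class = "mbeta_eval")
}

#' ROC points from scores and truth labels
#'
#' Sweeps a threshold over the score (smaller = more significant, e.g. a
#' p-value), accumulating the true positive fraction `TP / (TP + FN)` and
#' false positive fraction `FP / (FP + TN)`. Endpoints (0, 0) and (1, 1)
#' are always included. The area under the curve equals the Mann-Whitney
#' probability that a random truly differential feature scores more
#' significant than a random null feature.
#'
#' @param score Numeric score per feature; smaller means called earlier.
#' @param truth Logical truth label per feature; both classes must occur.
#' @return A tibble with columns `fpf`, `tpf`, sorted along the sweep, and
#'   an `auc` attribute.
#' @export
roc_points <- function(score, truth) {
  truth <- as.logical(truth)
  if (!any(truth) || all(truth)) {
    stop("truth must contain both classes for a ROC curve", call. = FALSE)
  }
  o <- order(score)
  lab <- truth[o]
  # pool tied scores into single steps
  brk <- cumsum(!duplicated(score[o]))
  tp <- cumsum(lab); fp <- cumsum(!lab)
  last <- !duplicated(brk, fromLast = TRUE)
  tpf <- c(0, tp[last] / sum(truth), 1)
  fpf <- c(0, fp[last] / sum(!truth), 1)
  out <- tibble::tibble(fpf = fpf, tpf = tpf)
  attr(out, "auc") <- sum(diff(fpf) * (utils::head(tpf, -1) + utils::tail(tpf, -1)) / 2)
  out
}

#' Stability order scores from per-scenario standard deviations
#'
#' Given a table of per-method standard deviations (of finding counts or of
#' true FDRs) across scenarios, ranks the methods within each scenario from
#' the smallest SD (most stable) to the largest, ties receiving the average
#' rank, and averages the ranks across scenarios. A smaller averaged order
#' score means higher stability.
#'
#' @param sd_table A data frame or tibble: one column `method` plus one
#'   numeric column per scenario, or a methods x scenarios matrix with
#'   rownames. Missing cells are an error.
#' @return A tibble with `method` and `order_score`, sorted ascending.
#' @export
stability_order_scores <- function(sd_table) {
  if (is.matrix(sd_table)) {
    methods <- rownames(sd_table)
    mat <- sd_table
  } else {
    methods <- as.character(sd_table[["method"]])
    mat <- as.matrix(sd_table[, setdiff(names(sd_table), "method"), drop = FALSE])
  }
  if (length(methods) < 2L || ncol(mat) < 1L) {
    stop("need at least 2 methods and 1 scenario", call. = FALSE)
  }
  if (anyNA(mat)) stop("missing SD cells in the stability table", call. = FALSE)
  ranks <- apply(mat, 2, rank)
  out <- tibble::tibble(method = methods, order_score = unname(rowMeans(ranks)))
  dplyr::arrange(out, .data$order_score)
}
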