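#' Log fold change against the shrunken t-statistic
#'
#' The diagnostic view of what the gap-factor adjustment does: null features
#' collapse into a narrow band of `t_star` around zero while well-separated
#' differential features are pushed outward, so the mixed region where true
#' and false positives overlap becomes narrow.
#'
#' @param object An `mbeta_result` from [mbeta_test].
#' @param statistic Which statistic to plot on the x axis, `"t_star"`
#'   (default) or `"t"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mbeta_result <- function(object, statistic = c("t_star", "t"), ...) {
  statistic <- match.arg(statistic)
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data[[statistic]], y = .data$log_fc,
                               colour = .data$decision)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                                 name = "called DE") +
    ggplot2::labs(x = statistic, y = "log2 fold change of proportions") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param roc A tibble from [roc_points] (columns `fpf`, `tpf`).
#' @return A ggplot object; the panel subtitle reports the area under the
#'   curve.
#' @export
plot_roc <- function(roc) {
  auc <- attr(roc, "auc")
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpf, y = .data$tpf)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(x = "false positive fraction", y = "true positive fraction",
                  subtitle = if (!is.null(auc)) sprintf("AUC = %.3f", auc)) +
    ggplot2::theme_minimal()
}
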