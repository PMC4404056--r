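#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a test result
#'
#' An `mbeta_result` is already a one-row-per-feature tibble; `tidy()`
#' strips the class and attributes so it composes cleanly, and `glance()`
#' gives the one-row run summary.
#'
#' @param x An `mbeta_result` from [mbeta_test].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mbeta_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.mbeta_result
#' @export
glance.mbeta_result <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(n_features = nrow(x),
                 n_discoveries = sum(x$decision),
                 omega = p$omega,
                 shrink = p$shrink,
                 alpha = p$alpha,
                 fdr_method = p$fdr_method,
                 p_method = p$p_method)
}

#' Tidy an omega calibration
#'
#' @param x An `mbeta_omega` from [calibrate_omega].
#' @param ... Unused.
#' @return `tidy()`: one row per null dataset (`dataset`, `omega`,
#'   `n_false_discoveries`); `glance()`: one summary row.
#' @export
tidy.mbeta_omega <- function(x, ...) {
  tibble::tibble(dataset = seq_len(x$S), omega = x$omegas,
                 n_false_discoveries = x$k)
}

#' @rdname tidy.mbeta_omega
#' @export
glance.mbeta_omega <- function(x, ...) {
  tibble::tibble(omega_bar = x$omega_bar, S = x$S, q_target = x$q_target,
                 fdr_cutoff = x$fdr_cutoff, seed = x$seed)
}

#' Tidy a benchmark
#'
#' @param x An `mbeta_benchmark` from [run_benchmark].
#' @param ... Unused.
#' @return `tidy()`: the per-run evaluation rows; `glance()`: the
#'   per-scenario summary.
#' @export
tidy.mbeta_benchmark <- function(x, ...) x$runs

#' @rdname tidy.mbeta_benchmark
#' @export
glance.mbeta_benchmark <- function(x, ...) x$summary
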