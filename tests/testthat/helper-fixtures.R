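# Worked-example count sets used throughout: a clean gap with low noise
# (ex1) and a gap with large within-condition noise (ex2).
ex1_A <- c(112, 122, 108, 127)
ex1_B <- c(302, 314, 322, 328)
ex2_A <- c(511, 230, 754, 335)
ex2_B <- c(771, 842, 1014, 798)

# Small deterministic count object: `mat` features x libraries.
make_counts <- function(mat, condition = rep(c("A", "B"), each = ncol(mat) / 2),
                        sizes = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("lib", seq_len(ncol(mat)))
  mbeta_counts(mat, condition = condition, library_sizes = sizes)
}

# Default small scenario for pipeline-level tests.
small_scenario <- function(n = 800, A = 100, P = 0.1, Q = 0.1, R = 3, seed = 1) {
  simulate_scenario(scenario_config(n_features = n, A = A, P = P, Q = Q,
                                    R = R, seed = seed))
}
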