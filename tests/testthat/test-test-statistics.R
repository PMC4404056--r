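test_that("t-statistic and Welch degrees of freedom match direct arithmetic", {
  expect_equal(t_statistic(0.01, 0.01, 1e-8, 3e-8, 1e4, 1e4)$t, 0)
  # symmetric case: df = 2 (N - 1)
  sym <- t_statistic(0.02, 0.01, 5e-9, 5e-9, 30000, 30000)
  expect_equal(sym$df, 2 * (30000 - 1))
  # independent evaluation
  tt <- t_statistic(0.002, 0.001, 1e-8, 2e-8, 30000, 30000)
  expect_equal(tt$t, 0.001 / sqrt(3e-8))
  expect_equal(tt$df, (3e-8)^2 / (1e-16 / 29999 + 4e-16 / 29999))
  expect_error(t_statistic(0.1, 0.2, 0, 0, 10, 10), "zero total variance")
})

test_that("gap-factor adjustment inflates and shrinks around the threshold", {
  expect_equal(t_shrink(2.5, 1.3, 1.3), 2.5)
  expect_equal(t_shrink(7, 0, 1), 0)
  expect_equal(t_shrink(3, 2, 1), 6)
  expect_equal(t_shrink(-3, 2, 1), -6)
  set.seed(10)
  for (i in 1:30) {
    t <- rnorm(1, 0, 4); rho <- runif(1, 0, 3); omega <- runif(1, 0.5, 2)
    ts <- t_shrink(t, rho, omega)
    expect_equal(sign(ts), sign(t * rho))
    if (rho > omega) expect_gte(abs(ts), abs(t))
    if (rho < omega) expect_lte(abs(ts), abs(t))
  }
  expect_error(t_shrink(1, 1, 0), "positive")
  expect_error(t_shrink(1, -0.1, 1), "non-negative")
})

test_that("t-distribution p-values match an independent integration oracle", {
  expect_equal(p_value_t(0, 7), 1)
  expect_equal(p_value_t(1.96, 1e6), 0.05, tolerance = 0.002)
  # numeric integration of the t density, df = 10
  dens <- function(x, df) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  tail_mass <- 2 * stats::integrate(dens, 2.5, Inf, df = 10,
                                    rel.tol = 1e-12)$value
  expect_equal(p_value_t(2.5, 10), tail_mass, tolerance = 1e-10)
  expect_error(p_value_t(1, 0), "positive")
})

test_that("bootstrap p-values are seeded, null-calibrated, and flag the clean gap", {
  N <- rep(1e5, 4)
  p1 <- p_value_bootstrap(ex1_A, ex1_B, N, N, B = 500, seed = 42)
  p2 <- p_value_bootstrap(ex1_A, ex1_B, N, N, B = 500, seed = 42)
  expect_identical(p1, p2)
  expect_lt(p1, 0.05)
  expect_error(p_value_bootstrap(ex1_A, ex1_B, N, N, B = 50), "at least 100")

  # identical conditions: p large in expectation over seeds
  ps <- vapply(1:5, function(s) {
    p_value_bootstrap(ex2_A, ex2_A, N, N, B = 300, seed = s)
  }, numeric(1))
  expect_gte(mean(ps), 0.4)

  # permutation cross-check: the observed labeling of the clean-gap example
  # is in the extreme tail of all C(8,4) relabelings
  pool <- c(ex1_A, ex1_B)
  combs <- utils::combn(8, 4)
  t_perm <- apply(combs, 2, function(ia) {
    mbetat:::mbeta_stat_one(pool[ia], pool[-ia], N, N)
  })
  t_obs <- mbetat:::mbeta_stat_one(ex1_A, ex1_B, N, N)
  expect_gte(abs(t_obs), quantile(abs(t_perm), 0.95))
})

test_that("FDR adjustment follows the step-up rule; Storey never exceeds BH", {
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.037), 0.037)
  set.seed(12)
  p <- runif(200)^2
  q_bh <- fdr_adjust(p, "BH")
  q_st <- fdr_adjust(p, "storey")
  expect_true(all(q_st <= q_bh + 1e-12))
  # monotone in p-value rank
  o <- order(p)
  expect_true(all(diff(q_bh[o]) >= -1e-12))
  expect_true(all(diff(q_st[o]) >= -1e-12))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("null p-values are conservative in the rejection tail", {
  for (s in 1:3) {
    sc <- simulate_scenario(scenario_config(n_features = 5000, A = 0, P = 0,
                                            Q = 0.1, R = 3, seed = 100 + s))
    res <- mbeta_test(sc$counts, omega = 1)
    n <- nrow(res)
    for (x in c(0.01, 0.05, 0.1)) {
      frac <- mean(res$p_value <= x)
      expect_lte(frac, x + 3 * sqrt(x * (1 - x) / n))
    }
  }
})

test_that("the adjustment compresses null statistics more than true signals", {
  sc <- small_scenario(n = 2000, A = 100, seed = 31)
  res <- mbeta_test(sc$counts, omega = 1)
  j <- merge(as.data.frame(tidy(res)), as.data.frame(sc$truth), by = "feature")
  infl <- abs(j$t_star) > abs(j$t)
  expect_lt(mean(infl[!j$de]), mean(infl[j$de]))
})

test_that("bootstrap and t-distribution p-values agree in rank order", {
  rhos <- vapply(1:3, function(s) {
    sc <- small_scenario(n = 200, A = 150, P = 0.3, R = 5, seed = s)
    res_t <- mbeta_test(sc$counts, omega = 1, p_method = "t")
    res_b <- mbeta_test(sc$counts, omega = 1, p_method = "bootstrap",
                        B = 1000, seed = 99)
    cor(res_t$p_value, res_b$p_value, method = "spearman")
  }, numeric(1))
  expect_gte(mean(rhos), 0.95)
})
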