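test_that("weights are symmetric, size-proportional in the degenerate limit, and match direct arithmetic", {
  expect_equal(beta_weights(c(1000, 1000, 1000), 17), rep(1 / 3, 3))
  expect_equal(beta_weights(c(100, 300), Inf), c(0.25, 0.75))
  # alpha+beta = 50, N = (100, 200): unnormalized (1/50+1/100)^-1 = 100/3,
  # (1/50+1/200)^-1 = 40 -> weights 5/11, 6/11
  expect_equal(beta_weights(c(100, 200), 50), c(5 / 11, 6 / 11))
  expect_error(beta_weights(c(-1, 10), 5), "positive")
  expect_error(beta_weights(c(10, 10), 0), "positive")
})

test_that("weight limits interpolate between uniform and size-proportional", {
  N <- c(120, 480, 1200)
  expect_equal(beta_weights(N, 1e12), N / sum(N), tolerance = 1e-6)
  expect_equal(beta_weights(N, 1e-9), rep(1 / 3, 3), tolerance = 1e-6)
  mid <- beta_weights(N, 500)
  expect_true(all(diff(mid) > 0))      # larger libraries never lose weight
  expect_lt(max(mid), max(N / sum(N))) # but less extreme than size-proportional
})

test_that("weighted proportion is a convex combination", {
  expect_equal(weighted_proportion(rep(0.01, 5), rep(0.2, 5)), 0.01)
  expect_equal(weighted_proportion(c(0.1, 0.3), c(0.5, 0.5)), 0.2)
  expect_equal(weighted_proportion(c(0.1, 0.3), c(0.25, 0.75)), 0.25)
  expect_error(weighted_proportion(c(0.1, 0.3), c(0.5, 0.6)), "sum to 1")
  set.seed(2)
  for (i in 1:20) {
    p <- runif(4)
    w <- beta_weights(sample(100:1000, 4), exp(runif(1, -2, 8)))
    ph <- weighted_proportion(p, w)
    expect_gte(ph, min(p)); expect_lte(ph, max(p))
  }
})

test_that("weighted unbiased variance matches the closed form and is clamped at zero", {
  expect_equal(var_unbiased(rep(0.02, 3), rep(1 / 3, 3)), 0)
  # independent one-line evaluation of the printed estimator
  p <- c(0.01, 0.03); w <- c(0.5, 0.5)
  direct <- (sum((w * p)^2) - sum(w^2) * sum(w * p)^2) / (1 - sum(w^2))
  expect_equal(var_unbiased(p, w), direct)
  expect_equal(direct, 1e-4)
  # equal weights reduce to var-of-mean
  set.seed(3)
  p <- runif(5)
  expect_equal(var_unbiased(p, rep(0.2, 5)), var(p) / 5)
  # clamp: size-proportional weights with proportional counts go negative
  # in raw form -> clamped
  set.seed(4)
  for (i in 1:50) {
    p <- runif(3, 0, 0.05)
    w <- beta_weights(sample(1e3:1e5, 3), exp(runif(1, -2, 10)))
    expect_gte(var_unbiased(p, w), 0)
  }
  expect_error(var_unbiased(0.5, 1), "2 libraries")
})

test_that("alternative variance: modified form exceeds the original and handles zeros", {
  # all-zero counts: original collapses to 0, modified stays positive
  expect_equal(var_floor_alt(c(0, 0, 0), rep(1000, 3), "original"), 0)
  expect_equal(var_floor_alt(c(0, 0, 0), rep(1000, 3), "modified"),
               (1 / 1000) * (1 - 1 / 1000) / 1000)
  # direct arithmetic for X = (2, 3), N = (1e4, 1e4)
  p_orig <- 5 / 20000
  expect_equal(var_floor_alt(c(2, 3), c(1e4, 1e4), "original"),
               p_orig * (1 - p_orig) / 20000)
  p_mod <- 6 / 10000
  expect_equal(var_floor_alt(c(2, 3), c(1e4, 1e4), "modified"),
               p_mod * (1 - p_mod) / 10000)
  # property: modified >= original over random sparse count data, m >= 2
  set.seed(5)
  for (i in 1:100) {
    m <- sample(2:6, 1)
    N <- sample(5e3:5e4, m)
    X <- rpois(m, runif(1, 0, 0.01) * mean(N))
    expect_gte(var_floor_alt(X, N, "modified"), var_floor_alt(X, N, "original"))
  }
  expect_error(var_floor_alt(c(-1, 2), c(10, 10)), "non-negative")
  expect_warning(v <- var_floor_alt(c(2000, 2000), c(1000, 1000), "modified"),
                 "clamped")
  expect_equal(v, 0)
})

test_that("variance floor takes the elementwise maximum and keeps t finite", {
  expect_equal(variance_floor(0, 1e-6), 1e-6)
  expect_equal(variance_floor(2e-6, 1e-6), 2e-6)
  # constant proportions: v_star 0, modified floor positive -> finite t
  X <- c(5, 5, 5); N <- rep(1e4, 3)
  vs <- var_unbiased(X / N, rep(1 / 3, 3))
  vh <- var_floor_alt(X, N, "modified")
  expect_equal(vs, 0)
  expect_gt(variance_floor(vs, vh), 0)
  tt <- t_statistic(5e-4, 6e-4, variance_floor(vs, vh), vh, 3e4, 3e4)
  expect_true(is.finite(tt$t) && is.finite(tt$df))
})

test_that("iterative fit: symmetric inputs are a fixed point and weights stay normalized", {
  fit <- fit_beta_condition(c(40, 40, 40), rep(2e4, 3))
  expect_equal(fit$w[[1]], rep(1 / 3, 3))
  expect_equal(fit$p_hat, 40 / 2e4)
  expect_equal(fit$v_star, 0)
  expect_equal(fit$v_final, fit$v_hash)
  expect_true(fit$converged)

  set.seed(6)
  for (i in 1:20) {
    m <- sample(2:5, 1)
    X <- rnbinom(m, mu = 50, size = 5)
    N <- sample(1e4:1e5, m)
    fit <- fit_beta_condition(X, N)
    expect_equal(sum(fit$w[[1]]), 1, tolerance = 1e-12)
    expect_gte(fit$p_hat, 0); expect_lte(fit$p_hat, 1)
    expect_gt(fit$alpha_plus_beta, 0)
    expect_equal(fit$v_final, max(fit$v_star, fit$v_hash))
    expect_gt(fit$v_final, 0)
  }
})

test_that("iterative fit agrees with a grid-search fixed-point oracle", {
  cases <- list(list(X = c(50, 90, 20), N = c(8000, 12000, 6000)),
                list(X = c(120, 300), N = c(10000, 30000)),
                list(X = c(7, 3, 11, 6), N = rep(5000, 4)))
  grid <- 10^seq(-6, 8, length.out = 4000)
  for (cs in cases) {
    X <- cs$X; N <- cs$N
    dis <- vapply(grid, function(ab) {
      w <- beta_weights(N, ab)
      p_i <- X / N
      p <- sum(w * p_i)
      v <- max((sum((w * p_i)^2) - sum(w^2) * p^2) / (1 - sum(w^2)), 0)
      ab2 <- if (v > 0 && p > 0 && p < 1) p * (1 - p) / v - 1 else 1e8
      abs(log(min(max(ab2, 1e-6), 1e8)) - log(ab))
    }, numeric(1))
    oracle_ab <- grid[which.min(dis)]
    fit <- fit_beta_condition(X, N)
    expect_equal(log10(fit$alpha_plus_beta), log10(oracle_ab), tolerance = 0.01)
    expect_equal(fit$p_hat,
                 weighted_proportion(X / N, beta_weights(N, oracle_ab)),
                 tolerance = 1e-4)
  }
})

test_that("weighted combination preserves the beta expectation", {
  # p_i ~ Beta(2, 8): weighted mean over many draws stays at 2/10
  set.seed(7)
  w <- beta_weights(c(1e4, 3e4, 2e4), 10)
  draws <- matrix(rbeta(3e4, 2, 8), ncol = 3)
  p_hat <- as.numeric(draws %*% w)
  expect_equal(mean(p_hat), 0.2, tolerance = 0.005)
})

test_that("all-zero condition yields p_hat 0 with the modified floor", {
  fit <- fit_beta_condition(c(0, 0, 0), rep(5e4, 3))
  expect_equal(fit$p_hat, 0)
  expect_equal(fit$v_final, fit$v_hash)
  expect_gt(fit$v_final, 0)
  expect_true(fit$converged)
})
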