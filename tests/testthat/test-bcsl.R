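test_that("orthonormal design with an exact sparse signal is recovered", {
  fit <- bcsl_fit(linear_system(diag(3), c(1, 0, 0)))
  expect_equal(fit$support, 1L)
  expect_equal(unname(coef(fit)), c(1, 0, 0), tolerance = 1e-8)
})

test_that("a target lying on a single column is attributed to it", {
  set.seed(2)
  X <- matrix(rnorm(8), 2, 4)
  fit <- bcsl_fit(linear_system(X, 3 * X[, 2]))
  # oracle: among all least-squares fits over supports of size <= 2, the
  # single-column support with zero residual is the answer
  oracle <- exhaustive_ls(X, 3 * X[, 2], max_size = 2)
  expect_equal(oracle$support, 2L)
  expect_equal(fit$support, 2L)
  expect_equal(unname(coef(fit)[2]), 3, tolerance = 1e-6)
})

test_that("noisy overdetermined systems match the exhaustive-support oracle", {
  for (seed in c(3, 11, 13)) {
    rs <- random_system(seed, N = 50, K = 6,
                        w = c(0, 2, 0, 0, -1, 0), sigma = 0.01)
    fit <- bcsl_fit(rs$system)
    oracle <- exhaustive_ls(rs$system$design, rs$system$target)
    expect_equal(fit$support, oracle$support)
    expect_lt(max(abs(coef(fit) - oracle$coefficients)), 3 * 0.01)
  }
})

test_that("noise-free targets in the span of few columns are recovered exactly", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(40 * 6), 40, 6)
    k <- sample(2:3, 1)
    s <- sort(sample(6, k))
    w <- numeric(6); w[s] <- sample(c(-3, -1, 2, 5), k)
    fit <- bcsl_fit(linear_system(X, drop(X %*% w)))
    expect_equal(fit$support, s)
    expect_lt(max(abs(coef(fit) - w)), 1e-8)
  }
})

test_that("fitting a normalized system reproduces the unnormalized fit", {
  rs <- random_system(5, N = 60, K = 5, w = c(0, 4, 0, -2, 0), sigma = 0.005)
  X <- rs$system$design
  sc <- c(1, 10, 0.1, 5, 2)
  Xs <- sweep(X, 2, sc, "*")
  f1 <- bcsl_fit(rs$system)
  f2 <- bcsl_fit(linear_system(Xs, rs$system$target))
  expect_equal(unname(coef(f2) * sc), unname(coef(f1)), tolerance = 1e-10)
})

test_that("bcsl attains the numerically maximized evidence on small systems", {
  for (seed in c(1, 4, 9)) {
    rs <- random_system(seed, N = 30, K = 5,
                        w = c(2, 0, 0, -1, 0), sigma = 0.05)
    fit <- bcsl_fit(rs$system)
    oracle <- oracle_max_evidence(rs$system, lam = fit$lam, max_size = 3)
    expect_gte(fit$log_evidence, oracle - 1e-6)
    # the rate hyperparameter satisfies its own stationary condition
    L <- length(fit$support)
    lam_expect <- if (L > 1) 2 * (L - 1) / sum(fit$gamma[fit$support]) else 0
    expect_equal(fit$lam, lam_expect, tolerance = 1e-10)
  }
})

test_that("reported evidence equals log_evidence at the returned state", {
  rs <- random_system(13, N = 40, K = 6, sigma = 0.02)
  fit <- bcsl_fit(rs$system)
  expect_equal(fit$log_evidence,
               log_evidence(rs$system, fit$gamma, fit$lam, fit$beta),
               tolerance = 1e-8)
})

test_that("evidence of the null model is the pure-noise Gaussian likelihood", {
  set.seed(6)
  g <- rnorm(20)
  sys <- linear_system(matrix(rnorm(60), 20, 3), g)
  beta <- 2.5
  expect_equal(log_evidence(sys, numeric(3), 0, beta),
               sum(dnorm(g, 0, sqrt(1 / beta), log = TRUE)))
})

test_that("one-column evidence matches a quadrature marginalization", {
  set.seed(8)
  phi <- rnorm(15)
  g <- 1.3 * phi + rnorm(15, 0, 0.3)
  sys <- linear_system(matrix(phi), g)
  beta <- 1 / 0.09
  gam <- 2
  # integrate the likelihood against the N(0, gamma) prior on the weight
  # of the unit-normalized column
  phin <- phi / sqrt(sum(phi^2))
  integrand <- function(w) {
    vapply(w, function(wi)
      exp(sum(dnorm(g, phin * wi, sqrt(1 / beta), log = TRUE)) +
            dnorm(wi, 0, sqrt(gam), log = TRUE)), 0)
  }
  quad <- stats::integrate(integrand, -50, 50, rel.tol = 1e-10)
  expect_equal(log_evidence(sys, gam, 0, beta), log(quad$value),
               tolerance = 1e-6)
})

test_that("evidence is invariant under column-gamma permutation", {
  rs <- random_system(10, N = 25, K = 4, sigma = 0.1)
  gam <- c(0.5, 0, 2, 1)
  perm <- c(3, 1, 4, 2)
  sys_p <- linear_system(rs$system$design[, perm], rs$system$target)
  expect_equal(log_evidence(rs$system, gam, 0.7, 3),
               log_evidence(sys_p, gam[perm], 0.7, 3))
})

test_that("ridge_fit matches closed-form solutions", {
  set.seed(20)
  X <- matrix(rnorm(9), 3, 3)
  g <- rnorm(3)
  f0 <- ridge_fit(linear_system(X, g), alpha = 0)
  expect_equal(unname(coef(f0)), drop(solve(X, g)), tolerance = 1e-8)

  X2 <- matrix(rnorm(30), 10, 3)
  g2 <- drop(X2 %*% c(1, -2, 0.5)) + rnorm(10, 0, 0.1)
  norms <- sqrt(colSums(X2^2))
  Xn <- sweep(X2, 2, norms, "/")
  w_ref <- drop(solve(crossprod(Xn) + diag(0.1, 3), crossprod(Xn, g2))) / norms
  expect_equal(unname(coef(ridge_fit(linear_system(X2, g2), alpha = 0.1))),
               w_ref, tolerance = 1e-10)

  f_inf <- ridge_fit(linear_system(X2, g2), alpha = 1e12)
  expect_lt(max(abs(coef(f_inf))), 1e-6)
})

test_that("ridge_fit flags rank deficiency and returns a minimum-norm fit", {
  X <- cbind(1:5, (1:5) * 2)          # collinear
  f <- ridge_fit(linear_system(X, drop(X %*% c(1, 1))), alpha = 0)
  expect_false(is.null(f$note))
  expect_equal(drop(X %*% coef(f)), drop(X %*% c(1, 1)), tolerance = 1e-6)
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(linear_system(matrix(c(1, NA), 1, 2), 1), "non-finite")
  expect_error(log_evidence(linear_system(diag(2), c(1, 1)),
                            c(1, 1), 0.5, -1), "beta")
  expect_error(ridge_fit(linear_system(diag(2), c(1, 1)), alpha = -1))
})
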