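test_that("increment statistics are exact identities", {
  tr <- trajectory(c(0, 0.1, 0.2), step = 0.1)
  st <- increments(tr)
  expect_equal(unname(st$F1[, 1]), c(1, 1))
  expect_equal(unname(st$F2[, 1]), c(0.05, 0.05))
  expect_equal(unname(st$positions[, 1]), c(0, 0.1))

  stc <- increments(trajectory(rep(2, 10), step = 0.5))
  expect_true(all(stc$F1 == 0) && all(stc$F2 == 0))

  # hand computation on arbitrary values
  v <- c(1.3, -0.2, 0.7, 0.7)
  st2 <- increments(trajectory(v, step = 0.25))
  expect_equal(unname(st2$F1[, 1]), diff(v) / 0.25)
  expect_equal(unname(st2$F2[, 1]), diff(v)^2 / 0.5)
})

test_that("the mean of F2 estimates the diffusion coefficient", {
  m <- sde_model(c("1" = 0), c("1" = 0.7))
  tr <- euler_maruyama(m, 0, 1e-3, 1e5, seed = 4)
  st <- increments(tr)
  # F2_i ~ c * chi^2_1, so sd(mean) = c * sqrt(2/N)
  se <- 0.7 * sqrt(2 / 1e5)
  expect_lt(abs(mean(st$F2) - 0.7), 3 * se)
})

test_that("bin averages and probabilities follow the histogram definitions", {
  tr <- trajectory(c(0, 0, 1, 1, 5), step = 1)   # positions 0,0,1,1
  bs <- bin_stats(increments(tr), Q = 2)
  expect_equal(bs$probs, c(0.5, 0.5))
  expect_equal(bs$centers, c(0.25, 0.75))
  expect_equal(sum(bs$probs), 1)

  # a bin holding F1 values {1, 3} averages to 2
  tr2 <- trajectory(c(0, 0.1, 0.4, 10), step = 0.1)  # F1 = 1, 3, 96
  bs2 <- bin_stats(increments(tr2), Q = 2)
  expect_equal(bs2$F1_bar[1], 2)

  expect_error(bin_stats(increments(trajectory(rep(1, 5), 0.1)), 4),
               "degenerate")
})

test_that("entropy threshold separates two well-separated probability levels", {
  set.seed(5)
  p <- c(rep(0.001, 30), rep(0.02, 20))
  p <- p / sum(p)
  lo <- max(p[1:30]); hi <- min(p[31:50])
  # exhaustive scan: every candidate between the levels gives the same
  # two-class split, so p* must fall strictly between them
  ps <- entropy_threshold(p, q = 0.8)
  expect_gt(ps, lo)
  expect_lt(ps, hi)
})

test_that("uniform probabilities disable filtering by convention", {
  p <- rep(0.05, 20)
  expect_equal(entropy_threshold(p), 0.05)
  bs <- list(probs = p, counts = rep(5, 20), mask = rep(TRUE, 20))
  class(bs) <- "binned_stats"
  expect_true(all(filter_bins(bs)$mask))
})

test_that("adding near-zero bins never evicts originally retained bins", {
  set.seed(11)
  base <- c(runif(15, 0.04, 0.08), runif(10, 1e-4, 5e-4))
  base <- base / sum(base)
  kept0 <- base >= entropy_threshold(base)
  high <- which(base >= sort(base, decreasing = TRUE)[15])
  for (extra_n in c(5, 20)) {
    p2 <- c(base, runif(extra_n, 1e-6, 1e-5))
    p2 <- p2 / sum(p2)
    kept2 <- p2 >= entropy_threshold(p2)
    expect_true(all(kept2[high]))
  }
})

test_that("filtering never removes the most probable bin", {
  for (seed in 1:5) {
    set.seed(seed)
    p <- rexp(40); p <- p / sum(p)
    ps <- entropy_threshold(p)
    expect_gte(max(p), ps)
  }
})

test_that("direct-mode fit_km recovers the double-well model", {
  tr <- dw_traj()
  fit <- fit_km(tr, mode = "direct", seed = 1)
  expect_equal(sort(names(fit$drift_coefs)), c("1", "x", "x^2", "x^3"))
  expect_equal(unname(fit$drift_coefs[c("1", "x", "x^2", "x^3")]),
               c(3, -18, 12, -2), tolerance = 0.15)
  expect_equal(names(fit$diff_coefs), "1")
  expect_equal(unname(fit$diff_coefs), 0.8, tolerance = 0.1)
})

test_that("binned fit at Q = 200 masks empty bins and identifies the well shape", {
  tr <- dw_traj()
  fit <- fit_km(tr, mode = "binned", Q = 200, filter = TRUE, seed = 1)
  expect_false(is.na(fit$binned$p_star))
  expect_true(all(fit$binned$counts[fit$binned$mask] > 0))
  # the probability filter keeps only well-populated bins, so the weakly
  # identified cubic tail may be dropped; the retained terms are a subset
  # of the direct-fit support with matching leading coefficients
  expect_true(all(names(fit$drift_coefs) %in% c("1", "x", "x^2", "x^3")))
  expect_true(all(c("1", "x") %in% names(fit$drift_coefs)))
  expect_equal(unname(fit$drift_coefs["x"]), -18, tolerance = 0.15)
  expect_equal(names(fit$diff_coefs), "1")
  expect_equal(unname(fit$diff_coefs), 0.8, tolerance = 0.1)
})

test_that("a manual p_star overrides the entropy heuristic", {
  tr <- dw_traj()
  fit <- fit_km(tr, mode = "binned", Q = 50, p_star = 0.002, seed = 1)
  expect_equal(fit$binned$p_star, 0.002)
  expect_true(all(fit$binned$probs[fit$binned$mask] >= 0.002))
})

test_that("an identified model can be simulated", {
  tr <- dw_traj()
  fit <- fit_km(tr, seed = 1)
  sim <- simulate(fit, nsim = 500, seed = 2, x0 = 0.2)
  expect_equal(nrow(sim$values), 501)
  expect_true(all(is.finite(sim$values)))
})
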