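test_that("the 4th-order stencil differentiates low-degree polynomials exactly", {
  t <- seq(0, 2, by = 0.1)
  d <- finite_difference(t^2, 0.1)
  i <- which(abs(t - 1) < 1e-12)
  expect_equal(d[i], 2.0, tolerance = 1e-10)
  expect_true(all(is.na(d[c(1, 2, length(d) - 1, length(d))])))
  expect_equal(finite_difference(rep(3, 10), 0.1)[3:8], rep(0, 6))
  d2 <- finite_difference(t^3, 0.1, order = 2)
  expect_equal(d2[i], 6.0, tolerance = 1e-9)
})

test_that("finite-difference error decays at fourth order", {
  err <- vapply(c(0.1, 0.05), function(h) {
    t <- seq(0, 2 * pi, by = h)
    d <- finite_difference(sin(t), h)
    max(abs(d - cos(t)), na.rm = TRUE)
  }, 0)
  expect_gt(err[1] / err[2], 12)   # ~16 for exact 4th order
})

test_that("periodic differentiation wraps without edge loss", {
  n <- 64
  x <- seq(0, 2 * pi, length.out = n + 1)[1:n]
  d <- finite_difference(sin(x), x[2] - x[1], periodic = TRUE)
  expect_false(anyNA(d))
  expect_lt(max(abs(d - cos(x))), 1e-4)
})

test_that("too-short series are rejected", {
  expect_error(finite_difference(1:4, 0.1), "fewer than 5")
})

test_that("monomial library sizes match combinatorial counts", {
  expect_length(monomial_library(c("x", "y", "z"), 5)$terms, 56)
  expect_length(monomial_library(c("x", "y", "z"), 4)$terms, 35)
  expect_equal(monomial_library("x", 3)$terms, c("1", "x", "x^2", "x^3"))
  expect_length(default_drift_library()$terms, 8)
  expect_length(default_diffusion_library()$terms, 6)
})

test_that("time modulation doubles the library and warns at omega = 0", {
  base <- monomial_library("x", 3)
  tm <- build_time_modulated_library(base, 2.5)
  expect_length(tm$terms, 8)
  expect_true("cos(w*t)*x^2" %in% tm$terms)
  expect_equal(tm$omega, 2.5)
  expect_warning(build_time_modulated_library(base, 0), "collinear")
})

test_that("an exponential trajectory identifies its growth rate", {
  tr <- trajectory(exp(2 * seq(0, 1, by = 0.01)), step = 0.01, names = "z")
  sys <- build_ode_system(tr, library_spec(c("1", "z"), "z"))
  fit <- atsbl(sys, seed = 1)
  expect_equal(names(coef(fit))[fit$support], "z")
  expect_equal(unname(coef(fit)["z"]), 2, tolerance = 1e-5)
})

test_that("library evaluation rejects non-finite terms by name", {
  expect_error(
    evaluate_library(library_spec(c("x", "log(x)"), "x"), list(x = c(1, 0))),
    "log\\(x\\)")
})

test_that("a pure diffusion field yields the diffusivity on the Laplacian term", {
  # analytic heat evolution on a periodic interval: modes decay as
  # exp(-D k^2 t); no solver involved
  D <- 0.3
  n <- 64
  L <- 2 * pi
  x <- seq(0, L, length.out = n + 1)[1:n]
  ts <- seq(0, 1, by = 0.02)
  u <- t(sapply(ts, function(tt)
    exp(-D * tt) * sin(x) + 0.5 * exp(-D * 9 * tt) * sin(3 * x)))
  fs <- field_series(list(u = u), dx = L / n, dt = 0.02)
  sys <- build_pde_system(fs, library_spec(c("u", "u_xx"), "u"), "u", seed = 1)
  fit <- atsbl(sys, seed = 1)
  expect_equal(names(coef(fit))[fit$support], "u_xx")
  expect_equal(unname(coef(fit)["u_xx"]), D, tolerance = 1e-4)
})

test_that("a constant field produces a null model", {
  u <- matrix(1.7, 40, 32)
  fs <- field_series(list(u = u), dx = 0.1, dt = 0.05)
  sys <- build_pde_system(fs, library_spec(c("u", "u_x", "u_xx"), "u"), "u")
  expect_true(all(abs(sys$target) < 1e-12))
  fit <- atsbl(sys, seed = 1)
  expect_length(fit$support, 0)
})

test_that("the reaction-diffusion library evaluates finitely on solver output", {
  fs <- solve_lambda_omega(n = 32, t_end = 0.1, spinup = 0.05)
  sys <- build_pde_system(fs, default_rd_library(), "u", subsample = 2000,
                          seed = 1)
  expect_true(all(is.finite(sys$design)))
  expect_true(all(is.finite(sys$target)))
  expect_equal(ncol(sys$design), 33)
})

test_that("system builders are deterministic and co-registered", {
  tr <- dw_traj()
  spec <- default_drift_library("x")
  s1 <- build_ode_system(tr, spec)
  s2 <- build_ode_system(tr, spec)
  expect_identical(s1$design, s2$design)
  # row i of the design evaluates the library at the position whose
  # derivative is row i of the target
  x <- tr$values[3:(nrow(tr$values) - 2), 1]
  expect_equal(unname(s1$design[, "x"]), unname(x))
})
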