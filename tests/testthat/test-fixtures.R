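test_that("fixture definitions match their potentials and printed forms", {
  m <- make_fixture("three_well")
  expect_equal(eval_model(m, 0), 0)    # no constant term in the drift
  # drift equals -dU/dx of the potential, checked against a numerical
  # derivative at random points
  U <- function(x) x^6 - 6 * x^4 + 0.5 * x^3 + 8 * x^2
  set.seed(1)
  xs <- runif(100, -2, 2)
  h <- 1e-6
  dU <- (U(xs + h) - U(xs - h)) / (2 * h)
  expect_equal(eval_model(m, xs), -dU, tolerance = 1e-6)

  mt <- make_fixture("time_dependent")
  a0 <- mt$params$a0
  x <- c(-1, 0.3, 2)
  expect_equal(eval_model(mt, x, t = 0), a0 * x - x^3, tolerance = 1e-12)

  mdw <- make_fixture("double_well")
  expect_equal(eval_model(mdw, 2), -2 * 8 + 12 * 4 - 18 * 2 + 3)
  expect_equal(eval_model(mdw, 5, what = "diffusion"), 0.8)
  msd <- make_fixture("space_dep_diffusion")
  expect_equal(eval_model(msd, 3, what = "diffusion"), 9 - 6 + 2)

  mp <- make_fixture("planar_field", b = 0.5)
  xy <- c(0.7, -1.1)
  expect_equal(eval_model(mp, matrix(xy, 1), component = 1),
               xy[1] * (1 - xy[1]^2 - xy[2]^2) +
                 xy[2] * (xy[1]^2 - xy[2]^2 - 0.5))
  expect_equal(eval_model(mp, matrix(xy, 1), component = 2),
               xy[2] * (1 - xy[1]^2 - xy[2]^2) +
                 xy[1] * (xy[1]^2 - xy[2]^2 - 0.5))
})

test_that("zero diffusion reduces Euler-Maruyama to forward Euler", {
  m <- sde_model(c("x" = -1), c("1" = 0))
  tr <- euler_maruyama(m, 1, 0.01, 100, seed = 1)
  x <- 1
  for (i in 1:100) x <- x - x * 0.01
  expect_equal(unname(tr$values[101, 1]), x, tolerance = 1e-12)
})

test_that("the discrete scheme reproduces the exact Gaussian variance law", {
  m <- sde_model(c("1" = 0), c("1" = 0.5))
  set.seed(9)
  finals <- replicate(2000, {
    tr <- euler_maruyama(m, 0, 0.01, 50)
    tr$values[51, 1]
  })
  v_true <- 2 * 0.5 * 50 * 0.01
  se <- v_true * sqrt(2 / 2000)
  expect_lt(abs(var(finals) - v_true), 3 * se)
})

test_that("the compiled and reference simulators agree path-for-path", {
  for (nm in c("double_well", "time_dependent")) {
    m <- make_fixture(nm)
    a <- euler_maruyama(m, 0.5, 0.005, 300, seed = 7)
    b <- euler_maruyama(m, 0.5, 0.005, 300, seed = 7, engine = "r")
    expect_equal(a$values, b$values, tolerance = 1e-12, info = nm)
  }
  # with a control force
  m <- make_fixture("three_well")
  ctrl <- list(weights = list(c("x" = -16, "x^3" = 24)), mu = 0, zeta = 1)
  a <- euler_maruyama(m, 0, 0.005, 300, seed = 8, control = ctrl)
  b <- euler_maruyama(m, 0, 0.005, 300, seed = 8, control = ctrl, engine = "r")
  expect_equal(a$values, b$values, tolerance = 1e-12)
  expect_equal(attr(a, "control"), attr(b, "control"), tolerance = 1e-12)
})

test_that("a zero control force leaves the path unchanged for the same seed", {
  m <- make_fixture("double_well")
  plain <- euler_maruyama(m, 0, 0.005, 500, seed = 3)
  zero <- euler_maruyama(m, 0, 0.005, 500, seed = 3,
                         control = list(weights = list(c("x" = 0)),
                                        mu = 0, zeta = 1))
  expect_equal(plain$values, zero$values)
  expect_true(all(attr(zero, "control") == 0))
})

test_that("the double-well trajectory occupies two clusters", {
  tr <- dw_traj()
  x <- tr$values[, 1]
  # outer roots of the drift polynomial are the stable wells; the low-x
  # well is much deeper, so occupancy is strongly asymmetric but both
  # wells must be visited and most time spent near one of them
  wells <- sort(Re(polyroot(c(3, -18, 12, -2))))[c(1, 3)]
  expect_lt(min(abs(x - wells[1])), 0.2)
  expect_lt(min(abs(x - wells[2])), 0.2)
  near <- abs(x - wells[1]) < 0.6 | abs(x - wells[2]) < 0.6
  expect_gt(mean(near), 0.5)
})

test_that("the Lorenz integrator respects equilibria and volume contraction", {
  tr0 <- integrate_lorenz(x0 = c(0, 0, 0), t_end = 0.1)
  expect_true(all(abs(tr0$values) < 1e-12))

  # divergence of the flow is -(a + 1 + c) everywhere; estimate it
  # numerically from the vector field
  a <- 10; b <- 28; cc <- 3 / 8
  f <- function(p) c(a * (p[2] - p[1]), p[1] * (b - p[3]) - p[2],
                     p[1] * p[2] - cc * p[3])
  set.seed(2)
  for (i in 1:5) {
    p <- rnorm(3, 0, 5)
    h <- 1e-5
    div <- sum(vapply(1:3, function(j) {
      e <- numeric(3); e[j] <- h
      (f(p + e)[j] - f(p - e)[j]) / (2 * h)
    }, 0))
    expect_equal(div, -(a + 1 + cc), tolerance = 1e-6)
  }

  tr <- integrate_lorenz(t_end = 2)
  expect_true(all(is.finite(tr$values)))
  expect_lt(max(abs(tr$values)), 100)
})

test_that("the lambda-omega solver holds fixed points and the ODE reduction", {
  # the zero field is a fixed point of the reaction-diffusion dynamics
  fs0 <- solve_lambda_omega(n = 16, t_end = 0.03, spinup = 0,
                            ic = "uniform", u0 = 0, v0 = 0)
  expect_true(all(abs(fs0$fields$u) < 1e-14))
  expect_true(all(abs(fs0$fields$v) < 1e-14))

  # a spatially uniform state makes diffusion inert: the run must match
  # the two-variable reaction ODE integrated independently
  dt <- 0.0034
  fs <- solve_lambda_omega(n = 16, dt = dt, t_end = 0.2, spinup = 0,
                           ic = "uniform", u0 = 0.4, v0 = -0.2)
  rhs <- function(t, y, p) {
    A2 <- (y[1]^2 + y[2]^2)^2
    list(c((1 - A2) * y[1] + 2 * A2 * y[2],
           -2 * A2 * y[1] + (1 - A2) * y[2]))
  }
  sol <- deSolve::ode(c(0.4, -0.2), (0:round(0.2 / dt)) * dt, rhs, NULL,
                      method = "rk4")
  expect_lt(max(abs(fs$fields$u[, 1, 1] - sol[, 2])), 1e-6)
  expect_lt(max(abs(fs$fields$v[, 1, 1] - sol[, 3])), 1e-6)
  # and the field stays uniform
  expect_lt(max(abs(sweep(fs$fields$u, 1, fs$fields$u[, 1, 1]))), 1e-12)
})

test_that("proportional noise matches its definition", {
  set.seed(6)
  X <- cbind(rnorm(5000, 0, 2), rep(1, 5000))
  Xn <- add_noise(X, 0.1, seed = 1)
  expect_equal(Xn[, 2], X[, 2])        # constant coordinate untouched
  ratio <- sd(Xn[, 1] - X[, 1]) / sd(X[, 1])
  expect_equal(ratio, 0.1, tolerance = 0.05)
  expect_identical(add_noise(X, 0), X)
})

test_that("denoising reduces the variance of pure noise", {
  set.seed(8)
  u <- array(rnorm(30 * 32 * 32), c(30, 32, 32))
  fs <- field_series(list(u = u), dx = 0.1, dt = 0.01)
  for (method in c("spectral_lowpass", "gaussian_smooth")) {
    out <- denoise(fs, method)
    expect_lt(var(as.numeric(out$fields$u)), var(as.numeric(u)))
  }
  expect_identical(denoise(fs, "none"), fs)
})

test_that("trajectory smoothing suppresses noise without biasing the signal", {
  t <- seq(0, 10, by = 0.01)
  clean <- sin(t)
  noisy <- clean + rnorm(length(t), 0, 0.1)
  sm <- denoise_trajectory(trajectory(noisy, 0.01), window = 41)
  expect_lt(mean((sm$values[, 1] - clean)^2), 0.1 * mean((noisy - clean)^2))
})
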