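poly_design <- function(n = 200, lo = -2, hi = 2) {
  x <- seq(lo, hi, length.out = n)
  X <- cbind(1, x, x^2, x^3, x^4)
  colnames(X) <- c("1", "x", "x^2", "x^3", "x^4")
  list(x = x, X = X)
}

test_that("hard_threshold and model_error match their definitions", {
  expect_equal(hard_threshold(c(0.3, -1, 2), 0), c(0.3, -1, 2))
  expect_equal(hard_threshold(c(0.1, -2), 0.5), c(0, -2))
  expect_equal(hard_threshold(c(0.1, -2), 5), c(0, 0))
  g <- c(1, 2, 2)
  expect_equal(model_error(c(0, 0), matrix(0, 3, 2), g, 1), sum(g^2))
  # exact weights on noise-free data: residual 0, two active terms
  X <- cbind(1:3, c(2, 0, 1))
  w <- c(1.5, -2)
  expect_equal(model_error(w, X, drop(X %*% w), 0.5), 1.0)
  e1 <- model_error(w, X, drop(X %*% w) + 1, 0.5)
  e2 <- model_error(w, X, drop(X %*% w) + 1, 1.0)
  expect_equal(e2 - e1, 0.5 * 2)   # doubling eta doubles only the penalty
})

test_that("an exactly representable cubic is recovered to high precision", {
  pd <- poly_design()
  fit <- atsbl(pd$X, 2 * pd$x^3 - pd$x, seed = 1)
  expect_equal(fit$support, c(2L, 4L))
  expect_equal(unname(coef(fit)[c(2, 4)]), c(-1, 2), tolerance = 1e-6)
  expect_equal(fit$eta, 1e-3 * fit$kappa)
})

test_that("a zero target yields the null model with zero error", {
  pd <- poly_design()
  fit <- atsbl(pd$X, rep(0, 200), seed = 1)
  expect_equal(unname(coef(fit)), rep(0, 5))
  expect_equal(fit$e, 0)
})

test_that("noisy recovery stays within standard errors of the oracle fit", {
  pd <- poly_design()
  set.seed(31)
  y <- 2 * pd$x^3 - pd$x + rnorm(200, 0, 0.01)
  fit <- atsbl(pd$X, y, seed = 1)
  expect_equal(fit$support, c(2L, 4L))
  ls <- lm(y ~ 0 + pd$X[, c(2, 4)])
  se <- sqrt(diag(vcov(ls)))
  expect_lt(max(abs(unname(coef(fit)[c(2, 4)]) - unname(coef(ls))) / se), 5)
})

test_that("the returned error never exceeds the unthresholded fit's error", {
  for (seed in c(2, 5)) {
    set.seed(seed)
    X <- matrix(rnorm(300 * 8), 300, 8)
    y <- drop(X %*% c(0, 3, 0, 0, -1, 0, 0, 0)) + rnorm(300, 0, 0.2)
    fit <- atsbl(X, y, seed = seed)
    n_tr <- round(0.8 * 300)
    idx_tr <- sparsedyn:::.with_seed(seed, sort(sample.int(300, n_tr)))
    idx_te <- setdiff(1:300, idx_tr)
    e_init <- model_error(unname(coef(fit$init_fit)),
                          X[idx_te, ], y[idx_te], fit$eta)
    expect_lte(fit$e, e_init + 1e-8)
  }
})

test_that("identical inputs and seed give bit-identical fits", {
  set.seed(77)
  X <- matrix(rnorm(500), 100, 5)
  y <- drop(X %*% c(1, 0, 0, -2, 0)) + rnorm(100, 0, 0.05)
  f1 <- atsbl(X, y, seed = 9)
  f2 <- atsbl(X, y, seed = 9)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$error_trace, f2$error_trace)
})

test_that("noise-free fixture drifts are recovered with the generating term count", {
  x <- seq(-2.2, 2.2, length.out = 400)
  t <- seq(0, 20, length.out = 400)
  specs <- list(
    double_well = make_fixture("double_well"),
    three_well = make_fixture("three_well"),
    space_dep_diffusion = make_fixture("space_dep_diffusion"),
    time_dependent = make_fixture("time_dependent"))
  for (nm in names(specs)) {
    m <- specs[[nm]]
    spec <- if (nm == "time_dependent")
      build_time_modulated_library(monomial_library("x", 5), m$omega)
    else default_drift_library("x")
    Th <- evaluate_library(spec, list(x = x, t = t))
    g <- drop(Th[, names(m$drift[[1]]), drop = FALSE] %*% m$drift[[1]])
    fit <- atsbl(linear_system(Th, g, column_names = spec$terms), seed = 1)
    expect_equal(sort(names(coef(fit))[fit$support]),
                 sort(names(m$drift[[1]])), info = nm)
    # diffusion maps likewise
    dspec <- default_diffusion_library("x")
    Th2 <- evaluate_library(dspec, list(x = x, t = t))
    g2 <- drop(Th2[, names(m$diffusion[[1]]), drop = FALSE] %*% m$diffusion[[1]])
    fit2 <- atsbl(linear_system(Th2, g2, column_names = dspec$terms), seed = 1)
    expect_equal(sort(names(coef(fit2))[fit2$support]),
                 sort(names(m$diffusion[[1]])), info = nm)
  }
  # the planar field drifts over a 2-d monomial library
  m2 <- make_fixture("planar_field")
  set.seed(3)
  xy <- cbind(runif(500, -1.5, 1.5), runif(500, -1.5, 1.5))
  spec2 <- monomial_library(c("x", "y"), 3)
  Th <- evaluate_library(spec2, list(x = xy[, 1], y = xy[, 2]))
  for (l in 1:2) {
    g <- drop(Th[, names(m2$drift[[l]])] %*% m2$drift[[l]])
    fit <- atsbl(linear_system(Th, g, column_names = spec2$terms), seed = 1)
    expect_equal(sort(names(coef(fit))[fit$support]), sort(names(m2$drift[[l]])))
  }
})

test_that("contiguous splits are supported and recorded", {
  pd <- poly_design()
  fit <- atsbl(pd$X, 2 * pd$x^3 - pd$x, seed = 1, split_type = "contiguous")
  expect_equal(fit$split_type, "contiguous")
  expect_equal(fit$support, c(2L, 4L))
})
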