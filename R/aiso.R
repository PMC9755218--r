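#' Gaussian-weighted control force opposing an inferred drift
#'
#' `c_l(x, t) = -Theta_l(x) . w  *  exp(-(x_l - mu_l)^2 / zeta_l)`:
#' the negative of the library-evaluated inferred drift, localized around
#' the trajectory mean `mu` with width given by the trajectory variance
#' `zeta`, so the force vanishes away from the region where the estimate
#' is trusted.
#'
#' @param x state vector (or `n x M` matrix of states).
#' @param t time (recycled).
#' @param weights list of named coefficient maps, one per component.
#' @param vars state-variable names.
#' @param mu per-component center.
#' @param zeta per-component width (variance units, `> 0`).
#' @param omega modulation frequency for time-dependent terms.
#' @return matrix of control-force values (`n x M`).
#' @export
control_force <- function(x, t, weights, vars, mu, zeta, omega = 0) {
  if (any(zeta <= 0)) stop("zeta must be positive")
  x <- if (is.matrix(x)) x else matrix(x, ncol = length(vars))
  M <- length(vars)
  out <- matrix(0, nrow(x), M)
  for (l in seq_len(M)) {
    th <- .eval_terms(weights[[l]], vars, x, rep_len(t, nrow(x)), omega)
    out[, l] <- -th * exp(-(x[, l] - mu[l])^2 / zeta[l])
  }
  out
}

#' Per-component mean and variance of a trajectory
#'
#' Population variance convention (divisor `N`), matching the Gaussian
#' width used by [control_force()].
#'
#' @param traj a [trajectory()].
#' @return list with `mu` and `zeta` (per-component).
#' @export
trajectory_moments <- function(traj) {
  X <- traj$values
  if (nrow(X) < 2) stop("need at least 2 samples")
  mu <- colMeans(X)
  zeta <- colMeans(sweep(X, 2L, mu)^2)
  list(mu = mu, zeta = zeta)
}

#' Automatic iterative sampling optimization (AISO)
#'
#' Active-learning identification of a Langevin system with metastable
#' states.  Each iteration simulates the system under the current control
#' force, accumulates positions and increment statistics (with the known
#' applied control subtracted from `F1`, since the sampled process obeys
#' drift `D1 + c`), refits drift and diffusion with [atsbl()] on all
#' accumulated data, and sets the next control to oppose the newest drift
#' estimate, localized at the latest trajectory's mean and variance.  The
#' first iteration runs uncontrolled; each iteration starts from the final
#' state of the previous one.  If a controlled simulation blows up, the
#' iteration is restarted with the control damped by half (with a
#' message).
#'
#' @param model the true [sde_model()] being sampled (simulator input and
#'   DIC reference).
#' @param drift_spec,diff_spec candidate libraries (defaults as in
#'   [fit_km()]).
#' @param n_iter number of iterations (default 10).
#' @param steps_per_iter Euler-Maruyama steps per iteration (default 1e5).
#' @param dt time step (default 5e-3).
#' @param seed RNG seed governing the whole run.
#' @param x0 initial state for the first iteration.
#' @param prior prior passed to [atsbl()].
#' @param zeta_floor lower bound on `zeta` as a fraction of the squared
#'   sampled range, guarding against singular Gaussian weights.
#' @param ... further arguments to [atsbl()].
#' @return object of class `aiso`: final `drift_coefs` / `diff_coefs`,
#'   `dic_trace` (per-iteration mean DIC of drift and diffusion against
#'   the true model), `moments` (per-iteration `mu`, `zeta`), the
#'   accumulated `positions`, `times`, `F1` (control-corrected), `F2`,
#'   and the per-iteration fits.
#' @export
aiso <- function(model, drift_spec = NULL, diff_spec = NULL,
                 n_iter = 10L, steps_per_iter = 1e5L, dt = 5e-3,
                 seed = 1L, x0 = NULL, prior = "laplace",
                 zeta_floor = 1e-6, ...) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  M <- length(model$vars)
  if (is.null(drift_spec)) drift_spec <- default_drift_library(model$vars[1])
  if (is.null(diff_spec)) diff_spec <- default_diffusion_library(model$vars[1])
  if (M > 1 && identical(drift_spec$vars, model$vars[1]))
    stop("supply multivariate libraries for a multivariate model")
  if (is.null(x0)) x0 <- numeric(M)
  set.seed(seed)

  acc_pos <- NULL; acc_t <- NULL; acc_F1 <- NULL; acc_F2 <- NULL
  acc_ctrl <- NULL; Theta_d_acc <- NULL; Theta_h_acc <- NULL
  control <- NULL
  dic_trace <- numeric(n_iter)
  moments <- vector("list", n_iter)
  fits <- vector("list", n_iter)
  t0 <- 0
  for (i in seq_len(n_iter)) {
    ctrl <- control
    traj <- NULL
    for (attempt in 1:6) {
      traj <- tryCatch(
        euler_maruyama(model, x0, dt, steps_per_iter, seed = NULL,
                       control = ctrl, t0 = t0),
        error = function(e) e)
      if (!inherits(traj, "error")) break
      if (is.null(ctrl)) stop(traj)
      message("iteration ", i, ": simulation failed (", conditionMessage(traj),
              "); damping control by half")
      ctrl$weights <- lapply(ctrl$weights, function(w) w / 2)
    }
    if (inherits(traj, "error")) stop(traj)

    st <- increments(traj)
    F1c <- st$F1
    cm <- attr(traj, "control")
    if (is.null(cm)) cm <- matrix(0, nrow(st$F1), M)
    F1c <- F1c - cm               # the sampled process obeys drift D1 + c
    acc_pos <- rbind(acc_pos, st$positions)
    acc_t <- c(acc_t, st$times)
    acc_F1 <- rbind(acc_F1, F1c)
    acc_F2 <- rbind(acc_F2, st$F2)
    acc_ctrl <- rbind(acc_ctrl, cm)

    # libraries are evaluated incrementally on the new rows only
    data_new <- as.list(as.data.frame(st$positions))
    names(data_new) <- model$vars
    data_new$t <- st$times
    Theta_d <- rbind(Theta_d_acc %||% NULL, evaluate_library(drift_spec, data_new))
    Theta_h <- rbind(Theta_h_acc %||% NULL, evaluate_library(diff_spec, data_new))
    Theta_d_acc <- Theta_d
    Theta_h_acc <- Theta_h
    fit_d <- list(); fit_h <- list()
    for (l in seq_len(M)) {
      fit_d[[l]] <- atsbl(linear_system(Theta_d, acc_F1[, l],
                                        column_names = drift_spec$terms),
                          prior = prior, seed = seed + i, ...)
      # drift-corrected second conditional moment: the sampled drift is
      # the current estimate plus the known applied control
      g_tot <- drop(Theta_d %*% coef(fit_d[[l]])) + acc_ctrl[, l]
      f1_raw <- acc_F1[, l] + acc_ctrl[, l]
      f2 <- acc_F2[, l] - dt * g_tot * f1_raw + dt * g_tot^2 / 2
      fit_h[[l]] <- atsbl(linear_system(Theta_h, f2,
                                        column_names = diff_spec$terms),
                          prior = prior, seed = seed + i, ...)
    }
    drift_coefs <- lapply(fit_d, function(f) { cf <- coef(f); cf[cf != 0] })
    diff_coefs <- lapply(fit_h, function(f) { cf <- coef(f); cf[cf != 0] })
    dic_trace[i] <- mean(c(
      vapply(seq_len(M), function(l) dic(drift_coefs[[l]], model$drift[[l]]), 0),
      vapply(seq_len(M), function(l) dic(diff_coefs[[l]], model$diffusion[[l]]), 0)))

    mom <- trajectory_moments(traj)
    rng2 <- apply(traj$values, 2L, function(v) diff(range(v))^2)
    mom$zeta <- pmax(mom$zeta, zeta_floor * pmax(rng2, .Machine$double.eps))
    moments[[i]] <- mom
    fits[[i]] <- list(drift = fit_d, diffusion = fit_h,
                      drift_coefs = drift_coefs, diff_coefs = diff_coefs)

    control <- list(weights = drift_coefs, mu = mom$mu, zeta = mom$zeta)
    x0 <- traj$values[nrow(traj$values), ]
    t0 <- t0 + steps_per_iter * dt
  }

  final <- fits[[n_iter]]
  structure(list(drift_coefs = if (M == 1) final$drift_coefs[[1]] else final$drift_coefs,
                 diff_coefs = if (M == 1) final$diff_coefs[[1]] else final$diff_coefs,
                 drift = if (M == 1) final$drift[[1]] else final$drift,
                 diffusion = if (M == 1) final$diffusion[[1]] else final$diffusion,
                 dic_trace = dic_trace,
                 moments = moments,
                 positions = acc_pos, times = acc_t,
                 F1 = acc_F1, F2 = acc_F2,
                 fits = fits,
                 model = model, vars = model$vars,
                 drift_spec = drift_spec, diff_spec = diff_spec,
                 n_iter = n_iter, steps_per_iter = steps_per_iter,
                 dt = dt, seed = seed,
                 call = match.call()),
            class = "aiso")
}

#' @export
print.aiso <- function(x, digits = 4, ...) {
  cat(sprintf("AISO run: %d iterations x %g steps (dt = %g)\n",
              x$n_iter, x$steps_per_iter, x$dt))
  M <- length(x$vars)
  dc <- if (M == 1) list(x$drift_coefs) else x$drift_coefs
  hc <- if (M == 1) list(x$diff_coefs) else x$diff_coefs
  for (l in seq_len(M)) {
    cat(" ", format_equation(dc[[l]], sprintf("D1_%s", x$vars[l]),
                             digits = digits), "\n")
    cat(" ", format_equation(hc[[l]], sprintf("D2_%s", x$vars[l]),
                             digits = digits), "\n")
  }
  cat("  DIC trace:", paste(format(x$dic_trace, digits = 3), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
plot.aiso <- function(x, ...) {
  graphics::plot(seq_along(x$dic_trace), x$dic_trace, type = "b", log = "y",
                 xlab = "iteration", ylab = "mean DIC", ...)
  invisible(x)
}

#' Count of distinct phase-space bins visited
#'
#' Utility for quantifying exploration: the number of occupied bins of a
#' `Q`-bin histogram per component, over the given positions.
#'
#' @param positions matrix of positions.
#' @param Q bins per component (default 50).
#' @param range optional 2 x M matrix of fixed bin ranges.
#' @return number of distinct occupied bins (product grid).
#' @export
bins_visited <- function(positions, Q = 50L, range = NULL) {
  positions <- as.matrix(positions)
  M <- ncol(positions)
  code <- 0
  mult <- 1
  for (j in seq_len(M)) {
    r <- if (is.null(range)) base::range(positions[, j]) else range[, j]
    br <- seq(r[1], r[2], length.out = Q + 1)
    ix <- findInterval(pmin(pmax(positions[, j], r[1]), r[2]), br,
                       rightmost.closed = TRUE)
    ix[ix > Q] <- Q
    code <- code + (ix - 1) * mult
    mult <- mult * Q
  }
  length(unique(code))
}
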