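#' Symbolic Langevin model (drift and diffusion coefficient maps)
#'
#' Drift and diffusion are given per component as named coefficient vectors
#' over the canonical term grammar (see [library_spec()]); the model is
#' evaluable at `(x, t)`, serves as simulator input, and doubles as the
#' ground truth when scoring identified equations with [dic()].
#'
#' @param drift list (one per component) of named coefficient vectors for
#'   the drift `D1`; a bare vector is taken as one component.
#' @param diffusion same for the diffusion `D2` (diagonal).
#' @param vars state-variable names.
#' @param params named constants (e.g. `a0`, `omega`, `b`), kept for
#'   provenance.
#' @param omega modulation frequency bound to `cos(w*t)` factors.
#' @return object of class `sde_model`.
#' @export
sde_model <- function(drift, diffusion, vars = "x", params = list(),
                      omega = 0) {
  if (!is.list(drift)) drift <- list(drift)
  if (!is.list(diffusion)) diffusion <- list(diffusion)
  if (length(drift) != length(vars) || length(diffusion) != length(vars))
    stop("drift/diffusion must have one coefficient map per component")
  structure(list(drift = drift, diffusion = diffusion, vars = vars,
                 params = params, omega = omega),
            class = "sde_model")
}

#' @export
print.sde_model <- function(x, ...) {
  for (j in seq_along(x$vars)) {
    cat(format_equation(x$drift[[j]],
                        sprintf("D1_%s(%s)", x$vars[j],
                                paste(x$vars, collapse = ","))), "\n")
    cat(format_equation(x$diffusion[[j]],
                        sprintf("D2_%s(%s)", x$vars[j],
                                paste(x$vars, collapse = ","))), "\n")
  }
  invisible(x)
}

#' Evaluate a model's drift or diffusion
#'
#' @param model an [sde_model()].
#' @param x states, vector (1-d) or matrix (n x M).
#' @param t times (recycled).
#' @param what `"drift"` or `"diffusion"`.
#' @param component component index.
#' @return numeric vector.
#' @export
eval_model <- function(model, x, t = 0, what = c("drift", "diffusion"),
                       component = 1L) {
  what <- match.arg(what)
  x <- if (is.matrix(x)) x else matrix(x, ncol = length(model$vars))
  .eval_terms(model[[if (what == "drift") "drift" else "diffusion"]][[component]],
              model$vars, x, rep_len(t, nrow(x)), model$omega)
}

#' Built-in benchmark Langevin systems
#'
#' Exact printed models for the in-package benchmarks:
#' \describe{
#'   \item{double_well}{`D1 = -2x^3 + 12x^2 - 18x + 3`, `D2 = 0.8`.}
#'   \item{time_dependent}{`D1 = [a0 + 1 - cos(wt)] x - x^3` with
#'     `a0 = 5e-3` (default `omega = 1`), `D2 = 0.8`.}
#'   \item{space_dep_diffusion}{double-well drift with
#'     `D2 = x^2 - 2x + 2`.}
#'   \item{three_well}{`D1 = -dU/dx` of
#'     `U = x^6 - 6x^4 + 0.5x^3 + 8x^2`, i.e.
#'     `-6x^5 + 24x^3 - 1.5x^2 - 16x`; `D2 = 1`.}
#'   \item{planar_field}{two-dimensional field
#'     `D1x = x(1 - x^2 - y^2) + y(x^2 - y^2 - b)`,
#'     `D1y = y(1 - x^2 - y^2) + x(x^2 - y^2 - b)`, `D2 = 1` (default
#'     `b = 1`).}
#' }
#'
#' @param name fixture name.
#' @param ... parameter overrides (`a0`, `omega`, `b`).
#' @return an [sde_model()].
#' @export
make_fixture <- function(name = c("double_well", "time_dependent",
                                  "space_dep_diffusion", "three_well",
                                  "planar_field"), ...) {
  name <- match.arg(name)
  ov <- list(...)
  p <- function(key, default) ov[[key]] %||% default
  switch(name,
    double_well = sde_model(
      c("1" = 3, "x" = -18, "x^2" = 12, "x^3" = -2),
      c("1" = 0.8)),
    time_dependent = {
      a0 <- p("a0", 5e-3); omega <- p("omega", 1)
      sde_model(c("x" = a0 + 1, "x^3" = -1, "cos(w*t)*x" = -1),
                c("1" = 0.8),
                params = list(a0 = a0, omega = omega), omega = omega)
    },
    space_dep_diffusion = sde_model(
      c("1" = 3, "x" = -18, "x^2" = 12, "x^3" = -2),
      c("1" = 2, "x" = -2, "x^2" = 1)),
    three_well = sde_model(
      c("x" = -16, "x^2" = -1.5, "x^3" = 24, "x^5" = -6),
      c("1" = 1)),
    planar_field = {
      b <- p("b", 1)
      sde_model(
        drift = list(
          c("x" = 1, "x^3" = -1, "x*y^2" = -1, "x^2*y" = 1, "y^3" = -1,
            "y" = -b),
          c("y" = 1, "x^2*y" = -1, "y^3" = -1, "x^3" = 1, "x*y^2" = -1,
            "x" = -b)),
        diffusion = list(c("1" = 1), c("1" = 1)),
        vars = c("x", "y"), params = list(b = b))
    })
}

#' Euler-Maruyama simulation of a Langevin model
#'
#' Ito-convention explicit scheme
#' `X_{i+1} = X_i + [D1(X_i, t_i) + c(X_i, t_i)] dt + sqrt(2 D2(X_i, t_i) dt) xi_i`
#' with independent standard-normal `xi_i`.  Reproducible from `seed`; an
#' optional Gaussian-weighted control force is applied and its values are
#' recorded in the `control` attribute of the result (zero control gives a
#' path identical to the uncontrolled one for the same seed).
#'
#' @param model an [sde_model()].
#' @param x0 initial state.
#' @param dt time step.
#' @param n_steps number of steps.
#' @param seed RNG seed; `NULL` continues the current RNG stream.
#' @param control `NULL`, or a list with `weights` (list of named
#'   coefficient maps, one per component, defining the inferred drift
#'   `Theta * w`), `mu` and `zeta` (per-component center and width of the
#'   Gaussian weight).
#' @param t0 start time.
#' @param engine `"cpp"` (default) or `"r"` (reference implementation).
#' @return a [trajectory()] of `n_steps + 1` samples; when a control is
#'   applied, the matrix of applied control values (one row per step) is
#'   attached as attribute `"control"`.
#' @export
euler_maruyama <- function(model, x0, dt, n_steps, seed = NULL,
                           control = NULL, t0 = 0,
                           engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (dt <= 0) stop("dt must be positive")
  M <- length(model$vars)
  if (length(x0) != M) stop("x0 has wrong length")
  if (!is.null(seed)) set.seed(seed)
  has_control <- !is.null(control)
  if (has_control) {
    if (any(control$zeta <= 0)) stop("control zeta must be positive")
    ctrl_terms <- lapply(control$weights, .encode_terms, vars = model$vars)
  } else {
    ctrl_terms <- lapply(seq_len(M), function(j) .encode_terms(numeric(0), model$vars))
  }
  drift_terms <- lapply(model$drift, .encode_terms, vars = model$vars)
  diff_terms <- lapply(model$diffusion, .encode_terms, vars = model$vars)

  if (engine == "cpp") {
    res <- em_simulate_cpp(drift_terms, diff_terms, as.numeric(x0), dt,
                           as.integer(n_steps), t0, model$omega,
                           has_control, ctrl_terms,
                           as.numeric(control$mu %||% numeric(M)),
                           as.numeric(control$zeta %||% rep(1, M)))
    X <- res$X
    Cm <- if (has_control) res$control else NULL
  } else {
    X <- matrix(NA_real_, n_steps + 1, M)
    Cm <- if (has_control) matrix(NA_real_, n_steps, M) else NULL
    x <- as.numeric(x0)
    X[1, ] <- x
    for (i in seq_len(n_steps)) {
      t <- t0 + (i - 1) * dt
      xi <- stats::rnorm(M)
      xn <- numeric(M)
      for (j in seq_len(M)) {
        d1 <- .eval_terms(model$drift[[j]], model$vars, matrix(x, 1), t, model$omega)
        d2 <- .eval_terms(model$diffusion[[j]], model$vars, matrix(x, 1), t, model$omega)
        if (d2 < 0) stop("diffusion coefficient negative at step ", i)
        cc <- 0
        if (has_control) {
          cc <- -.eval_terms(control$weights[[j]], model$vars, matrix(x, 1), t,
                             model$omega) *
            exp(-(x[j] - control$mu[j])^2 / control$zeta[j])
          Cm[i, j] <- cc
        }
        xn[j] <- x[j] + (d1 + cc) * dt + sqrt(2 * d2 * dt) * xi[j]
        if (!is.finite(xn[j]))
          stop("trajectory blow-up at step ", i, " (last valid index ", i - 1, ")")
      }
      x <- xn
      X[i + 1, ] <- x
    }
  }
  out <- trajectory(X, step = dt, t0 = t0, names = model$vars)
  attr(out, "control") <- Cm
  out
}

#' Lorenz-system trajectory
#'
#' Integrates `dx/dt = a(y - x)`, `dy/dt = x(b - z) - y`,
#' `dz/dt = xy - cz` with classical fourth-order Runge-Kutta at fixed step
#' `dt` (deterministic).  Defaults follow the in-package ODE benchmark:
#' `a = 10`, `b = 28`, `c = 3/8`, `x0 = (-8, 8, 27)`, `dt = 2e-4`,
#' `t_end = 25`.
#'
#' @param a,b,c system parameters.
#' @param x0 initial state (length 3).
#' @param dt time step.
#' @param t_end end time.
#' @return a [trajectory()] with components `x`, `y`, `z`.
#' @export
integrate_lorenz <- function(a = 10, b = 28, c = 3/8,
                             x0 = c(-8, 8, 27), dt = 2e-4, t_end = 25) {
  if (dt <= 0 || t_end <= dt) stop("need dt > 0 and t_end > dt")
  rhs <- function(t, y, parms) {
    list(c(parms$a * (y[2] - y[1]),
           y[1] * (parms$b - y[3]) - y[2],
           y[1] * y[2] - parms$c * y[3]))
  }
  tms <- seq(0, t_end, by = dt)
  sol <- deSolve::ode(y = c(x = x0[1], y = x0[2], z = x0[3]), times = tms,
                      func = rhs, parms = list(a = a, b = b, c = c),
                      method = "rk4")
  if (any(!is.finite(sol))) stop("Lorenz integration blow-up")
  trajectory(unname(sol[, 2:4]), step = dt, t0 = 0, names = c("x", "y", "z"))
}

#' Reference coefficient maps of the Lorenz system
#'
#' Ground-truth coefficients of each component's equation over a monomial
#' library in `(x, y, z)`, for scoring with [dic()].
#' @inheritParams integrate_lorenz
#' @return list of three named coefficient vectors (`x`, `y`, `z`).
#' @export
lorenz_reference <- function(a = 10, b = 28, c = 3/8) {
  list(x = c("x" = -a, "y" = a),
       y = c("x" = b, "y" = -1, "x*z" = -1),
       z = c("z" = -c, "x*y" = 1))
}

#' Spectral solution of the lambda-omega reaction-diffusion system
#'
#' Two-component system
#' `du/dt = Du lap u + lambda(A) u - omega(A) v`,
#' `dv/dt = Dv lap v + omega(A) u + lambda(A) v`, with
#' `A = u^2 + v^2`, `omega = -beta A^2`, `lambda = 1 - A^2`, on a periodic
#' square.  Diffusion is applied exactly in Fourier space and the local
#' reaction is advanced with a pointwise RK4 step (Strang splitting).
#' Defaults follow the in-package PDE benchmark: `beta = 2`, domain
#' `20 x 20`, `256^2` grid, `dt = 0.0034`, `t_end = 0.6`.
#'
#' @param Du,Dv diffusivities.
#' @param beta reaction parameter.
#' @param L domain side length.
#' @param n grid points per side.
#' @param dt time step.
#' @param t_end end time.
#' @param ic `"spiral"` (interleaved spiral arms), `"random"`, or
#'   `"uniform"` (spatially constant `u0`, `v0`; diffusion is then inert
#'   and the run reduces to the two-variable reaction ODE).
#' @param u0,v0 initial values for `ic = "uniform"`.
#' @param seed seed for the random initial condition.
#' @param stride keep every `stride`-th snapshot.
#' @param spinup equilibration time integrated before recording starts
#'   (default 0.2).  The seeded spiral is not exactly periodic at the
#'   domain wrap, so the first few dozen steps carry spectral ringing that
#'   is not part of the reaction-diffusion dynamics; the spin-up lets the
#'   pattern settle onto a smooth developed spiral before `t = 0`.
#' @return a [field_series()] with components `u`, `v`.
#' @export
solve_lambda_omega <- function(Du = 0.1, Dv = 0.1, beta = 2, L = 20,
                               n = 256, dt = 0.0034, t_end = 0.6,
                               ic = c("spiral", "random", "uniform"),
                               seed = 1L, stride = 1L, spinup = 0.2,
                               u0 = 0.4, v0 = -0.2) {
  ic <- match.arg(ic)
  xs <- seq(-L / 2, L / 2, length.out = n + 1)[seq_len(n)]
  if (ic == "spiral") {
    r <- sqrt(outer(xs^2, xs^2, "+"))
    th <- outer(xs, xs, function(x, y) atan2(y, x))
    u <- tanh(r) * cos(th - r)
    v <- tanh(r) * sin(th - r)
  } else if (ic == "uniform") {
    u <- matrix(u0, n, n)
    v <- matrix(v0, n, n)
  } else {
    u <- .with_seed(seed, matrix(stats::runif(n * n, -0.5, 0.5), n, n))
    v <- .with_seed(seed + 1L, matrix(stats::runif(n * n, -0.5, 0.5), n, n))
  }
  k <- 2 * pi / L * c(0:(n / 2), -(n / 2 - 1):-1)[seq_len(n)]
  k2 <- outer(k^2, k^2, "+")
  # stability heuristic for the explicit reaction step (diffusion is exact)
  rate0 <- (1 + beta) * max((u^2 + v^2)^2, 1)
  if (dt * rate0 > 2)
    warning("dt looks too large for the explicit reaction update ",
            "(dt * reaction rate = ", format(dt * rate0, digits = 3), ")")
  Eu <- exp(-Du * k2 * dt / 2)
  Ev <- exp(-Dv * k2 * dt / 2)
  react <- function(u, v) {
    A2 <- (u^2 + v^2)^2
    lam <- 1 - A2
    om <- -beta * A2
    list(du = lam * u - om * v, dv = om * u + lam * v)
  }
  rk4_react <- function(u, v) {
    k1 <- react(u, v)
    k2_ <- react(u + dt / 2 * k1$du, v + dt / 2 * k1$dv)
    k3 <- react(u + dt / 2 * k2_$du, v + dt / 2 * k2_$dv)
    k4 <- react(u + dt * k3$du, v + dt * k3$dv)
    list(u = u + dt / 6 * (k1$du + 2 * k2_$du + 2 * k3$du + k4$du),
         v = v + dt / 6 * (k1$dv + 2 * k2_$dv + 2 * k3$dv + k4$dv))
  }
  diffuse <- function(a, E) Re(stats::fft(E * stats::fft(a), inverse = TRUE)) / (n * n)
  step_once <- function(u, v) {
    u <- diffuse(u, Eu); v <- diffuse(v, Ev)
    st <- rk4_react(u, v)
    list(u = diffuse(st$u, Eu), v = diffuse(st$v, Ev))
  }
  for (i in seq_len(round(spinup / dt))) {
    st <- step_once(u, v); u <- st$u; v <- st$v
  }
  n_steps <- round(t_end / dt)
  keep <- seq(0, n_steps, by = stride)
  U <- array(NA_real_, c(length(keep), n, n))
  V <- array(NA_real_, c(length(keep), n, n))
  ki <- 1L
  if (0 %in% keep) { U[ki, , ] <- u; V[ki, , ] <- v; ki <- ki + 1L }
  for (i in seq_len(n_steps)) {
    st <- step_once(u, v); u <- st$u; v <- st$v
    if (any(!is.finite(u)) || any(!is.finite(v)))
      stop("reaction-diffusion blow-up at step ", i,
           " (time step too large for the explicit reaction update)")
    if (i %in% keep) { U[ki, , ] <- u; V[ki, , ] <- v; ki <- ki + 1L }
  }
  field_series(list(u = U, v = V), dx = L / n, dt = dt * stride,
               boundary = "periodic")
}

#' Reference coefficient maps of the lambda-omega system
#'
#' Expanded ground truth over the monomial + Laplacian grammar used by
#' [default_rd_library()].
#' @param Du,Dv diffusivities used in the simulation.
#' @param beta reaction parameter.
#' @return list of named coefficient vectors (`u`, `v`).
#' @export
lambda_omega_reference <- function(Du = 0.1, Dv = 0.1, beta = 2) {
  # lambda(A) u - omega(A) v = u - A^2 u + beta A^2 v, A^2 = (u^2+v^2)^2
  list(u = c("lap_u" = Du, "u" = 1,
             "u^5" = -1, "u^3*v^2" = -2, "u*v^4" = -1,
             "u^4*v" = beta, "u^2*v^3" = 2 * beta, "v^5" = beta),
       v = c("lap_v" = Dv, "v" = 1,
             "u^4*v" = -1, "u^2*v^3" = -2, "v^5" = -1,
             "u^5" = -beta, "u^3*v^2" = -2 * beta, "u*v^4" = -beta))
}

#' Add proportional Gaussian noise
#'
#' Zero-mean Gaussian noise with per-coordinate standard deviation equal
#' to `fraction` times the standard deviation of that coordinate's
#' noise-free data.  Coordinates are columns for matrices/trajectories and
#' components for field series; a constant coordinate is left unchanged.
#'
#' @param data a matrix, array, [trajectory()] or [field_series()].
#' @param fraction noise level (e.g. `0.02` for 2 percent).
#' @param seed RNG seed; `NULL` continues the current stream.
#' @return same shape/class as the input.
#' @export
add_noise <- function(data, fraction, seed = NULL) {
  if (fraction < 0) stop("fraction must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  if (fraction == 0) return(data)
  noisy_mat <- function(m) {
    for (j in seq_len(ncol(m))) {
      s <- stats::sd(m[, j])
      if (s > 0) m[, j] <- m[, j] + stats::rnorm(nrow(m), 0, fraction * s)
    }
    m
  }
  if (inherits(data, "trajectory")) {
    data$values <- noisy_mat(data$values)
    return(data)
  }
  if (inherits(data, "field_series")) {
    data$fields <- lapply(data$fields, function(a) {
      s <- stats::sd(a)
      if (s > 0) a + array(stats::rnorm(length(a), 0, fraction * s), dim(a)) else a
    })
    return(data)
  }
  if (is.matrix(data)) return(noisy_mat(data))
  s <- stats::sd(data)
  if (s > 0) data + stats::rnorm(length(data), 0, fraction * s) else data
}

#' Denoise a field series
#'
#' Interchangeable pre-processing stage ahead of PDE inference.  Methods:
#' `"none"`; `"spectral_lowpass"` — per-snapshot 2-d Fourier box filter
#' keeping spatial modes with `|k| <= keep_frac * k_nyquist` on each axis;
#' `"gaussian_smooth"` — per-snapshot Fourier-domain Gaussian kernel of
#' width `sigma` (grid units).  Both filtering methods optionally smooth
#' along time with a Savitzky-Golay filter (`time_window` odd, 0 to
#' disable), which preserves low-order temporal structure without assuming
#' periodicity in time.  Method and parameters are recorded in the
#' `provenance` attribute.
#'
#' @param field a [field_series()].
#' @param method one of `"none"`, `"gaussian_smooth"`, `"spectral_lowpass"`.
#' @param keep_frac spatial cutoff as a fraction of Nyquist (lowpass;
#'   default 0.3, wide enough to retain the nonlinear harmonics of the
#'   benchmark patterns).
#' @param sigma Gaussian width in grid cells (gaussian_smooth).
#' @param time_window Savitzky-Golay window length (odd; default 21).
#'   The first and last `time_window` frames should be discarded before
#'   derivative-based fitting, as the endpoint filters distort them.
#' @param time_order Savitzky-Golay polynomial order (default 3).
#' @return filtered [field_series()].
#' @export
denoise <- function(field, method = c("none", "gaussian_smooth",
                                      "spectral_lowpass"),
                    keep_frac = 0.3, sigma = 2, time_window = 21L,
                    time_order = 3L) {
  method <- match.arg(method)
  if (method == "none") return(field)
  d <- dim(field$fields[[1]])
  n1 <- d[2]; n2 <- if (length(d) == 3) d[3] else 1L
  fr1 <- .fft_freq(n1); fr2 <- .fft_freq(n2)
  Hmask <- if (method == "spectral_lowpass") {
    outer(abs(fr1) <= keep_frac * 0.5, abs(fr2) <= keep_frac * 0.5, "&") * 1
  } else {
    outer(exp(-2 * (pi * sigma * fr1)^2), exp(-2 * (pi * sigma * fr2)^2))
  }
  out <- field
  out$fields <- lapply(field$fields, function(a) {
    for (i in seq_len(d[1])) {
      sl <- if (length(d) == 3) a[i, , ] else matrix(a[i, ], ncol = 1)
      f <- stats::fft(sl)
      sm <- Re(stats::fft(f * Hmask, inverse = TRUE)) / length(sl)
      if (length(d) == 3) a[i, , ] <- sm else a[i, ] <- sm
    }
    if (time_window >= 5 && d[1] > time_window) {
      flat <- matrix(a, nrow = d[1])
      flat <- apply(flat, 2L, function(col)
        signal::sgolayfilt(col, p = time_order, n = time_window))
      a <- array(flat, d)
    }
    a
  })
  attr(out, "provenance") <- list(method = method, keep_frac = keep_frac,
                                  sigma = sigma, time_window = time_window,
                                  time_order = time_order)
  out
}

#' Denoise a trajectory by Savitzky-Golay smoothing
#'
#' Local polynomial smoothing along time, applied per component.  Used as
#' a pre-processing stage ahead of finite-difference derivative estimation
#' when the trajectory carries additive measurement noise; the window must
#' stay well below the signal's characteristic timescale (in samples) to
#' avoid biasing the derivatives.
#'
#' @param traj a [trajectory()].
#' @param window filter window length (odd; default 41 samples).
#' @param order local polynomial order (default 3).
#' @return the smoothed [trajectory()].
#' @export
denoise_trajectory <- function(traj, window = 41L, order = 3L) {
  if (window %% 2 == 0) window <- window + 1L
  if (nrow(traj$values) <= window) stop("trajectory shorter than the window")
  traj$values <- apply(traj$values, 2L, function(v)
    signal::sgolayfilt(v, p = order, n = window))
  colnames(traj$values) <- traj$names
  traj
}

.fft_freq <- function(n) {
  if (n == 1) return(0)
  c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)[seq_len(n)] / n
}
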