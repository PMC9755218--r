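#' Per-sample drift and diffusion increment statistics
#'
#' From a trajectory sampled at step `s`, builds the finite-time
#' Kramers-Moyal estimator sequences
#' `F1_i = (X_{i+1} - X_i) / s` and `F2_i = (X_{i+1} - X_i)^2 / (2 s)`,
#' aligned with the positions `X_i` (the final sample is dropped).
#'
#' @param traj a [trajectory()] with at least 2 samples.
#' @return object of class `increment_stats`: matrices `F1`, `F2`
#'   (`(N-1) x M`), `positions`, `times`, `step`.
#' @export
increments <- function(traj) {
  X <- traj$values
  N <- nrow(X)
  if (N < 2) stop("need at least 2 samples")
  dX <- X[-1, , drop = FALSE] - X[-N, , drop = FALSE]
  structure(list(F1 = dX / traj$step,
                 F2 = dX^2 / (2 * traj$step),
                 positions = X[-N, , drop = FALSE],
                 times = times(traj)[-N],
                 step = traj$step,
                 names = traj$names),
            class = "increment_stats")
}

#' Bin-averaged increment statistics (one dimension)
#'
#' Groups a one-dimensional trajectory into `Q` equal-width bins spanning
#' the sampled range and averages positions and increment statistics per
#' bin.  Bin probabilities are occupation fractions (summing to 1 over all
#' bins); empty bins are masked out.
#'
#' @param stats an [increments()] result with `M = 1`.
#' @param Q number of bins (>= 2).
#' @return object of class `binned_stats`: `centers`, `F1_bar`, `F2_bar`,
#'   `probs`, `counts`, `mask` (retained-bin flags, initially the
#'   non-empty bins), `p_star` (NA until filtering is applied).
#' @export
bin_stats <- function(stats, Q) {
  if (ncol(stats$positions) != 1)
    stop("binning is defined for one-dimensional trajectories")
  if (Q < 2) stop("Q must be >= 2")
  x <- stats$positions[, 1]
  rng <- range(x)
  if (diff(rng) == 0) stop("degenerate position range (min = max)")
  breaks <- seq(rng[1], rng[2], length.out = Q + 1)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  idx[idx > Q] <- Q
  counts <- tabulate(idx, nbins = Q)
  sum_by <- function(v) {
    out <- numeric(Q)
    agg <- tapply(v, idx, sum)
    out[as.integer(names(agg))] <- agg
    out
  }
  nz <- counts > 0
  F1b <- sum_by(stats$F1[, 1]); F1b[nz] <- F1b[nz] / counts[nz]; F1b[!nz] <- NA
  F2b <- sum_by(stats$F2[, 1]); F2b[nz] <- F2b[nz] / counts[nz]; F2b[!nz] <- NA
  structure(list(centers = (breaks[-1] + breaks[-(Q + 1)]) / 2,
                 F1_bar = F1b, F2_bar = F2b,
                 probs = counts / length(x),
                 counts = counts,
                 mask = nz,
                 p_star = NA_real_,
                 Q = Q),
            class = "binned_stats")
}

#' @export
print.binned_stats <- function(x, ...) {
  cat(sprintf("<binned_stats> Q = %d bins, %d occupied%s\n", x$Q,
              sum(x$counts > 0),
              if (!is.na(x$p_star))
                sprintf(", p* = %.3g (%d retained)", x$p_star, sum(x$mask))
              else ""))
  invisible(x)
}

#' Entropy-maximizing probability threshold
#'
#' Two-step automatic threshold separating noise-dominated from
#' signal-dominated bins by their occupation probabilities.  Candidate
#' thresholds are midpoints between consecutive distinct probability
#' values.  Step 1 picks the candidate maximizing the summed Shannon
#' entropies of the below- and above-threshold classes (Kapur-style, each
#' class renormalized).  Step 2 refines it by maximizing the two-class
#' Tsallis criterion `S_q(A) + S_q(B) + (1 - q) S_q(A) S_q(B)` with
#' entropic index `q`, breaking ties toward the Shannon candidate.  Bins
#' with `p >= p*` are retained, so the most probable bin always survives.
#'
#' @param probs bin probabilities (normalized over all bins; zeros from
#'   empty bins are ignored).
#' @param q Tsallis index (`q > 0`, `q != 1`; default 0.8).
#' @return the probability threshold `p*`; with all-equal probabilities
#'   the convention `p* = min(probs)` (no filtering) is returned.
#' @export
entropy_threshold <- function(probs, q = 0.8) {
  if (q <= 0 || q == 1) stop("need q > 0 and q != 1")
  p <- probs[probs > 0]
  if (!length(p)) stop("no positive probabilities")
  lev <- sort(unique(p))
  if (length(lev) == 1) return(lev[1])
  cand <- (lev[-1] + lev[-length(lev)]) / 2
  shannon <- function(cls) {
    P <- sum(cls)
    w <- cls / P
    -sum(w * log(w))
  }
  tsallis <- function(cls) {
    P <- sum(cls)
    (1 - sum((cls / P)^q)) / (q - 1)
  }
  crit_sh <- vapply(cand, function(th)
    shannon(p[p < th]) + shannon(p[p >= th]), 0)
  th_sh <- cand[which.max(crit_sh)]
  crit_ts <- vapply(cand, function(th) {
    a <- tsallis(p[p < th]); b <- tsallis(p[p >= th])
    a + b + (1 - q) * a * b
  }, 0)
  best <- which(crit_ts >= max(crit_ts) - 1e-12)
  cand[best][which.min(abs(cand[best] - th_sh))]
}

#' Apply a probability filter to binned statistics
#'
#' @param bs a [bin_stats()] result.
#' @param p_star manual threshold; default determined by
#'   [entropy_threshold()].
#' @param q Tsallis index passed on.
#' @return the `binned_stats` with `mask` and `p_star` updated (bins with
#'   `p >= p*` retained).
#' @export
filter_bins <- function(bs, p_star = NULL, q = 0.8) {
  if (is.null(p_star)) p_star <- entropy_threshold(bs$probs, q)
  bs$p_star <- p_star
  bs$mask <- bs$counts > 0 & bs$probs >= p_star
  if (!any(bs$mask)) stop("probability filter removed every bin; ",
                          "use fewer bins or disable filtering")
  bs
}

#' Identify a Langevin SDE from a trajectory
#'
#' Estimates analytic drift and diffusion coefficients by two [atsbl()]
#' solves sharing one candidate library: targets are the increment
#' statistics `F1` and `F2` evaluated either per sample (`mode =
#' "direct"`) or bin-averaged over `Q` bins with optional entropy-based
#' probability filtering (`mode = "binned"`, one-dimensional
#' trajectories).
#'
#' @param traj a [trajectory()].
#' @param drift_spec library for the drift ([default_drift_library()] if
#'   missing).
#' @param diff_spec library for the diffusion
#'   ([default_diffusion_library()] if missing).
#' @param mode `"direct"` or `"binned"`.
#' @param Q number of bins (binned mode; default 200).
#' @param filter apply the probability filter (binned mode; default TRUE).
#' @param prior `"laplace"` or `"gaussian"`, passed to [atsbl()].
#' @param seed seed for the train/test splits.
#' @param p_star manual probability threshold overriding the entropy
#'   heuristic.
#' @param tsallis_q Tsallis index for the filter.
#' @param diffusion_correction use the drift-corrected second conditional
#'   moment `(dX - D1_hat s)^2 / (2s)` as the diffusion target (default
#'   TRUE).  The raw estimator `F2` carries a finite-step contribution
#'   `(s/2) D1(x)^2` from the drift which is systematic structure in
#'   held-out error and pollutes the identified diffusion support;
#'   subtracting the fitted drift removes it at leading order.  Set FALSE
#'   for the uncorrected estimator.
#' @param ... further arguments to [atsbl()].
#' @return object of class `km_fit`: `drift` and `diffusion` [atsbl()]
#'   fits, the coefficient maps `drift_coefs` / `diff_coefs`, the mode and
#'   binned statistics when applicable.
#' @export
fit_km <- function(traj, drift_spec = NULL, diff_spec = NULL,
                   mode = c("direct", "binned"), Q = 200L, filter = TRUE,
                   prior = "laplace", seed = 1L, p_star = NULL,
                   tsallis_q = 0.8, diffusion_correction = TRUE, ...) {
  mode <- match.arg(mode)
  M <- ncol(traj$values)
  if (is.null(drift_spec)) drift_spec <- default_drift_library(traj$names[1])
  if (is.null(diff_spec)) diff_spec <- default_diffusion_library(traj$names[1])
  st <- increments(traj)
  s <- st$step
  bs <- NULL
  need_full <- mode == "direct" || diffusion_correction
  Theta_d_full <- NULL
  if (need_full) {
    data_full <- as.list(as.data.frame(st$positions))
    names(data_full) <- st$names
    data_full$t <- st$times
    Theta_d_full <- evaluate_library(drift_spec, data_full)
  }

  fits_d <- list(); fits_h <- list()
  if (mode == "direct") {
    Theta_h <- evaluate_library(diff_spec, data_full)
    for (l in seq_len(M)) {
      fits_d[[l]] <- atsbl(linear_system(Theta_d_full, st$F1[, l],
                                         column_names = drift_spec$terms),
                           prior = prior, seed = seed, ...)
      f2 <- st$F2[, l]
      if (diffusion_correction) {
        g_hat <- drop(Theta_d_full %*% coef(fits_d[[l]]))
        f2 <- f2 - s * g_hat * st$F1[, l] + s * g_hat^2 / 2
      }
      fits_h[[l]] <- atsbl(linear_system(Theta_h, f2,
                                         column_names = diff_spec$terms),
                           prior = prior, seed = seed, ...)
    }
  } else {
    if (M != 1) stop("binned mode requires a one-dimensional trajectory")
    bs <- bin_stats(st, Q)
    if (filter) bs <- filter_bins(bs, p_star = p_star, q = tsallis_q)
    keep <- bs$mask
    data <- stats::setNames(list(bs$centers[keep]), st$names[1])
    Theta_d <- evaluate_library(drift_spec, data)
    Theta_h <- evaluate_library(diff_spec, data)
    if (nrow(Theta_d) < 2) stop("too few retained bins for regression; ",
                                "use fewer bins or disable filtering")
    fits_d[[1]] <- atsbl(linear_system(Theta_d, bs$F1_bar[keep],
                                       column_names = drift_spec$terms),
                         prior = prior, seed = seed, ...)
    f2b <- bs$F2_bar[keep]
    if (diffusion_correction) {
      # correct per sample with the fitted drift, then re-bin
      g_hat <- drop(Theta_d_full %*% coef(fits_d[[1]]))
      f2adj <- st$F2[, 1] - s * g_hat * st$F1[, 1] + s * g_hat^2 / 2
      st2 <- st; st2$F2[, 1] <- f2adj
      bs2 <- bin_stats(st2, Q)
      f2b <- bs2$F2_bar[keep]
    }
    fits_h[[1]] <- atsbl(linear_system(Theta_h, f2b,
                                       column_names = diff_spec$terms),
                         prior = prior, seed = seed, ...)
  }
  drift_coefs <- lapply(fits_d, function(f) { cf <- coef(f); cf[cf != 0] })
  diff_coefs <- lapply(fits_h, function(f) { cf <- coef(f); cf[cf != 0] })
  structure(list(drift = if (M == 1) fits_d[[1]] else fits_d,
                 diffusion = if (M == 1) fits_h[[1]] else fits_h,
                 drift_coefs = if (M == 1) drift_coefs[[1]] else drift_coefs,
                 diff_coefs = if (M == 1) diff_coefs[[1]] else diff_coefs,
                 drift_spec = drift_spec, diff_spec = diff_spec,
                 mode = mode, binned = bs, vars = traj$names,
                 step = traj$step, seed = seed,
                 call = match.call()),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Kramers-Moyal fit (%s mode)\n", x$mode))
  M <- length(x$vars)
  dc <- if (M == 1) list(x$drift_coefs) else x$drift_coefs
  hc <- if (M == 1) list(x$diff_coefs) else x$diff_coefs
  for (l in seq_len(M)) {
    cat(" ", format_equation(dc[[l]], sprintf("D1_%s", x$vars[l]),
                             digits = digits), "\n")
    cat(" ", format_equation(hc[[l]], sprintf("D2_%s", x$vars[l]),
                             digits = digits), "\n")
  }
  if (!is.null(x$binned) && !is.na(x$binned$p_star))
    cat(sprintf("  probability filter: p* = %.3g, %d/%d bins retained\n",
                x$binned$p_star, sum(x$binned$mask), x$binned$Q))
  invisible(x)
}

#' @export
coef.km_fit <- function(object, ...)
  list(drift = object$drift_coefs, diffusion = object$diff_coefs)

#' Turn a Kramers-Moyal fit into a simulatable model
#'
#' @param object a `km_fit` (one-dimensional or multivariate with
#'   list-valued coefficient maps).
#' @return an [sde_model()] built from the identified coefficients.
#' @export
as_sde_model <- function(object) {
  M <- length(object$vars)
  dc <- if (M == 1) list(object$drift_coefs) else object$drift_coefs
  hc <- if (M == 1) list(object$diff_coefs) else object$diff_coefs
  sde_model(dc, hc, vars = object$vars,
            omega = object$drift_spec$omega %||% 0)
}

#' Simulate from an identified model
#'
#' @param object a `km_fit`.
#' @param nsim number of steps.
#' @param seed RNG seed.
#' @param x0 initial state.
#' @param dt time step (defaults to the fitted trajectory's step).
#' @param ... unused.
#' @return a [trajectory()].
#' @export
simulate.km_fit <- function(object, nsim = 1000L, seed = NULL,
                            x0 = NULL, dt = NULL, ...) {
  model <- as_sde_model(object)
  if (is.null(x0)) x0 <- numeric(length(object$vars))
  euler_maruyama(model, x0, dt %||% object$step, nsim, seed = seed)
}

#' Plot identified drift and diffusion against increment statistics
#'
#' One-dimensional fits only: scatters the per-sample estimators `F1`,
#' `F2` of a trajectory against position and overlays the identified
#' analytic drift and diffusion curves.
#'
#' @param x a `km_fit`.
#' @param traj the trajectory the fit was computed from.
#' @param n_points maximum number of scatter points drawn.
#' @param ... passed to `plot`.
#' @export
plot.km_fit <- function(x, traj, n_points = 5000L, ...) {
  if (length(x$vars) != 1) stop("plotting is implemented for 1-d fits")
  st <- increments(traj)
  idx <- if (nrow(st$positions) > n_points)
    seq(1, nrow(st$positions), length.out = n_points) else seq_len(nrow(st$positions))
  xs <- seq(min(st$positions), max(st$positions), length.out = 200)
  model <- as_sde_model(x)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(st$positions[idx, 1], st$F1[idx, 1], pch = ".",
                 col = "grey50", xlab = x$vars, ylab = "F1 (drift)", ...)
  graphics::lines(xs, eval_model(model, xs), col = "red3", lwd = 2)
  graphics::plot(st$positions[idx, 1], st$F2[idx, 1], pch = ".",
                 col = "grey50", xlab = x$vars, ylab = "F2 (diffusion)", ...)
  graphics::lines(xs, eval_model(model, xs, what = "diffusion"),
                  col = "red3", lwd = 2)
  invisible(x)
}

#' DIC of a Kramers-Moyal fit against a reference model
#'
#' Average of the drift and diffusion [dic()] values (per component, then
#' averaged).
#'
#' @param fit a `km_fit` (or a list with `drift_coefs` / `diff_coefs`).
#' @param model the reference [sde_model()].
#' @return scalar mean DIC.
#' @export
km_dic <- function(fit, model) {
  M <- length(model$vars)
  dc <- if (M == 1) list(fit$drift_coefs) else fit$drift_coefs
  hc <- if (M == 1) list(fit$diff_coefs) else fit$diff_coefs
  vals <- c(vapply(seq_len(M), function(l) dic(dc[[l]], model$drift[[l]]), 0),
            vapply(seq_len(M), function(l) dic(hc[[l]], model$diffusion[[l]]), 0))
  mean(vals)
}
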