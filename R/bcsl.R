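#' Linear inverse system container
#'
#' Bundles a design matrix of candidate functions with a target vector for
#' the generic sparse linear problem g = Phi w + s, where s is i.i.d.
#' Gaussian residual noise with precision beta (never materialized).
#'
#' @param design numeric matrix, N x K, all entries finite.
#' @param target numeric vector of length N.
#' @param column_names optional character vector of K term labels.
#' @param column_scales optional positive scale factors already applied to
#'   the columns (bookkeeping only; solvers always report coefficients on the
#'   original column scale).
#' @param kappa optional 2-norm condition number of the column-normalized
#'   design; computed on demand by [atsbl()] when missing.
#' @return an object of class `linear_system`.
#' @export
linear_system <- function(design, target, column_names = NULL,
                          column_scales = NULL, kappa = NULL) {
  design <- as.matrix(design)
  target <- as.numeric(target)
  if (nrow(design) < 1L || ncol(design) < 1L)
    stop("design must have at least one row and one column")
  if (nrow(design) != length(target))
    stop("design and target dimensions disagree")
  if (!all(is.finite(design)))
    stop("design contains non-finite entries")
  if (!all(is.finite(target)))
    stop("target contains non-finite entries")
  if (is.null(column_names))
    column_names <- colnames(design) %||% paste0("c", seq_len(ncol(design)))
  if (is.null(column_scales)) column_scales <- rep(1, ncol(design))
  if (any(column_scales <= 0)) stop("column_scales must be positive")
  colnames(design) <- column_names
  structure(list(design = design, target = target,
                 column_names = column_names,
                 column_scales = as.numeric(column_scales),
                 kappa = kappa),
            class = "linear_system")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.linear_system <- function(x, ...) {
  cat(sprintf("<linear_system> %d rows x %d terms\n",
              nrow(x$design), ncol(x$design)))
  cat("terms:", paste(utils::head(x$column_names, 8), collapse = ", "),
      if (length(x$column_names) > 8) "..." else "", "\n")
  invisible(x)
}

# Sufficient statistics on unit-norm columns.  All solver arithmetic runs on
# these so the cost of a fit is independent of N after one pass over the data.
.gram_stats <- function(system) {
  X <- system$design
  norms <- sqrt(colSums(X^2))
  norms[norms == 0] <- 1       # all-zero column: leave as-is, never selected
  Xn <- sweep(X, 2L, norms, "/")
  list(GtG = crossprod(Xn), Gty = drop(crossprod(Xn, system$target)),
       yty = sum(system$target^2), sum_y = sum(system$target),
       N = nrow(X), K = ncol(X), norms = norms)
}

.default_bcsl_options <- function() {
  list(max_iter = 1000L, tol = 1e-8, beta_init = NULL, beta_max_scale = 1e12,
       n_starts = 64L)
}

#' Sparse Bayesian fit with a hierarchical Laplace prior
#'
#' Solves g = Phi w + s by fast sequential evidence maximization.  The model
#' is a three-stage hierarchy: Gaussian likelihood with noise precision
#' `beta`, per-weight Gaussian prior with variances `gamma`, and an
#' exponential hyperprior with rate `lam/2` on each gamma, so that the
#' marginal prior on the weights is a Laplace distribution.  One basis
#' column is added, re-estimated, or deleted per step, choosing the move
#' that most increases the log evidence; `lam` and `beta` are re-estimated
#' from their stationary conditions after each move.  Because correlated
#' libraries give the evidence many local maxima, the maximization is
#' restarted from the empty model, from a dense ridge-seeded model that is
#' pruned down, and from single-column seeds, keeping the best converged
#' state.  Columns are normalized to unit 2-norm internally and results
#' are reported on the original scale.  The fit is deterministic.
#'
#' @param system a [linear_system()].
#' @param options list overriding any of `max_iter` (default 1000), `tol`
#'   (convergence tolerance on the log-evidence change, default 1e-8),
#'   `beta_init` (default `100 / var(g)`), `beta_max_scale` (cap on
#'   `beta * var(g)`, default 1e12, reached only on noise-free data),
#'   `n_starts` (maximum number of single-column restart seeds, default
#'   64; the most target-correlated columns are used for larger
#'   libraries).
#' @return an object of class `sbl_fit`: coefficients (original scale, zeros
#'   off the support), `support`, `prior`, `beta`, `gamma`, `lam`,
#'   `posterior_cov` (active set, original scale), `uncertainty`
#'   (per-weight posterior sd), `log_evidence`.
#' @seealso [ridge_fit()], [log_evidence()], [atsbl()]
#' @export
bcsl_fit <- function(system, options = list()) {
  opt <- utils::modifyList(.default_bcsl_options(), options)
  st <- .gram_stats(system)
  fit <- .bcsl_gram(st, opt)
  .finish_sbl(fit, st, system, prior = "laplace")
}

# Core sequential solver on Gram statistics.  The marginal likelihood of
# strongly correlated libraries has many local optima, so evidence
# maximization is restarted from a family of deterministic
# initializations -- the empty model, a dense ridge-seeded model that is
# pruned, and each single-column seed -- and the converged state with the
# highest evidence is returned.  The whole procedure is deterministic.
.bcsl_gram <- function(st, opt) {
  K <- st$K
  w_r <- tryCatch(drop(solve(st$GtG + diag(1e-4, K), st$Gty)),
                  error = function(e) rep(0, K))
  starts <- c(list(numeric(K), pmax(w_r^2, 1e-6 * max(w_r^2, 1))),
              lapply(.start_columns(st, opt), function(j) {
                g <- numeric(K); g[j] <- max(st$yty, 1); g
              }))
  best <- NULL
  for (g0 in starts) {
    run <- .bcsl_run(st, opt, g0)
    if (is.null(best) || run$log_evidence > best$log_evidence) best <- run
  }
  best
}

# single-column seeds: all columns for small libraries, otherwise the
# columns most correlated with the target
.start_columns <- function(st, opt) {
  K <- st$K
  n_seed <- opt$n_starts %||% 64L
  if (K <= n_seed) seq_len(K)
  else order(abs(st$Gty), decreasing = TRUE)[seq_len(n_seed)]
}

.bcsl_run <- function(st, opt, gamma_init) {
  GtG <- st$GtG; Gty <- st$Gty; yty <- st$yty; N <- st$N; K <- st$K
  var_g <- yty / N - (st$sum_y / N)^2
  if (!is.finite(var_g) || var_g <= 0) var_g <- max(yty / N, 1)
  beta <- opt$beta_init %||% (100 / var_g)
  beta_max <- opt$beta_max_scale / var_g
  lam <- 0
  gamma <- gamma_init
  active <- which(gamma > 0)
  Sigma <- matrix(0, 0, 0)
  w <- numeric(0)

  refresh <- function() {
    # posterior over active set and the (S, Q) statistics for all columns
    if (length(active)) {
      H <- beta * GtG[active, active, drop = FALSE] +
        diag(1 / gamma[active], length(active))
      Sig <- tryCatch(chol2inv(chol(H)), error = function(e) {
        stop("singular restricted normal matrix for columns {",
             paste(active, collapse = ","), "}: ", conditionMessage(e))
      })
      ww <- beta * drop(Sig %*% Gty[active])
      B <- GtG[, active, drop = FALSE] %*% Sig
      S <- beta * diag(GtG) - beta^2 * rowSums(B * GtG[, active, drop = FALSE])
      Q <- beta * Gty - beta^2 * drop(B %*% Gty[active])
    } else {
      Sig <- matrix(0, 0, 0); ww <- numeric(0)
      S <- beta * diag(GtG); Q <- beta * Gty
    }
    list(Sigma = Sig, w = ww, S = S, Q = Q)
  }

  gauss_ev <- function() {
    if (length(active)) {
      H <- beta * GtG[active, active, drop = FALSE] +
        diag(1 / gamma[active], length(active))
      R <- chol(H)
      wA <- beta * drop(chol2inv(R) %*% Gty[active])
      0.5 * (N * log(beta) - N * log(2 * pi) -
               sum(log(gamma[active])) - 2 * sum(log(diag(R))) -
               beta * max(yty - sum(Gty[active] * wA), 0))
    } else {
      0.5 * (N * log(beta) - N * log(2 * pi) - beta * yty)
    }
  }
  evidence <- function() {
    e <- gauss_ev()
    if (lam > 0 && length(active))
      e <- e + sum(log(lam / 2) - lam * gamma[active] / 2) - log(lam)
    e
  }

  ev_old <- -Inf
  for (iter in seq_len(opt$max_iter)) {
    rf <- refresh()
    S <- rf$S; Q <- rf$Q
    denom <- 1 - gamma * S
    denom[denom < 1e-12] <- 1e-12
    s_ <- ifelse(gamma > 0, S / denom, S)
    q_ <- ifelse(gamma > 0, Q / denom, Q)
    # s is a variance-like quantity; clamp roundoff negatives
    s_[!is.finite(s_) | s_ < 1e-300] <- 1e-300
    q_[!is.finite(q_)] <- 0

    occ <- if (lam > 0) log(lam / 2) else 0
    # vectorized scan over all candidate single-column moves
    gn <- if (lam <= 0) {
      ifelse(q_^2 > s_, (q_^2 - s_) / s_^2, 0)
    } else {
      u <- (-s_ + sqrt(s_^2 + 4 * lam * q_^2)) / (2 * lam)
      ifelse(u > 1, (u - 1) / s_, 0)
    }
    ell_v <- function(g) 0.5 * (q_^2 * g / (1 + g * s_) - log1p(g * s_)) -
      lam * g / 2
    delta <- ell_v(gn) - ell_v(gamma) + occ * ((gn > 0) - (gamma > 0))
    delta[(gn <= 0 & gamma <= 0) | !is.finite(delta)] <- 0
    i_best <- which.max(delta)
    best <- if (length(i_best) && delta[i_best] > 1e-15)
      list(delta = delta[i_best], i = i_best, gnew = gn[i_best])
    else list(delta = 0, i = 0L, gnew = 0)
    if (best$i > 0L) {
      gamma[best$i] <- best$gnew
      active <- which(gamma > 0)
    }

    # hyperparameter re-estimation at the current support
    L <- length(active)
    lam <- if (L > 1 && sum(gamma[active]) > 0) 2 * (L - 1) / sum(gamma[active]) else 0
    rf <- refresh()
    if (L > 0) {
      w <- rf$w
      resid <- yty - 2 * sum(Gty[active] * w) +
        drop(t(w) %*% GtG[active, active, drop = FALSE] %*% w)
      resid <- max(resid, 0)
      dof <- sum(1 - diag(rf$Sigma) / gamma[active])
      beta_new <- if (resid > 0) (N - dof) / resid else beta_max
      if (!is.finite(beta_new) || beta_new <= 0) beta_new <- beta
      beta <- min(beta_new, beta_max)
    }
    ev <- evidence()
    if (!is.finite(ev)) stop("non-finite evidence at iteration ", iter)
    if (best$i == 0L || abs(ev - ev_old) < opt$tol) { ev_old <- ev; break }
    ev_old <- ev
  }

  rf <- refresh()
  list(gamma = gamma, lam = lam, beta = beta, active = which(gamma > 0),
       w_active = rf$w, Sigma = rf$Sigma, log_evidence = ev_old,
       iterations = iter)
}

# Map a Gram-space solution back to the original column scale.
.finish_sbl <- function(fit, st, system, prior, note = NULL) {
  K <- st$K
  weights <- numeric(K)
  unc <- numeric(K)
  Sig_orig <- NULL
  if (length(fit$active)) {
    sc <- st$norms[fit$active]
    weights[fit$active] <- fit$w_active / sc
    if (!is.null(fit$Sigma) && length(fit$Sigma)) {
      Sig_orig <- sweep(sweep(fit$Sigma, 1L, sc, "/"), 2L, sc, "/")
      unc[fit$active] <- sqrt(pmax(diag(Sig_orig), 0))
    }
  }
  names(weights) <- system$column_names
  names(unc) <- system$column_names
  structure(list(coefficients = weights,
                 support = fit$active,
                 prior = prior,
                 beta = fit$beta,
                 gamma = fit$gamma,
                 lam = fit$lam,
                 posterior_cov = Sig_orig,
                 uncertainty = unc,
                 log_evidence = fit$log_evidence,
                 iterations = fit$iterations,
                 column_names = system$column_names,
                 note = note),
            class = "sbl_fit")
}

#' Ridge (Gaussian-prior) fit
#'
#' Fixed-regularization ridge regression on unit-norm columns,
#' `w = (Phi'Phi + alpha I)^-1 Phi' g`, reported on the original column
#' scale.  With `alpha = 0` and a rank-deficient design, the minimum-norm
#' least-squares solution is returned and flagged in `note`.
#'
#' @param system a [linear_system()].
#' @param alpha non-negative regularization parameter (normalized scale).
#' @return an `sbl_fit` with `prior = "gaussian"`; `gamma` and `lam` unset.
#' @export
ridge_fit <- function(system, alpha = 1e-5) {
  if (alpha < 0) stop("alpha must be non-negative")
  st <- .gram_stats(system)
  K <- st$K
  note <- NULL
  A <- st$GtG + diag(alpha, K)
  ok <- TRUE
  w_n <- tryCatch(drop(solve(A, st$Gty)), error = function(e) { ok <<- FALSE; NULL })
  if (!ok || anyNA(w_n)) {
    # rank-deficient with alpha = 0: minimum-norm solution via pseudoinverse
    e <- eigen(st$GtG, symmetric = TRUE)
    pos <- e$values > max(e$values) * 1e-12
    w_n <- drop(e$vectors[, pos, drop = FALSE] %*%
                  ((crossprod(e$vectors[, pos, drop = FALSE], st$Gty)) / e$values[pos]))
    note <- "rank-deficient design; minimum-norm solution"
  }
  resid <- max(st$yty - 2 * sum(st$Gty * w_n) +
                 drop(t(w_n) %*% st$GtG %*% w_n), 0)
  beta <- st$N / max(resid, .Machine$double.eps * st$yty + .Machine$double.xmin)
  Sig <- tryCatch(chol2inv(chol(A)) / beta, error = function(e) NULL)
  fit <- list(gamma = rep(NA_real_, K), lam = NA_real_, beta = beta,
              active = which(w_n != 0), w_active = w_n[w_n != 0],
              Sigma = if (!is.null(Sig)) Sig[w_n != 0, w_n != 0, drop = FALSE],
              log_evidence = NA_real_, iterations = 1L)
  .finish_sbl(fit, st, system, prior = "gaussian", note = note)
}

#' Log type-II marginal likelihood of the Laplace hierarchy
#'
#' Evidence of the data with the weights integrated out, at hyperparameters
#' `(gamma, lam, beta)`:
#' the Gaussian marginal `log N(g; 0, I/beta + Phi_A diag(gamma_A) Phi_A')`
#' over the active set `A = {i: gamma_i > 0}`, plus the exponential
#' hyperprior terms `sum_A [log(lam/2) - lam gamma_i / 2]` and a Jeffreys
#' hyperprior `-log lam` on the rate.  `lam = 0` is the flat-prior
#' convention: only the Gaussian marginal is returned.  Hyperparameters are
#' interpreted on the unit-column-norm scale used internally by
#' [bcsl_fit()]; this function is the slow, explicit counterpart of the
#' quantity that solver maximizes.
#'
#' @param system a [linear_system()].
#' @param gamma non-negative per-weight prior variances, length K.
#' @param lam Laplace rate hyperparameter, `>= 0`.
#' @param beta residual precision, `> 0`.
#' @return scalar log evidence.
#' @export
log_evidence <- function(system, gamma, lam, beta) {
  if (beta <= 0) stop("beta must be positive")
  if (lam < 0) stop("lam must be non-negative")
  if (any(gamma < 0)) stop("gamma must be non-negative")
  st <- .gram_stats(system)
  if (length(gamma) != st$K) stop("gamma has wrong length")
  active <- which(gamma > 0)
  N <- st$N
  if (length(active)) {
    H <- beta * st$GtG[active, active, drop = FALSE] +
      diag(1 / gamma[active], length(active))
    R <- tryCatch(chol(H), error = function(e)
      stop("non-positive-definite posterior; reciprocal condition estimate ",
           format(rcond(H))))
    wA <- beta * drop(chol2inv(R) %*% st$Gty[active])
    ev <- 0.5 * (N * log(beta) - N * log(2 * pi) -
                   sum(log(gamma[active])) - 2 * sum(log(diag(R))) -
                   beta * max(st$yty - sum(st$Gty[active] * wA), 0))
  } else {
    ev <- 0.5 * (N * log(beta) - N * log(2 * pi) - beta * st$yty)
  }
  if (lam > 0 && length(active))
    ev <- ev + sum(log(lam / 2) - lam * gamma[active] / 2) - log(lam)
  ev
}

#' @export
print.sbl_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<sbl_fit> prior = %s, %d/%d active terms\n",
              x$prior, length(x$support), length(x$coefficients)))
  if (length(x$support)) {
    cf <- x$coefficients[x$support]
    sd <- x$uncertainty[x$support]
    for (i in seq_along(cf))
      cat(sprintf("  %-14s %s (sd %s)\n", names(cf)[i],
                  format(cf[i], digits = digits), format(sd[i], digits = 2)))
  } else cat("  (null model)\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @export
coef.sbl_fit <- function(object, ...) object$coefficients
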