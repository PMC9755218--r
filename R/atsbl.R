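#' Hard thresholding of a coefficient vector
#'
#' Entries with absolute value below `tol` are set to zero; others are
#' unchanged.
#'
#' @param weights numeric vector.
#' @param tol threshold, `>= 0`.
#' @return thresholded vector.
#' @export
hard_threshold <- function(weights, tol) {
  if (tol < 0) stop("tol must be non-negative")
  weights[abs(weights) < tol] <- 0
  weights
}

#' Penalized test error of a candidate sparse model
#'
#' `e = || Theta_test w - g_test ||_2^2 + eta * ||w||_0`, with the zero-norm
#' counting nonzero entries.
#'
#' @param weights coefficient vector.
#' @param test_design held-out design matrix.
#' @param test_target held-out target vector.
#' @param eta sparsity penalty factor.
#' @return scalar error.
#' @export
model_error <- function(weights, test_design, test_target, eta) {
  r <- test_target - drop(test_design %*% weights)
  sum(r^2) + eta * sum(weights != 0)
}

# Same quantity from Gram statistics (O(K^2), independent of test size).
.model_error_gram <- function(w_n, G, b, yty, eta) {
  sse <- yty - 2 * sum(w_n * b) + drop(t(w_n) %*% G %*% w_n)
  max(sse, 0) + eta * sum(w_n != 0)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Automatic-threshold sparse Bayesian learning
#'
#' The package's main solver.  The rows of the system are split into a
#' training and a test part; a prior-based fit (Laplace via [bcsl_fit()] or
#' Gaussian via [ridge_fit()]) on the training rows gives an initial dense
#' estimate, which is then hard-thresholded at an adaptively tuned cutoff
#' `tol`, refitted by least squares on the surviving support, and scored on
#' the test rows with [model_error()] using the penalty
#' `eta = 1e-3 * kappa(Theta)`.  On improvement the threshold is increased;
#' otherwise it is decreased and the increment `d_tol` is refined.  The
#' returned model minimizes the penalized test error over all iterations.
#'
#' @param system a [linear_system()], or a design matrix (then `target`
#'   must be given).
#' @param target target vector when `system` is a bare matrix.
#' @param prior `"laplace"` (default) or `"gaussian"`.
#' @param n_iters maximum thresholding iterations (default 100).
#' @param d_tol initial threshold increment; default `max|w0| / n_iters`
#'   from the initial unthresholded fit.
#' @param split fraction of rows used for training (default 0.8).
#' @param split_type `"random"` (default) or `"contiguous"` (first block
#'   trains; useful for strongly time-correlated rows).
#' @param seed integer seed for the random row split (stored; the fit is
#'   bit-reproducible given identical inputs and seed).
#' @param alpha ridge regularization when `prior = "gaussian"`.
#' @param eta sparsity penalty; default `1e-3 * kappa` of the
#'   column-normalized design.
#' @param options options passed to [bcsl_fit()].
#' @return an object of class `atsbl` with components `coefficients`
#'   (original scale, named), `support`, `uncertainty`, `e` (best penalized
#'   test error), `error_trace`, `tol_trace`, `eta`, `kappa`, `prior`,
#'   `seed`, and the initial dense fit `init_fit`.
#' @examples
#' x <- seq(-1, 1, length.out = 200)
#' X <- cbind(1, x, x^2, x^3, x^4)
#' colnames(X) <- c("1", "x", "x^2", "x^3", "x^4")
#' fit <- atsbl(X, 2 * x^3 - x, seed = 1)
#' coef(fit)
#' @export
atsbl <- function(system, target = NULL,
                  prior = c("laplace", "gaussian"),
                  n_iters = 100L, d_tol = NULL,
                  split = 0.8, split_type = c("random", "contiguous"),
                  seed = 1L, alpha = 1e-5, eta = NULL, options = list()) {
  prior <- match.arg(prior)
  split_type <- match.arg(split_type)
  if (!inherits(system, "linear_system"))
    system <- linear_system(system, target)
  X <- system$design
  y <- system$target
  N <- nrow(X); K <- ncol(X)
  if (n_iters < 1) stop("n_iters must be >= 1")

  norms <- sqrt(colSums(X^2)); norms[norms == 0] <- 1
  Xn <- sweep(X, 2L, norms, "/")

  n_tr <- max(1L, min(N - 1L, round(split * N)))
  idx_tr <- if (split_type == "random")
    .with_seed(seed, sort(sample.int(N, n_tr))) else seq_len(n_tr)
  idx_te <- setdiff(seq_len(N), idx_tr)

  G_tr <- crossprod(Xn[idx_tr, , drop = FALSE])
  b_tr <- drop(crossprod(Xn[idx_tr, , drop = FALSE], y[idx_tr]))
  yty_tr <- sum(y[idx_tr]^2)
  G_te <- crossprod(Xn[idx_te, , drop = FALSE])
  b_te <- drop(crossprod(Xn[idx_te, , drop = FALSE], y[idx_te]))
  yty_te <- sum(y[idx_te]^2)

  G_full <- G_tr + G_te
  kappa <- system$kappa %||% .kappa_gram(G_full)
  if (is.null(eta)) eta <- 1e-3 * kappa

  zero_col <- colSums(X != 0) == 0
  ols_train <- function(s) {
    # least squares on the surviving support (removes shrinkage bias)
    w_n <- numeric(K)
    s <- s[!zero_col[s]]
    if (!length(s)) return(w_n)
    sol <- tryCatch(solve(G_tr[s, s, drop = FALSE], b_tr[s]),
                    error = function(e) NULL)
    if (is.null(sol)) {
      e <- eigen(G_tr[s, s, drop = FALSE], symmetric = TRUE)
      pos <- e$values > max(e$values, 0) * 1e-12
      if (!any(pos)) return(w_n)
      sol <- drop(e$vectors[, pos, drop = FALSE] %*%
                    (crossprod(e$vectors[, pos, drop = FALSE], b_tr[s]) / e$values[pos]))
    }
    w_n[s] <- sol
    w_n
  }

  # initial dense fit on the training rows
  opt <- utils::modifyList(.default_bcsl_options(), options)
  st_tr <- list(GtG = G_tr, Gty = b_tr, yty = yty_tr, sum_y = sum(y[idx_tr]),
                N = n_tr, K = K, norms = norms)
  init <- if (prior == "laplace") {
    .finish_sbl(.bcsl_gram(st_tr, opt), st_tr, system, prior = "laplace")
  } else {
    w_n <- tryCatch(drop(solve(G_tr + diag(alpha, K), b_tr)),
                    error = function(e) numeric(K))
    cf <- w_n / norms; names(cf) <- system$column_names
    structure(list(coefficients = cf, support = which(cf != 0),
                   prior = "gaussian", column_names = system$column_names),
              class = "sbl_fit")
  }
  w0 <- unname(init$coefficients)           # original scale

  refit_at <- function(tol) {
    # STRidge-style inner loop: threshold, refit on the survivors, repeat
    # until the support is stable
    w <- w0
    s_prev <- integer(0)
    for (r in 1:10) {
      s <- which(hard_threshold(w, tol) != 0)
      if (!length(s)) return(numeric(K))
      if (identical(s, s_prev)) break
      w <- ols_train(s) / norms
      s_prev <- s
    }
    w
  }
  err_of <- function(w) .model_error_gram(w * norms, G_te, b_te, yty_te, eta)

  # the null model is always a valid candidate (e = ||g_test||^2)
  best_w <- numeric(K)
  best_e <- err_of(best_w)
  e_w0 <- err_of(w0)
  if (e_w0 <= best_e) { best_w <- w0; best_e <- e_w0 }
  if (is.null(d_tol)) d_tol <- if (max(abs(w0)) > 0) max(abs(w0)) / n_iters else 1
  d_tol0 <- d_tol
  tol <- d_tol
  e_trace <- numeric(n_iters)
  tol_trace <- numeric(n_iters)
  for (it in seq_len(n_iters)) {
    w <- refit_at(tol)
    e <- err_of(w)
    e_trace[it] <- e
    tol_trace[it] <- tol
    if (e <= best_e) {
      best_e <- e; best_w <- w
      tol <- tol + d_tol
    } else {
      tol <- max(0, tol - 2 * d_tol)
      d_tol <- 2 * d_tol / max(1L, n_iters - it)
      tol <- tol + d_tol
    }
  }

  best_w <- unname(best_w)
  support <- which(best_w != 0)
  # posterior uncertainty from a support-restricted fit on all rows
  unc <- setNames(numeric(K), system$column_names)
  restricted <- NULL
  if (length(support)) {
    st_s <- list(GtG = G_full[support, support, drop = FALSE],
                 Gty = b_tr[support] + b_te[support],
                 yty = yty_tr + yty_te, sum_y = sum(y), N = N,
                 K = length(support), norms = norms[support])
    sys_s <- list(column_names = system$column_names[support])
    restricted <- .finish_sbl(.bcsl_gram(st_s, opt), st_s, sys_s, prior = "laplace")
    unc[support] <- restricted$uncertainty
  }

  structure(list(coefficients = setNames(best_w, system$column_names),
                 support = support,
                 uncertainty = unc,
                 e = best_e,
                 error_trace = e_trace,
                 tol_trace = tol_trace,
                 eta = eta, kappa = kappa,
                 prior = prior, seed = seed,
                 split = split, split_type = split_type,
                 d_tol0 = d_tol0, n_iters = n_iters,
                 init_fit = init,
                 restricted_fit = restricted,
                 column_names = system$column_names,
                 n = N,
                 call = match.call()),
            class = "atsbl")
}

.kappa_gram <- function(G) {
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (max(ev) == 0) return(1)
  lo <- min(ev[ev > max(ev) * .Machine$double.eps])
  sqrt(max(ev) / lo)
}

#' @export
print.atsbl <- function(x, digits = 4, ...) {
  cat(sprintf("ATSBL fit (%s prior), %d rows, %d candidate terms\n",
              x$prior, x$n, length(x$coefficients)))
  cat(sprintf("kappa = %.3g, eta = %.3g, penalized test error e = %.4g\n",
              x$kappa, x$eta, x$e))
  if (length(x$support)) {
    cat("selected terms:\n")
    cf <- x$coefficients[x$support]; sd <- x$uncertainty[x$support]
    for (i in seq_along(cf))
      cat(sprintf("  %-14s %s (sd %s)\n", names(cf)[i],
                  format(cf[i], digits = digits), format(sd[i], digits = 2)))
  } else cat("null model (all terms pruned)\n")
  invisible(x)
}

#' @export
summary.atsbl <- function(object, ...) {
  s <- object$support
  tab <- data.frame(term = object$column_names[s],
                    coefficient = unname(object$coefficients[s]),
                    sd = unname(object$uncertainty[s]))
  structure(list(terms = tab, e = object$e, kappa = object$kappa,
                 eta = object$eta, prior = object$prior,
                 n = object$n, seed = object$seed), class = "summary.atsbl")
}

#' @export
print.summary.atsbl <- function(x, ...) {
  cat(sprintf("ATSBL (%s prior): n = %d, kappa = %.3g, e = %.4g\n",
              x$prior, x$n, x$kappa, x$e))
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' @export
coef.atsbl <- function(object, ...) object$coefficients

#' Predict from an ATSBL fit
#'
#' @param object an `atsbl` fit.
#' @param newdata design matrix with the same columns (by name or order) as
#'   the fitted system.
#' @param ... unused.
#' @return fitted values `newdata %*% coef`.
#' @export
predict.atsbl <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      all(object$column_names %in% colnames(newdata)))
    newdata <- newdata[, object$column_names, drop = FALSE]
  drop(newdata %*% object$coefficients)
}

#' @export
plot.atsbl <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$error_trace, type = "l", xlab = "iteration",
                 ylab = "penalized test error e", log = "y", ...)
  graphics::plot(x$tol_trace, type = "l", xlab = "iteration",
                 ylab = "threshold tol", ...)
  invisible(x)
}
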