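#' Regularly sampled multivariate trajectory
#'
#' @param values numeric matrix (or vector), N samples x M components.
#' @param step uniform sampling interval.
#' @param t0 time of the first sample.
#' @param names component labels; default `x`, `y`, `z`, then `x4`, ...
#' @return object of class `trajectory`.
#' @export
trajectory <- function(values, step, t0 = 0,
                       names = NULL) {
  values <- as.matrix(values)
  if (is.null(names))
    names <- c("x", "y", "z", paste0("x", seq_len(max(0, ncol(values) - 3)) + 3))[
      seq_len(ncol(values))]
  if (step <= 0) stop("step must be positive")
  colnames(values) <- names
  structure(list(values = values, step = step, t0 = t0, names = names),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d samples x %d components (%s), step = %g\n",
              nrow(x$values), ncol(x$values),
              paste(x$names, collapse = ", "), x$step))
  invisible(x)
}

#' @export
times.trajectory <- function(x) x$t0 + (seq_len(nrow(x$values)) - 1) * x$step

#' Sample times of a trajectory
#' @param x a `trajectory`.
#' @export
times <- function(x) UseMethod("times")

#' Space-time field series on a regular grid
#'
#' @param fields named list of per-component arrays, each `T x Rx` (one
#'   space dimension) or `T x Rx x Ry` (two).
#' @param dx,dy,dt grid spacings (`dy` ignored in one dimension).
#' @param boundary `"periodic"` or `"open"` (spatial axes).
#' @param t0 time of the first snapshot.
#' @return object of class `field_series`.
#' @export
field_series <- function(fields, dx, dt, dy = dx, boundary = c("periodic", "open"),
                         t0 = 0) {
  boundary <- match.arg(boundary)
  dims <- lapply(fields, dim)
  if (length(unique(vapply(dims, paste, collapse = "x", FUN.VALUE = ""))) != 1)
    stop("field components have inconsistent shapes")
  structure(list(fields = fields, dx = dx, dy = dy, dt = dt,
                 boundary = boundary, t0 = t0),
            class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  d <- dim(x$fields[[1]])
  cat(sprintf("<field_series> components %s, %s snapshots on a %s grid (%s)\n",
              paste(names(x$fields), collapse = ", "), d[1],
              paste(d[-1], collapse = " x "), x$boundary))
  invisible(x)
}

#' Fourth-order central finite differences
#'
#' Interior points use the 5-point fourth-order stencil; for open
#' boundaries the outermost two points per edge are returned as `NA` and
#' must be excluded from regression rows, while periodic axes wrap.
#'
#' @param series numeric vector, matrix or 3-d array.
#' @param step grid spacing along the differentiated axis.
#' @param order derivative order, 1 or 2.
#' @param axis axis index to differentiate along (1 = first).
#' @param periodic wrap instead of trimming edges.
#' @return array of the same shape.
#' @export
finite_difference <- function(series, step, order = 1L, axis = 1L,
                              periodic = FALSE) {
  d <- dim(series) %||% length(series)
  n <- d[axis]
  if (n < 5) stop("axis ", axis, " has fewer than 5 points")
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  sh <- function(k) .shift_axis(series, k, axis, periodic)
  out <- if (order == 1L) {
    (sh(-2) - 8 * sh(-1) + 8 * sh(1) - sh(2)) / (12 * step)
  } else {
    (-sh(-2) + 16 * sh(-1) - 30 * series + 16 * sh(1) - sh(2)) / (12 * step^2)
  }
  if (!periodic) out <- .mask_edges(out, axis, 2L)
  out
}

# shift along an axis by k (positive = values from larger indices move down,
# i.e. sh(1)[i] = series[i+1]); non-periodic out-of-range entries become NA
.shift_axis <- function(a, k, axis, periodic) {
  d <- dim(a)
  if (is.null(d)) {
    n <- length(a)
    idx <- seq_len(n) + k
    if (periodic) idx <- ((idx - 1) %% n) + 1 else idx[idx < 1 | idx > n] <- NA
    return(a[idx])
  }
  n <- d[axis]
  idx <- seq_len(n) + k
  if (periodic) idx <- ((idx - 1) %% n) + 1 else idx[idx < 1 | idx > n] <- NA
  args <- rep(list(quote(expr = )), length(d))
  args[[axis]] <- idx
  do.call(`[`, c(list(a), args, list(drop = FALSE)))
}

.mask_edges <- function(a, axis, width) {
  d <- dim(a)
  if (is.null(d)) {
    n <- length(a)
    a[c(seq_len(width), n - seq_len(width) + 1L)] <- NA
    return(a)
  }
  n <- d[axis]
  args <- rep(list(quote(expr = )), length(d))
  args[[axis]] <- c(seq_len(width), n - seq_len(width) + 1L)
  do.call(`[<-`, c(list(a), args, list(value = NA)))
}

#' Candidate-function library specification
#'
#' A library is an ordered set of term expressions in a canonical grammar:
#' `1`, `x`, `x^2*y`, `sin(x)`, `cos(x)`, `cos(w*t)*x`, `u_xx`, `u*v^2`.
#' Expressions are parsed by R and evaluated against named data columns
#' (plus `t` for time and `w` for a known modulation frequency), so any
#' derivative symbol such as `u_xx` simply refers to a precomputed data
#' column of that name.
#'
#' @param terms character vector of term expressions; names must be unique.
#' @param vars character vector of state-variable names the terms refer to.
#' @param omega modulation frequency bound to `w` (for `cos(w*t)` factors).
#' @return object of class `library_spec`.
#' @export
library_spec <- function(terms, vars, omega = NULL) {
  if (anyDuplicated(terms)) stop("term names must be unique")
  structure(list(terms = as.character(terms), vars = vars, omega = omega),
            class = "library_spec")
}

#' @export
print.library_spec <- function(x, ...) {
  cat(sprintf("<library_spec> %d terms over (%s)%s\n", length(x$terms),
              paste(x$vars, collapse = ", "),
              if (!is.null(x$omega)) sprintf(", omega = %g", x$omega) else ""))
  cat(" ", paste(x$terms, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.library_spec <- function(x) length(x$terms)

#' Monomial library up to a total degree
#'
#' All monomials in `vars` with total degree between 1 and `max_degree`,
#' optionally preceded by the constant term `1`.  For 3 variables and
#' `max_degree = 5` this gives 56 terms including the constant.
#'
#' @param vars variable names.
#' @param max_degree maximum total degree.
#' @param include_constant include the `1` term (default TRUE).
#' @param extra additional term expressions appended verbatim.
#' @param omega optional modulation frequency (see [library_spec()]).
#' @export
monomial_library <- function(vars, max_degree, include_constant = TRUE,
                             extra = character(0), omega = NULL) {
  M <- length(vars)
  grids <- rep(list(0:max_degree), M)
  ex <- as.matrix(do.call(expand.grid, grids))
  ex <- ex[rowSums(ex) >= 1 & rowSums(ex) <= max_degree, , drop = FALSE]
  # canonical order: by total degree, then lexicographically by exponents
  ord <- do.call(order, c(list(rowSums(ex)), lapply(seq_len(M), function(j) ex[, j])))
  ex <- ex[ord, , drop = FALSE]
  terms <- apply(ex, 1L, function(e) .monomial_name(vars, e))
  if (include_constant) terms <- c("1", terms)
  library_spec(c(terms, extra), vars, omega = omega)
}

.monomial_name <- function(vars, exps) {
  keep <- exps > 0
  paste(ifelse(exps[keep] == 1, vars[keep],
               paste0(vars[keep], "^", exps[keep])), collapse = "*")
}

#' Default 1-d drift library (8 terms)
#'
#' Monomials of degree 0..7.  A pure polynomial basis is used because
#' trigonometric terms are near-collinear with low-order polynomials over
#' the typical sampled range of a metastable trajectory, which makes the
#' generating support non-identifiable; `sin`/`cos` columns can be added
#' through `monomial_library(extra = )` when the dynamics call for them.
#' The degree cap covers all built-in benchmark drifts (maximum degree 5)
#' with margin while keeping the library's condition number moderate.
#' @param var variable name.
#' @export
default_drift_library <- function(var = "x") monomial_library(var, 7)

#' Default 1-d diffusion library (6 terms)
#'
#' Monomials of degree 0..5.
#' @param var variable name.
#' @export
default_diffusion_library <- function(var = "x") monomial_library(var, 5)

#' Time-modulated library
#'
#' Doubles a base library: the original terms plus copies multiplied by
#' `cos(w*t)` with a known modulation frequency.  With `omega = 0` the
#' modulated copies are collinear with the originals and a rank-deficiency
#' warning is raised.
#'
#' @param base_spec a [library_spec()].
#' @param omega modulation frequency (known, finite).
#' @export
build_time_modulated_library <- function(base_spec, omega) {
  if (!is.finite(omega)) stop("omega must be finite")
  if (omega == 0)
    warning("omega = 0: modulated copies are collinear with the base terms")
  mod <- ifelse(base_spec$terms == "1", "cos(w*t)",
                paste0("cos(w*t)*", base_spec$terms))
  library_spec(c(base_spec$terms, mod), base_spec$vars, omega = omega)
}

#' Evaluate a library on named data
#'
#' @param spec a [library_spec()].
#' @param data named list or data.frame of equal-length vectors (state
#'   variables, derivative columns, and `t` when needed).
#' @return numeric matrix with one named column per term.
#' @export
evaluate_library <- function(spec, data) {
  data <- as.list(data)
  if (!is.null(spec$omega)) data$w <- spec$omega
  n <- length(data[[which(names(data) != "w")[1]]])
  out <- matrix(NA_real_, n, length(spec$terms),
                dimnames = list(NULL, spec$terms))
  env <- list2env(data, parent = baseenv())
  for (j in seq_along(spec$terms)) {
    v <- eval(parse(text = spec$terms[j])[[1]], envir = env)
    if (length(v) == 1) v <- rep(v, n)
    if (any(!is.finite(v)))
      stop("library term '", spec$terms[j], "' evaluates to non-finite values")
    out[, j] <- v
  }
  out
}

#' Build the regression system for an ODE component
#'
#' Target: the fourth-order finite-difference time derivative of component
#' `component`; design: the library evaluated at the same time points.  The
#' two samples at each end of the series (invalid for the stencil) are
#' dropped, keeping targets and design rows co-registered.
#'
#' @param traj a [trajectory()] (N >= 5).
#' @param spec a [library_spec()] over the trajectory's components.
#' @param component index or name of the differentiated component.
#' @return a [linear_system()].
#' @export
build_ode_system <- function(traj, spec, component = 1L) {
  if (is.character(component)) component <- match(component, traj$names)
  dz <- finite_difference(traj$values[, component], traj$step, order = 1L)
  valid <- which(!is.na(dz))
  data <- c(as.list(as.data.frame(traj$values[valid, , drop = FALSE])),
            list(t = times(traj)[valid]))
  names(data)[seq_along(traj$names)] <- traj$names
  design <- evaluate_library(spec, data)
  linear_system(design, dz[valid], column_names = spec$terms)
}

#' Build the regression system for a PDE component
#'
#' Spatial derivatives named in the library (grammar: `u_x`, `u_y`, `u_xx`,
#' `u_yy`, `u_xy`, `lap_u`, and likewise for other components) are computed
#' with fourth-order central differences, wrapping on periodic boundaries.
#' The time derivative of `component` is the regression target.  Valid
#' space-time samples are optionally subsampled to keep the regression
#' desk-scale.
#'
#' @param fields a [field_series()].
#' @param spec a [library_spec()] whose variables are the field components.
#' @param component index or name of the component whose time derivative is
#'   the target.
#' @param subsample maximum number of rows kept (default 50000); `Inf`
#'   keeps all valid rows.
#' @param seed seed for the row subsample.
#' @return a [linear_system()].
#' @export
build_pde_system <- function(fields, spec, component = 1L,
                             subsample = 50000L, seed = 1L) {
  comps <- names(fields$fields)
  if (is.numeric(component)) component <- comps[component]
  periodic <- fields$boundary == "periodic"
  data <- fields$fields
  # derivative columns requested by the library
  toks <- unique(unlist(lapply(spec$terms, function(tm)
    all.vars(parse(text = tm)[[1]]))))
  for (v in toks) {
    if (v %in% c(comps, "t", "w")) next
    data[[v]] <- .field_derivative(fields, v, periodic)
  }
  dz <- finite_difference(fields$fields[[component]], fields$dt,
                          order = 1L, axis = 1L, periodic = FALSE)
  keep <- !is.na(dz)
  for (v in names(data)) keep <- keep & !is.na(data[[v]])
  valid <- which(keep)
  if (!length(valid)) stop("no valid rows after boundary trimming")
  if (is.finite(subsample) && length(valid) > subsample)
    valid <- .with_seed(seed, sort(sample(valid, subsample)))
  cols <- lapply(data, function(a) a[valid])
  cols$t <- NULL
  design <- evaluate_library(spec, cols)
  linear_system(design, dz[valid], column_names = spec$terms)
}

# parse names like u_xx, lap_u, v_xy into derivative arrays
.field_derivative <- function(fields, name, periodic) {
  if (grepl("^lap_", name)) {
    comp <- sub("^lap_", "", name)
    a <- fields$fields[[comp]]
    if (is.null(a)) stop("unknown component in derivative term '", name, "'")
    out <- finite_difference(a, fields$dx, 2L, axis = 2L, periodic = periodic)
    if (length(dim(a)) == 3)
      out <- out + finite_difference(a, fields$dy, 2L, axis = 3L,
                                     periodic = periodic)
    return(out)
  }
  m <- regmatches(name, regexec("^([a-zA-Z0-9]+)_([xy]+)$", name))[[1]]
  if (length(m) != 3) stop("unrecognized derivative term '", name, "'")
  a <- fields$fields[[m[2]]]
  if (is.null(a)) stop("unknown component in derivative term '", name, "'")
  sx <- sum(strsplit(m[3], "")[[1]] == "x")
  sy <- sum(strsplit(m[3], "")[[1]] == "y")
  out <- a
  if (sx == 2) out <- finite_difference(out, fields$dx, 2L, axis = 2L, periodic = periodic)
  else if (sx == 1) out <- finite_difference(out, fields$dx, 1L, axis = 2L, periodic = periodic)
  if (sy == 2) out <- finite_difference(out, fields$dy, 2L, axis = 3L, periodic = periodic)
  else if (sy == 1) out <- finite_difference(out, fields$dy, 1L, axis = 3L, periodic = periodic)
  out
}

#' Default library for two-component reaction-diffusion fields
#'
#' Monomials in `(u, v)` of total degree <= 5 (21 terms), the second
#' spatial derivatives `u_xx, u_yy, u_xy, v_xx, v_yy, v_xy` (6), first
#' derivatives `u_x, u_y, v_x, v_y` (4), and the Laplacians `lap_u, lap_v`
#' (2): 33 terms.
#' @export
default_rd_library <- function() {
  base <- monomial_library(c("u", "v"), 5)
  library_spec(c(base$terms,
                 "u_xx", "u_yy", "u_xy", "v_xx", "v_yy", "v_xy",
                 "u_x", "u_y", "v_x", "v_y", "lap_u", "lap_v"),
               c("u", "v"))
}
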