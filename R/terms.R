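# Canonical term grammar shared by the simulator encoding, equation
# formatting and report parsing: a term is a product of an optional
# cos(w*t) factor, monomial factors `var` / `var^k`, and at most one
# sin(var) or cos(var) factor.  Returns NULL when the expression is not in
# the grammar (e.g. derivative columns like u_xx, which are data-defined).
.parse_term <- function(term, vars) {
  exps <- stats::setNames(integer(length(vars)), vars)
  trig <- 0L; trigvar <- 0L; tmod <- 0L
  s <- gsub(" ", "", term)
  if (s == "1") return(list(exps = exps, trig = trig, trigvar = trigvar, tmod = tmod))
  # pull out the time-modulation factor first; its argument contains '*'
  if (grepl("cos(w*t)", s, fixed = TRUE)) {
    tmod <- 1L
    s <- gsub("\\*?cos\\(w\\*t\\)\\*?", "", s)
    if (s == "") return(list(exps = exps, trig = trig, trigvar = trigvar, tmod = tmod))
  }
  for (f in strsplit(s, "*", fixed = TRUE)[[1]]) {
    m <- regmatches(f, regexec("^(sin|cos)\\(([^)]+)\\)$", f))[[1]]
    if (length(m) == 3) {
      if (trig != 0L) return(NULL)      # at most one trig factor
      j <- match(m[3], vars)
      if (is.na(j)) return(NULL)
      trig <- if (m[2] == "sin") 1L else 2L
      trigvar <- j
      next
    }
    m <- regmatches(f, regexec("^([a-zA-Z][a-zA-Z0-9]*)(\\^([0-9]+))?$", f))[[1]]
    if (length(m) == 0) return(NULL)
    j <- match(m[2], vars)
    if (is.na(j)) return(NULL)
    exps[j] <- exps[j] + if (m[4] == "") 1L else as.integer(m[4])
  }
  list(exps = exps, trig = trig, trigvar = trigvar, tmod = tmod)
}

# Encode a coefficient map (named numeric vector) for the compiled
# simulator: matrix with columns [coef, exps (M), trig, trigvar, tmod].
.encode_terms <- function(coefs, vars) {
  if (!length(coefs)) return(matrix(0, 0, length(vars) + 4L))
  rows <- lapply(names(coefs), function(nm) {
    p <- .parse_term(nm, vars)
    if (is.null(p))
      stop("term '", nm, "' is not evaluable as a state function")
    c(unname(coefs[[nm]]), p$exps, p$trig, p$trigvar, p$tmod)
  })
  do.call(rbind, rows)
}

# Evaluate a coefficient map at states x (n x M matrix) and times t in R;
# the reference implementation mirrored by the compiled path.
.eval_terms <- function(coefs, vars, x, t, omega = 0) {
  x <- as.matrix(x)
  out <- numeric(nrow(x))
  for (nm in names(coefs)) {
    p <- .parse_term(nm, vars)
    if (is.null(p)) stop("term '", nm, "' is not evaluable as a state function")
    v <- rep(1, nrow(x))
    for (j in seq_along(vars)) if (p$exps[[j]] > 0) v <- v * x[, j]^p$exps[[j]]
    if (p$trig == 1L) v <- v * sin(x[, p$trigvar])
    if (p$trig == 2L) v <- v * cos(x[, p$trigvar])
    if (p$tmod == 1L) v <- v * cos(omega * t)
    out <- out + coefs[[nm]] * v
  }
  out
}
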