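#' Deviation of identified coefficients (DIC)
#'
#' Mean relative coefficient error between an identified equation and a
#' reference equation:
#' `DIC = (1/K) * sum |w_i - w'_i| / max(|w_i|, |w'_i|)`,
#' where the sum runs over the union support (terms with at least one of
#' the pair nonzero) and `K` is its size.  Terms are matched by canonical
#' name, so differing library orderings compare correctly; a term absent
#' from one map counts as zero.  DIC is 0 exactly when the maps agree on
#' the union support, it is symmetric in its arguments, and each per-term
#' contribution is bounded by 2 (= 1 whenever one of the pair is zero).
#'
#' @param est named numeric vector of identified coefficients.
#' @param ref named numeric vector of reference coefficients.
#' @return scalar DIC.
#' @export
dic <- function(est, ref) {
  est <- est[est != 0]
  ref <- ref[ref != 0]
  nms <- union(names(est), names(ref))
  if (!length(nms)) stop("DIC undefined: both coefficient maps are empty")
  w <- ifelse(nms %in% names(est), est[nms], 0)
  wp <- ifelse(nms %in% names(ref), ref[nms], 0)
  mean(abs(w - wp) / pmax(abs(w), abs(wp)))
}

#' Format a fitted sparse model as an equation string
#'
#' @param coefs named coefficient vector (or an `atsbl`/`sbl_fit` object).
#' @param target_name left-hand side, e.g. `"dx/dt"`.
#' @param digits significant digits for the printed coefficients.
#' @return character scalar like `"dx/dt = 3 - 18 x + 12 x^2 - 2 x^3"`.
#' @export
format_equation <- function(coefs, target_name = "dx/dt", digits = 6) {
  if (inherits(coefs, c("atsbl", "sbl_fit"))) coefs <- stats::coef(coefs)
  coefs <- coefs[coefs != 0]
  if (!length(coefs)) return(paste(target_name, "= 0"))
  parts <- character(length(coefs))
  for (i in seq_along(coefs)) {
    mag <- format(abs(coefs[i]), digits = digits)
    term <- names(coefs)[i]
    body <- if (term == "1") mag else paste(mag, gsub("\\*", " ", term))
    parts[i] <- paste(if (coefs[i] < 0) "-" else if (i > 1) "+" else "", body)
  }
  paste(target_name, "=", trimws(paste(trimws(parts), collapse = " ")))
}

#' Parse an equation string back into a coefficient map
#'
#' Inverse of [format_equation()] for its output grammar.
#'
#' @param eq equation string, `"lhs = c1 term1 + c2 term2 ..."`.
#' @return named numeric vector of coefficients (term `1` for constants).
#' @export
parse_equation <- function(eq) {
  rhs <- trimws(sub("^.*?=", "", eq))
  if (rhs == "0") return(stats::setNames(numeric(0), character(0)))
  rhs <- gsub("- ", "+ -", rhs, fixed = TRUE)
  if (startsWith(rhs, "-")) rhs <- paste0("+ ", rhs)
  pieces <- trimws(strsplit(rhs, "+", fixed = TRUE)[[1]])
  pieces <- pieces[pieces != ""]
  coefs <- numeric(0)
  for (p in pieces) {
    p <- gsub("^- *", "-", p)
    toks <- strsplit(p, " +")[[1]]
    val <- suppressWarnings(as.numeric(toks[1]))
    if (is.na(val)) stop("cannot parse equation piece '", p, "'")
    term <- if (length(toks) > 1) paste(toks[-1], collapse = "*") else "1"
    coefs[term] <- val
  }
  coefs
}

#' Equation report for one fitted component
#'
#' Machine-readable record of a fit: term names, coefficients,
#' uncertainties, optional reference coefficients and the DIC against them.
#'
#' @param fit an `atsbl` fit.
#' @param target_name label of the left-hand side.
#' @param reference optional named reference coefficient map.
#' @return list with class `equation_report`, serializable to JSON.
#' @export
equation_report <- function(fit, target_name = "dx/dt", reference = NULL) {
  s <- fit$support
  terms <- lapply(s, function(i) list(name = fit$column_names[i],
                                      coef = unname(fit$coefficients[i]),
                                      sd = unname(fit$uncertainty[i])))
  rep <- list(target = target_name, terms = terms,
              equation = format_equation(fit, target_name),
              fit = list(prior = fit$prior, e = fit$e, kappa = fit$kappa,
                         eta = fit$eta, seed = fit$seed, n = fit$n))
  if (!is.null(reference)) {
    rep$reference <- as.list(reference)
    rep$dic <- dic(fit$coefficients, reference)
  }
  structure(rep, class = "equation_report")
}

#' @export
print.equation_report <- function(x, ...) {
  cat(x$equation, "\n")
  if (!is.null(x$dic)) cat(sprintf("DIC vs reference: %.4g\n", x$dic))
  invisible(x)
}
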