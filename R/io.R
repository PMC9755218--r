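#' Read a trajectory from delimited text
#'
#' Expects a header row, first column time, remaining columns state
#' components, and uniform time spacing (relative tolerance 1e-9).
#'
#' @param path file path (any delimiter `data.table::fread` detects).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path) {
  dt <- data.table::fread(path)
  if (ncol(dt) < 2) stop("trajectory file needs a time column and at least one component")
  if (anyNA(dt)) stop("trajectory file contains missing values")
  tv <- dt[[1]]
  if (length(tv) < 2) stop("trajectory file needs at least 2 rows")
  steps <- diff(tv)
  s <- stats::median(steps)
  if (s <= 0) stop("non-increasing time column")
  bad <- which(abs(steps - s) > 1e-9 * max(abs(tv), s))
  if (length(bad))
    stop("irregular sampling at row ", bad[1] + 1L,
         " (step ", format(steps[bad[1]]), " vs ", format(s), ")")
  trajectory(as.matrix(dt[, -1]), step = s, t0 = tv[1],
             names = names(dt)[-1])
}

#' Write a trajectory to delimited text
#'
#' Lossless round-trip: values are written with shortest round-trip
#' decimal representation.
#'
#' @param traj a [trajectory()].
#' @param path output path (CSV).
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(t = times(traj), traj$values, check.names = FALSE)
  # 17 significant digits guarantee exact double round-trips
  df[] <- lapply(df, function(v) formatC(v, digits = 17, format = "g"))
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

#' Write / read a field series
#'
#' Stored as an RDS file with a JSON metadata sidecar (`<path>.json`)
#' recording grid spacings, shapes and boundary type.
#'
#' @param fs a [field_series()].
#' @param path output path.
#' @export
write_field_series <- function(fs, path) {
  saveRDS(fs, path)
  meta <- list(components = names(fs$fields), shape = dim(fs$fields[[1]]),
               dx = fs$dx, dy = fs$dy, dt = fs$dt, boundary = fs$boundary)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_field_series
#' @export
read_field_series <- function(path) readRDS(path)

#' Execute a configured task
#'
#' Dispatches the pipeline tasks behind the command-line interface:
#' \describe{
#'   \item{simulate}{simulate a named fixture, write a trajectory CSV and
#'     a JSON metadata sidecar.}
#'   \item{fit-sde}{read a trajectory, fit drift and diffusion with
#'     [fit_km()], write a JSON report.}
#'   \item{fit-ode}{read a trajectory, fit each component's ODE over a
#'     monomial library with [atsbl()], write a JSON report.}
#'   \item{fit-pde}{read a field series (RDS, see [write_field_series()]),
#'     fit each component's PDE over [default_rd_library()].}
#'   \item{aiso}{run [aiso()] on a named fixture, write per-iteration DIC
#'     and the final equations.}
#'   \item{score}{compute the DIC between a report and a named fixture.}
#' }
#'
#' @param config named list (or path to a YAML/JSON file) with a `task`
#'   field and task-specific entries; unknown keys raise an error.
#' @return the result invisibly; artifacts are written to `config$out`.
#' @export
run <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  known <- c("task", "model", "params", "steps", "dt", "x0", "seed", "out",
             "input", "mode", "bins", "filter", "p_star", "tsallis_q",
             "prior", "n_iters", "d_tol", "split", "max_degree", "iters",
             "steps_per_iter", "report", "omega")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config key: ", bad[1])
  task <- config$task %||% stop("config needs a task")
  seed <- config$seed %||% 1L
  prov <- list(task = task, seed = seed,
               package = as.character(utils::packageVersion("sparsedyn")),
               config = config[setdiff(names(config), "out")])
  switch(task,
    simulate = {
      model <- do.call(make_fixture, c(list(config$model %||% "double_well"),
                                       config$params %||% list()))
      traj <- euler_maruyama(model, config$x0 %||% numeric(length(model$vars)),
                             config$dt %||% 5e-3,
                             config$steps %||% 1e4, seed = seed)
      if (!is.null(config$out)) {
        write_trajectory(traj, config$out)
        jsonlite::write_json(c(prov, list(model = config$model %||% "double_well")),
                             paste0(config$out, ".json"), auto_unbox = TRUE)
      }
      invisible(traj)
    },
    `fit-sde` = {
      traj <- if (inherits(config$input, "trajectory")) config$input
              else read_trajectory(config$input)
      omega <- config$omega
      dspec <- default_drift_library(traj$names[1])
      if (!is.null(omega))
        dspec <- build_time_modulated_library(monomial_library(traj$names[1], 5), omega)
      fit <- fit_km(traj, drift_spec = dspec,
                    mode = config$mode %||% "direct",
                    Q = config$bins %||% 200L,
                    filter = config$filter %||% TRUE,
                    p_star = config$p_star,
                    tsallis_q = config$tsallis_q %||% 0.8,
                    prior = config$prior %||% "laplace", seed = seed)
      rep <- list(provenance = prov,
                  drift = unclass(equation_report(fit$drift, "D1")),
                  diffusion = unclass(equation_report(fit$diffusion, "D2")))
      if (!is.null(config$out))
        jsonlite::write_json(rep, config$out, auto_unbox = TRUE, digits = NA)
      invisible(fit)
    },
    `fit-ode` = {
      traj <- if (inherits(config$input, "trajectory")) config$input
              else read_trajectory(config$input)
      spec <- monomial_library(traj$names, config$max_degree %||% 5)
      reps <- lapply(seq_along(traj$names), function(l) {
        fit <- atsbl(build_ode_system(traj, spec, l),
                     prior = config$prior %||% "laplace", seed = seed)
        unclass(equation_report(fit, paste0("d", traj$names[l], "/dt")))
      })
      out <- list(provenance = prov, equations = reps)
      if (!is.null(config$out))
        jsonlite::write_json(out, config$out, auto_unbox = TRUE, digits = NA)
      invisible(out)
    },
    `fit-pde` = {
      fs <- if (inherits(config$input, "field_series")) config$input
            else read_field_series(config$input)
      spec <- default_rd_library()
      reps <- lapply(names(fs$fields), function(comp) {
        fit <- atsbl(build_pde_system(fs, spec, comp, seed = seed),
                     prior = config$prior %||% "laplace", seed = seed)
        unclass(equation_report(fit, paste0("d", comp, "/dt")))
      })
      out <- list(provenance = prov, equations = reps)
      if (!is.null(config$out))
        jsonlite::write_json(out, config$out, auto_unbox = TRUE, digits = NA)
      invisible(out)
    },
    aiso = {
      model <- do.call(make_fixture, c(list(config$model %||% "three_well"),
                                       config$params %||% list()))
      res <- aiso(model, n_iter = config$iters %||% 10L,
                  steps_per_iter = config$steps_per_iter %||% 1e5,
                  dt = config$dt %||% 5e-3, seed = seed)
      out <- list(provenance = prov, dic_trace = res$dic_trace,
                  drift = format_equation(res$drift_coefs, "D1"),
                  diffusion = format_equation(res$diff_coefs, "D2"))
      if (!is.null(config$out))
        jsonlite::write_json(out, config$out, auto_unbox = TRUE, digits = NA)
      invisible(res)
    },
    score = {
      rep <- if (is.character(config$report))
        jsonlite::read_json(config$report, simplifyVector = TRUE) else config$report
      model <- do.call(make_fixture, c(list(config$model), config$params %||% list()))
      est_d <- parse_equation(rep$drift$equation)
      est_h <- parse_equation(rep$diffusion$equation)
      res <- list(dic_drift = dic(est_d, model$drift[[1]]),
                  dic_diffusion = dic(est_h, model$diffusion[[1]]))
      if (!is.null(config$out))
        jsonlite::write_json(c(prov, res), config$out, auto_unbox = TRUE, digits = NA)
      invisible(res)
    },
    stop("unknown task '", task, "'"))
}
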