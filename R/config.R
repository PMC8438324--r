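#' Run configuration
#'
#' A validated, serializable description of a single analysis run: model id,
#' parameter map, initial state, horizon, solver options, analysis options
#' and seed.  All parameter invariants are enforced here (via the model
#' parameter constructors), and unknown keys anywhere are rejected with an
#' error naming every offending key.
#'
#' @param model model id (`"lv"`, `"allee"`, `"ti"`, `"ti-reduced"`).
#' @param params named list of model parameters (for `"allee"`/`"ti"`,
#'   `response` is itself a list `(b, alpha, h)`).
#' @param init nonnegative initial state in compartment order.
#' @param t_end integration horizon.
#' @param solver optional list: `rtol`, `atol`, `ext_floor`, `n_out`.
#' @param analysis optional list: `burn_in`, `amp_floor`, `eps`,
#'   `inefficiency`, `ratio`, `state`, `method`, `t_end`.
#' @param seed optional integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(model, params, init, t_end, solver = list(),
                       analysis = list(), seed = NULL) {
  model <- normalize_model(model)
  info <- model_info(model)
  pobj <- params_from_list(model, params)
  if (length(init) != length(info$compartments) ||
      any(!is.finite(init)) || any(init < 0))
    abort_validation(sprintf("'init' must be %d nonnegative densities (%s)",
                             length(info$compartments),
                             paste(info$compartments, collapse = ", ")))
  chk_num(t_end, "t_end", 0, strict = TRUE)
  solver <- fill_defaults(solver, list(rtol = 1e-9, atol = 1e-12,
                                       ext_floor = 1e-9, n_out = 2000),
                          "solver")
  analysis <- fill_defaults(analysis,
                            list(burn_in = NULL, amp_floor = 1e-4, eps = 1e-9,
                                 inefficiency = NULL, ratio = NULL,
                                 state = NULL, method = "both", t_end = NULL),
                            "analysis")
  structure(list(model = model, params = pobj, init = as.numeric(init),
                 t_end = as.numeric(t_end), solver = solver,
                 analysis = analysis,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "run_config")
}

fill_defaults <- function(x, defaults, what) {
  if (is.null(x)) x <- list()
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown))
    abort_validation(sprintf("unknown %s option(s): %s", what,
                             paste(unknown, collapse = ", ")))
  utils::modifyList(defaults, x)
}

params_from_list <- function(model, params) {
  model <- normalize_model(model)
  if (inherits(params, model_info(model)$class)) return(params)
  if (!is.list(params)) abort_validation("'params' must be a named list")
  ctor <- switch(model, lv = lv_params, allee = allee_params, ti = ti_params,
                 ti_reduced = NULL)
  if (is.null(ctor)) {
    # reduced models are specified through full ti parameters
    return(qss_reduce(params_from_list("ti", params)))
  }
  known <- names(formals(ctor))
  unknown <- setdiff(names(params), known)
  if (length(unknown))
    abort_validation(sprintf("unknown parameter(s) for model '%s': %s", model,
                             paste(unknown, collapse = ", ")))
  missing <- setdiff(setdiff(known, c("g", "alpha", "h", "allee_L")), names(params))
  if (length(missing))
    abort_validation(sprintf("missing parameter(s) for model '%s': %s", model,
                             paste(missing, collapse = ", ")))
  if (!is.null(params$response)) params$response <- as_response(params$response)
  do.call(ctor, params)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> model '%s', t_end = %g, init = (%s), seed = %s\n",
              x$model, x$t_end, paste(x$init, collapse = ", "),
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

config_to_list <- function(cfg) {
  p <- cfg$params
  plain <- unclass(p)
  if (!is.null(plain$response)) plain$response <- unclass(plain$response)
  plain <- plain[!vapply(plain, is.null, logical(1))]
  analysis <- cfg$analysis[!vapply(cfg$analysis, is.null, logical(1))]
  out <- list(model = cfg$model, params = plain, init = cfg$init,
              t_end = cfg$t_end, solver = cfg$solver, analysis = analysis)
  if (!is.null(cfg$seed)) out$seed <- cfg$seed
  out
}

#' Load / save a run configuration
#'
#' Declarative configuration files in YAML (`.yaml`/`.yml`) or JSON
#' (`.json`), validated on load: parameter invariants are enforced, defaults
#' filled in, and unknown keys rejected with an error listing every offending
#' key.  `save_config()` followed by `load_config()` reproduces an identical
#' configuration.
#'
#' @param path configuration file path.
#' @return A [run_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("config file '%s' not found", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else abort_validation("config must be a .yaml, .yml or .json file")
  known <- c("model", "params", "init", "t_end", "solver", "analysis", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    abort_validation(sprintf("unknown config key(s): %s",
                             paste(unknown, collapse = ", ")))
  missing <- setdiff(c("model", "params", "init", "t_end"), names(raw))
  if (length(missing))
    abort_validation(sprintf("missing config key(s): %s",
                             paste(missing, collapse = ", ")))
  run_config(model = raw$model, params = raw$params, init = raw$init,
             t_end = raw$t_end, solver = raw$solver %||% list(),
             analysis = raw$analysis %||% list(), seed = raw$seed)
}

#' @rdname load_config
#' @param cfg a [run_config()] object.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  lst <- config_to_list(cfg)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(lst, path, precision = 15)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
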