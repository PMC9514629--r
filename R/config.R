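#' Run configuration
#'
#' A run configuration bundles everything a reproducible run needs: the
#' parameter registry values, the calibrated subset, integration and DE
#' settings, seeds and the synthetic-noise level. `default_run_config()`
#' builds the default, `read_run_config()`/`write_run_config()` round-trip
#' it through YAML and `validate_run_config()` checks a configuration
#' against the expected schema, naming the offending field.
#'
#' @return `default_run_config()`: a named list of class `osteo_config`.
#' @export
default_run_config <- function() {
  structure(list(
    parameters = as.list(unclass(model_parameters())),
    free = parameter_priors()$name,
    dt = 1,
    switch_on = "time",
    swap_branches = FALSE,
    de = de_settings(),
    n_runs = 20,
    tolerance = 0.05,
    seed = 1,
    noise_cv = 0.1
  ), class = "osteo_config")
}

# field -> predicate; validation errors name the field
config_schema <- function() {
  list(
    parameters = function(v) is.list(v) &&
      setequal(names(v), names(default_parameter_values())),
    free = function(v) is.character(v) &&
      all(v %in% names(default_parameter_values())),
    dt = function(v) is.numeric(v) && length(v) == 1 && v > 0,
    switch_on = function(v) is.character(v) && v %in% c("time", "maturity"),
    swap_branches = function(v) is.logical(v) && length(v) == 1,
    de = function(v) is.list(v) &&
      all(c("pop", "generations", "F", "CR") %in% names(v)),
    n_runs = function(v) is.numeric(v) && length(v) == 1 && v >= 2,
    tolerance = function(v) is.numeric(v) && length(v) == 1 && v > 0,
    seed = function(v) is.numeric(v) && length(v) == 1,
    noise_cv = function(v) is.numeric(v) && length(v) == 1 && v >= 0
  )
}

#' @rdname default_run_config
#' @param config A configuration list.
#' @return `validate_run_config()`: the validated config, invisibly; errors
#'   name the missing or invalid field.
#' @export
validate_run_config <- function(config) {
  schema <- config_schema()
  for (field in names(schema)) {
    if (!field %in% names(config)) {
      stop(sprintf("config is missing required field '%s'", field),
           call. = FALSE)
    }
    if (!isTRUE(schema[[field]](config[[field]]))) {
      stop(sprintf("config field '%s' is invalid", field), call. = FALSE)
    }
  }
  theta <- model_parameters(strict = FALSE)
  theta[names(config$parameters)] <- unlist(config$parameters)
  msg <- check_parameters(theta)
  if (!is.null(msg)) {
    stop(sprintf("config field 'parameters' is invalid: %s", msg),
         call. = FALSE)
  }
  invisible(structure(config, class = "osteo_config"))
}

#' @rdname default_run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
  structure(cfg, class = "osteo_config")
}

#' @rdname default_run_config
#' @export
write_run_config <- function(config, path) {
  validate_run_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_run_config
#' @return `config_parameters()`: the [model_parameters()] registry stored
#'   in a configuration.
#' @export
config_parameters <- function(config) {
  do.call(model_parameters, config$parameters)
}
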