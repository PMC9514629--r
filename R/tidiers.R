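#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a repeated-calibration fit
#'
#' @param x An `osteo_calibration` object from [calibrate_repeated()].
#' @param ... Unused.
#' @return One row per calibrated parameter: `parameter`, `estimate` (mean
#'   of per-run bests), `half1_mean`, `half2_mean`, `sd`, prior bounds and
#'   the half-split gap as a fraction of the prior length.
#' @export
tidy.osteo_calibration <- function(x, ...) {
  out <- x$summary
  names(out)[names(out) == "mean"] <- "estimate"
  tibble::as_tibble(out)
}

#' @rdname tidy.osteo_calibration
#' @return `glance()`: a one-row tibble with `n_runs`, `mean_fitness`,
#'   `best_fitness`, `converged` and `tolerance`.
#' @export
glance.osteo_calibration <- function(x, ...) {
  tibble::tibble(
    n_runs = x$n_runs,
    mean_fitness = mean(x$runs$fitness),
    best_fitness = max(x$runs$fitness),
    converged = x$converged,
    tolerance = x$tolerance
  )
}

#' @export
tidy.osteo_de_run <- function(x, ...) {
  tibble::tibble(parameter = names(x$par), estimate = unname(x$par))
}

#' @export
glance.osteo_de_run <- function(x, ...) {
  tibble::tibble(fitness = x$fitness, seed = x$seed, n_eval = x$n_eval)
}
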