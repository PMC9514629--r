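#' Two-level fractional factorial design
#'
#' Builds an orthogonal two-level `2^(b-p)` design for `n_params` factors:
#' each factor is assigned a distinct interaction column of a full
#' factorial in `b` base factors. Resolution III uses all non-empty
#' subsets (capacity `2^b - 1` columns in `2^b` runs, e.g. the saturated
#' 8-run design for 7 factors); resolution IV uses only odd-cardinality
#' subsets (capacity `2^(b-1)`), which leaves main effects unconfounded
#' with two-factor interactions. Every column is balanced (equal +1/-1
#' counts) and any two columns are orthogonal.
#'
#' @param n_params Number of factors (>= 2).
#' @param resolution 3 or 4.
#' @return A `runs x n_params` matrix of -1/+1 levels.
#' @examples
#' d <- ffd_design(7, resolution = 3)  # 8 runs
#' colSums(d)                          # balanced
#' @export
ffd_design <- function(n_params, resolution = 4) {
  if (n_params < 2) stop("n_params must be >= 2", call. = FALSE)
  if (!resolution %in% c(3, 4)) {
    stop("resolution must be 3 (saturated) or 4 (main effects clear of two-factor interactions)",
         call. = FALSE)
  }
  capacity <- function(b) if (resolution == 3) 2^b - 1 else 2^(b - 1)
  b <- 2
  while (capacity(b) < n_params) {
    b <- b + 1
    if (b > 20) stop("design infeasible for this many parameters", call. = FALSE)
  }
  base <- as.matrix(expand.grid(rep(list(c(-1, 1)), b)))
  subsets <- unlist(lapply(seq_len(b), function(k) {
    if (resolution == 4 && k %% 2 == 0) return(NULL)
    utils::combn(b, k, simplify = FALSE)
  }), recursive = FALSE)
  subsets <- subsets[seq_len(n_params)]
  design <- vapply(subsets, function(s) {
    apply(base[, s, drop = FALSE], 1, prod)
  }, numeric(nrow(base)))
  dimnames(design) <- NULL
  design
}

# multiply selected registry entries by factors, then clip the perturbed
# values back into their prior bounds (perturbations around inferred values
# may otherwise escape the priors); returns the vector plus the clipped names
perturb_parameters <- function(theta, names_, factors) {
  theta[names_] <- theta[names_] * factors
  pri <- parameter_priors()
  idx <- match(names_, pri$name)
  clipped <- character(0)
  for (i in seq_along(names_)) {
    v <- theta[[names_[i]]]
    v2 <- min(max(v, pri$lower[idx[i]]), pri$upper[idx[i]])
    if (v2 != v) clipped <- c(clipped, names_[i])
    theta[names_[i]] <- v2
  }
  attr(theta, "clipped") <- clipped
  theta
}

#' Small-scale individual parameter perturbation (SSIP)
#'
#' Perturbs the parameters one at a time by +/- `magnitude` (default 15
#' percent) around the supplied values and reports, per measurement item,
#' the mean absolute percentage change of the simulated output relative to
#' the unperturbed value and the standard deviation across the +/- pair
#' (the SSIP error bars). Perturbed values escaping the prior bounds are
#' clipped.
#'
#' @param theta The inferred [model_parameters()] registry.
#' @param designs List of [study_design()] objects (default all five).
#' @param magnitude Relative perturbation (default 0.15).
#' @param parameters Registry names to perturb; default is the union of the
#'   designs' relevant subsets.
#' @inheritParams simulate_study
#' @return A tibble with one row per (parameter, study, condition, marker,
#'   day): `base`, `value_minus`, `value_plus`, `pct_change`, `sd`.
#' @export
ssip <- function(theta = model_parameters(), designs = builtin_designs(),
                 magnitude = 0.15, parameters = NULL,
                 switch_on = "time", swap_branches = FALSE) {
  if (is.null(parameters)) {
    parameters <- unique(unlist(lapply(
      vapply(designs, `[[`, integer(1), "study_id"), relevant_parameters)))
    parameters <- intersect(names(theta), parameters)
  }
  cache <- new.env(parent = emptyenv())
  base_preds <- simulate_studies(designs, theta, switch_on, swap_branches,
                                 cache)
  key <- c("study_id", "condition", "marker", "day")
  y0 <- base_preds$predicted
  out <- purrr::map_dfr(parameters, function(pn) {
    sims <- lapply(c(-1, 1), function(sgn) {
      th <- perturb_parameters(theta, pn, 1 + sgn * magnitude)
      simulate_studies(designs, structure(th, class = "osteo_params"),
                       switch_on, swap_branches, cache)$predicted
    })
    tibble::tibble(
      parameter = pn,
      base_preds[, key],
      base = y0,
      value_minus = sims[[1]],
      value_plus = sims[[2]],
      pct_change = 100 * (abs(sims[[1]] - y0) + abs(sims[[2]] - y0)) / (2 * y0),
      sd = apply(cbind(sims[[1]], sims[[2]]), 1, stats::sd)
    )
  })
  out$magnitude <- magnitude
  out
}

#' Large-scale simultaneous parameter perturbation (LSSP)
#'
#' Perturbs the relevant parameters of each study simultaneously by
#' +/- `magnitude` (default 50 percent) following a two-level fractional
#' factorial design, runs an ANOVA of the simulated outputs on the coded
#' factors, and ranks the parameters by main-effect magnitude. Responses
#' are normalized per measurement item by their across-run mean, so the
#' ranking is invariant to rescaling any output by a positive constant.
#' When measurement data are supplied, the mean fitness is included as an
#' auxiliary response.
#'
#' @param theta The inferred [model_parameters()] registry.
#' @param designs List of [study_design()] objects; each is analysed with
#'   its own relevant parameter subset unless `parameters` is given.
#' @param magnitude Relative perturbation (default 0.5).
#' @param parameters Optional fixed set of registry names to perturb for
#'   every design (parameters without influence rank last).
#' @param resolution Design resolution passed to [ffd_design()].
#' @param data Optional measurement tibble for the auxiliary fitness
#'   response.
#' @param top_n How many leading parameters to flag (default 5).
#' @inheritParams simulate_study
#' @return A tibble with one row per (study, parameter): `effect` (mean
#'   absolute normalized main effect), `fitness_effect` (if data given),
#'   `rank` and `top` (logical, rank <= `top_n`).
#' @export
lssp <- function(theta = model_parameters(), designs = builtin_designs(),
                 magnitude = 0.5, parameters = NULL, resolution = 4,
                 data = NULL, top_n = 5,
                 switch_on = "time", swap_branches = FALSE) {
  cache <- new.env(parent = emptyenv())
  purrr::map_dfr(designs, function(design) {
    pars <- if (is.null(parameters)) {
      intersect(names(theta), relevant_parameters(design$study_id))
    } else {
      parameters
    }
    D <- ffd_design(length(pars), resolution)
    sdata <- if (!is.null(data)) {
      data[data$study_id == design$study_id, , drop = FALSE]
    }
    responses <- lapply(seq_len(nrow(D)), function(r) {
      th <- perturb_parameters(theta, pars, 1 + D[r, ] * magnitude)
      th <- structure(th, class = "osteo_params")
      preds <- simulate_study(design, th, switch_on, swap_branches, cache)
      fit <- if (!is.null(sdata) && nrow(sdata) > 0) {
        objective_fitness(th, sdata, list(design), switch_on, swap_branches,
                          cache)
      } else {
        NA_real_
      }
      list(pred = preds$predicted, fitness = fit)
    })
    Y <- do.call(rbind, lapply(responses, `[[`, "pred"))
    # normalize each item by its across-run mean (scale invariance)
    Y <- sweep(Y, 2, pmax(colMeans(Y), .Machine$double.eps), "/")
    # balanced orthogonal design: the lm coefficients on the coded +/-1
    # factors are the ANOVA main effects (half the high-low difference)
    effects <- vapply(seq_len(ncol(Y)), function(j) {
      abs(stats::coef(stats::lm(Y[, j] ~ D))[-1])
    }, numeric(length(pars)))
    effects <- matrix(effects, nrow = length(pars))
    fit_effect <- if (!is.null(sdata) && nrow(sdata) > 0) {
      fy <- vapply(responses, `[[`, numeric(1), "fitness")
      abs(stats::coef(stats::lm(fy ~ D))[-1])
    } else {
      rep(NA_real_, length(pars))
    }
    res <- tibble::tibble(
      study_id = design$study_id,
      parameter = pars,
      effect = rowMeans(effects),
      fitness_effect = unname(fit_effect)
    )
    res$rank <- rank(-res$effect, ties.method = "first")
    res$top <- res$rank <= top_n
    res[order(res$rank), ]
  })
}
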