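#' Goodness-of-fit of a single measurement
#'
#' The per-item fitness is one minus the normalized absolute difference
#' between the empirical value `E` and the simulated value `S`,
#' `max(0, 1 - |E - S| / E)`: 1 denotes a perfect fit and the score is
#' clamped at 0 when the relative error exceeds 100 percent. The score is
#' scale-free (invariant to rescaling `E` and `S` by the same positive
#' constant).
#'
#' @param E Empirical value(s), strictly positive.
#' @param S Simulated value(s).
#' @param raw If `TRUE`, return the raw discrepancy `|E - S| / E` instead.
#' @return Numeric vector of fitness values in `[0, 1]` (or raw
#'   discrepancies).
#' @examples
#' fitness_item(2, 1)  # 0.5
#' @export
fitness_item <- function(E, S, raw = FALSE) {
  if (any(!is.finite(E)) || any(E <= 0)) {
    stop("empirical values E must be finite and positive", call. = FALSE)
  }
  d <- abs(E - S) / E
  if (isTRUE(raw)) d else pmax(0, 1 - d)
}

# join measurement items to the predictions of the referenced studies;
# errors on items that no design/condition/marker/day resolves
match_predictions <- function(data, preds) {
  key <- c("study_id", "condition", "marker", "day")
  merged <- dplyr::left_join(data, preds, by = key)
  bad <- which(is.na(merged$predicted))
  if (length(bad) > 0) {
    r <- merged[bad[1], ]
    stop(sprintf(
      "measurement item not resolvable in the designs: study %s, condition '%s', %s day %s",
      r$study_id, r$condition, r$marker, r$day), call. = FALSE)
  }
  merged
}

#' Objective fitness of a parameter set against measurement data
#'
#' Simulates every study referenced by the data and averages the per-item
#' fitness. `fitness_table()` returns the per-item scores (the per-item
#' averages reported alongside the fits), `objective_fitness()` their mean.
#'
#' @param theta A [model_parameters()] registry.
#' @param data Measurement tibble (e.g. from [generate_synthetic()] or
#'   [read_measurements()]).
#' @param designs List of [study_design()] objects covering the studies in
#'   `data`.
#' @inheritParams simulate_study
#' @return `objective_fitness()`: a single mean fitness in `[0, 1]`.
#' @export
objective_fitness <- function(theta, data, designs = builtin_designs(),
                              switch_on = "time", swap_branches = FALSE,
                              cache = NULL) {
  mean(fitness_table(theta, data, designs, switch_on, swap_branches,
                     cache)$fitness)
}

#' @rdname objective_fitness
#' @return `fitness_table()`: a tibble with one row per measurement item,
#'   columns `study_id`, `condition`, `marker`, `day`, `value`, `predicted`
#'   and `fitness`.
#' @export
fitness_table <- function(theta, data, designs = builtin_designs(),
                          switch_on = "time", swap_branches = FALSE,
                          cache = NULL) {
  stopifnot(is.data.frame(data), all(c("study_id", "condition", "marker",
                                       "day", "value") %in% names(data)))
  used <- vapply(designs, `[[`, integer(1), "study_id") %in%
    unique(data$study_id)
  if (!any(used)) stop("no design matches the studies in the data", call. = FALSE)
  preds <- simulate_studies(designs[used], theta, switch_on, swap_branches,
                            cache)
  merged <- match_predictions(tibble::as_tibble(data), preds)
  merged$fitness <- fitness_item(merged$value, merged$predicted)
  merged[, c("study_id", "condition", "marker", "day", "value", "predicted",
             "fitness")]
}

#' Build a calibration objective over a free-parameter subset
#'
#' Returns a closure `f(par)` mapping a named vector of free-parameter
#' values to the mean fitness, holding the remaining registry entries fixed
#' at `base_theta`. Candidates violating the registry's ordering
#' constraints score 0. Fuzzy controller evaluations are memoised across
#' calls, so optimizing a subset that leaves the controller anchors fixed
#' re-runs only the cheap maturity arithmetic.
#'
#' @param data Measurement tibble.
#' @param free Character vector of registry names to expose; defaults to
#'   the full 30-entry registry.
#' @param base_theta Fixed values for the remaining parameters.
#' @inheritParams objective_fitness
#' @return A function `f(par)` returning the mean fitness in `[0, 1]`.
#' @export
calibration_objective <- function(data, free = NULL,
                                  base_theta = model_parameters(),
                                  designs = builtin_designs(),
                                  switch_on = "time", swap_branches = FALSE) {
  if (is.null(free)) free <- names(base_theta)
  unknown <- setdiff(free, names(base_theta))
  if (length(unknown) > 0) {
    stop(sprintf("unknown free parameter(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  cache <- new.env(parent = emptyenv())
  fast_eval <- build_fast_objective(data, designs, switch_on, swap_branches)
  function(par) {
    stopifnot(!is.null(names(par)), all(names(par) %in% free))
    theta <- base_theta
    theta[names(par)] <- par
    if (!is.null(check_parameters(theta))) return(0)
    tryCatch(fast_eval(theta, cache), error = function(e) 0)
  }
}

# time-based maturity at one time point for piecewise-constant hourly rates
# (overlap of each segment with the early window [0, T_e] and the late
# window [T_e, t]); clamped at 1
maturity_time_based <- function(t_h, t_start, t_end, r_e_h, r_l_h, T_e_h) {
  e_len <- pmax(0, pmin(t_end, t_h, T_e_h) - t_start)
  l_len <- pmax(0, pmin(t_end, t_h) - pmax(t_start, T_e_h))
  min(1, sum(r_e_h * e_len + r_l_h * l_len))
}

CTRL_PAR_NAMES <- c("p_ms", "p_md", "p_8f", "p_1bs", "p_1bie",
                    "p_es", "p_ef", "p_evf", "p_ls", "p_lf")

# Pre-resolves every measurement item against the designs so the per-theta
# evaluation is plain arithmetic: per condition, fuzzy segment rates
# (memoised on input + controller-anchor values) -> exact piecewise maturity
# at the measurement days -> marker values -> optional fold normalization ->
# mean per-item fitness.
build_fast_objective <- function(data, designs, switch_on = "time",
                                 swap_branches = FALSE) {
  design_ids <- vapply(designs, `[[`, integer(1), "study_id")
  units <- lapply(unique(data$study_id), function(sid) {
    di <- match(sid, design_ids)
    if (is.na(di)) {
      stop(sprintf("no design for study %s in the data", sid), call. = FALSE)
    }
    design <- designs[[di]]
    sdata <- data[data$study_id == sid, ]
    meas <- design$measurements
    midx <- match(paste(sdata$marker, sdata$day),
                  paste(meas$marker, meas$day))
    conds <- unique(sdata$condition)
    if (design$normalization == "fold") conds <- union(conds, design$control)
    known <- conds %in% names(design$conditions)
    if (any(is.na(midx)) || !all(known)) {
      bad <- if (!all(known)) {
        sprintf("condition '%s'", conds[!known][1])
      } else {
        r <- sdata[which(is.na(midx))[1], ]
        sprintf("condition '%s', %s day %s", r$condition, r$marker, r$day)
      }
      stop(sprintf("measurement item not resolvable in study %s design: %s",
                   sid, bad), call. = FALSE)
    }
    # precompile each condition's segments with their fuzzy-cache key stems
    scheds <- lapply(design$conditions[conds], function(sched) {
      n <- length(sched$t_start)
      dur <- sched$t_end - sched$t_start
      exposure <- c(0, cumsum(as.numeric(sched$il10 > 0) * dur))[seq_len(n)]
      rows <- lapply(seq_len(n), function(i) {
        list(mg = sched$mg[i], tnf = sched$tnf[i], il10 = sched$il10[i],
             il8 = sched$il8[i], il1b = sched$il1b[i],
             il10_exposure = exposure[i])
      })
      list(t_start = sched$t_start, t_end = sched$t_end, rows = rows,
           stems = vapply(rows, function(r) {
             paste(unlist(r, use.names = FALSE), collapse = "|")
           }, character(1)))
    })
    list(study_id = design$study_id, scheds = scheds, conds = conds,
         fold = design$normalization == "fold",
         control_i = match(design$control, conds),
         days = meas$day, markers = meas$marker, midx = midx,
         cidx = match(sdata$condition, conds), E = sdata$value)
  })
  function(theta, cache = NULL) {
    ctrl_key <- paste(theta[CTRL_PAR_NAMES], collapse = "|")
    T_d <- theta[["T_d"]]; M_t <- theta[["M_t"]]
    T_e_h <- M_t * T_d * 24
    a_es <- theta[["alpha_es"]]; a_ei <- theta[["alpha_ei"]]
    a_ls <- theta[["alpha_ls"]]; a_li <- theta[["alpha_li"]]
    if (isTRUE(swap_branches)) {
      tmp <- a_es; a_es <- a_ei; a_ei <- tmp
      tmp <- a_ls; a_ls <- a_li; a_li <- tmp
    }
    r0_h <- 1 / (T_d * 24)
    total <- 0; n_items <- 0
    for (u in units) {
      n_meas <- length(u$days)
      P <- matrix(NA_real_, length(u$conds), n_meas)
      b <- c(ALP = theta[["beta_ALP"]], OC = theta[["beta_OC"]],
             ARS = theta[["beta_ARS"]])
      nn <- c(ALP = theta[["n_ALP"]], OC = theta[["n_OC"]],
              ARS = theta[["n_ARS"]])
      kk <- vapply(u$markers, function(mk) {
        theta[[paste0("k_", mk, "_", u$study_id)]]
      }, numeric(1))
      for (ci in seq_along(u$conds)) {
        sc <- u$scheds[[ci]]
        nseg <- length(sc$t_start)
        f_e <- numeric(nseg); f_l <- numeric(nseg)
        for (s in seq_len(nseg)) {
          key <- paste0(sc$stems[s], "|", ctrl_key)
          hit <- if (!is.null(cache)) cache[[key]] else NULL
          if (is.null(hit)) {
            hit <- infer_rates_one(sc$rows[[s]], theta)
            if (!is.null(cache)) cache[[key]] <- hit
          }
          f_e[s] <- hit[[1]]; f_l[s] <- hit[[2]]
        }
        r_e_h <- pmax(0, 1 + 2 * ifelse(f_e > 0.5, a_es, a_ei) * (f_e - 0.5)) * r0_h
        r_l_h <- pmax(0, 1 + 2 * ifelse(f_l > 0.5, a_ls, a_li) * (f_l - 0.5)) * r0_h
        for (mi in seq_len(n_meas)) {
          if (switch_on == "time") {
            m <- maturity_time_based(u$days[mi] * 24, sc$t_start, sc$t_end,
                                     r_e_h, r_l_h, T_e_h)
          } else {
            sr <- list(t_start = sc$t_start, t_end = sc$t_end,
                       r_e = r_e_h * 24, r_l = r_l_h * 24)
            m <- maturity_exact(u$days[mi], sr, theta, switch_on)
          }
          mk <- u$markers[mi]
          x <- if (mk == "ALP") min(m, M_t) else m
          P[ci, mi] <- (x + b[[mk]])^nn[[mk]] * kk[[mi]]
        }
      }
      if (u$fold) {
        ctrl <- P[u$control_i, ]
        if (any(ctrl <= 0)) {
          stop("control condition predicts non-positive values", call. = FALSE)
        }
        P <- sweep(P, 2, ctrl, "/")
      }
      S <- P[cbind(u$cidx, u$midx)]
      total <- total + sum(pmax(0, 1 - abs(u$E - S) / u$E))
      n_items <- n_items + length(u$E)
    }
    total / n_items
  }
}

#' Differential-evolution settings
#'
#' Defaults: DE/rand/1/bin with mutation factor `F = 0.8`, crossover rate
#' `CR = 0.9`, population 15 and 200 generations.
#'
#' @param pop Population size (>= 4).
#' @param generations Number of generations.
#' @param F Differential weight in (0, 2].
#' @param CR Crossover probability in [0, 1].
#' @export
de_settings <- function(pop = 15, generations = 200, F = 0.8, CR = 0.9) {
  stopifnot(pop >= 4, generations >= 1, F > 0, F <= 2, CR >= 0, CR <= 1)
  list(pop = as.integer(pop), generations = as.integer(generations),
       F = F, CR = CR)
}

# transform to/from the DE search space (log10 for log-scale priors)
to_search <- function(x, scale) ifelse(scale == "log", log10(x), x)
from_search <- function(z, scale) ifelse(scale == "log", 10^z, z)

#' Maximize an objective with differential evolution
#'
#' DE/rand/1/bin over box priors: each generation every member is
#' challenged by a trial vector built from three distinct others
#' (`x_r1 + F * (x_r2 - x_r3)`, clipped to the bounds) with binomial
#' crossover, and replaced when the trial scores at least as high.
#' Log-scale priors are searched in log10 space. Reproducible for a fixed
#' seed.
#'
#' @param objective Function of a named parameter vector returning a scalar
#'   to maximize (e.g. from [calibration_objective()]).
#' @param priors Tibble with columns `name`, `lower`, `upper`, `scale`
#'   (subset of [parameter_priors()]).
#' @param settings A [de_settings()] list.
#' @param seed Integer seed.
#' @return A list of class `osteo_de_run` with elements `par` (named best
#'   vector), `fitness`, `seed` and `n_eval`.
#' @export
run_de <- function(objective, priors, settings = de_settings(), seed = 1) {
  stopifnot(all(c("name", "lower", "upper", "scale") %in% names(priors)),
            all(priors$lower < priors$upper))
  d <- nrow(priors)
  lo <- to_search(priors$lower, priors$scale)
  hi <- to_search(priors$upper, priors$scale)
  eval_member <- function(z) {
    par <- from_search(z, priors$scale)
    names(par) <- priors$name
    objective(par)
  }
  with_preserved_seed(seed, {
    np <- max(settings$pop, 4L)
    pop <- matrix(stats::runif(np * d, rep(lo, each = np), rep(hi, each = np)),
                  nrow = np)
    fit <- apply(pop, 1, eval_member)
    n_eval <- np
    for (gen in seq_len(settings$generations)) {
      for (i in seq_len(np)) {
        r <- sample(setdiff(seq_len(np), i), 3)
        mutant <- pop[r[1], ] + settings$F * (pop[r[2], ] - pop[r[3], ])
        mutant <- pmin(pmax(mutant, lo), hi)
        jrand <- sample.int(d, 1)
        cross <- stats::runif(d) < settings$CR
        cross[jrand] <- TRUE
        trial <- ifelse(cross, mutant, pop[i, ])
        f_trial <- eval_member(trial)
        n_eval <- n_eval + 1
        if (f_trial >= fit[i]) {
          pop[i, ] <- trial
          fit[i] <- f_trial
        }
      }
    }
    best <- which.max(fit)
    par <- from_search(pop[best, ], priors$scale)
    names(par) <- priors$name
    structure(list(par = par, fitness = fit[best], seed = seed,
                   n_eval = n_eval),
              class = "osteo_de_run")
  })
}

#' @export
print.osteo_de_run <- function(x, ...) {
  cat("<osteo_de_run: fitness ", format(x$fitness, digits = 4),
      " after ", x$n_eval, " evaluations (seed ", x$seed, ")>\n", sep = "")
  print(x$par)
  invisible(x)
}

#' Repeated differential-evolution calibration
#'
#' Because single DE runs land on different solutions, the calibration
#' protocol repeats the optimization `n_runs` times with consecutive seeds
#' and infers each parameter as the mean of the per-run bests. Convergence
#' of the repetition count is declared when, for every parameter, the means
#' of the first and second halves of the runs differ by at most `tolerance`
#' times the prior length (the half-split check).
#'
#' @param data Measurement tibble.
#' @param priors Prior tibble (rows define the calibrated subset); default
#'   the full registry priors.
#' @param settings A [de_settings()] list.
#' @param n_runs Number of repeated runs (>= 2). Odd counts split
#'   floor/ceiling.
#' @param base_seed Run `i` uses seed `base_seed + i - 1`.
#' @param tolerance Half-split tolerance as a fraction of each prior's
#'   length (default 0.05).
#' @inheritParams calibration_objective
#' @return An object of class `osteo_calibration`: a list with `runs` (one
#'   row per run: seed, best fitness, best parameters), `summary` (per
#'   parameter: mean, half-means, sd, relative half-gap), `converged`,
#'   `tolerance`, `settings` and `n_runs`. Use [generics::tidy()] /
#'   [generics::glance()] to extract tibbles.
#' @export
calibrate_repeated <- function(data, priors = parameter_priors(),
                               settings = de_settings(), n_runs = 20,
                               base_seed = 1, tolerance = 0.05,
                               base_theta = model_parameters(),
                               designs = builtin_designs(),
                               switch_on = "time", swap_branches = FALSE) {
  if (n_runs < 2) stop("n_runs must be at least 2 (half-split check)", call. = FALSE)
  objective <- calibration_objective(data, free = priors$name,
                                     base_theta = base_theta,
                                     designs = designs,
                                     switch_on = switch_on,
                                     swap_branches = swap_branches)
  runs <- purrr::map(seq_len(n_runs), function(i) {
    de <- run_de(objective, priors, settings, seed = base_seed + i - 1)
    tibble::tibble(run = i, seed = de$seed, fitness = de$fitness,
                   !!!as.list(de$par))
  })
  runs <- dplyr::bind_rows(runs)
  first_half <- seq_len(floor(n_runs / 2))
  par_mat <- as.matrix(runs[, priors$name, drop = FALSE])
  summary <- tibble::tibble(
    parameter = priors$name,
    mean = unname(colMeans(par_mat)),
    half1_mean = unname(colMeans(par_mat[first_half, , drop = FALSE])),
    half2_mean = unname(colMeans(par_mat[-first_half, , drop = FALSE])),
    sd = unname(apply(par_mat, 2, stats::sd)),
    lower = priors$lower,
    upper = priors$upper
  )
  summary$rel_gap <- abs(summary$half1_mean - summary$half2_mean) /
    (summary$upper - summary$lower)
  structure(list(runs = runs, summary = summary,
                 converged = all(summary$rel_gap <= tolerance),
                 tolerance = tolerance, settings = settings,
                 n_runs = n_runs, base_seed = base_seed),
            class = "osteo_calibration")
}

#' @export
print.osteo_calibration <- function(x, ...) {
  cat("<osteo_calibration: ", x$n_runs, " DE runs, mean best fitness ",
      format(mean(x$runs$fitness), digits = 4), ", half-split ",
      if (x$converged) "converged" else "NOT converged",
      " at tolerance ", x$tolerance, ">\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Inferred parameter registry from a calibration
#'
#' @param x An `osteo_calibration` object.
#' @param base_theta Registry supplying the uncalibrated entries.
#' @return A full [model_parameters()] registry with the calibrated entries
#'   replaced by their per-run means.
#' @export
calibrated_parameters <- function(x, base_theta = model_parameters()) {
  stopifnot(inherits(x, "osteo_calibration"))
  base_theta[x$summary$parameter] <- x$summary$mean
  structure(base_theta, class = "osteo_params")
}

#' Write a calibration summary and its provenance record
#'
#' Writes the per-parameter summary as CSV and a JSON provenance record
#' (settings, seeds, tolerance, data hash) sufficient to reproduce the run.
#'
#' @param x An `osteo_calibration` object.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @param data The measurement tibble the calibration used (hashed into the
#'   provenance record).
#' @return Invisibly, the provenance list.
#' @export
write_calibration <- function(x, csv_path, json_path = NULL, data = NULL) {
  stopifnot(inherits(x, "osteo_calibration"))
  if (!is.null(csv_path)) readr::write_csv(x$summary, csv_path)
  prov <- list(
    package = "osteofuzz",
    version = as.character(utils::packageVersion("osteofuzz")),
    n_runs = x$n_runs, base_seed = x$base_seed, seeds = x$runs$seed,
    tolerance = x$tolerance, settings = x$settings,
    converged = x$converged,
    mean_fitness = mean(x$runs$fitness),
    data_hash = if (!is.null(data)) {
      sum(as.numeric(utils::head(data$value, 1e4))) + nrow(data)
    }
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(prov, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(prov)
}
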