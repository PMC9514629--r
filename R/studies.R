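#' Study designs
#'
#' A study design bundles the experimental conditions (labelled treatment
#' schedules), the markers with their measurement days, the normalization
#' mode and the control condition of one cell-culture experiment.
#'
#' @param study_id Integer id.
#' @param conditions Named list of schedules (see [make_schedule()]); names
#'   are the condition labels.
#' @param measurements Data frame with columns `marker` and `day`.
#' @param normalization `"absolute"` or `"fold"` (fold-change over the
#'   control condition per marker and day).
#' @param control Label of the control condition.
#' @return An object of class `study_design`.
#' @export
study_design <- function(study_id, conditions, measurements,
                         normalization = c("absolute", "fold"),
                         control = names(conditions)[1]) {
  normalization <- match.arg(normalization)
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    stop("conditions must be a named list of schedules", call. = FALSE)
  }
  if (!control %in% names(conditions)) {
    stop(sprintf("control condition '%s' is not among the conditions", control),
         call. = FALSE)
  }
  measurements <- tibble::as_tibble(measurements)
  stopifnot(all(c("marker", "day") %in% names(measurements)))
  if (any(measurements$day <= 0)) stop("measurement days must be positive", call. = FALSE)
  conditions <- lapply(conditions, make_schedule)
  horizon <- min(vapply(conditions, function(s) max(s$t_end), numeric(1)))
  if (max(measurements$day) * 24 > horizon + 1e-9) {
    stop("measurement days exceed the schedule horizon", call. = FALSE)
  }
  structure(list(study_id = as.integer(study_id), conditions = conditions,
                 measurements = measurements, normalization = normalization,
                 control = control),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design ", x$study_id, ": ", length(x$conditions),
      " conditions (control '", x$control, "'), ",
      nrow(x$measurements), " marker-day measurements, ",
      x$normalization, " reporting>\n", sep = "")
  invisible(x)
}

#' The five built-in cell-culture study designs
#'
#' Encodings of the five published experiments the model is calibrated
#' against:
#' * Study 1 - Mg2+ at 0.08, 0.8 and 8 mM, ALP at days 3 and 7 (control
#'   0.08 mM).
#' * Study 2 - Mg2+ at 0.8 and 5 mM, ALP at day 7 and OC at day 21.
#' * Study 3 - IL-10 at 0.1/1/10 ng/ml and TNF-alpha at 1/10/100 ng/ml
#'   applied for 48 h; ALP at day 14, ARS at day 21.
#' * Study 4 - IL-10 at 0.1/1/10/100 ng/ml applied for 48 h; ALP at day 3
#'   and ARS at day 9, reported as fold over the undifferentiated control.
#' * Study 5 - IL-8 at 10/100 ng/ml, IL-1beta at 10 ng/ml and the combined
#'   IL-8 100 + IL-1beta 10 ng/ml condition, applied continuously; ALP at
#'   day 9.
#'
#' @return A named list of five [study_design()] objects
#'   (`study1` .. `study5`).
#' @export
builtin_designs <- function() {
  list(
    study1 = study_design(
      1L,
      conditions = list(
        "mg_0.08" = constant_schedule(7 * 24, mg = 0.08),
        "mg_0.8"  = constant_schedule(7 * 24, mg = 0.8),
        "mg_8"    = constant_schedule(7 * 24, mg = 8)
      ),
      measurements = tibble::tibble(marker = "ALP", day = c(3, 7)),
      control = "mg_0.08"
    ),
    study2 = study_design(
      2L,
      conditions = list(
        "mg_0.8" = constant_schedule(21 * 24, mg = 0.8),
        "mg_5"   = constant_schedule(21 * 24, mg = 5)
      ),
      measurements = tibble::tibble(marker = c("ALP", "OC"), day = c(7, 21)),
      control = "mg_0.8"
    ),
    study3 = study_design(
      3L,
      conditions = list(
        "control"  = constant_schedule(21 * 24),
        "il10_0.1" = pulse_schedule(21 * 24, 48, il10 = 0.1),
        "il10_1"   = pulse_schedule(21 * 24, 48, il10 = 1),
        "il10_10"  = pulse_schedule(21 * 24, 48, il10 = 10),
        "tnf_1"    = pulse_schedule(21 * 24, 48, tnf = 1),
        "tnf_10"   = pulse_schedule(21 * 24, 48, tnf = 10),
        "tnf_100"  = pulse_schedule(21 * 24, 48, tnf = 100)
      ),
      measurements = tibble::tibble(marker = c("ALP", "ARS"), day = c(14, 21)),
      control = "control"
    ),
    study4 = study_design(
      4L,
      conditions = list(
        "ctr"       = constant_schedule(9 * 24),
        "il10_0.1"  = pulse_schedule(9 * 24, 48, il10 = 0.1),
        "il10_1"    = pulse_schedule(9 * 24, 48, il10 = 1),
        "il10_10"   = pulse_schedule(9 * 24, 48, il10 = 10),
        "il10_100"  = pulse_schedule(9 * 24, 48, il10 = 100)
      ),
      measurements = tibble::tibble(marker = c("ALP", "ARS"), day = c(3, 9)),
      normalization = "fold",
      control = "ctr"
    ),
    study5 = study_design(
      5L,
      conditions = list(
        "control"           = constant_schedule(9 * 24),
        "il8_10"            = constant_schedule(9 * 24, il8 = 10),
        "il8_100"           = constant_schedule(9 * 24, il8 = 100),
        "il1b_10"           = constant_schedule(9 * 24, il1b = 10),
        "il8_100_il1b_10"   = constant_schedule(9 * 24, il8 = 100, il1b = 10)
      ),
      measurements = tibble::tibble(marker = "ALP", day = 9),
      control = "control"
    )
  )
}

#' Simulate one study design
#'
#' Runs the full model (controller, maturity integration, marker mapping)
#' for every condition of a design and returns one predicted value per
#' (condition, marker, day). For fold-reporting designs each prediction is
#' divided by the control condition's value at the same marker and day, so
#' the control reports 1 by construction.
#'
#' @param design A [study_design()].
#' @param theta A [model_parameters()] registry.
#' @param switch_on Phase-switch criterion, see [integrate_maturity()].
#' @inheritParams scale_rate
#' @param cache Optional environment memoising fuzzy controller evaluations
#'   across repeated calls (used by calibration).
#' @return A tibble with columns `study_id`, `condition`, `marker`, `day`,
#'   `predicted`.
#' @examples
#' simulate_study(builtin_designs()$study1, model_parameters())
#' @export
simulate_study <- function(design, theta = model_parameters(),
                           switch_on = "time", swap_branches = FALSE,
                           cache = NULL) {
  stopifnot(inherits(design, "study_design"))
  per_cond <- purrr::imap(design$conditions, function(sched, label) {
    seg_rates <- schedule_rates(sched, theta, cache = cache,
                                swap_branches = swap_branches)
    mat <- maturity_exact(design$measurements$day, seg_rates, theta,
                          switch_on = switch_on)
    tibble::tibble(
      study_id = design$study_id,
      condition = label,
      marker = design$measurements$marker,
      day = design$measurements$day,
      predicted = purrr::map2_dbl(mat, design$measurements$marker, function(m, mk) {
        marker_value(m, mk, design$study_id, theta)
      })
    )
  })
  out <- dplyr::bind_rows(per_cond)
  if (design$normalization == "fold") {
    ctrl <- out[out$condition == design$control,
                c("marker", "day", "predicted")]
    names(ctrl)[3] <- "control_value"
    if (any(ctrl$control_value <= 0)) {
      stop("control condition predicts non-positive values; cannot fold-normalize",
           call. = FALSE)
    }
    out <- dplyr::left_join(out, ctrl, by = c("marker", "day"))
    out$predicted <- out$predicted / out$control_value
    out$control_value <- NULL
  }
  out
}

#' Simulate all designs
#'
#' @param designs List of [study_design()] objects, default the five
#'   built-in designs.
#' @inheritParams simulate_study
#' @return A tibble of predictions for all designs, as in
#'   [simulate_study()].
#' @export
simulate_studies <- function(designs = builtin_designs(),
                             theta = model_parameters(),
                             switch_on = "time", swap_branches = FALSE,
                             cache = NULL) {
  dplyr::bind_rows(lapply(designs, simulate_study, theta = theta,
                          switch_on = switch_on, swap_branches = swap_branches,
                          cache = cache))
}

# canonical measurement CSV header (exact order)
MEASUREMENT_COLUMNS <- c("study_id", "marker", "day", "condition", "mg_mM",
                         "tnf_ng_ml", "il10_ng_ml", "il8_ng_ml",
                         "il1b_ng_ml", "exposure_h", "value", "sd",
                         "normalization")

# condition metadata (treatment concentrations and application duration)
# taken from the first segment of the condition's schedule
condition_metadata <- function(design) {
  purrr::imap_dfr(design$conditions, function(sched, label) {
    tibble::tibble(
      study_id = design$study_id, condition = label,
      mg_mM = sched$mg[1], tnf_ng_ml = sched$tnf[1],
      il10_ng_ml = sched$il10[1], il8_ng_ml = sched$il8[1],
      il1b_ng_ml = sched$il1b[1], exposure_h = sched$t_end[1] - sched$t_start[1]
    )
  })
}

#' Generate synthetic measurements
#'
#' Simulates all designs under a generating parameter set and perturbs each
#' predicted value with multiplicative lognormal noise of a given
#' coefficient of variation (mean-one noise; `noise_cv = 0` returns the
#' model predictions exactly). This replaces the empirical values of the
#' original experiments, which were published only as figure bars, and is
#' the input for parameter-recovery experiments.
#'
#' @param theta_true Generating [model_parameters()] registry.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0); the default 0.1 is a typical between-replicate spread for
#'   colorimetric ALP/ARS assays.
#' @param seed Integer seed; output is deterministic for a fixed seed.
#' @param designs List of [study_design()] objects.
#' @return A tibble in the measurement schema (see [read_measurements()]):
#'   one row per (study, condition, marker, day) with columns `value` and
#'   `sd` (`sd = noise_cv * value`).
#' @export
generate_synthetic <- function(theta_true = model_parameters(),
                               noise_cv = 0.1, seed = 1,
                               designs = builtin_designs()) {
  if (!is.numeric(noise_cv) || noise_cv < 0) {
    stop("noise_cv must be >= 0", call. = FALSE)
  }
  preds <- simulate_studies(designs, theta_true)
  meta <- dplyr::bind_rows(lapply(designs, condition_metadata))
  norm <- tibble::tibble(
    study_id = vapply(designs, `[[`, integer(1), "study_id"),
    normalization = vapply(designs, `[[`, character(1), "normalization")
  )
  out <- preds |>
    dplyr::left_join(meta, by = c("study_id", "condition")) |>
    dplyr::left_join(norm, by = "study_id")
  noise <- with_preserved_seed(seed, {
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      stats::rlnorm(nrow(out), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      rep(1, nrow(out))
    }
  })
  out$value <- out$predicted * noise
  out$sd <- noise_cv * out$value
  out$predicted <- NULL
  out[, MEASUREMENT_COLUMNS]
}

# evaluate expr under set.seed(seed) without disturbing the caller's RNG
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Read and write measurement tables
#'
#' Measurement CSVs use the fixed header `study_id, marker, day, condition,
#' mg_mM, tnf_ng_ml, il10_ng_ml, il8_ng_ml, il1b_ng_ml, exposure_h, value,
#' sd, normalization`. Reading validates the schema and reports the first
#' offending row: values must be positive, standard deviations
#' non-negative, markers one of ALP/OC/ARS.
#'
#' @param path File path.
#' @return `read_measurements()`: a tibble of measurement items.
#' @export
read_measurements <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  missing <- setdiff(MEASUREMENT_COLUMNS, trimws(gsub('"', "", header)))
  if (length(missing) > 0) {
    stop(sprintf("measurement file is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          study_id = "i", marker = "c", day = "d",
                          condition = "c", mg_mM = "d", tnf_ng_ml = "d",
                          il10_ng_ml = "d", il8_ng_ml = "d", il1b_ng_ml = "d",
                          exposure_h = "d", value = "d", sd = "d",
                          normalization = "c"
                        ))
  missing <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop(sprintf("measurement file is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- tibble::as_tibble(df)[, MEASUREMENT_COLUMNS]
  if (nrow(df) == 0) return(df)
  check_row <- function(cond, what) {
    bad <- which(cond)
    if (length(bad) > 0) {
      stop(sprintf("measurement schema error in row %d: %s", bad[1], what),
           call. = FALSE)
    }
  }
  check_row(!df$marker %in% c("ALP", "OC", "ARS"),
            "marker must be one of ALP, OC, ARS")
  check_row(!is.finite(df$value) | df$value <= 0, "value must be positive")
  check_row(!is.finite(df$sd) | df$sd < 0, "sd must be non-negative")
  check_row(!is.finite(df$day) | df$day <= 0, "day must be positive")
  check_row(!df$normalization %in% c("absolute", "fold"),
            "normalization must be 'absolute' or 'fold'")
  df
}

#' @rdname read_measurements
#' @param items Measurement tibble in the schema above.
#' @export
write_measurements <- function(items, path) {
  missing <- setdiff(MEASUREMENT_COLUMNS, names(items))
  if (length(missing) > 0) {
    stop(sprintf("measurement table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  readr::write_csv(items[, MEASUREMENT_COLUMNS], path)
  invisible(path)
}
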