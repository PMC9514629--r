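# Cytokine axes are fuzzified on a log10 scale because their anchors span
# four decades (0.01-100 ng/ml); Mg is fuzzified on a linear mM axis.
# A zero concentration maps to the lower domain boundary of the log axis.
LOG_DOMAIN <- c(-3, 3)

conc_to_log <- function(x) {
  z <- ifelse(x <= 10^LOG_DOMAIN[1], LOG_DOMAIN[1], log10(x))
  pmin(pmax(z, LOG_DOMAIN[1]), LOG_DOMAIN[2])
}

#' Cellular input signals
#'
#' Builds a tibble of cellular input states, one row per condition: the
#' extracellular Mg2+ concentration, the four cytokine concentrations and
#' the cumulative IL-10 exposure time. IL-10 exposure at or below 48 h
#' selects the short-term membership set; longer exposure the long-term set.
#'
#' @param mg Mg2+ concentration, mM (physiological 0.8).
#' @param tnf,il10,il8,il1b Cytokine concentrations, ng/ml.
#' @param il10_exposure Cumulative IL-10 application time, hours.
#' @return A tibble with one row per input combination (inputs are recycled
#'   to a common length).
#' @examples
#' cell_inputs(mg = c(0.08, 0.8, 8))
#' @export
cell_inputs <- function(mg = 0.8, tnf = 0, il10 = 0, il8 = 0, il1b = 0,
                        il10_exposure = 0) {
  out <- tibble::tibble(mg = mg, tnf = tnf, il10 = il10, il8 = il8,
                        il1b = il1b, il10_exposure = il10_exposure)
  bad <- vapply(out, function(v) any(!is.finite(v) | v < 0), logical(1))
  if (any(bad)) {
    stop(sprintf("inputs must be finite and non-negative: %s",
                 paste(names(out)[bad], collapse = ", ")), call. = FALSE)
  }
  out
}

#' Input linguistic variables of the osteogenesis controller
#'
#' Construct the five input variables. Mg2+ carries six levels (Inhibitory
#' ED below physiological, Physiological at 0.8 mM, Stimulatory peaking at
#' `p_ms`, Ineffective as the Stimulatory-to-Inhibitory transition around
#' `p_md`, Inhibitory LD above 1.8 mM, Destructive above 20 mM). TNF-alpha
#' is Stimulatory at 1, Ineffective (neutral) at 10 and Inhibitory at
#' 100 ng/ml. IL-10 has two exposure-dependent membership sets: for
#' applications up to 48 h the stimulatory degree rises steadily from 0 to
#' 10 ng/ml; beyond 48 h it peaks at 0.1 ng/ml and 10 ng/ml or more is
#' inhibitory. IL-8 is increasingly stimulatory up to 100 ng/ml with a
#' Favorable intermediate peaking at `p_8f`; IL-1beta is stimulatory at low
#' doses with peak `p_1bs` and support ending at `p_1bie`.
#'
#' @param theta An [model_parameters()] registry (only the anchor entries
#'   are used).
#' @param exposure_h IL-10 cumulative exposure in hours (selects the
#'   membership set).
#' @return A [fz_variable()].
#' @export
build_mg_variable <- function(theta = model_parameters()) {
  p_ms <- theta[["p_ms"]]; p_md <- theta[["p_md"]]
  if (p_md <= p_ms) stop("p_md must exceed p_ms", call. = FALSE)
  fz_variable(
    "mg", 0, 30, units = "mM",
    levels = list(
      "Inhibitory ED"  = mf_trapezoidal(0, 0, 0.08, 0.8),
      "Physiological"  = mf_triangular(0.08, 0.8, 2),
      "Stimulatory"    = mf_triangular(0.8, p_ms, p_md),
      "Ineffective"    = mf_triangular(p_ms, p_md, 20),
      "Inhibitory LD"  = mf_trapezoidal(1.8, 5, 18, 24),
      "Destructive"    = mf_trapezoidal(15, 20, 30, 30)
    )
  )
}

#' @rdname build_mg_variable
#' @export
build_tnf_variable <- function() {
  fz_variable(
    "tnf", LOG_DOMAIN[1], LOG_DOMAIN[2], units = "log10 ng/ml",
    levels = list(
      "Negligible"  = mf_trapezoidal(-3, -3, -1, 0),
      "Stimulatory" = mf_triangular(-1, 0, 1),
      "Ineffective" = mf_triangular(0, 1, 2),
      "Inhibitory"  = mf_trapezoidal(1, 2, 3, 3)
    )
  )
}

#' @rdname build_mg_variable
#' @export
build_il10_variable <- function(exposure_h = 0) {
  if (!is.numeric(exposure_h) || length(exposure_h) != 1L || exposure_h < 0) {
    stop("exposure_h must be a single non-negative number", call. = FALSE)
  }
  if (exposure_h <= 48) {
    levels <- list(
      "Negligible"  = mf_trapezoidal(-3, -3, -2, -1),
      "Favorable"   = mf_triangular(-2, -1, 1),
      "Stimulatory" = mf_trapezoidal(-2, 1, 3, 3),
      "Inhibitory"  = mf_trapezoidal(1, 2, 3, 3)
    )
  } else {
    levels <- list(
      "Negligible"  = mf_trapezoidal(-3, -3, -2.5, -2),
      "Favorable"   = mf_triangular(-2.5, -1.75, -1),
      "Stimulatory" = mf_triangular(-2, -1, 1),
      "Inhibitory"  = mf_trapezoidal(-1, 1, 3, 3)
    )
  }
  fz_variable("il10", LOG_DOMAIN[1], LOG_DOMAIN[2],
              units = "log10 ng/ml", levels = levels)
}

#' @rdname build_mg_variable
#' @export
build_il8_variable <- function(theta = model_parameters()) {
  z8f <- conc_to_log(theta[["p_8f"]])
  fz_variable(
    "il8", LOG_DOMAIN[1], LOG_DOMAIN[2], units = "log10 ng/ml",
    levels = list(
      "Negligible"  = mf_trapezoidal(-3, -3, -1, 0),
      "Favorable"   = mf_triangular(-1, z8f, max(2, z8f)),
      "Stimulatory" = mf_trapezoidal(z8f, 2, 3, 3)
    )
  )
}

#' @rdname build_mg_variable
#' @export
build_il1b_variable <- function(theta = model_parameters()) {
  zs <- conc_to_log(theta[["p_1bs"]]); ze <- conc_to_log(theta[["p_1bie"]])
  if (ze <= zs) stop("p_1bie must exceed p_1bs", call. = FALSE)
  fz_variable(
    "il1b", LOG_DOMAIN[1], LOG_DOMAIN[2], units = "log10 ng/ml",
    levels = list(
      "Negligible"  = mf_trapezoidal(-3, -3, -1, 0),
      "Stimulatory" = mf_triangular(-1, zs, ze),
      "Ineffective" = mf_trapezoidal(zs, ze, 3, 3)
    )
  )
}

# Output variables: Gaussian levels (activation 1, sigma 0.05) on [0, 1],
# 0.5 is the physiological rate. The early-differentiation variable carries
# six levels; "Arrested" (center 0.05) is never referenced by rules and only
# completes the stated level count. The Extremely-fast center is fixed at
# 0.95 and the fifth late-differentiation level ("Very fast") at 0.85; only
# the Slow/Fast(/Very-fast) centers are free parameters.
OUTPUT_SIGMA <- 0.05

build_ed_variable <- function(theta = model_parameters()) {
  fz_variable(
    "ed", 0, 1, units = "rate",
    levels = list(
      "Arrested"       = mf_gaussian(0.05, OUTPUT_SIGMA),
      "Slow"           = mf_gaussian(theta[["p_es"]], OUTPUT_SIGMA),
      "Physiological"  = mf_gaussian(0.5, OUTPUT_SIGMA),
      "Fast"           = mf_gaussian(theta[["p_ef"]], OUTPUT_SIGMA),
      "Very fast"      = mf_gaussian(theta[["p_evf"]], OUTPUT_SIGMA),
      "Extremely fast" = mf_gaussian(0.95, OUTPUT_SIGMA)
    )
  )
}

build_ld_variable <- function(theta = model_parameters()) {
  fz_variable(
    "ld", 0, 1, units = "rate",
    levels = list(
      "Arrested"      = mf_gaussian(0.05, OUTPUT_SIGMA),
      "Slow"          = mf_gaussian(theta[["p_ls"]], OUTPUT_SIGMA),
      "Physiological" = mf_gaussian(0.5, OUTPUT_SIGMA),
      "Fast"          = mf_gaussian(theta[["p_lf"]], OUTPUT_SIGMA),
      "Very fast"     = mf_gaussian(0.85, OUTPUT_SIGMA)
    )
  )
}

#' The osteogenic rule base
#'
#' Encodes the fuzzy rules linking the five inputs to the early (ED) and
#' late (LD) differentiation rates. Disjunctive table rows ("any of") are
#' expanded into one rule per alternative; under min-AND/max-aggregation
#' this is equivalent to an OR within the slot. "Not Negligible" clauses use
#' the standard complement. The IL-1beta antagonism of IL-8 is encoded by
#' gating the Extremely-fast response on IL-1beta being Negligible: when
#' both cytokines are present the response saturates at Very fast instead.
#'
#' @return List of [fz_rule()] objects.
#' @export
build_rule_base <- function() {
  rules <- list()
  add <- function(...) rules[[length(rules) + 1L]] <<- fz_rule(...)

  # --- early differentiation ---
  add("ed", "Slow", fz_clause("tnf", "Inhibitory"))
  add("ed", "Slow", fz_clause("il10", "Inhibitory"))
  add("ed", "Slow", fz_clause("mg", "Inhibitory ED"))
  add("ed", "Slow", fz_clause("mg", "Destructive"))
  # Physiological: conjunction with per-slot alternatives, expanded cartesian
  for (tnf_lv in c("Negligible", "Ineffective"))
    for (il1b_lv in c("Negligible", "Ineffective"))
      for (mg_lv in c("Physiological", "Ineffective"))
        add("ed", "Physiological",
            fz_clause("tnf", tnf_lv), fz_clause("il10", "Negligible"),
            fz_clause("il8", "Negligible"), fz_clause("il1b", il1b_lv),
            fz_clause("mg", mg_lv))
  add("ed", "Fast", fz_clause("tnf", "Stimulatory"))
  add("ed", "Fast", fz_clause("il10", "Favorable"))
  add("ed", "Fast", fz_clause("mg", "Stimulatory"))
  add("ed", "Very fast", fz_clause("il10", "Stimulatory"))
  add("ed", "Very fast",
      fz_clause("il8", "Favorable"), fz_clause("il1b", "Negligible"))
  add("ed", "Very fast",
      fz_clause("il8", "Negligible"), fz_clause("il1b", "Stimulatory"))
  add("ed", "Very fast",
      fz_clause("il8", "Negligible", negated = TRUE),
      fz_clause("il1b", "Negligible", negated = TRUE))
  add("ed", "Extremely fast",
      fz_clause("il8", "Stimulatory"), fz_clause("il1b", "Negligible"))

  # --- late differentiation ---
  add("ld", "Slow", fz_clause("tnf", "Inhibitory"))
  add("ld", "Slow", fz_clause("il10", "Inhibitory"))
  add("ld", "Slow", fz_clause("mg", "Inhibitory LD"))
  add("ld", "Slow", fz_clause("mg", "Destructive"))
  for (tnf_lv in c("Negligible", "Ineffective"))
    add("ld", "Physiological",
        fz_clause("tnf", tnf_lv), fz_clause("il10", "Negligible"),
        fz_clause("mg", "Inhibitory LD", negated = TRUE))
  add("ld", "Fast", fz_clause("tnf", "Stimulatory"))
  add("ld", "Fast", fz_clause("il10", "Favorable"))
  add("ld", "Very fast", fz_clause("il10", "Stimulatory"))

  rules
}

#' Assemble the osteogenesis fuzzy controller
#'
#' @param theta A [model_parameters()] registry.
#' @param exposure_h IL-10 cumulative exposure (hours); selects the IL-10
#'   membership set.
#' @return A list with the input variables, the output variables and the
#'   rule base, of class `osteo_controller`.
#' @export
osteo_controller <- function(theta = model_parameters(), exposure_h = 0) {
  structure(list(
    inputs = list(
      mg   = build_mg_variable(theta),
      tnf  = build_tnf_variable(),
      il10 = build_il10_variable(exposure_h),
      il8  = build_il8_variable(theta),
      il1b = build_il1b_variable(theta)
    ),
    outputs = list(ed = build_ed_variable(theta), ld = build_ld_variable(theta)),
    rules = build_rule_base(),
    exposure_h = exposure_h
  ), class = "osteo_controller")
}

# crisp rates for one input row (list/1-row data frame with mg..il10_exposure)
infer_rates_one <- function(row, theta) {
  ctrl <- osteo_controller(theta, exposure_h = row$il10_exposure)
  degs <- list(
    mg   = fuzzify(ctrl$inputs$mg, row$mg),
    tnf  = fuzzify(ctrl$inputs$tnf, conc_to_log(row$tnf)),
    il10 = fuzzify(ctrl$inputs$il10, conc_to_log(row$il10)),
    il8  = fuzzify(ctrl$inputs$il8, conc_to_log(row$il8)),
    il1b = fuzzify(ctrl$inputs$il1b, conc_to_log(row$il1b))
  )
  agg <- apply_rules(ctrl$rules, degs)
  if (is.null(agg$ed) || is.null(agg$ld)) {
    stop("rule base does not cover this input state", call. = FALSE)
  }
  c(f_e = defuzzify_centroid(ctrl$outputs$ed, agg$ed),
    f_l = defuzzify_centroid(ctrl$outputs$ld, agg$ld))
}

#' Fuzzy early and late differentiation rates
#'
#' Runs the full Mamdani pipeline (fuzzification, rule evaluation, centroid
#' defuzzification) for each row of a signal table and appends the crisp
#' fuzzy rates `f_e` and `f_l`, both in `[0, 1]` with 0.5 denoting the
#' physiological rate.
#'
#' @param signals A data frame with columns `mg`, `tnf`, `il10`, `il8`,
#'   `il1b` and optionally `il10_exposure` (default 0 h), e.g. from
#'   [cell_inputs()].
#' @param theta A [model_parameters()] registry.
#' @return The input as a tibble with numeric columns `f_e` and `f_l` added.
#' @examples
#' infer_rates(cell_inputs(mg = c(0.8, 6)))
#' @export
infer_rates <- function(signals, theta = model_parameters()) {
  stopifnot(is.data.frame(signals))
  needed <- c("mg", "tnf", "il10", "il8", "il1b")
  missing <- setdiff(needed, names(signals))
  if (length(missing) > 0) {
    stop(sprintf("signals is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  signals <- tibble::as_tibble(signals)
  if (!"il10_exposure" %in% names(signals)) signals$il10_exposure <- 0
  rates <- purrr::map(seq_len(nrow(signals)), function(i) {
    infer_rates_one(as.list(signals[i, ]), theta)
  })
  signals$f_e <- vapply(rates, `[[`, numeric(1), "f_e")
  signals$f_l <- vapply(rates, `[[`, numeric(1), "f_l")
  signals
}
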