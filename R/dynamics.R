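#' Scale a fuzzy rate to a physical rate multiplier
#'
#' Piecewise-linear scaling of a fuzzy rate `x` in `[0, 1]` around the
#' physiological point 0.5: `S(x) = 1 + 2 * alpha_s * (x - 0.5)` on the
#' stimulatory branch (`x > 0.5`) and `1 + 2 * alpha_i * (x - 0.5)` on the
#' inhibitory branch (`x <= 0.5`). `S(0.5) = 1` on both branches and the
#' result is clamped at 0 from below (a differentiation rate cannot be
#' negative).
#'
#' @param x Fuzzy rate(s) in `[0, 1]`.
#' @param alpha_s,alpha_i Stimulatory/inhibitory sensitivity coefficients
#'   (>= 0).
#' @param swap_branches If `TRUE`, attach `alpha_s` to the `x <= 0.5` branch
#'   instead (the transposed reading of the scaling rule); default `FALSE`.
#' @return Numeric vector of non-negative rate multipliers.
#' @examples
#' scale_rate(c(0, 0.5, 1), alpha_s = 0.4, alpha_i = 0.6)
#' @export
scale_rate <- function(x, alpha_s, alpha_i, swap_branches = FALSE) {
  if (any(!is.finite(x)) || any(x < 0 | x > 1)) {
    stop("fuzzy rate x must lie in [0, 1]", call. = FALSE)
  }
  if (isTRUE(swap_branches)) {
    tmp <- alpha_s; alpha_s <- alpha_i; alpha_i <- tmp
  }
  a <- ifelse(x > 0.5, alpha_s, alpha_i)
  pmax(0, 1 + 2 * a * (x - 0.5))
}

#' Physical differentiation rates
#'
#' Converts crisp fuzzy rates into physical early/late differentiation
#' rates: `r_e = r_0 * S(f_e)`, `r_l = r_0 * S(f_l)` with the physiological
#' rate `r_0 = 1 / T_d` (per day).
#'
#' @param rates A data frame with columns `f_e` and `f_l` (e.g. from
#'   [infer_rates()]).
#' @param theta A [model_parameters()] registry.
#' @inheritParams scale_rate
#' @return The input tibble with columns `r_e` and `r_l` (1/day) added.
#' @export
physical_rates <- function(rates, theta = model_parameters(),
                           swap_branches = FALSE) {
  stopifnot(is.data.frame(rates), all(c("f_e", "f_l") %in% names(rates)))
  r0 <- 1 / theta[["T_d"]]
  rates <- tibble::as_tibble(rates)
  rates$r_e <- r0 * scale_rate(rates$f_e, theta[["alpha_es"]],
                               theta[["alpha_ei"]], swap_branches)
  rates$r_l <- r0 * scale_rate(rates$f_l, theta[["alpha_ls"]],
                               theta[["alpha_li"]], swap_branches)
  rates
}

#' Treatment schedules
#'
#' A schedule is a tibble of contiguous, non-overlapping segments covering
#' `[0, horizon]` hours, each with constant signal concentrations.
#' `make_schedule()` validates an existing segment table;
#' `constant_schedule()` builds a one-segment schedule and
#' `pulse_schedule()` a treatment pulse followed by reversion to baseline
#' conditions (physiological Mg 0.8 mM, cytokines 0 ng/ml).
#'
#' @param segments Data frame with columns `t_start`, `t_end` (hours) and
#'   `mg`, `tnf`, `il10`, `il8`, `il1b` (concentrations).
#' @return A tibble of schedule segments.
#' @export
make_schedule <- function(segments) {
  needed <- c("t_start", "t_end", "mg", "tnf", "il10", "il8", "il1b")
  missing <- setdiff(needed, names(segments))
  if (length(missing) > 0) {
    stop(sprintf("schedule is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  segments <- tibble::as_tibble(segments)[, needed]
  segments <- segments[order(segments$t_start), ]
  if (nrow(segments) == 0 || segments$t_start[1] != 0) {
    stop("schedule must start at t = 0", call. = FALSE)
  }
  if (any(segments$t_end <= segments$t_start)) {
    stop("schedule segments must have positive duration", call. = FALSE)
  }
  if (nrow(segments) > 1 &&
      any(abs(segments$t_start[-1] - segments$t_end[-nrow(segments)]) > 1e-9)) {
    stop("schedule segments must be contiguous and non-overlapping",
         call. = FALSE)
  }
  segments
}

#' @rdname make_schedule
#' @param horizon_h Total schedule length, hours.
#' @param mg,tnf,il10,il8,il1b Constant concentrations for the schedule (or
#'   the pulse).
#' @export
constant_schedule <- function(horizon_h, mg = 0.8, tnf = 0, il10 = 0,
                              il8 = 0, il1b = 0) {
  make_schedule(tibble::tibble(t_start = 0, t_end = horizon_h, mg = mg,
                               tnf = tnf, il10 = il10, il8 = il8, il1b = il1b))
}

#' @rdname make_schedule
#' @param pulse_h Duration of the treatment pulse, hours; afterwards the
#'   signals revert to baseline until `horizon_h`.
#' @export
pulse_schedule <- function(horizon_h, pulse_h, mg = 0.8, tnf = 0, il10 = 0,
                           il8 = 0, il1b = 0) {
  if (pulse_h >= horizon_h) {
    return(constant_schedule(horizon_h, mg, tnf, il10, il8, il1b))
  }
  make_schedule(tibble::tibble(
    t_start = c(0, pulse_h), t_end = c(pulse_h, horizon_h),
    mg = c(mg, 0.8), tnf = c(tnf, 0), il10 = c(il10, 0),
    il8 = c(il8, 0), il1b = c(il1b, 0)
  ))
}

# Fuzzy + physical rates per schedule segment, as a plain list (fast path
# used inside optimization loops). IL-10 exposure entering a segment is the
# accumulated time IL-10 was applied in earlier segments. `cache` is an
# optional environment memoising fuzzy rates across calls that share
# controller parameters (used heavily during calibration).
seg_rates_core <- function(sched, theta, cache = NULL, swap_branches = FALSE) {
  n <- length(sched$t_start)
  dur <- sched$t_end - sched$t_start
  il10_on <- as.numeric(sched$il10 > 0) * dur
  exposure <- c(0, cumsum(il10_on))[seq_len(n)]
  f_e <- numeric(n); f_l <- numeric(n)
  ctrl_par <- theta[c("p_ms", "p_md", "p_8f", "p_1bs", "p_1bie",
                      "p_es", "p_ef", "p_evf", "p_ls", "p_lf")]
  for (i in seq_len(n)) {
    row <- list(mg = sched$mg[i], tnf = sched$tnf[i], il10 = sched$il10[i],
                il8 = sched$il8[i], il1b = sched$il1b[i],
                il10_exposure = exposure[i])
    key <- paste(c(unlist(row, use.names = FALSE), ctrl_par), collapse = "|")
    hit <- if (!is.null(cache)) cache[[key]] else NULL
    if (is.null(hit)) {
      hit <- infer_rates_one(row, theta)
      if (!is.null(cache)) cache[[key]] <- hit
    }
    f_e[i] <- hit[[1]]; f_l[i] <- hit[[2]]
  }
  r0 <- 1 / theta[["T_d"]]
  list(t_start = sched$t_start, t_end = sched$t_end,
       il10_exposure = exposure, f_e = f_e, f_l = f_l,
       r_e = r0 * scale_rate(f_e, theta[["alpha_es"]], theta[["alpha_ei"]],
                             swap_branches),
       r_l = r0 * scale_rate(f_l, theta[["alpha_ls"]], theta[["alpha_li"]],
                             swap_branches))
}

schedule_rates <- function(sched, theta, cache = NULL, swap_branches = FALSE) {
  core <- seg_rates_core(sched, theta, cache, swap_branches)
  out <- tibble::as_tibble(sched)
  for (col in c("il10_exposure", "f_e", "f_l", "r_e", "r_l")) {
    out[[col]] <- core[[col]]
  }
  out
}

# Piecewise-exact maturity at given times (days). Rates are constant within
# each schedule segment, so the trajectory is piecewise linear; the early
# phase ends at T_e = M_t * T_d (time criterion, default) or when maturity
# first reaches M_t (maturity criterion). Maturity is clamped to [0, 1]
# (rates are non-negative, so min(1, integral) is the clamped trajectory).
maturity_exact <- function(days, seg_rates, theta, switch_on = c("time", "maturity")) {
  switch_on <- match.arg(switch_on)
  M_t <- theta[["M_t"]]; T_d <- theta[["T_d"]]
  r_e_h <- seg_rates$r_e / 24  # per hour
  r_l_h <- seg_rates$r_l / 24
  n_seg <- length(seg_rates$t_start)
  horizon <- seg_rates$t_end[n_seg]
  bounds <- c(seg_rates$t_start, horizon)
  T_e_h <- M_t * T_d * 24
  if (switch_on == "time" && T_e_h > 0 && T_e_h < horizon) {
    bounds <- sort(unique(c(bounds, T_e_h)))
  }
  # walk intervals accumulating maturity; record (t, maturity) knots
  knots_t <- 0; knots_m <- 0
  m <- 0; early <- TRUE
  i <- 1
  while (i < length(bounds)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1]
    if (t0 >= bounds[length(bounds)]) break
    seg <- findInterval(t0, seg_rates$t_start)
    seg <- min(max(seg, 1L), n_seg)
    if (switch_on == "time") early <- t0 < T_e_h
    r <- if (early) r_e_h[seg] else r_l_h[seg]
    if (switch_on == "maturity" && early && r > 0 && m + r * (t1 - t0) > M_t) {
      t_cross <- t0 + (M_t - m) / r
      bounds <- sort(unique(c(bounds, t_cross)))
      next  # re-enter interval split at the crossing
    }
    m_new <- m + r * (t1 - t0)
    if (switch_on == "maturity" && early && m_new >= M_t) early <- FALSE
    m <- m_new
    knots_t <- c(knots_t, t1); knots_m <- c(knots_m, m)
    i <- i + 1
  }
  t_h <- days * 24
  if (any(t_h > max(knots_t) + 1e-9)) {
    stop("measurement time exceeds the schedule horizon", call. = FALSE)
  }
  pmin(1, stats::approx(knots_t, knots_m, xout = pmin(t_h, max(knots_t)),
                        rule = 2)$y)
}

#' Integrate cell maturity over a treatment schedule
#'
#' Forward-Euler accumulation of the maturity state over a
#' piecewise-constant schedule: at each step the active rate is the early
#' rate `r_e` while `t <= T_e = M_t * T_d` and the late rate `r_l`
#' afterwards, with the fuzzy controller re-evaluated whenever the schedule
#' segment changes. Maturity is clamped to `[0, 1]`. Because the rates are
#' constant within segments, the Euler trajectory coincides with the exact
#' piecewise-linear solution whenever segment boundaries and `T_e` fall on
#' grid points.
#'
#' @param sched A schedule from [make_schedule()] and friends.
#' @param theta A [model_parameters()] registry.
#' @param dt Step size, hours; must not exceed the shortest segment.
#' @param switch_on Phase-switch criterion: `"time"` (at `T_e = M_t * T_d`,
#'   the default) or `"maturity"` (when maturity first reaches `M_t`).
#' @inheritParams scale_rate
#' @return A tibble with columns `t_h`, `t_day`, `phase` and `maturity`.
#' @examples
#' traj <- integrate_maturity(constant_schedule(21 * 24))
#' tail(traj, 1)  # full maturation at T_d under physiological inputs
#' @export
integrate_maturity <- function(sched, theta = model_parameters(), dt = 1,
                               switch_on = c("time", "maturity"),
                               swap_branches = FALSE) {
  switch_on <- match.arg(switch_on)
  sched <- make_schedule(sched)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (dt > min(sched$t_end - sched$t_start) + 1e-9) {
    stop("dt must not exceed the shortest schedule segment", call. = FALSE)
  }
  seg_rates <- schedule_rates(sched, theta, swap_branches = swap_branches)
  horizon <- sched$t_end[nrow(sched)]
  t <- seq(0, horizon, by = dt)
  if (t[length(t)] < horizon) t <- c(t, horizon)
  T_e_h <- theta[["M_t"]] * theta[["T_d"]] * 24
  n <- length(t)
  maturity <- numeric(n)
  phase <- character(n)
  m <- 0
  early <- TRUE
  for (i in seq_len(n)) {
    # the step starting at t uses the early rate while t < T_e (continuity
    # at T_e makes the boundary choice value-neutral)
    if (switch_on == "time") early <- t[i] < T_e_h
    phase[i] <- if (early) "early" else "late"
    maturity[i] <- m
    if (i == n) break
    seg <- min(max(findInterval(t[i], sched$t_start), 1L), nrow(sched))
    r_h <- (if (early) seg_rates$r_e[seg] else seg_rates$r_l[seg]) / 24
    m <- min(1, m + r_h * (t[i + 1] - t[i]))
    if (switch_on == "maturity" && early && m >= theta[["M_t"]]) early <- FALSE
  }
  tibble::tibble(t_h = t, t_day = t / 24, phase = phase, maturity = maturity)
}

#' Closed-form maturity under constant rates
#'
#' The piecewise maturity law for constant early/late rates:
#' `maturity = T * r_e` for `T <= T_e` and
#' `T_e * r_e + (T - T_e) * r_l` beyond, with `T_e = M_t * T_d`, clamped to
#' `[0, 1]`.
#'
#' @param T_days Evaluation time(s), days.
#' @param r_e,r_l Constant early/late rates, 1/day.
#' @param M_t Early maturation threshold in (0, 1).
#' @param T_d Full differentiation time, days.
#' @return Maturity value(s) in `[0, 1]`.
#' @export
maturity_closed_form <- function(T_days, r_e, r_l, M_t, T_d) {
  T_e <- M_t * T_d
  m <- ifelse(T_days <= T_e, T_days * r_e, T_e * r_e + (T_days - T_e) * r_l)
  pmin(pmax(m, 0), 1)
}

#' Map maturity to a differentiation marker
#'
#' Marker read-out `y = (x + beta)^n * k`, where `x` is the conditioned
#' maturity: for ALP (the early marker) `x = min(maturity, M_t)` -- ALP
#' tracks maturity only up to the early maturation threshold and stays
#' constant afterwards -- while OC and ARS (late markers) track maturity
#' over its whole range. `beta` is the marker baseline (detectable signal at
#' maturity zero), `n` the degree of nonlinearity and `k` the per-study
#' correction factor absorbing unit differences between experiments.
#'
#' @param maturity Maturity value(s) in `[0, 1]`.
#' @param marker One of `"ALP"`, `"OC"`, `"ARS"`.
#' @param study_id Study id 1..5 (selects the correction factor).
#' @param theta A [model_parameters()] registry.
#' @return Numeric marker value(s), in the study's reporting units.
#' @export
marker_value <- function(maturity, marker, study_id,
                         theta = model_parameters()) {
  if (any(maturity < 0 | maturity > 1)) {
    stop("maturity must lie in [0, 1]", call. = FALSE)
  }
  marker <- match.arg(marker, c("ALP", "OC", "ARS"))
  k_name <- paste0("k_", marker, "_", as.integer(study_id))
  if (!k_name %in% names(theta)) {
    stop(sprintf("no correction factor '%s' in the registry: marker %s is not measured in study %s",
                 k_name, marker, study_id), call. = FALSE)
  }
  x <- if (marker == "ALP") pmin(maturity, theta[["M_t"]]) else maturity
  (x + theta[[paste0("beta_", marker)]])^theta[[paste0("n_", marker)]] *
    theta[[k_name]]
}
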