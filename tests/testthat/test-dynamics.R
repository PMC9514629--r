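theta0 <- model_parameters()

test_that("rate scaling is piecewise linear, continuous at 0.5 and clamped", {
  expect_equal(scale_rate(0.5, 0.9, 0.9), 1)
  expect_equal(scale_rate(1, 0.4, 0.1), 1.4)
  expect_equal(scale_rate(0, 0.1, 0.6), 0.4)
  expect_equal(scale_rate(0, 0.1, 1), 0)  # lower clamp at zero
  # continuity at the physiological point
  eps <- 1e-9
  expect_equal(scale_rate(0.5 + eps, 0.3, 0.8), scale_rate(0.5 - eps, 0.3, 0.8),
               tolerance = 1e-6)
  # branch swap exchanges the coefficients
  expect_equal(scale_rate(1, 0.4, 0.1, swap_branches = TRUE), 1.1)
  expect_error(scale_rate(1.2, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("physical rates derive from the physiological rate 1/T_d", {
  r <- physical_rates(tibble::tibble(f_e = 0.5, f_l = 0.5),
                      model_parameters(T_d = 21))
  expect_equal(r$r_e, 1 / 21)
  expect_equal(r$r_l, 1 / 21)
  r <- physical_rates(tibble::tibble(f_e = 1, f_l = 0),
                      model_parameters(T_d = 20, alpha_es = 1, alpha_li = 1))
  expect_equal(r$r_e, 0.1)  # fully saturated stimulation doubles r0
  expect_equal(r$r_l, 0)
  r <- physical_rates(tibble::tibble(f_e = 1, f_l = 0.5),
                      model_parameters(T_d = 20, alpha_es = 0.5))
  expect_equal(r$r_e, 1.5 / 20)
})

test_that("closed-form maturity reproduces the worked example and boundaries", {
  # M_t = 0.4, T_d = 20 d, r_e = 2 r0, r_l = r0 / 2
  r0 <- 1 / 20
  expect_equal(maturity_closed_form(8, 2 * r0, r0 / 2, 0.4, 20), 0.8)
  expect_equal(maturity_closed_form(12, 2 * r0, r0 / 2, 0.4, 20), 0.9)
  expect_equal(maturity_closed_form(0, 2 * r0, r0 / 2, 0.4, 20), 0)
  # physiological rates reach full maturity exactly at T_d
  expect_equal(maturity_closed_form(20, r0, r0, 0.4, 20), 1)
  # continuity at T_e for arbitrary rates
  T_e <- 0.4 * 20
  expect_equal(maturity_closed_form(T_e - 1e-9, 2 * r0, r0 / 2, 0.4, 20),
               maturity_closed_form(T_e + 1e-9, 2 * r0, r0 / 2, 0.4, 20),
               tolerance = 1e-8)
})

test_that("Euler integration matches the closed form under constant inputs", {
  traj <- integrate_maturity(constant_schedule(21 * 24), theta0, dt = 1)
  expect_equal(max(traj$maturity), 1)
  closed <- maturity_closed_form(traj$t_day, 1 / 21, 1 / 21,
                                 theta0[["M_t"]], 21)
  expect_equal(traj$maturity, closed, tolerance = 1e-9)
  # non-decreasing and bounded
  expect_true(all(diff(traj$maturity) >= 0))
  expect_true(all(traj$maturity >= 0 & traj$maturity <= 1))
})

test_that("Euler trajectory obeys the first-order error bound under stimulation", {
  th <- model_parameters(T_d = 20, M_t = 0.4)
  sched <- constant_schedule(20 * 24, mg = 6)
  for (dt in c(12, 3, 1)) {
    traj <- integrate_maturity(sched, th, dt = dt)
    sr <- osteofuzz:::seg_rates_core(sched, th)
    closed <- maturity_closed_form(traj$t_day, sr$r_e, sr$r_l, 0.4, 20)
    bound <- dt / 24 * max(sr$r_e, sr$r_l) + 1e-12
    expect_lt(max(abs(traj$maturity - closed)), bound)
  }
})

test_that("exact segment-sum maturity equals the Euler trajectory on pulses", {
  th <- model_parameters(T_d = 20, M_t = 0.4)
  sched <- pulse_schedule(9 * 24, 48, il10 = 1)
  traj <- integrate_maturity(sched, th, dt = 1)
  sr <- osteofuzz:::seg_rates_core(sched, th)
  days <- c(1, 2, 3, 7, 9)
  exact <- osteofuzz:::maturity_exact(days, sr, th)
  euler <- traj$maturity[match(days * 24, traj$t_h)]
  expect_equal(exact, euler, tolerance = 1e-9)
})

test_that("maturity-based switching leaves the early phase at maturity M_t", {
  # stimulated early phase reaches M_t before T_e = M_t * T_d
  th <- model_parameters(T_d = 20, M_t = 0.4, alpha_es = 1)
  sched <- constant_schedule(20 * 24, mg = 6)
  tr_time <- integrate_maturity(sched, th, dt = 1, switch_on = "time")
  tr_mat <- integrate_maturity(sched, th, dt = 1, switch_on = "maturity")
  switch_idx <- which(tr_mat$phase == "late")[1]
  expect_equal(tr_mat$maturity[switch_idx], th[["M_t"]], tolerance = 0.02)
  # time-based switching keeps the early rate for longer here
  expect_gte(which(tr_time$phase == "late")[1], switch_idx)
})

test_that("a larger alpha_es speeds maturation under stimulatory signals", {
  sched <- constant_schedule(10 * 24, mg = 6)
  m <- vapply(c(0.2, 0.5, 0.9), function(a) {
    traj <- integrate_maturity(sched, model_parameters(alpha_es = a))
    traj$maturity[nrow(traj)]
  }, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("marker mapping applies baseline, nonlinearity and correction factor", {
  th <- model_parameters(beta_ALP = 0.5, n_ALP = 1, k_ALP_1 = 1)
  expect_equal(marker_value(0, "ALP", 1, th), 0.5)
  th2 <- model_parameters(beta_OC = 0.5, n_OC = 2, k_OC_2 = 2)
  expect_equal(marker_value(0.5, "OC", 2, th2), 2)
  # ALP is invariant to maturity above M_t
  th3 <- model_parameters(M_t = 0.4)
  expect_equal(marker_value(0.6, "ALP", 1, th3), marker_value(0.9, "ALP", 1, th3))
  # OC/ARS are strictly increasing in maturity
  m <- seq(0, 1, by = 0.1)
  expect_true(all(diff(marker_value(m, "ARS", 3, theta0)) > 0))
  expect_error(marker_value(0.5, "OC", 1, theta0), "not measured")
  expect_error(marker_value(1.5, "ALP", 1, theta0), "\\[0, 1\\]")
})

test_that("schedule validation catches gaps, overlaps and oversized steps", {
  expect_error(make_schedule(tibble::tibble(
    t_start = c(0, 50), t_end = c(48, 100), mg = 0.8, tnf = 0, il10 = 0,
    il8 = 0, il1b = 0)), "contiguous")
  expect_error(make_schedule(tibble::tibble(
    t_start = 5, t_end = 10, mg = 0.8, tnf = 0, il10 = 0, il8 = 0,
    il1b = 0)), "start at t = 0")
  expect_error(integrate_maturity(pulse_schedule(10 * 24, 48), dt = 72),
               "shortest")
  expect_error(integrate_maturity(constant_schedule(24), dt = -1), "positive")
})
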