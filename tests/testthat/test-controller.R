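theta0 <- model_parameters()

max_level <- function(var, x) names(which.max(fuzzify(var, x)))

test_that("Mg variable honours the concentration anchors", {
  mg <- build_mg_variable(theta0)
  expect_equal(max_level(mg, 0.8), "Physiological")
  expect_equal(max_level(mg, 0.08), "Inhibitory ED")
  expect_gt(fuzzify(mg, 25)[["Destructive"]], 0)
  expect_equal(max_level(mg, theta0[["p_ms"]]), "Stimulatory")
  # late-phase inhibition rises above 1.8 mM
  expect_gt(fuzzify(mg, 5)[["Inhibitory LD"]],
            fuzzify(mg, 1.5)[["Inhibitory LD"]])
  expect_error(build_mg_variable(model_parameters(p_md = 3, strict = FALSE)),
               "p_md")
})

test_that("TNF variable is stimulatory at 1, neutral at 10, inhibitory at 100 ng/ml", {
  tnf <- build_tnf_variable()
  z <- function(x) log10(x)
  expect_equal(max_level(tnf, z(1)), "Stimulatory")
  expect_equal(max_level(tnf, z(10)), "Ineffective")
  expect_equal(max_level(tnf, z(100)), "Inhibitory")
  expect_equal(max_level(tnf, -3), "Negligible")
})

test_that("IL-10 membership switches with exposure time", {
  short <- build_il10_variable(48)
  long <- build_il10_variable(72)
  zs <- log10(seq(0.01, 10, length.out = 50))
  # short-term: stimulatory degree non-decreasing from 0 to 10 ng/ml
  stim <- vapply(zs, function(z) fuzzify(short, z)[["Stimulatory"]], numeric(1))
  expect_true(all(diff(stim) >= -1e-12))
  # long-term: stimulatory peaks at 0.1 ng/ml on the decade grid
  grid <- c(0.01, 0.1, 1, 10, 100)
  stim_l <- vapply(log10(grid), function(z) fuzzify(long, z)[["Stimulatory"]],
                   numeric(1))
  expect_equal(grid[which.max(stim_l)], 0.1)
  # long-term 10 ng/ml: inhibition dominates stimulation
  d10 <- fuzzify(long, 1)
  expect_gt(d10[["Inhibitory"]], d10[["Stimulatory"]])
  expect_error(build_il10_variable(-1), "non-negative")
})

test_that("IL-8 and IL-1beta variables honour their anchors", {
  il8 <- build_il8_variable(theta0)
  il1b <- build_il1b_variable(theta0)
  expect_equal(max_level(il8, -3), "Negligible")
  expect_equal(max_level(il8, log10(theta0[["p_8f"]])), "Favorable")
  expect_equal(max_level(il8, 2), "Stimulatory")
  expect_equal(max_level(il1b, log10(theta0[["p_1bs"]])), "Stimulatory")
  expect_equal(max_level(il1b, -3), "Negligible")
  expect_error(build_il1b_variable(model_parameters(p_1bs = 60, p_1bie = 50,
                                                    strict = FALSE)),
               "p_1bie")
})

test_that("rule base activates the expected intensities", {
  rules <- build_rule_base()
  fuzz_all <- function(mg, tnf, il10, il8, il1b, exposure = 0) {
    list(mg = fuzzify(build_mg_variable(theta0), mg),
         tnf = fuzzify(build_tnf_variable(), osteofuzz:::conc_to_log(tnf)),
         il10 = fuzzify(build_il10_variable(exposure),
                        osteofuzz:::conc_to_log(il10)),
         il8 = fuzzify(build_il8_variable(theta0),
                       osteofuzz:::conc_to_log(il8)),
         il1b = fuzzify(build_il1b_variable(theta0),
                        osteofuzz:::conc_to_log(il1b)))
  }
  # all-physiological: only the Physiological level fires for ED and LD
  agg <- apply_rules(rules, fuzz_all(0.8, 0, 0, 0, 0))
  expect_equal(agg$ed[["Physiological"]], 1)
  expect_equal(agg$ld[["Physiological"]], 1)
  others <- c(agg$ed[setdiff(names(agg$ed), "Physiological")],
              agg$ld[setdiff(names(agg$ld), "Physiological")])
  expect_true(all(others == 0))
  # stimulatory IL-8 with negligible IL-1beta reaches Extremely fast
  agg <- apply_rules(rules, fuzz_all(0.8, 0, 0, 100, 0))
  expect_gt(agg$ed[["Extremely fast"]], 0)
  # IL-1beta antagonism: both present -> Very fast fires, Extremely fast not
  agg <- apply_rules(rules, fuzz_all(0.8, 0, 0, 100, theta0[["p_1bs"]]))
  expect_gt(agg$ed[["Very fast"]], 0)
  expect_equal(agg$ed[["Extremely fast"]], 0)
})

test_that("physiological inputs give the physiological crisp rates", {
  r <- infer_rates(cell_inputs())
  expect_equal(r$f_e, 0.5, tolerance = 1e-3)
  expect_equal(r$f_l, 0.5, tolerance = 1e-3)
})

test_that("crisp rates respond to Mg with the expected directions", {
  r <- infer_rates(cell_inputs(mg = c(0.08, 0.8, 8)))
  expect_true(all(diff(r$f_e) > 0))  # early rate strictly increasing
  # stimulatory Mg inhibits the late phase (above 1.8 mM)
  rs <- infer_rates(cell_inputs(mg = theta0[["p_ms"]]))
  expect_gt(rs$f_e, 0.5)
  expect_lt(rs$f_l, 0.5)
  # high TNF inhibits both phases
  ri <- infer_rates(cell_inputs(tnf = 100))
  expect_lt(ri$f_e, 0.5)
  expect_lt(ri$f_l, 0.5)
})

test_that("crisp rates stay in [0,1] over an input grid sweep", {
  grid <- expand.grid(mg = c(0, 0.8, 8, 25), tnf = c(0, 10, 100),
                      il10 = c(0, 1, 100), il8 = c(0, 100), il1b = c(0, 10))
  r <- infer_rates(grid)
  expect_true(all(r$f_e >= 0 & r$f_e <= 1))
  expect_true(all(r$f_l >= 0 & r$f_l <= 1))
})

test_that("IL-1beta blunts the IL-8 driven early response", {
  r <- infer_rates(cell_inputs(il8 = c(100, 100),
                               il1b = c(0, theta0[["p_1bs"]])))
  expect_gte(r$f_e[1], r$f_e[2])
})

test_that("input validation rejects negative concentrations and bad columns", {
  expect_error(cell_inputs(mg = -1), "non-negative")
  expect_error(infer_rates(data.frame(mg = 1)), "missing column")
})

test_that("the free-parameter registry has exactly 30 entries with priors", {
  expect_length(model_parameters(), 30)
  pri <- parameter_priors()
  expect_setequal(pri$name, names(model_parameters()))
  expect_true(all(pri$lower < pri$upper))
  # per-study subsets exclude other studies' correction factors
  for (s in 1:5) {
    rel <- relevant_parameters(s)
    expect_true(all(rel %in% pri$name))
    foreign_k <- setdiff(grep("^k_", pri$name, value = TRUE),
                         grep(paste0("_", s, "$"), pri$name, value = TRUE))
    expect_length(intersect(rel, foreign_k), 0)
  }
  expect_error(model_parameters(M_t = 1.5), "M_t")
  expect_error(model_parameters(p_evf = 0.6, p_ef = 0.9), "p_ef < p_evf")
  expect_error(model_parameters(bogus = 1), "unknown parameter")
})
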