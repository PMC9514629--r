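theta0 <- model_parameters()

test_that("per-item fitness is 1 - |E-S|/E clamped to [0, 1] and scale-free", {
  expect_equal(fitness_item(2, 2), 1)
  expect_equal(fitness_item(2, 1), 0.5)
  expect_equal(fitness_item(1, 3), 0)  # clamped at zero
  expect_equal(fitness_item(4, 2), 0.5)
  # scale-free: fitness(cE, cS) = fitness(E, S)
  withr::with_seed(3, {
    E <- runif(50, 0.1, 10); S <- runif(50, 0.1, 10); cc <- runif(50, 0.1, 5)
    expect_equal(fitness_item(cc * E, cc * S), fitness_item(E, S))
  })
  # raw discrepancy option
  expect_equal(fitness_item(2, 1, raw = TRUE), 0.5)
  expect_equal(fitness_item(1, 3, raw = TRUE), 2)
  expect_error(fitness_item(0, 1), "positive")
  expect_error(fitness_item(-2, 1), "positive")
})

test_that("objective fitness is 1 at the generating parameters and averages items", {
  syn <- generate_synthetic(theta0, noise_cv = 0, seed = 1)
  expect_equal(objective_fitness(theta0, syn), 1)
  # doubling one empirical value halves that item's fitness
  one <- syn[syn$study_id == 1, ][1, ]
  one$value <- 2 * one$value
  expect_equal(objective_fitness(theta0, one), 0.5)
  two <- dplyr::bind_rows(syn[syn$study_id == 1, ][1, ], one)
  expect_equal(objective_fitness(theta0, two), 0.75)
  # unresolvable items are data errors
  ghost <- one
  ghost$condition <- "mg_99"
  expect_error(objective_fitness(theta0, ghost), "not resolvable")
  expect_error(fitness_table(theta0, dplyr::mutate(one, study_id = 9L)),
               "no design")
})

test_that("the compiled objective agrees with the plain simulation route", {
  syn <- generate_synthetic(theta0, noise_cv = 0.1, seed = 2)
  free <- c("M_t", "T_d", "alpha_es", "p_ms", "beta_ALP", "k_ALP_1")
  obj <- calibration_objective(syn, free = free)
  withr::with_seed(4, {
    pri <- parameter_priors()
    for (i in 1:5) {
      par <- vapply(free, function(nm) {
        row <- pri[pri$name == nm, ]
        runif(1, row$lower, row$upper)
      }, numeric(1))
      theta <- theta0
      theta[free] <- par
      skip_invalid <- !is.null(osteofuzz:::check_parameters(theta))
      if (skip_invalid) next
      expect_equal(obj(par), objective_fitness(theta, syn), tolerance = 1e-12)
    }
  })
  # invalid orderings score zero instead of erroring
  expect_equal(obj(c(M_t = 0.5, T_d = 21, alpha_es = 0.5, p_ms = 6,
                     beta_ALP = 0.5, k_ALP_1 = 1)[free]),
               objective_fitness(theta0, syn))
  bad <- c(M_t = 0.5, T_d = 21, alpha_es = 0.5, p_ms = 9.9, beta_ALP = 0.5,
           k_ALP_1 = 1)
  bad["p_ms"] <- 9.9
  obj2 <- calibration_objective(syn, free = c("p_ms", "p_md"))
  expect_equal(obj2(c(p_ms = 9.9, p_md = 5)), 0)
})

test_that("differential evolution solves a convex toy problem reproducibly", {
  pri <- tibble::tibble(name = "x", lower = -5, upper = 5, scale = "linear")
  obj <- function(par) -par[["x"]]^2
  de <- run_de(obj, pri, de_settings(pop = 12, generations = 80), seed = 9)
  expect_lt(abs(de$par[["x"]]), 1e-3)
  de2 <- run_de(obj, pri, de_settings(pop = 12, generations = 80), seed = 9)
  expect_identical(de$par, de2$par)
  de3 <- run_de(obj, pri, de_settings(pop = 12, generations = 80), seed = 10)
  expect_false(identical(de$par, de3$par))
  # log-scale priors are searched in log space but reported naturally
  pri_log <- tibble::tibble(name = "k", lower = 0.1, upper = 10, scale = "log")
  de4 <- run_de(function(p) -(log10(p[["k"]]))^2, pri_log,
                de_settings(pop = 10, generations = 60), seed = 1)
  expect_equal(de4$par[["k"]], 1, tolerance = 1e-2)
})

test_that("a miniature repeated calibration recovers T_d and passes the half-split check", {
  syn1 <- generate_synthetic(theta0, noise_cv = 0, seed = 1,
                             designs = builtin_designs()["study1"])
  pri <- parameter_priors()
  pri <- pri[pri$name == "T_d", ]
  fit <- calibrate_repeated(syn1, pri,
                            settings = de_settings(pop = 8, generations = 40),
                            n_runs = 4, base_seed = 11, tolerance = 0.1)
  expect_s3_class(fit, "osteo_calibration")
  expect_equal(fit$summary$mean, 21, tolerance = 0.15 * 21)
  expect_true(fit$converged)
  expect_true(all(fit$runs$fitness > 0.99))
  expect_equal(fit$runs$seed, 11:14)
  # inferred registry carries the calibrated mean
  est <- calibrated_parameters(fit)
  expect_equal(est[["T_d"]], fit$summary$mean)
  expect_length(est, 30)
  expect_error(calibrate_repeated(syn1, pri, n_runs = 1), "at least 2")
})

test_that("odd run counts split the halves floor/ceiling", {
  syn1 <- generate_synthetic(theta0, noise_cv = 0, seed = 1,
                             designs = builtin_designs()["study1"])
  pri <- parameter_priors()[parameter_priors()$name == "M_t", ]
  fit <- calibrate_repeated(syn1, pri,
                            settings = de_settings(pop = 6, generations = 10),
                            n_runs = 3, base_seed = 2, tolerance = 1)
  vals <- fit$runs$M_t
  expect_equal(fit$summary$half1_mean, mean(vals[1]))
  expect_equal(fit$summary$half2_mean, mean(vals[2:3]))
})

test_that("calibration summaries write CSV plus a provenance record", {
  syn1 <- generate_synthetic(theta0, noise_cv = 0, seed = 1,
                             designs = builtin_designs()["study1"])
  pri <- parameter_priors()[parameter_priors()$name == "T_d", ]
  fit <- calibrate_repeated(syn1, pri,
                            settings = de_settings(pop = 6, generations = 10),
                            n_runs = 2, base_seed = 5, tolerance = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  prov <- write_calibration(fit, csv, js, data = syn1)
  expect_equal(readr::read_csv(csv, show_col_types = FALSE)$parameter, "T_d")
  rec <- jsonlite::read_json(js)
  expect_equal(rec$n_runs, 2)
  expect_equal(unlist(rec$seeds), c(5, 6))
  expect_true(is.numeric(prov$data_hash))
})
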