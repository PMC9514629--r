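test_that("membership shapes evaluate piecewise-linearly / gaussian", {
  expect_equal(fz_degree(mf_triangular(0, 1, 2), 1), 1)
  expect_equal(fz_degree(mf_triangular(0, 1, 2), c(0.5, 1.5)), c(0.5, 0.5))
  expect_equal(fz_degree(mf_gaussian(0.5, 0.05), 0.5), 1)
  expect_equal(fz_degree(mf_gaussian(0.5, 0.05), 0.55),
               exp(-0.05^2 / (2 * 0.05^2)))
  expect_equal(fz_degree(mf_trapezoidal(0, 1, 2, 3), 2.5), 0.5)
  expect_equal(fz_degree(mf_trapezoidal(0, 1, 2, 3), 1.5), 1)
  # vertical shoulders at degenerate edges
  expect_equal(fz_degree(mf_triangular(0, 0, 1), 0), 1)
  expect_equal(fz_degree(mf_trapezoidal(0, 0, 1, 1), c(0, 1)), c(1, 1))
  # activation scales the peak
  expect_equal(fz_degree(mf_triangular(0, 1, 2, activation = 0.6), 1), 0.6)
})

test_that("membership degrees stay within [0, activation] for random inputs", {
  withr::with_seed(42, {
    mfs <- list(mf_triangular(-1, 0.3, 2), mf_trapezoidal(-2, -1, 1, 4),
                mf_gaussian(0.2, 0.4, activation = 0.8))
    x <- runif(500, -10, 10)
    for (mf in mfs) {
      d <- fz_degree(mf, x)
      expect_true(all(d >= 0 & d <= mf$activation))
    }
  })
})

test_that("invalid membership parameters and inputs are rejected", {
  expect_error(mf_triangular(2, 1, 0), "non-decreasing|a <= b")
  expect_error(mf_trapezoidal(0, 2, 1, 3), "a <= b <= c <= d")
  expect_error(mf_gaussian(0, -1), "sigma")
  expect_error(mf_triangular(0, 1, 2, activation = 1.5), "activation")
  expect_error(fz_degree(mf_triangular(0, 1, 2), NA_real_), "finite")
  expect_error(fz_degree(mf_triangular(0, 1, 2), Inf), "finite")
})

test_that("fuzzify maps crisp values to per-level degrees", {
  duo <- two_level_variable()
  expect_equal(fuzzify(duo, 0), c(lo = 1, hi = 0))
  expect_equal(fuzzify(duo, 0.5), c(lo = 0.5, hi = 0.5))
  # clamping (default) vs domain error
  expect_equal(fuzzify(duo, 2), fuzzify(duo, 1))
  strict <- fz_variable("strict", 0, 1, duo$levels, clamp = FALSE)
  expect_error(fuzzify(strict, 2), "outside domain")
})

test_that("partition-of-unity degrees sum to one over random draws", {
  pou <- partition_variable()
  withr::with_seed(7, {
    x <- runif(1000, 0, 3)
    sums <- vapply(x, function(xi) sum(fuzzify(pou, xi)), numeric(1))
    expect_equal(sums, rep(1, 1000), tolerance = 1e-12)
  })
})

test_that("rule firing is min-AND with complement for NOT and max aggregation", {
  degs <- list(a = c(hi = 0.7, lo = 0.3), b = c(hi = 0.4, lo = 0.6))
  r1 <- fz_rule("out", "L", fz_clause("a", "hi"), fz_clause("b", "hi"))
  expect_equal(apply_rules(list(r1), degs)$out[["L"]], 0.4)
  # two rules onto the same level aggregate by max
  r2 <- fz_rule("out", "L", fz_clause("b", "lo"))
  agg <- apply_rules(list(r1, r2), degs)
  expect_equal(agg$out[["L"]], 0.6)
  # NOT contributes 1 - degree
  r3 <- fz_rule("out", "M", fz_clause("a", "lo", negated = TRUE))
  expect_equal(apply_rules(list(r3), degs)$out[["M"]], 0.7)
  # unresolvable references are configuration errors
  expect_error(apply_rules(list(fz_rule("out", "L", fz_clause("zz", "hi"))), degs),
               "unknown variable")
  expect_error(apply_rules(list(fz_rule("out", "L", fz_clause("a", "zz"))), degs),
               "unknown level")
})

test_that("aggregation is monotone in firing strength", {
  # raising a clause degree can only raise the consequent activation
  rule <- fz_rule("out", "L", fz_clause("a", "hi"))
  acts <- vapply(seq(0, 1, by = 0.1), function(d) {
    apply_rules(list(rule), list(a = c(hi = d)))$out[["L"]]
  }, numeric(1))
  expect_true(all(diff(acts) >= 0))
})

test_that("centroid of symmetric activations recovers the symmetry point", {
  out <- fz_variable("y", 0, 1, levels = list(
    A = mf_gaussian(0.3, 0.05), B = mf_gaussian(0.5, 0.05),
    C = mf_gaussian(0.7, 0.05)
  ))
  # single clipped symmetric level: centroid equals its center at any height
  for (h in c(0.2, 0.6, 1)) {
    expect_equal(defuzzify_centroid(out, c(B = h)), 0.5, tolerance = 1e-9)
  }
  # equal activations of two symmetric levels
  expect_equal(defuzzify_centroid(out, c(A = 0.4, C = 0.4)), 0.5,
               tolerance = 1e-9)
  expect_error(defuzzify_centroid(out, c(A = 0, B = 0)), "zero")
  expect_error(defuzzify_centroid(out, c(Z = 1)), "unknown output level")
})

test_that("analytic centroid agrees with the brute-force integration oracle", {
  out <- fz_variable("y", 0, 1, levels = list(
    S = mf_gaussian(0.25, 0.05), P = mf_gaussian(0.5, 0.05),
    F = mf_gaussian(0.75, 0.05), V = mf_gaussian(0.9, 0.05)
  ))
  withr::with_seed(11, {
    for (i in 1:25) {
      act <- stats::setNames(runif(4), names(out$levels))
      expect_equal(defuzzify_centroid(out, act),
                   centroid_bruteforce(out, act),
                   tolerance = 1e-3)
    }
  })
})

test_that("rule bases round-trip through the IF/THEN text format", {
  rules <- build_rule_base()
  txt <- rules_to_text(rules)
  expect_true(all(grepl("^IF .* THEN (ed|ld) IS ", txt)))
  back <- rules_from_text(c("# comment", "", txt))
  expect_equal(length(back), length(rules))
  expect_equal(rules_to_text(back), txt)
  expect_error(rules_from_text("nonsense line"), "cannot parse")
})
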