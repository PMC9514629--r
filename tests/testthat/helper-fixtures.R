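# shared fixtures: all built in code, no stored data

# brute-force centroid by trapezoid integration on a fine grid -- the
# independent oracle for the analytic centroid path
centroid_bruteforce <- function(var, activations, n = 1e5) {
  x <- seq(var$min, var$max, length.out = n)
  mu <- rep(0, n)
  for (lv in names(activations)) {
    a <- activations[[lv]]
    if (a <= 0) next
    mu <- pmax(mu, pmin(a, fz_degree(var$levels[[lv]], x)))
  }
  w <- c(diff(x) / 2, 0) + c(0, diff(x) / 2)  # trapezoid weights
  sum(mu * x * w) / sum(mu * w)
}

# a partition-of-unity variable: interior triangles + shoulder trapezoids
# on [0, 3]; degrees sum to 1 everywhere
partition_variable <- function() {
  fz_variable("pou", 0, 3, levels = list(
    L1 = mf_triangular(0, 0, 1),
    L2 = mf_triangular(0, 1, 2),
    L3 = mf_triangular(1, 2, 3),
    L4 = mf_triangular(2, 3, 3)
  ))
}

# two complementary triangles crossing at 0.5
two_level_variable <- function() {
  fz_variable("duo", 0, 1, levels = list(
    lo = mf_triangular(0, 0, 1),
    hi = mf_triangular(0, 1, 1)
  ))
}

# tiny single-condition design for cheap generator statistics
tiny_design <- function() {
  study_design(
    1L,
    conditions = list("mg_0.8" = constant_schedule(3 * 24)),
    measurements = tibble::tibble(marker = "ALP", day = 3)
  )
}
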