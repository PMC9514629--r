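#' Membership functions
#'
#' Constructors for the three parametric membership shapes used by the
#' Mamdani engine. A membership function maps a crisp value to a degree of
#' membership in `[0, activation]`.
#'
#' * `mf_triangular(a, b, c)` rises linearly from `a` to the apex `b` and
#'   falls to `c`. Degenerate edges (`a == b` or `b == c`) give a vertical
#'   shoulder.
#' * `mf_trapezoidal(a, b, c, d)` rises over `[a, b]`, holds the plateau over
#'   `[b, c]` and falls over `[c, d]`.
#' * `mf_gaussian(center, sigma)` is `activation * exp(-(x - center)^2 /
#'   (2 * sigma^2))`.
#'
#' @param a,b,c,d Abscissae, non-decreasing.
#' @param center,sigma Gaussian center and width; `sigma > 0`.
#' @param activation Peak membership degree in `(0, 1]`.
#' @return An object of class `fz_mf`.
#' @examples
#' mf <- mf_triangular(0, 1, 2)
#' fz_degree(mf, c(0, 1, 1.5))
#' @export
mf_triangular <- function(a, b, c, activation = 1) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (!(a <= b && b <= c)) {
    stop("triangular abscissae must satisfy a <= b <= c", call. = FALSE)
  }
  new_fz_mf("triangular", list(a = a, b = b, c = c), activation)
}

#' @rdname mf_triangular
#' @export
mf_trapezoidal <- function(a, b, c, d, activation = 1) {
  if (!(a <= b && b <= c && c <= d)) {
    stop("trapezoidal abscissae must satisfy a <= b <= c <= d", call. = FALSE)
  }
  new_fz_mf("trapezoidal", list(a = a, b = b, c = c, d = d), activation)
}

#' @rdname mf_triangular
#' @export
mf_gaussian <- function(center, sigma, activation = 1) {
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("gaussian sigma must be > 0", call. = FALSE)
  }
  new_fz_mf("gaussian", list(center = center, sigma = sigma), activation)
}

new_fz_mf <- function(kind, pars, activation) {
  if (!is.numeric(activation) || activation <= 0 || activation > 1) {
    stop("activation must lie in (0, 1]", call. = FALSE)
  }
  structure(list(kind = kind, pars = pars, activation = activation),
            class = "fz_mf")
}

#' @export
print.fz_mf <- function(x, ...) {
  cat("<fz_mf ", x$kind, "(",
      paste(names(x$pars), unlist(x$pars), sep = "=", collapse = ", "),
      "), activation=", x$activation, ">\n", sep = "")
  invisible(x)
}

#' Evaluate a membership function
#'
#' @param mf A membership function created with [mf_triangular()],
#'   [mf_trapezoidal()] or [mf_gaussian()].
#' @param x Numeric vector of crisp values (finite).
#' @return Numeric vector of degrees in `[0, activation]`.
#' @export
fz_degree <- function(mf, x) {
  stopifnot(inherits(mf, "fz_mf"))
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("x must be finite numeric", call. = FALSE)
  }
  p <- mf$pars
  deg <- switch(
    mf$kind,
    triangular = {
      up <- ramp_up(x, p$a, p$b)
      dn <- ramp_down(x, p$b, p$c)
      pmin(up, dn)
    },
    trapezoidal = {
      up <- ramp_up(x, p$a, p$b)
      dn <- ramp_down(x, p$c, p$d)
      pmin(up, dn)
    },
    gaussian = exp(-(x - p$center)^2 / (2 * p$sigma^2))
  )
  pmin(pmax(deg, 0), 1) * mf$activation
}

# linear ramp 0 -> 1 over [lo, hi]; vertical shoulder when lo == hi
ramp_up <- function(x, lo, hi) {
  if (hi > lo) pmin(pmax((x - lo) / (hi - lo), 0), 1) else as.numeric(x >= hi)
}

ramp_down <- function(x, lo, hi) {
  if (hi > lo) pmin(pmax((hi - x) / (hi - lo), 0), 1) else as.numeric(x <= lo)
}

#' Linguistic variables
#'
#' A linguistic variable carries a domain interval and a named set of
#' membership levels over that domain.
#'
#' @param name Variable name.
#' @param min,max Domain interval bounds.
#' @param levels Named list of `fz_mf` membership functions; names are the
#'   linguistic level names and must be unique.
#' @param units Optional unit string (documentation only).
#' @param clamp Should values outside `[min, max]` be clamped to the boundary
#'   when fuzzifying? Default `TRUE`; with `FALSE`, out-of-domain values are
#'   an error.
#' @return An object of class `fz_variable`.
#' @export
fz_variable <- function(name, min, max, levels, units = "", clamp = TRUE) {
  stopifnot(is.character(name), is.numeric(min), is.numeric(max), min < max)
  if (is.null(names(levels)) || anyDuplicated(names(levels)) > 0 ||
      any(names(levels) == "")) {
    stop("levels must be a uniquely named list", call. = FALSE)
  }
  ok <- vapply(levels, inherits, logical(1), what = "fz_mf")
  if (!all(ok)) stop("all levels must be fz_mf objects", call. = FALSE)
  structure(list(name = name, min = min, max = max, units = units,
                 levels = levels, clamp = clamp),
            class = "fz_variable")
}

#' @export
print.fz_variable <- function(x, ...) {
  cat("<fz_variable '", x$name, "' on [", x$min, ", ", x$max, "] ",
      x$units, " with ", length(x$levels), " levels: ",
      paste(names(x$levels), collapse = ", "), ">\n", sep = "")
  invisible(x)
}

#' Fuzzify a crisp value
#'
#' Maps a crisp value to its degree of membership in every level of a
#' linguistic variable.
#'
#' @param var A [fz_variable()].
#' @param x A single finite numeric value.
#' @return Named numeric vector of degrees, one per level, each in `[0, 1]`.
#' @export
fuzzify <- function(var, x) {
  stopifnot(inherits(var, "fz_variable"))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("x must be a single finite numeric value", call. = FALSE)
  }
  if (x < var$min || x > var$max) {
    if (!var$clamp) {
      stop(sprintf("value %g outside domain [%g, %g] of '%s'",
                   x, var$min, var$max, var$name), call. = FALSE)
    }
    x <- min(max(x, var$min), var$max)
  }
  vapply(var$levels, fz_degree, numeric(1), x = x)
}

#' Fuzzy rules
#'
#' A rule has a conjunctive antecedent (all clauses combined with min-AND)
#' and a single consequent `(output variable, output level)`. A clause can be
#' negated, in which case it contributes `1 - degree` (standard complement).
#'
#' @param output,level Consequent output-variable name and level name.
#' @param ... Antecedent clauses built with [fz_clause()]; at least one.
#' @return An object of class `fz_rule`.
#' @export
fz_rule <- function(output, level, ...) {
  clauses <- list(...)
  if (length(clauses) == 0L) stop("a rule needs at least one clause", call. = FALSE)
  ok <- vapply(clauses, inherits, logical(1), what = "fz_clause")
  if (!all(ok)) stop("antecedent terms must be fz_clause objects", call. = FALSE)
  structure(list(output = output, level = level, clauses = clauses),
            class = "fz_rule")
}

#' @rdname fz_rule
#' @param variable Input-variable name the clause tests.
#' @param negated If `TRUE` the clause reads "NOT level".
#' @export
fz_clause <- function(variable, level, negated = FALSE) {
  structure(list(variable = variable, level = level, negated = isTRUE(negated)),
            class = "fz_clause")
}

#' Apply a rule base to fuzzified inputs
#'
#' Mamdani composition: each rule fires with strength `min` over its clause
#' degrees (a negated clause contributes `1 - degree`); per output level the
#' activation is the `max` over the firing strengths of all rules with that
#' consequent.
#'
#' @param rules List of [fz_rule()] objects.
#' @param input_degrees Named list, one entry per input variable, each a
#'   named numeric vector of level degrees (as returned by [fuzzify()]).
#' @return Named list, one entry per output variable, each a named numeric
#'   vector of per-level activation strengths in `[0, 1]`.
#' @export
apply_rules <- function(rules, input_degrees) {
  out <- list()
  for (rule in rules) {
    strength <- 1
    for (cl in rule$clauses) {
      degs <- input_degrees[[cl$variable]]
      if (is.null(degs)) {
        stop(sprintf("rule references unknown variable '%s'", cl$variable),
             call. = FALSE)
      }
      if (!cl$level %in% names(degs)) {
        stop(sprintf("rule references unknown level '%s' of '%s'",
                     cl$level, cl$variable), call. = FALSE)
      }
      d <- unname(degs[[cl$level]])
      if (cl$negated) d <- 1 - d
      strength <- min(strength, d)
    }
    if (is.null(out[[rule$output]])) out[[rule$output]] <- numeric(0)
    cur <- out[[rule$output]]
    prev <- if (rule$level %in% names(cur)) cur[[rule$level]] else 0
    out[[rule$output]][[rule$level]] <- max(prev, strength)
  }
  out
}

#' Centroid defuzzification
#'
#' Clips each activated level's membership function at its activation
#' strength (min-implication), takes the pointwise max union over levels, and
#' returns the centroid of the union on a uniform grid over the variable
#' domain.
#'
#' @param var The output [fz_variable()].
#' @param activations Named numeric vector of per-level activation strengths
#'   (levels absent from the vector count as 0).
#' @param n_grid Number of grid points; the default resolves an output
#'   Gaussian of width 0.05 on `[0, 1]` with ~50 points per standard
#'   deviation.
#' @return The crisp centroid value, inside the variable domain.
#' @export
defuzzify_centroid <- function(var, activations, n_grid = 1001L) {
  stopifnot(inherits(var, "fz_variable"))
  unknown <- setdiff(names(activations), names(var$levels))
  if (length(unknown) > 0) {
    stop(sprintf("unknown output level(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (length(activations) == 0L || all(activations <= 0)) {
    stop("all activations are zero: rule base does not cover this state",
         call. = FALSE)
  }
  grid <- seq(var$min, var$max, length.out = n_grid)
  mu <- rep(0, n_grid)
  for (lv in names(activations)) {
    a <- activations[[lv]]
    if (a <= 0) next
    mu <- pmax(mu, pmin(a, fz_degree(var$levels[[lv]], grid)))
  }
  sum(mu * grid) / sum(mu)
}

#' Serialize a rule base to IF/THEN text
#'
#' Writes (and reads back) rules in a plain declarative format, one rule per
#' line:
#' `IF tnf IS Stimulatory AND il10 IS NOT Negligible THEN ed IS Fast`.
#'
#' @param rules List of [fz_rule()] objects.
#' @return `rules_to_text()`: character vector of IF/THEN lines.
#' @export
rules_to_text <- function(rules) {
  vapply(rules, function(r) {
    ante <- vapply(r$clauses, function(cl) {
      paste(cl$variable, if (cl$negated) "IS NOT" else "IS", cl$level)
    }, character(1))
    paste0("IF ", paste(ante, collapse = " AND "),
           " THEN ", r$output, " IS ", r$level)
  }, character(1))
}

#' @rdname rules_to_text
#' @param lines Character vector of IF/THEN lines as produced by
#'   `rules_to_text()`; blank lines and `#` comments are ignored.
#' @return `rules_from_text()`: list of [fz_rule()] objects.
#' @export
rules_from_text <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(ln) {
    m <- regmatches(ln, regexec("^IF\\s+(.*)\\s+THEN\\s+(\\S+)\\s+IS\\s+(.+)$", ln))[[1]]
    if (length(m) != 4) stop(sprintf("cannot parse rule line: '%s'", ln), call. = FALSE)
    clauses <- lapply(strsplit(m[2], "\\s+AND\\s+")[[1]], function(part) {
      cm <- regmatches(part, regexec("^(\\S+)\\s+IS(\\s+NOT)?\\s+(.+)$", part))[[1]]
      if (length(cm) != 4) stop(sprintf("cannot parse clause: '%s'", part), call. = FALSE)
      fz_clause(cm[2], trimws(cm[4]), negated = nzchar(trimws(cm[3])))
    })
    do.call(fz_rule, c(list(output = m[3], level = trimws(m[4])), clauses))
  })
}
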