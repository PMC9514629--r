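#' The free-parameter registry
#'
#' The model has exactly 30 free parameters: five input-membership anchors
#' (`p_ms`, `p_md`, `p_8f`, `p_1bs`, `p_1bie`), five output-level centers
#' (`p_es`, `p_ef`, `p_evf`, `p_ls`, `p_lf`), the early maturation threshold
#' `M_t`, the full differentiation time `T_d` (days), four rate-scaling
#' coefficients (`alpha_es`, `alpha_ei`, `alpha_ls`, `alpha_li`), three
#' marker baselines (`beta_ALP`, `beta_OC`, `beta_ARS`), three nonlinearity
#' exponents (`n_ALP`, `n_OC`, `n_ARS`) and eight per-study correction
#' factors (`k_ALP_1`, `k_ALP_2`, `k_OC_2`, `k_ALP_3`, `k_ARS_3`, `k_ALP_4`,
#' `k_ARS_4`, `k_ALP_5`).
#'
#' `model_parameters()` builds the full registry (defaults overridable by
#' name); `parameter_priors()` returns the prior bounds used by calibration
#' and `relevant_parameters()` the subset of the registry that enters a
#' single study's computation.
#'
#' Default anchor values honour the textual anchors of the underlying
#' biology: physiological Mg is 0.8 mM, the stimulatory window 2-10 mM with
#' peak effect at 6 mM, late-phase inhibition above 1.8 mM and loss of
#' viability above 20 mM; TNF-alpha is stimulatory at 1, neutral at 10 and
#' inhibitory at 100 ng/ml; `T_d = 21` days matches the usual three-week
#' osteogenic differentiation assay.
#'
#' @param ... Named parameter overrides, e.g. `model_parameters(M_t = 0.4)`.
#' @param strict If `TRUE` (default) invalid values or orderings raise an
#'   error; with `FALSE` the constructor returns the vector unvalidated
#'   (used by optimizers, which penalize invalid candidates instead).
#' @return `model_parameters()`: a named numeric vector of length 30 with
#'   class `osteo_params`.
#' @examples
#' theta <- model_parameters(T_d = 14)
#' length(theta)
#' @export
model_parameters <- function(..., strict = TRUE) {
  theta <- default_parameter_values()
  dots <- list(...)
  if (length(dots) > 0) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(dots), names(theta))
    if (length(unknown) > 0) {
      stop(sprintf("unknown parameter(s): %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
    theta[names(dots)] <- vapply(dots, as.numeric, numeric(1))
  }
  theta <- structure(theta, class = "osteo_params")
  if (strict) {
    msg <- check_parameters(theta)
    if (!is.null(msg)) stop(msg, call. = FALSE)
  }
  theta
}

default_parameter_values <- function() {
  c(
    p_ms = 6, p_md = 15, p_8f = 10, p_1bs = 5, p_1bie = 50,
    p_es = 0.3, p_ef = 0.7, p_evf = 0.85, p_ls = 0.3, p_lf = 0.7,
    M_t = 0.5, T_d = 21,
    alpha_es = 0.5, alpha_ei = 0.5, alpha_ls = 0.5, alpha_li = 0.5,
    beta_ALP = 0.5, beta_OC = 0.5, beta_ARS = 0.5,
    n_ALP = 1, n_OC = 1, n_ARS = 1,
    k_ALP_1 = 1, k_ALP_2 = 1, k_OC_2 = 1, k_ALP_3 = 1, k_ARS_3 = 1,
    k_ALP_4 = 1, k_ARS_4 = 1, k_ALP_5 = 1
  )
}

# NULL when valid, otherwise a message describing the first violation
check_parameters <- function(theta) {
  p <- as.list(theta)
  checks <- list(
    list(p$p_ms >= 2 && p$p_ms <= 10, "p_ms must lie in [2, 10] mM"),
    list(p$p_md > p$p_ms, "p_md must exceed p_ms"),
    list(p$p_8f > 0, "p_8f must be positive"),
    list(p$p_1bs > 0 && p$p_1bs < p$p_1bie, "p_1bs must be positive and below p_1bie"),
    list(p$p_es > 0 && p$p_es < 0.5, "p_es must lie in (0, 0.5)"),
    list(p$p_ef > 0.5 && p$p_ef < p$p_evf && p$p_evf < 1,
         "output centers must satisfy 0.5 < p_ef < p_evf < 1"),
    list(p$p_ls > 0 && p$p_ls < 0.5, "p_ls must lie in (0, 0.5)"),
    list(p$p_lf > 0.5 && p$p_lf < 1, "p_lf must lie in (0.5, 1)"),
    list(p$M_t > 0 && p$M_t < 1, "M_t must lie in (0, 1)"),
    list(p$T_d > 0, "T_d must be positive"),
    list(all(unlist(p[c("alpha_es", "alpha_ei", "alpha_ls", "alpha_li")]) >= 0),
         "scaling coefficients alpha must be >= 0"),
    list(all(unlist(p[c("beta_ALP", "beta_OC", "beta_ARS")]) >= 0),
         "marker baselines beta must be >= 0"),
    list(all(unlist(p[c("n_ALP", "n_OC", "n_ARS")]) > 0),
         "nonlinearity exponents n must be > 0"),
    list(all(unlist(p[grepl("^k_", names(p))]) > 0),
         "correction factors k must be > 0")
  )
  for (chk in checks) if (!isTRUE(chk[[1]])) return(chk[[2]])
  NULL
}

#' @export
print.osteo_params <- function(x, ...) {
  cat("<osteo_params: ", length(x), " free parameters>\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' @rdname model_parameters
#' @return `parameter_priors()`: a tibble with columns `name`, `lower`,
#'   `upper`, `scale` (`"linear"` or `"log"`), one row per registry entry.
#' @export
parameter_priors <- function() {
  k_names <- grep("^k_", names(default_parameter_values()), value = TRUE)
  pri <- tibble::tribble(
    ~name,       ~lower, ~upper, ~scale,
    "p_ms",      2,      10,     "linear",
    "p_md",      10,     20,     "linear",
    "p_8f",      1,      100,    "linear",
    "p_1bs",     1,      10,     "linear",
    "p_1bie",    10,     100,    "linear",
    "p_es",      0.05,   0.45,   "linear",
    "p_ef",      0.55,   0.95,   "linear",
    "p_evf",     0.6,    0.99,   "linear",
    "p_ls",      0.05,   0.45,   "linear",
    "p_lf",      0.55,   0.95,   "linear",
    "M_t",       0.1,    0.9,    "linear",
    "T_d",       7,      30,     "linear",
    "alpha_es",  0,      1,      "linear",
    "alpha_ei",  0,      1,      "linear",
    "alpha_ls",  0,      1,      "linear",
    "alpha_li",  0,      1,      "linear"
  )
  beta_n <- tibble::tibble(
    name = c("beta_ALP", "beta_OC", "beta_ARS", "n_ALP", "n_OC", "n_ARS"),
    lower = c(0, 0, 0, 0.5, 0.5, 0.5),
    upper = c(2, 2, 2, 3, 3, 3),
    scale = "linear"
  )
  ks <- tibble::tibble(name = k_names, lower = 0.1, upper = 10, scale = "log")
  dplyr::bind_rows(pri, beta_n, ks)
}

#' @rdname model_parameters
#' @param study_id Integer study id in 1..5.
#' @return `relevant_parameters()`: character vector of registry names that
#'   enter the given study's computation (other studies' correction factors
#'   and unused signal anchors are excluded).
#' @export
relevant_parameters <- function(study_id) {
  study_id <- as.integer(study_id)
  if (!study_id %in% 1:5) stop("study_id must be in 1..5", call. = FALSE)
  core <- c("p_es", "p_ef", "p_evf", "p_ls", "p_lf", "M_t", "T_d",
            "alpha_es", "alpha_ei", "alpha_ls", "alpha_li")
  switch(
    study_id,
    c("p_ms", "p_md", core, "beta_ALP", "n_ALP", "k_ALP_1"),
    c("p_ms", "p_md", core, "beta_ALP", "n_ALP", "beta_OC", "n_OC",
      "k_ALP_2", "k_OC_2"),
    c(core, "beta_ALP", "n_ALP", "beta_ARS", "n_ARS", "k_ALP_3", "k_ARS_3"),
    c(core, "beta_ALP", "n_ALP", "beta_ARS", "n_ARS", "k_ALP_4", "k_ARS_4"),
    c("p_8f", "p_1bs", "p_1bie", core, "beta_ALP", "n_ALP", "k_ALP_5")
  )
}

#' @export
tidy.osteo_params <- function(x, ...) {
  tibble::tibble(name = names(x), value = as.numeric(x)) |>
    dplyr::left_join(parameter_priors(), by = "name")
}
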