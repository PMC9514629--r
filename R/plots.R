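#' Plot the membership functions of a linguistic variable
#'
#' @param object A [fz_variable()].
#' @param n Number of abscissa points.
#' @param ... Unused.
#' @return A ggplot with one curve per linguistic level.
#' @export
autoplot.fz_variable <- function(object, n = 400, ...) {
  grid <- seq(object$min, object$max, length.out = n)
  df <- purrr::imap_dfr(object$levels, function(mf, lv) {
    tibble::tibble(x = grid, degree = fz_degree(mf, grid), level = lv)
  })
  df$level <- factor(df$level, levels = names(object$levels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$degree,
                                   colour = .data$level)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = paste0(object$name,
                             if (nzchar(object$units)) paste0(" [", object$units, "]")),
                  y = "membership degree", colour = NULL,
                  title = paste("Linguistic variable:", object$name)) +
    ggplot2::theme_minimal()
}

#' Plot a maturity trajectory
#'
#' @param trajectory A tibble from [integrate_maturity()].
#' @return A ggplot of maturity over time, coloured by phase.
#' @export
plot_maturity <- function(trajectory) {
  stopifnot(all(c("t_day", "maturity", "phase") %in% names(trajectory)))
  ggplot2::ggplot(trajectory,
                  ggplot2::aes(x = .data$t_day, y = .data$maturity,
                               colour = .data$phase, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [days]", y = "maturity") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a repeated-calibration summary
#'
#' Shows the inferred value of each parameter (mean over DE runs) with the
#' first/second-half means overlaid, all scaled by the prior length -- the
#' visual form of the half-split convergence check.
#'
#' @param object An `osteo_calibration` object.
#' @param ... Unused.
#' @export
autoplot.osteo_calibration <- function(object, ...) {
  s <- object$summary
  len <- s$upper - s$lower
  df <- tidyr::pivot_longer(
    tibble::tibble(parameter = s$parameter,
                   all = (s$mean - s$lower) / len,
                   half1 = (s$half1_mean - s$lower) / len,
                   half2 = (s$half2_mean - s$lower) / len),
    -"parameter", names_to = "runs", values_to = "scaled")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter, y = .data$scaled,
                                   shape = .data$runs, colour = .data$runs)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "inferred value (scaled by prior length)", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot an LSSP sensitivity ranking
#'
#' @param ranking A tibble from [lssp()].
#' @param top_n Show the leading `top_n` parameters per study.
#' @return A bar chart of main-effect magnitudes, faceted by study.
#' @export
plot_sensitivity <- function(ranking, top_n = 5) {
  stopifnot(all(c("study_id", "parameter", "effect", "rank") %in% names(ranking)))
  df <- ranking[ranking$rank <= top_n, ]
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$parameter, -.data$effect),
                                   y = .data$effect)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~study_id, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "main effect (normalized outputs)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
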