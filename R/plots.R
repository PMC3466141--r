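#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a match-quality report
#'
#' Lollipop chart of one-sided p-values per matching variable, with the
#' reading guides at 0.05 (peer matching significantly better) and 0.95
#' (listed matching significantly better).
#'
#' @param object An `mq_quality_report` from [match_quality_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mq_quality_report <- function(object, ...) {
  df <- object[!is.na(object$p_one_sided), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_one_sided,
                                   y = stats::reorder(.data$variable,
                                                      .data$p_one_sided))) +
    ggplot2::geom_vline(xintercept = c(0.05, 0.95), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_segment(ggplot2::aes(x = 0.5, xend = .data$p_one_sided,
                                       yend = stats::reorder(.data$variable,
                                                             .data$p_one_sided)),
                          colour = "grey70") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(
      x = "one-sided p (toward 0: peer matching better; toward 1: listed better)",
      y = NULL, title = "Pair-level match quality by variable")
}

#' Plot a marginal-test report
#'
#' Two-sided p-values per variable, one panel column per comparison group.
#'
#' @param object An `mq_marginal_report` from [marginal_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mq_marginal_report <- function(object, ...) {
  df <- object[!is.na(object$p_two_sided), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_two_sided, y = .data$variable)) +
    ggplot2::geom_vline(xintercept = 0.05, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::facet_wrap(~group_pair) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "two-sided p (marginal distributions)", y = NULL,
                  title = "Marginal-distribution tests")
}

#' Plot the permutation null distribution
#'
#' Histogram of the null statistics with the observed statistic and its null
#' expectation marked.
#'
#' @param object A `perm_test` object retaining its null statistics.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perm_test <- function(object, ...) {
  if (is.null(object$null_statistics)) {
    mq_abort("this perm_test did not retain its null statistics",
             class = "matchqual_config_error")
  }
  df <- tibble::tibble(statistic = object$null_statistics)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey75", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$statistic, colour = "red") +
    ggplot2::geom_vline(xintercept = object$e_null, linetype = "dashed") +
    ggplot2::labs(x = "null statistic", y = "count",
                  title = "Permutation null distribution",
                  subtitle = sprintf("observed = %.2f (red), null mean = %.2f",
                                     object$statistic, object$e_null))
}

#' Plot recruitment funnels
#'
#' Stacked bar of funnel-stage counts per recruitment arm.
#'
#' @param ledger A recruitment ledger (see [validate_ledger()]).
#' @return A ggplot object.
#' @export
plot_recruitment_funnel <- function(ledger) {
  validate_ledger(ledger)
  stage_cols <- c("n_completed", intersect(ledger_stage_columns(), names(ledger)))
  long <- tidyr::pivot_longer(ledger[, c("arm", stage_cols)],
                              -"arm", names_to = "stage", values_to = "count")
  long$stage <- sub("^n_", "", long$stage)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$arm, y = .data$count,
                                     fill = .data$stage)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "telephone numbers",
                  title = "Recruitment funnel by arm")
}
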