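#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a structured permutation test
#'
#' @param x A `perm_test` (or `marginal_test`) object.
#' @param ... Unused.
#' @return A one-row tibble with the observed statistic, p-values, method
#'   and sample-structure counts.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    statistic_type = x$statistic_type,
    p_one_sided = x$p_one_sided,
    p_two_sided = x$p_two_sided,
    method = x$method,
    n_permutations = x$n_permutations %||% NA_integer_,
    n_paired = x$n_paired %||% NA_integer_)
}

#' Glance at a structured permutation test
#'
#' @inheritParams tidy.perm_test
#' @return A one-row tibble of design counts: group sizes, paired and
#'   unpaired contributions, and the size of the permutation space.
#' @export
glance.perm_test <- function(x, ...) {
  tibble::tibble(
    n_a = x$n_a,
    n_b = x$n_b,
    n_paired = x$n_paired %||% NA_integer_,
    n_arrangements = x$n_arrangements,
    e_null = x$e_null,
    method = x$method)
}

#' Tidy a study report into one long table
#'
#' Stacks the match-quality and marginal rows of a [run_study()] report into
#' a single tibble with an `analysis` column, convenient for downstream
#' filtering and plotting.
#'
#' @param x A `study_report`.
#' @param ... Unused.
#' @return A tibble with columns `analysis`, `variable`, `group_pair`,
#'   `statistic`, `p_value`, `method`.
#' @export
tidy.study_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      analysis = "match_quality",
      variable = x$quality$variable,
      group_pair = "peer_vs_listed",
      statistic = x$quality$statistic,
      p_value = x$quality$p_one_sided,
      method = x$quality$method),
    tibble::tibble(
      analysis = "marginal",
      variable = x$marginal$variable,
      group_pair = x$marginal$group_pair,
      statistic = x$marginal$statistic,
      p_value = x$marginal$p_two_sided,
      method = x$marginal$method))
}
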