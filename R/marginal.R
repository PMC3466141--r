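# Marginal (whole-group) distribution tests with a permutation null that
# respects the matched structure: within each matched set the group labels are
# permuted preserving the set's group counts; observations in sets without a
# counterpart are pooled and re-assigned preserving the overall group counts.

# Build exchangeability blocks for index vs comparison values.
# index_values: named by survivor_id (unique names); comparison_values: named
# by the survivor they are matched to (names may repeat when a survivor has
# two peers).
marginal_blocks <- function(index_values, comparison_values) {
  index_values <- index_values[!is.na(index_values)]
  comparison_values <- comparison_values[!is.na(comparison_values)]
  ids <- names(index_values)
  cmp_ids <- names(comparison_values)
  blocks <- list()
  unpaired_a <- c()
  unpaired_b <- c()
  for (id in ids) {
    cv <- comparison_values[cmp_ids == id]
    if (length(cv)) {
      blocks[[length(blocks) + 1L]] <-
        list(a = unname(index_values[[id]]), b = unname(cv))
    } else {
      unpaired_a <- c(unpaired_a, unname(index_values[[id]]))
    }
  }
  n_paired <- length(blocks)
  orphan <- !cmp_ids %in% ids
  if (any(orphan)) unpaired_b <- c(unpaired_b, unname(comparison_values[orphan]))
  if (length(unpaired_a) || length(unpaired_b)) {
    blocks[[length(blocks) + 1L]] <- list(a = unpaired_a, b = unpaired_b)
  }
  attr(blocks, "n_paired") <- n_paired
  blocks
}

marginal_counts <- function(blocks) {
  n_index <- sum(vapply(blocks, function(b) length(b$a), integer(1)))
  n_cmp <- sum(vapply(blocks, function(b) length(b$b), integer(1)))
  list(n_index = n_index, n_comparison = n_cmp,
       n_paired = attr(blocks, "n_paired"))
}

#' Marginal permutation test for a continuous variable
#'
#' Two-sided test of whether the marginal distribution of a variable in the
#' index group (survivors) differs from that in a comparison group, using the
#' rank-sum statistic and a permutation null that respects the matched
#' structure: labels are swapped within matched sets, and subjects without a
#' counterpart are pooled and re-assigned preserving group counts. The
#' two-sided p-value is the null probability of a rank sum at least as far
#' from its null expectation as the observed one.
#'
#' @param index_values Named numeric vector of index-group values, names are
#'   survivor identifiers.
#' @param comparison_values Named numeric vector of comparison-group values,
#'   named by the survivor each subject is matched to (names may repeat when
#'   a survivor nominated two peers).
#' @inheritParams permutation_test_partially_paired
#' @return A `marginal_test`/`perm_test` object with `p_two_sided`,
#'   group sizes, and per-group summaries (mean, SD).
#' @examples
#' # identical marginal multisets in a fully paired design: p = 1
#' s <- c(a = 1, b = 10, c = 1, d = 10)
#' p <- c(a = 10, b = 1, c = 10, d = 1)
#' marginal_test_continuous(s, p)$p_two_sided
#' @export
marginal_test_continuous <- function(index_values, comparison_values,
                                     n_permutations = 2000L, seed = NULL,
                                     method = c("auto", "exact_enumeration",
                                                "monte_carlo"),
                                     exact_cap = 1e6) {
  method <- match.arg(method)
  index_values <- index_values[!is.na(index_values)]
  comparison_values <- comparison_values[!is.na(comparison_values)]
  if (length(index_values) < 2 || length(comparison_values) < 2) {
    mq_abort("need at least two complete cases per group",
             class = "matchqual_insufficient_data")
  }
  blocks <- marginal_blocks(index_values, comparison_values)
  res <- perm_test_blocks(blocks, statistic = "ranksum",
                          n_permutations = n_permutations, seed = seed,
                          method = method, exact_cap = exact_cap)
  res[names(marginal_counts(blocks))] <- marginal_counts(blocks)
  res$summary_index <- c(mean = mean(index_values), sd = stats::sd(index_values))
  res$summary_comparison <- c(mean = mean(comparison_values),
                              sd = stats::sd(comparison_values))
  class(res) <- c("marginal_test", class(res))
  res
}

#' Marginal permutation test for a categorical variable
#'
#' Two-sided test of whether category compositions differ between the index
#' and a comparison group. The statistic is the chi-square deviation of the
#' 2-by-K group-by-category table from its margins-fixed expectation; the
#' p-value comes from the same matched-structure permutation null as
#' [marginal_test_continuous()] (the table margins are invariant under these
#' permutations, so the statistic is comparable across arrangements). A
#' single pooled category is a degenerate input and yields p = 1 with a
#' `degenerate` flag.
#'
#' @param index_values,comparison_values Named character/factor vectors (see
#'   [marginal_test_continuous()] for the naming convention).
#' @inheritParams marginal_test_continuous
#' @return A `marginal_test`/`perm_test` object; summaries are category
#'   proportions.
#' @export
marginal_test_categorical <- function(index_values, comparison_values,
                                      n_permutations = 2000L, seed = NULL,
                                      method = c("auto", "exact_enumeration",
                                                 "monte_carlo"),
                                      exact_cap = 1e6) {
  method <- match.arg(method)
  index_values <- index_values[!is.na(index_values)]
  comparison_values <- comparison_values[!is.na(comparison_values)]
  if (length(index_values) < 2 || length(comparison_values) < 2) {
    mq_abort("need at least two complete cases per group",
             class = "matchqual_insufficient_data")
  }
  blocks <- marginal_blocks(index_values, comparison_values)
  res <- perm_test_blocks(blocks, statistic = "chisq",
                          n_permutations = n_permutations, seed = seed,
                          method = method, exact_cap = exact_cap)
  res[names(marginal_counts(blocks))] <- marginal_counts(blocks)
  res$summary_index <- proportions(table(index_values))
  res$summary_comparison <- proportions(table(comparison_values))
  class(res) <- c("marginal_test", class(res))
  res
}

#' Marginal-distribution report for both comparison groups
#'
#' Runs the appropriate marginal test (rank-sum for continuous/ordinal-rank
#' variables, chi-square deviation for binary/nominal) for every declared
#' variable against each comparison group. Complete cases are taken per
#' variable and group pair; survivors lacking a comparison subject in the
#' tested group contribute as unpaired observations, so the survivor sample
#' size stays at its complete-case maximum.
#'
#' @inheritParams match_quality_report
#' @return A tibble of class `mq_marginal_report` with one row per
#'   (variable, group pair): sample sizes, list-column summaries, statistic,
#'   `p_two_sided`, `method`, `seed`, `note`.
#' @export
marginal_report <- function(cohort, varspecs = default_varspecs(),
                            n_permutations = 2000L, seed = NULL,
                            method = c("auto", "exact_enumeration",
                                       "monte_carlo"),
                            exact_cap = 1e6) {
  method <- match.arg(method)
  cohort <- as_cohort(cohort, varspecs)
  if (nrow(cohort$participants) == 0) {
    mq_abort("cohort is empty", class = "matchqual_insufficient_data")
  }
  p <- cohort$participants
  survivors <- p[p$group == "survivor", , drop = FALSE]

  grid <- tidyr::expand_grid(vi = seq_len(nrow(varspecs)),
                             cmp_group = c("peer", "listed"))
  rows <- purrr::pmap_dfr(grid, function(vi, cmp_group) {
    spec <- varspecs[vi, ]
    var <- spec$name
    cmp <- p[p$group == cmp_group, , drop = FALSE]
    idx_vals <- stats::setNames(survivors[[var]], survivors$subject_id)
    cmp_vals <- stats::setNames(cmp[[var]], cmp$survivor_link)
    # ordinal variables are tested on their rank scale
    if (spec$scale == "ordinal") {
      lv <- spec$levels[[1]]
      idx_vals <- stats::setNames(match(idx_vals, lv), names(idx_vals))
      cmp_vals <- stats::setNames(match(cmp_vals, lv), names(cmp_vals))
    }
    continuous <- spec$scale %in% c("continuous", "ordinal")
    seed_v <- derive_seed(seed, 100L + 2L * vi + (cmp_group == "listed"))
    group_pair <- paste0("survivor_vs_", cmp_group)

    n_idx <- sum(!is.na(idx_vals)); n_cmp <- sum(!is.na(cmp_vals))
    if (n_idx < 2 || n_cmp < 2) {
      return(tibble::tibble(
        variable = var, group_pair = group_pair,
        n_index = n_idx, n_comparison = n_cmp,
        summary_index = list(NULL), summary_comparison = list(NULL),
        statistic = NA_real_, p_two_sided = NA_real_,
        method = NA_character_, seed = seed_v %||% NA_integer_,
        note = "insufficient data: fewer than two complete cases in a group"))
    }
    fit <- if (continuous) {
      marginal_test_continuous(idx_vals, cmp_vals,
                               n_permutations = n_permutations,
                               seed = seed_v, method = method,
                               exact_cap = exact_cap)
    } else {
      marginal_test_categorical(idx_vals, cmp_vals,
                                n_permutations = n_permutations,
                                seed = seed_v, method = method,
                                exact_cap = exact_cap)
    }
    tibble::tibble(
      variable = var, group_pair = group_pair,
      n_index = fit$n_index, n_comparison = fit$n_comparison,
      summary_index = list(fit$summary_index),
      summary_comparison = list(fit$summary_comparison),
      statistic = fit$statistic, p_two_sided = fit$p_two_sided,
      method = fit$method, seed = seed_v %||% NA_integer_,
      note = if (isTRUE(fit$degenerate)) {
        "degenerate input: single pooled category"
      } else NA_character_)
  })
  class(rows) <- c("mq_marginal_report", class(rows))
  rows
}
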