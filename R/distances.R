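#' Within-pair distance on one matching variable
#'
#' The absolute difference between an index subject's value and a comparison
#' subject's value, on the scale declared in the variable specification:
#' continuous variables use the absolute difference, ordinal variables the
#' absolute rank difference on the declared level order, and binary/nominal
#' variables a 0/1 mismatch indicator. Any missing input yields a missing
#' distance (complete-case handling happens per variable downstream).
#' Vectorised over the value pair.
#'
#' @param index_value,comparison_value Values of the variable for the two
#'   members of a pair.
#' @param spec A one-row varspec tibble (see [varspec()]).
#' @return Non-negative numeric distance(s), `NA` where either value is
#'   missing.
#' @examples
#' pair_distance(64, 64, varspec("age", "continuous")) # 0
#' pair_distance(1, 10, varspec("x", "continuous"))    # 9
#' pair_distance("post-HS", "less-than-HS",
#'   varspec("education", "ordinal",
#'           levels = c("less-than-HS", "HS-grad", "post-HS"))) # 2
#' @export
pair_distance <- function(index_value, comparison_value, spec) {
  stopifnot(is.data.frame(spec), nrow(spec) == 1)
  scale <- spec$scale
  if (scale == "continuous") {
    return(abs(as.numeric(index_value) - as.numeric(comparison_value)))
  }
  if (scale == "ordinal") {
    lv <- spec$levels[[1]]
    ri <- match(as.character(index_value), lv)
    rc <- match(as.character(comparison_value), lv)
    bad <- (!is.na(index_value) & is.na(ri)) | (!is.na(comparison_value) & is.na(rc))
    if (any(bad)) {
      vals <- unique(c(as.character(index_value), as.character(comparison_value)))
      mq_abort(sprintf(
        "value(s) %s of ordinal variable '%s' are not in the declared levels (%s)",
        paste(setdiff(vals[!is.na(vals)], lv), collapse = ", "),
        spec$name, paste(lv, collapse = " < ")),
        class = "matchqual_spec_error")
    }
    return(abs(ri - rc))
  }
  # binary / nominal: mismatch indicator
  ifelse(is.na(index_value) | is.na(comparison_value), NA_real_,
         as.numeric(as.character(index_value) != as.character(comparison_value)))
}

#' Per-variable pair distances for a cohort
#'
#' Computes, for every matched set and every declared variable, the
#' within-pair distance between the survivor and each comparison group.
#' Survivors with two completed peers contribute one peer distance per the
#' `peer_rule`: `"first"` (default) uses the first enrolled peer (lowest
#' subject identifier), `"mean"` averages the available peers' distances.
#'
#' @param cohort A `cohort` object (or participant data frame).
#' @param varspecs Variable specifications.
#' @param peer_rule How a survivor with two peers contributes: `"first"` or
#'   `"mean"`.
#' @return A tibble with columns `variable`, `survivor_id`, `group`
#'   (`"peer"` or `"listed"`), `distance` (`NA` when a value is missing or no
#'   comparison subject exists).
#' @export
pair_distances <- function(cohort, varspecs = default_varspecs(),
                           peer_rule = c("first", "mean")) {
  peer_rule <- match.arg(peer_rule)
  cohort <- as_cohort(cohort, varspecs)
  p <- cohort$participants
  sets <- cohort$matched_sets

  value_of <- function(ids, var) p[[var]][match(ids, p$subject_id)]

  purrr::map_dfr(seq_len(nrow(varspecs)), function(vi) {
    spec <- varspecs[vi, ]
    var <- spec$name
    sv <- value_of(sets$survivor_id, var)

    peer_dist <- purrr::map2_dbl(sets$peer_ids, sv, function(pids, s) {
      if (length(pids) == 0) return(NA_real_)
      if (peer_rule == "first") pids <- pids[1]
      d <- pair_distance(rep(s, length(pids)), value_of(pids, var), spec)
      d <- d[!is.na(d)]
      if (length(d) == 0) NA_real_ else mean(d)
    })
    listed_dist <- ifelse(is.na(sets$listed_id), NA_real_,
                          pair_distance(sv, value_of(sets$listed_id, var), spec))

    tibble::tibble(
      variable = var,
      survivor_id = rep(sets$survivor_id, 2),
      group = rep(c("peer", "listed"), each = nrow(sets)),
      distance = c(peer_dist, listed_dist))
  })
}

#' Match-quality report: one permutation test per matching variable
#'
#' For each variable, computes the within-pair absolute differences for the
#' peer-nominated and listed comparison groups and runs the partially paired
#' rank-sum permutation test of [permutation_test_partially_paired()].
#' Small one-sided p-values mean the peer matching is better (peer distances
#' stochastically smaller); values near 1 mean the listed matching is better.
#' Complete cases are taken per variable, so the contributing sample sizes
#' vary across rows. Variables for which one group has no usable distance are
#' flagged rather than dropped.
#'
#' @inheritParams pair_distances
#' @inheritParams permutation_test_partially_paired
#' @param seed Base seed; each variable uses a seed derived from it, so the
#'   whole report is reproducible.
#' @return A tibble of class `mq_quality_report` with columns `variable`,
#'   `n_peer`, `n_listed`, `n_paired`, `statistic`, `p_one_sided`, `method`,
#'   `seed`, `note`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_survivors = 30), seed = 1)
#' match_quality_report(cohort, n_permutations = 200, seed = 1)
#' @export
match_quality_report <- function(cohort, varspecs = default_varspecs(),
                                 n_permutations = 2000L, seed = NULL,
                                 method = c("auto", "exact_enumeration",
                                            "monte_carlo"),
                                 peer_rule = c("first", "mean"),
                                 exact_cap = 1e6) {
  method <- match.arg(method)
  peer_rule <- match.arg(peer_rule)
  cohort <- as_cohort(cohort, varspecs)
  if (nrow(cohort$participants) == 0) {
    mq_abort("cohort is empty", class = "matchqual_insufficient_data")
  }
  dist <- pair_distances(cohort, varspecs, peer_rule = peer_rule)

  rows <- purrr::map_dfr(seq_len(nrow(varspecs)), function(vi) {
    var <- varspecs$name[vi]
    d <- dist[dist$variable == var & !is.na(dist$distance), , drop = FALSE]
    peer <- stats::setNames(d$distance[d$group == "peer"],
                            d$survivor_id[d$group == "peer"])
    listed <- stats::setNames(d$distance[d$group == "listed"],
                              d$survivor_id[d$group == "listed"])
    seed_v <- derive_seed(seed, vi)
    if (length(peer) == 0 || length(listed) == 0) {
      return(tibble::tibble(
        variable = var, n_peer = length(peer), n_listed = length(listed),
        n_paired = 0L, statistic = NA_real_, p_one_sided = NA_real_,
        method = NA_character_, seed = seed_v %||% NA_integer_,
        note = "insufficient data: one group has no usable distances"))
    }
    res <- permutation_test_partially_paired(
      peer, listed, n_permutations = n_permutations, seed = seed_v,
      method = method, exact_cap = exact_cap)
    tibble::tibble(
      variable = var, n_peer = length(peer), n_listed = length(listed),
      n_paired = res$n_paired, statistic = res$statistic,
      p_one_sided = res$p_one_sided, method = res$method,
      seed = seed_v %||% NA_integer_, note = NA_character_)
  })
  class(rows) <- c("mq_quality_report", class(rows))
  rows
}
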