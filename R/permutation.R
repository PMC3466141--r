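#' Rank-sum statistic with midranks
#'
#' Sum of the pooled-sample midranks (average ranks for ties) of the first
#' group. This is the Wilcoxon rank-sum statistic used as the test statistic
#' throughout the package; p-values always come from a structured permutation
#' null, never from the asymptotic distribution.
#'
#' @param group_a,group_b Numeric vectors of observations (e.g. within-pair
#'   absolute differences). Both must be non-empty.
#' @return The sum of midranks of `group_a` within the pooled sample.
#' @examples
#' rank_sum_statistic(c(1, 2), c(3, 4)) # ranks 1 + 2 = 3
#' @export
rank_sum_statistic <- function(group_a, group_b) {
  group_a <- as.numeric(group_a)
  group_b <- as.numeric(group_b)
  if (length(group_a) == 0 || length(group_b) == 0) {
    mq_abort("both groups must contain at least one observation",
             class = "matchqual_insufficient_data")
  }
  if (anyNA(group_a) || anyNA(group_b)) {
    mq_abort("rank_sum_statistic() does not accept missing values",
             class = "matchqual_data_error")
  }
  r <- rank(c(group_a, group_b), ties.method = "average")
  sum(r[seq_along(group_a)])
}

# ---------------------------------------------------------------------------
# Exchangeability-block permutation engine.
#
# A "block" is a set of observations whose group labels are exchangeable under
# the null while the number assigned to group A stays fixed:
#   * a paired survivor contributes a block of size 2 with one A-slot
#     (within-pair label swap);
#   * a matched set with one survivor and two comparison subjects is a block
#     of size 3 with one A-slot;
#   * all unpaired observations form a single block whose A-slot count is the
#     observed number of unpaired A observations (count-preserving
#     reassignment).
# The null distribution is over independent uniform re-assignments within each
# block. Exact mode enumerates the cartesian product of within-block choices;
# Monte Carlo samples it.
# ---------------------------------------------------------------------------

# blocks: list of list(a = values observed in group A, b = values in group B)
# statistic: "ranksum" (values numeric; lower-tail and two-sided p reported)
#            "chisq"   (values are category labels; upper-tail p reported)
perm_test_blocks <- function(blocks,
                             statistic = c("ranksum", "chisq"),
                             n_permutations = 2000L,
                             seed = NULL,
                             method = c("auto", "exact_enumeration", "monte_carlo"),
                             exact_cap = 1e6) {
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  n_permutations <- as.integer(n_permutations)
  if (!is.na(n_permutations) && n_permutations < 1) {
    mq_abort("n_permutations must be a positive integer",
             class = "matchqual_config_error")
  }

  a_all <- unlist(lapply(blocks, `[[`, "a"), use.names = FALSE)
  b_all <- unlist(lapply(blocks, `[[`, "b"), use.names = FALSE)
  if (length(a_all) == 0 || length(b_all) == 0) {
    mq_abort("each group needs at least one observation",
             class = "matchqual_insufficient_data")
  }

  pooled <- c(a_all, b_all)
  if (statistic == "ranksum") {
    vals <- rank(as.numeric(pooled), ties.method = "average")
  } else {
    f <- factor(pooled)
    vals <- as.integer(f)
    n_cat <- nlevels(f)
  }
  # re-slot pooled-scale values back into the block structure
  sizes_a <- vapply(blocks, function(b) length(b$a), integer(1))
  sizes_b <- vapply(blocks, function(b) length(b$b), integer(1))
  a_idx <- split(seq_len(length(a_all)), rep(seq_along(blocks), sizes_a))
  b_idx <- split(length(a_all) + seq_len(length(b_all)),
                 rep(seq_along(blocks), sizes_b))
  blk <- lapply(seq_along(blocks), function(j) {
    av <- vals[a_idx[[as.character(j)]] %||% integer(0)]
    bv <- vals[b_idx[[as.character(j)]] %||% integer(0)]
    list(values = c(av, bv), n_a = length(av), m = length(av) + length(bv))
  })
  names(blk) <- NULL

  n_a_total <- length(a_all)
  n_total <- length(pooled)

  log_arr <- sum(vapply(blk, function(b) lchoose(b$m, b$n_a), numeric(1)))
  n_arrangements <- if (log_arr < log(.Machine$double.xmax)) exp(log_arr) else Inf
  if (method == "auto") {
    method <- if (n_arrangements <= exact_cap) "exact_enumeration" else "monte_carlo"
  }
  if (method == "exact_enumeration" && n_arrangements > exact_cap) {
    mq_abort(sprintf(paste0(
      "exact enumeration needs %.3g arrangements (cap %.3g); ",
      "use method = \"monte_carlo\""), n_arrangements, exact_cap),
      class = "matchqual_capacity_error")
  }

  if (statistic == "ranksum") {
    obs <- sum(vapply(blk, function(b) {
      if (b$n_a) sum(b$values[seq_len(b$n_a)]) else 0
    }, numeric(1)))
    e_null <- sum(vapply(blk, function(b) {
      b$n_a / b$m * sum(b$values)
    }, numeric(1)))
    if (method == "exact_enumeration") {
      null_stats <- exact_ranksum_stats(blk)
      p_one <- mean(null_stats <= obs + STAT_TOL)
      p_two <- mean(abs(null_stats - e_null) >= abs(obs - e_null) - STAT_TOL)
      p_tie <- mean(abs(null_stats - obs) <= STAT_TOL)
    } else {
      null_stats <- with_local_seed(seed, mc_ranksum_stats(blk, n_permutations))
      p_one <- (1 + sum(null_stats <= obs + STAT_TOL)) / (n_permutations + 1)
      p_two <- (1 + sum(abs(null_stats - e_null) >= abs(obs - e_null) - STAT_TOL)) /
        (n_permutations + 1)
      p_tie <- (1 + sum(abs(null_stats - obs) <= STAT_TOL)) / (n_permutations + 1)
    }
  } else {
    tot_counts <- tabulate(vals, nbins = n_cat)
    obs_counts <- tabulate(
      unlist(lapply(blk, function(b) b$values[seq_len(b$n_a)]), use.names = FALSE),
      nbins = n_cat)
    chisq_of <- function(counts_a) {
      # counts_a: matrix (arrangements x categories) of group-A counts
      e_a <- n_a_total * tot_counts / n_total
      e_b <- (n_total - n_a_total) * tot_counts / n_total
      counts_b <- matrix(tot_counts, nrow(counts_a), n_cat, byrow = TRUE) - counts_a
      rowSums(sweep(counts_a, 2, e_a)^2 / rep(e_a, each = nrow(counts_a))) +
        rowSums(sweep(counts_b, 2, e_b)^2 / rep(e_b, each = nrow(counts_b)))
    }
    obs <- chisq_of(matrix(obs_counts, 1))
    e_null <- NA_real_
    degenerate <- n_cat < 2
    if (degenerate) {
      return(new_perm_test(
        statistic = 0, statistic_type = "chisq", p_one_sided = 1, p_two_sided = 1,
        p_tie = 1, e_null = 0, method = "exact_enumeration",
        n_permutations = NA_integer_, seed = seed,
        n_arrangements = 1, n_a = n_a_total, n_b = n_total - n_a_total,
        null_statistics = 0, degenerate = TRUE))
    }
    if (method == "exact_enumeration") {
      counts <- exact_category_counts(blk, n_cat)
      null_stats <- chisq_of(counts)
      p_two <- mean(null_stats >= obs - STAT_TOL)
      p_one <- p_two
      p_tie <- mean(abs(null_stats - obs) <= STAT_TOL)
    } else {
      counts <- with_local_seed(seed, mc_category_counts(blk, n_cat, n_permutations))
      null_stats <- chisq_of(counts)
      p_two <- (1 + sum(null_stats >= obs - STAT_TOL)) / (n_permutations + 1)
      p_one <- p_two
      p_tie <- (1 + sum(abs(null_stats - obs) <= STAT_TOL)) / (n_permutations + 1)
    }
    e_null <- mean(null_stats)
  }

  new_perm_test(
    statistic = as.numeric(obs),
    statistic_type = statistic,
    p_one_sided = p_one,
    p_two_sided = p_two,
    p_tie = p_tie,
    e_null = e_null,
    method = method,
    n_permutations = if (method == "monte_carlo") n_permutations else NA_integer_,
    seed = if (method == "monte_carlo") seed else NULL,
    n_arrangements = n_arrangements,
    n_a = n_a_total,
    n_b = n_total - n_a_total,
    null_statistics = if (length(null_stats) <= 1e5) as.numeric(null_stats) else NULL,
    degenerate = FALSE)
}

new_perm_test <- function(...) {
  structure(list(...), class = "perm_test")
}

# enumerate the null rank-sum distribution by expanding block-wise
# combination sums (cartesian product over blocks)
exact_ranksum_stats <- function(blk) {
  sums <- 0
  for (b in blk) {
    if (b$n_a == 0 || b$n_a == b$m) {
      bs <- if (b$n_a) sum(b$values) else 0
    } else if (b$n_a == 1) {
      bs <- b$values
    } else {
      bs <- utils::combn(b$values, b$n_a, sum)
    }
    sums <- as.vector(outer(sums, bs, `+`))
  }
  sums
}

mc_ranksum_stats <- function(blk, B) {
  total <- numeric(B)
  # vectorise the common block shapes
  swap2 <- Filter(function(b) b$m == 2 && b$n_a == 1, blk)
  rest <- Filter(function(b) !(b$m == 2 && b$n_a == 1), blk)
  if (length(swap2)) {
    v1 <- vapply(swap2, function(b) b$values[1], numeric(1))
    v2 <- vapply(swap2, function(b) b$values[2], numeric(1))
    k <- length(swap2)
    s <- matrix(stats::runif(k * B) < 0.5, k, B)
    total <- total + sum(v1) + drop((v2 - v1) %*% s)
  }
  for (b in rest) {
    if (b$n_a == 0) next
    if (b$n_a == b$m) {
      total <- total + sum(b$values)
    } else if (choose(b$m, b$n_a) <= 5000) {
      bs <- if (b$n_a == 1) b$values else utils::combn(b$values, b$n_a, sum)
      total <- total + bs[sample.int(length(bs), B, replace = TRUE)]
    } else {
      total <- total + vapply(seq_len(B), function(i) {
        sum(b$values[sample.int(b$m, b$n_a)])
      }, numeric(1))
    }
  }
  total
}

exact_category_counts <- function(blk, n_cat) {
  counts <- matrix(0, 1, n_cat)
  for (b in blk) {
    if (b$n_a == 0) next
    if (b$n_a == b$m) {
      counts <- counts + matrix(tabulate(b$values, n_cat),
                                nrow(counts), n_cat, byrow = TRUE)
      next
    }
    choice_idx <- utils::combn(b$m, b$n_a)
    bc <- t(apply(choice_idx, 2, function(ix) tabulate(b$values[ix], n_cat)))
    n0 <- nrow(counts); n1 <- nrow(bc)
    counts <- counts[rep(seq_len(n0), times = n1), , drop = FALSE] +
      bc[rep(seq_len(n1), each = n0), , drop = FALSE]
  }
  counts
}

mc_category_counts <- function(blk, n_cat, B) {
  counts <- matrix(0, B, n_cat)
  swap2 <- Filter(function(b) b$m == 2 && b$n_a == 1, blk)
  rest <- Filter(function(b) !(b$m == 2 && b$n_a == 1), blk)
  if (length(swap2)) {
    k <- length(swap2)
    c1 <- vapply(swap2, function(b) b$values[1], integer(1))
    c2 <- vapply(swap2, function(b) b$values[2], integer(1))
    s <- matrix(stats::runif(k * B) < 0.5, k, B)
    chosen <- matrix(c1, k, B) + s * (matrix(c2, k, B) - matrix(c1, k, B))
    for (bi in seq_len(B)) {
      counts[bi, ] <- counts[bi, ] + tabulate(chosen[, bi], n_cat)
    }
  }
  for (b in rest) {
    if (b$n_a == 0) next
    if (b$n_a == b$m) {
      counts <- counts + matrix(tabulate(b$values, n_cat), B, n_cat, byrow = TRUE)
    } else {
      for (bi in seq_len(B)) {
        ix <- sample.int(b$m, b$n_a)
        counts[bi, ] <- counts[bi, ] + tabulate(b$values[ix], n_cat)
      }
    }
  }
  counts
}

#' Permutation test for match quality with partially paired distances
#'
#' Tests whether within-pair distances in one comparison group (the
#' peer-nominated group) are stochastically smaller — i.e. the matching is
#' better — than in the other (the listed sample), when some index subjects
#' contribute a distance to both groups (correlated observations) and others
#' to only one. The test statistic is the midrank sum of the peer distances
#' in the pooled sample. The null distribution respects the dependence
#' structure: for every survivor with a distance in both groups the two
#' labels are swapped with probability 1/2; all remaining (unpaired)
#' distances are pooled and re-assigned labels uniformly, preserving the
#' observed group counts. Exact mode enumerates every arrangement; Monte
#' Carlo samples them and counts the observed arrangement among the
#' permutations, so p-values are never zero.
#'
#' The one-sided p-value is the null probability of a rank sum less than or
#' equal to the observed one: small values mean the peer distances are
#' unusually small (peer matching better); values near 1 mean the listed
#' matching is better.
#'
#' @param peer_distances,listed_distances Non-negative numeric vectors of
#'   within-pair distances, named by the survivor (index subject) identifier.
#'   Shared names define the paired part of the data.
#' @param n_permutations Number of Monte Carlo permutations (ignored in exact
#'   mode).
#' @param seed Integer seed for the Monte Carlo draw; `NULL` leaves the RNG
#'   state untouched.
#' @param method `"auto"` picks exact enumeration whenever the total number
#'   of label arrangements is at most `exact_cap`, otherwise Monte Carlo.
#' @param exact_cap Largest enumeration size accepted in exact mode.
#' @return A `perm_test` object with elements `statistic` (observed peer rank
#'   sum), `p_one_sided`, `p_two_sided` (null probability of a deviation from
#'   the null mean at least as large as observed), `p_tie`, `method`,
#'   `n_paired`, `n_peer_only`, `n_listed_only`, `n_arrangements`, and the
#'   null statistics. Use [generics::tidy()] for a one-row tibble.
#' @examples
#' peer <- c(s1 = 0, s2 = 0, s3 = 0, s4 = 0)
#' listed <- c(s1 = 5, s2 = 5, s3 = 5, s4 = 5)
#' permutation_test_partially_paired(peer, listed)$p_one_sided # 1/16
#' @export
permutation_test_partially_paired <- function(peer_distances,
                                              listed_distances,
                                              n_permutations = 2000L,
                                              seed = NULL,
                                              method = c("auto", "exact_enumeration",
                                                         "monte_carlo"),
                                              exact_cap = 1e6) {
  method <- match.arg(method)
  peer_distances <- peer_distances[!is.na(peer_distances)]
  listed_distances <- listed_distances[!is.na(listed_distances)]
  if (length(peer_distances) == 0 || length(listed_distances) == 0) {
    mq_abort("each comparison group needs at least one usable distance",
             class = "matchqual_insufficient_data")
  }
  if (any(peer_distances < 0) || any(listed_distances < 0)) {
    mq_abort("distances must be non-negative", class = "matchqual_data_error")
  }
  if (is.null(names(peer_distances)) || is.null(names(listed_distances))) {
    mq_abort("distance vectors must be named by survivor identifier",
             class = "matchqual_data_error")
  }
  paired_ids <- intersect(names(peer_distances), names(listed_distances))
  peer_only <- setdiff(names(peer_distances), paired_ids)
  listed_only <- setdiff(names(listed_distances), paired_ids)

  blocks <- lapply(paired_ids, function(id) {
    list(a = unname(peer_distances[id]), b = unname(listed_distances[id]))
  })
  if (length(peer_only) || length(listed_only)) {
    blocks <- c(blocks, list(list(a = unname(peer_distances[peer_only]),
                                  b = unname(listed_distances[listed_only]))))
  }

  res <- perm_test_blocks(blocks, statistic = "ranksum",
                          n_permutations = n_permutations, seed = seed,
                          method = method, exact_cap = exact_cap)
  res$n_paired <- length(paired_ids)
  res$n_peer_only <- length(peer_only)
  res$n_listed_only <- length(listed_only)
  res$groups <- c("peer", "listed")
  res
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Structured permutation test (", x$statistic_type, " statistic)\n", sep = "")
  cat("  observed statistic:", format(x$statistic), "\n")
  if (!is.null(x$n_paired)) {
    cat("  paired:", x$n_paired, " A-only:", x$n_peer_only %||% x$n_index_only,
        " B-only:", x$n_listed_only %||% x$n_comparison_only, "\n")
  }
  cat("  method:", x$method,
      if (x$method == "monte_carlo") paste0("(", x$n_permutations, " permutations)")
      else sprintf("(%.0f arrangements)", x$n_arrangements), "\n")
  if (x$statistic_type == "ranksum") {
    cat("  p (one-sided, group A smaller):", format(x$p_one_sided), "\n")
  }
  cat("  p (two-sided):", format(x$p_two_sided), "\n")
  invisible(x)
}
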