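test_that("rank-sum statistic uses midranks for ties", {
  expect_equal(rank_sum_statistic(c(1, 2), c(3, 4)), 3)
  # pooled {1,1,1,2} has midranks (2,2,2,4); frozen via the oracle routine
  expect_equal(oracle_ranksum(c(1, 1), c(1, 2)), 4)
  expect_equal(rank_sum_statistic(c(1, 1), c(1, 2)), 4)
  # identical multisets of size n: symmetry forces n(2n+1)/2
  for (n in c(2, 5, 9)) {
    x <- stats::rnorm(n)
    expect_equal(rank_sum_statistic(x, x), n * (2 * n + 1) / 2)
  }
  expect_error(rank_sum_statistic(numeric(0), 1),
               class = "matchqual_insufficient_data")
})

test_that("exact enumeration reproduces hand-derived p-values", {
  peer <- c(s1 = 0, s2 = 0, s3 = 0, s4 = 0)
  listed <- c(s1 = 5, s2 = 5, s3 = 5, s4 = 5)
  res <- permutation_test_partially_paired(peer, listed)
  expect_equal(res$method, "exact_enumeration")
  expect_equal(res$p_one_sided, 1 / 16)
  expect_equal(res$n_paired, 4)

  # all distances identical: every permutation ties the observed statistic
  tied <- permutation_test_partially_paired(
    c(a = 2, b = 2, u = 2), c(a = 2, b = 2, v = 2))
  expect_equal(tied$p_one_sided, 1)
  expect_equal(tied$p_two_sided, 1)
})

test_that("exact enumeration agrees with the brute-force oracle", {
  for (seed in 1:8) {
    fx <- random_fixture(seed, max_paired = 5)
    ora <- oracle_partially_paired(fx$peer, fx$listed)
    res <- permutation_test_partially_paired(fx$peer, fx$listed,
                                             method = "exact_enumeration")
    expect_equal(res$statistic, ora$obs, info = paste("seed", seed))
    expect_equal(res$p_one_sided, ora$p_one, info = paste("seed", seed))
    expect_equal(res$p_two_sided, ora$p_two, info = paste("seed", seed))
    expect_equal(sort(res$null_statistics), sort(ora$stats),
                 info = paste("seed", seed))
  }
})

test_that("Monte Carlo converges to the exact p-value", {
  peer <- c(s1 = 0, s2 = 0, s3 = 0, s4 = 0)
  listed <- c(s1 = 5, s2 = 5, s3 = 5, s4 = 5)
  B <- 1e5
  res <- permutation_test_partially_paired(peer, listed, n_permutations = B,
                                           seed = 42, method = "monte_carlo")
  se <- sqrt(0.0625 * (1 - 0.0625) / B)
  expect_lt(abs(res$p_one_sided - 0.0625), 3 * se)
})

test_that("results are deterministic given input, seed and n_permutations", {
  fx <- random_fixture(21)
  a <- permutation_test_partially_paired(fx$peer, fx$listed,
                                         n_permutations = 500, seed = 7,
                                         method = "monte_carlo")
  b <- permutation_test_partially_paired(fx$peer, fx$listed,
                                         n_permutations = 500, seed = 7,
                                         method = "monte_carlo")
  expect_identical(a[c("statistic", "p_one_sided", "p_two_sided")],
                   b[c("statistic", "p_one_sided", "p_two_sided")])
})

test_that("swapping the groups maps exact p to 1 - p + P(tie)", {
  for (seed in 11:16) {
    fx <- random_fixture(seed, max_paired = 5)
    fwd <- permutation_test_partially_paired(fx$peer, fx$listed,
                                             method = "exact_enumeration")
    rev <- permutation_test_partially_paired(fx$listed, fx$peer,
                                             method = "exact_enumeration")
    expect_equal(rev$p_one_sided, 1 - fwd$p_one_sided + fwd$p_tie,
                 tolerance = 1e-12, info = paste("seed", seed))
  }
})

test_that("p-values stay in [0, 1] across random inputs", {
  for (seed in 31:40) {
    fx <- random_fixture(seed)
    res <- permutation_test_partially_paired(fx$peer, fx$listed,
                                             n_permutations = 200, seed = seed)
    expect_gte(res$p_one_sided, 0)
    expect_lte(res$p_one_sided, 1)
    expect_gte(res$p_two_sided, 0)
    expect_lte(res$p_two_sided, 1)
  }
})

test_that("capacity and degenerate-input errors are raised", {
  n <- 40
  peer <- stats::setNames(stats::runif(n), sprintf("s%d", 1:n))
  listed <- stats::setNames(stats::runif(n), sprintf("s%d", 1:n))
  expect_error(
    permutation_test_partially_paired(peer, listed,
                                      method = "exact_enumeration"),
    "monte_carlo", class = "matchqual_capacity_error")
  # auto mode falls back to Monte Carlo instead
  res <- permutation_test_partially_paired(peer, listed, n_permutations = 100,
                                           seed = 1)
  expect_equal(res$method, "monte_carlo")
  expect_error(
    permutation_test_partially_paired(c(a = 1), numeric(0)),
    class = "matchqual_insufficient_data")
  expect_error(
    permutation_test_partially_paired(c(a = -1), c(a = 1)),
    class = "matchqual_data_error")
})
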