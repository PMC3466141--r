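test_that("identical marginal multisets in a paired design give p = 1", {
  s <- c(a = 1, b = 10, c = 1, d = 10)
  p <- c(a = 10, b = 1, c = 10, d = 1)
  res <- marginal_test_continuous(s, p, method = "exact_enumeration")
  expect_equal(res$p_two_sided, 1)
  expect_equal(unname(res$summary_index[["mean"]]), 5.5)
  expect_equal(unname(res$summary_comparison[["mean"]]), 5.5)

  # literally identical vectors tie every permutation too
  same <- c(a = 3, b = 4, c = 5)
  expect_equal(marginal_test_continuous(same, same,
                                        method = "exact_enumeration")$p_two_sided, 1)
})

test_that("a fully separated paired sample gives exact two-sided p = 2/16", {
  s <- c(a = 1, b = 2, c = 3, d = 4)
  cmp <- c(a = 11, b = 12, c = 13, d = 14)
  res <- marginal_test_continuous(s, cmp, method = "exact_enumeration")
  expect_equal(res$p_two_sided, 2 / 16)
})

test_that("categorical marginal test matches enumeration on small designs", {
  # perfectly disjoint categories, 5 pairs: only identity and full swap are
  # as extreme, 2 of 32 arrangements
  ix <- stats::setNames(rep("A", 5), letters[1:5])
  cx <- stats::setNames(rep("B", 5), letters[1:5])
  res <- marginal_test_categorical(ix, cx, method = "exact_enumeration")
  expect_equal(res$p_two_sided, 2 / 32)

  # identical compositions with paired structure: observed deviation is the
  # minimum, so p = 1
  ix2 <- stats::setNames(rep(c("M", "F"), c(5, 2)), sprintf("s%d", 1:7))
  cx2 <- stats::setNames(rep(c("M", "F"), c(5, 2)), sprintf("s%d", 1:7))
  res2 <- marginal_test_categorical(ix2, cx2, method = "exact_enumeration")
  expect_equal(res2$p_two_sided, 1)
})

test_that("a single pooled category is degenerate: p = 1 plus a flag", {
  ix <- stats::setNames(rep("M", 4), letters[1:4])
  cx <- stats::setNames(rep("M", 4), letters[1:4])
  res <- marginal_test_categorical(ix, cx)
  expect_equal(res$p_two_sided, 1)
  expect_true(res$degenerate)
})

test_that("the two-sided p is invariant to exchanging the group labels", {
  set.seed(99)
  for (i in 1:5) {
    n <- sample(3:6, 1)
    ids <- sprintf("s%d", seq_len(n))
    a <- stats::setNames(round(stats::rnorm(n, 0, 2), 1), ids)
    b <- stats::setNames(round(stats::rnorm(n, 1, 2), 1), ids)
    # add an unpaired observation on each side
    a <- c(a, ua = 1.5)
    b <- c(b, ub = -0.5)
    f <- marginal_test_continuous(a, b, method = "exact_enumeration")
    r <- marginal_test_continuous(b, a, method = "exact_enumeration")
    expect_equal(f$p_two_sided, r$p_two_sided, tolerance = 1e-12)
  }
})

test_that("two-peer matched sets enter as three-member exchangeability blocks", {
  # one survivor with two peers: 3 x 2 = 6 arrangements with the second set
  idx <- c(s1 = 1, s2 = 2)
  cmp <- stats::setNames(c(10, 11, 12), c("s1", "s1", "s2"))
  res <- marginal_test_continuous(idx, cmp, method = "exact_enumeration")
  expect_equal(res$n_arrangements, 6)
  expect_equal(res$n_index, 2)
  expect_equal(res$n_comparison, 3)
})

test_that("marginal_report covers both group pairs with per-variable Ns", {
  cohort <- generate_cohort(cohort_config(n_survivors = 25), seed = 3)
  rep <- marginal_report(cohort, n_permutations = 200, seed = 5)
  expect_equal(nrow(rep), 2 * nrow(default_varspecs()))
  expect_setequal(unique(rep$group_pair),
                  c("survivor_vs_peer", "survivor_vs_listed"))
  ok <- !is.na(rep$p_two_sided)
  expect_true(all(rep$p_two_sided[ok] >= 0 & rep$p_two_sided[ok] <= 1))
  # survivor complete-case N is not reduced by missing comparison subjects
  age_rows <- rep[rep$variable == "age", ]
  expect_equal(age_rows$n_index, c(25L, 25L))

  # determinism
  rep2 <- marginal_report(cohort, n_permutations = 200, seed = 5)
  expect_identical(rep$p_two_sided, rep2$p_two_sided)
})

test_that("an all-identical cohort yields p = 1 everywhere", {
  df <- dplyr::bind_rows(
    purrr::map_dfr(1:6, function(i) {
      blank_participant_row(sprintf("S%d", i), "survivor", sprintf("S%d", i))
    }),
    purrr::map_dfr(1:6, function(i) {
      blank_participant_row(sprintf("P%d", i), "peer", sprintf("S%d", i))
    }),
    purrr::map_dfr(1:6, function(i) {
      blank_participant_row(sprintf("L%d", i), "listed", sprintf("S%d", i))
    }))
  rep <- marginal_report(df, n_permutations = 100, seed = 1)
  ok <- !is.na(rep$p_two_sided)
  expect_true(any(ok))
  expect_true(all(rep$p_two_sided[ok] == 1))
})
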