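test_that("cost per completed interview reproduces the published table", {
  expect_equal(cost_per_complete(25, 0.65), 38.46)
  expect_equal(cost_per_complete(25, 0.40), 62.50)
  expect_equal(cost_per_complete(25, 0.60), 41.66) # truncation at cents
  expect_equal(cost_per_complete(25, 0.60, rounding = "half_up"), 41.67)
  expect_error(cost_per_complete(25, 0), class = "matchqual_domain_error")
})

test_that("total arm costs multiply out exactly to cents", {
  expect_equal(total_cost(62.50, 44), 2750.00)
  expect_equal(total_cost(41.66, 101), 4207.66)
  expect_equal(total_cost(38.46, 0), 0)
  expect_error(total_cost(-1, 10), class = "matchqual_domain_error")
})

test_that("yields reproduce each published figure under its convention", {
  expect_equal(yield_rate(100, 372, digits = 0, rounding = "half_up"), 27)
  expect_equal(yield_rate(44, 91), 48.3)
  expect_equal(yield_rate(101, 544, digits = 0, rounding = "half_up"), 19)
  expect_equal(yield_rate(0, 50), 0)
  expect_error(yield_rate(1, 0), class = "matchqual_domain_error")
  expect_error(yield_rate(5, 4), class = "matchqual_domain_error")
})

test_that("yield is invariant to scaling numerator and denominator", {
  for (k in c(2L, 7L, 30L)) {
    expect_equal(yield_rate(44 * k, 91 * k), yield_rate(44, 91))
  }
})

test_that("total cost agrees with rate * n / productivity up to cent rounding", {
  set.seed(1)
  for (i in 1:50) {
    r <- stats::runif(1, 10, 60)
    c_hr <- stats::runif(1, 0.2, 1.5)
    n <- sample(1:200, 1)
    tc <- total_cost(cost_per_complete(r, c_hr), n)
    expect_lt(abs(tc - r * n / c_hr), 0.01 * n + 0.005)
    expect_gte(tc, 0)
    expect_equal(tc, round(tc, 2))
  }
})

test_that("accounting report composes yields, costs and stage echo per arm", {
  ledger <- tibble::tibble(
    arm = c("survivor", "peer", "listed"),
    n_candidates = c(378, 91, 980),
    n_usable = c(372, 91, 544),
    n_completed = c(100, 44, 101),
    n_refused = c(20, 12, 117),
    completes_per_hour = c(0.65, 0.40, 0.60),
    hourly_rate = 25,
    yield_denom = c("usable", "candidates", "usable"))
  rep <- accounting_report(ledger)
  expect_equal(rep$cost_per_complete, c(38.46, 62.50, 41.66))
  expect_equal(rep$total_cost[rep$arm == "peer"], 2750.00)
  expect_equal(rep$total_cost[rep$arm == "listed"], 4207.66)
  expect_equal(rep$yield_pct, c(27, 48, 19))
  expect_true("n_refused" %in% names(rep))

  expect_error(accounting_report(dplyr::bind_rows(ledger, ledger[1, ])),
               class = "matchqual_schema_error")
  expect_equal(nrow(accounting_report(ledger[0, ])), 0)
})

test_that("ledger validation enforces funnel count ordering", {
  bad <- tibble::tibble(arm = "peer", n_candidates = 50, n_usable = 60,
                        n_completed = 10, completes_per_hour = 0.4,
                        hourly_rate = 25, yield_denom = "usable")
  expect_error(validate_ledger(bad), class = "matchqual_validation_error")
  bad2 <- bad
  bad2$n_usable <- 40; bad2$n_completed <- 45
  expect_error(validate_ledger(bad2), class = "matchqual_validation_error")
})
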