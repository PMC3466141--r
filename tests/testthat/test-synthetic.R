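test_that("generation is deterministic given config and seed", {
  cfg <- cohort_config(n_survivors = 12)
  a <- generate_cohort(cfg, seed = 8)
  b <- generate_cohort(cfg, seed = 8)
  expect_identical(a$participants, b$participants)
  c <- generate_cohort(cfg, seed = 9)
  expect_false(identical(a$participants, c$participants))
})

test_that("hard matching constraints hold on every generated row", {
  cohort <- generate_cohort(cohort_config(n_survivors = 60), seed = 2)
  p <- cohort$participants
  sv <- p[p$group == "survivor", ]
  li <- p[p$group == "listed", ]
  m <- match(li$survivor_link, sv$subject_id)
  expect_true(all(li$sex == sv$sex[m]))
  expect_true(all(abs(li$age - sv$age[m]) <= 5))
  expect_false(any(p$cancer_history[p$group != "survivor"]))
  expect_true(all(p$age > 0))
  expect_true(all(p$days_smoked_30 >= 0 & p$days_smoked_30 <= 30))
})

test_that("perfect fidelity copies each survivor into its peers exactly", {
  cfg <- cohort_config(n_survivors = 25, fidelity = perfect_fidelity(),
                       missing_rate = 0)
  p <- generate_cohort(cfg, seed = 6)$participants
  pe <- p[p$group == "peer", ]
  sv <- p[p$group == "survivor", ]
  m <- match(pe$survivor_link, sv$subject_id)
  for (v in c("sex", "race", "age", "education", "employment",
              "days_smoked_30", "age_first_cig", "age_last_cig",
              "is_current_smoker", "alc_freq_month", "alc_typical",
              "alc_six_freq")) {
    expect_equal(pe[[v]], sv[[v]][m], info = v)
  }
})

test_that("shift = 0 reduces the shifted generator to the null generator", {
  cfg <- cohort_config(n_survivors = 20)
  a <- generate_null_cohort(cfg, seed = 13)
  b <- generate_shifted_cohort(cfg, shift = 0, seed = 13)
  expect_identical(a$participants, b$participants)
  expect_error(generate_shifted_cohort(cfg, shift = -1, seed = 1),
               class = "matchqual_config_error")
})

test_that("a positive shift inflates listed age distances by that amount", {
  cfg <- cohort_config(n_survivors = 200, missing_rate = 0)
  null_d <- distance_vectors(generate_null_cohort(cfg, seed = 3),
                             age_only_varspec())
  shift_d <- distance_vectors(generate_shifted_cohort(cfg, shift = 4, seed = 3),
                              age_only_varspec())
  # same seed: listed distances grow by exactly the shift, peers untouched
  expect_equal(shift_d$peer, null_d$peer)
  expect_equal(unname(shift_d$listed), unname(null_d$listed) + 4,
               tolerance = 1e-9)
})

test_that("nomination funnel hits its configured expectations", {
  cfg <- cohort_config(n_survivors = 100)
  counts <- vapply(1:40, function(i) {
    p <- generate_cohort(cfg, seed = 300 + i)$participants
    pe <- p[p$group == "peer", ]
    c(nominating = length(unique(pe$survivor_link)), peers = nrow(pe))
  }, numeric(2))
  # completed peers average near 91 * 0.483 = 44; nominating survivors with
  # a completed peer are fewer than the 61 nominators (contact failures)
  expect_lt(abs(mean(counts["peers", ]) - 44), 3)
  expect_true(all(counts["peers", ] <= 200))
})

test_that("recruitment ledger generation conserves funnel counts", {
  led <- generate_recruitment_ledger(cohort_config(), seed = 4)
  expect_identical(led, generate_recruitment_ledger(cohort_config(), seed = 4))
  stage_cols <- c("n_completed", "n_refused", "n_callback", "n_ineligible",
                  "n_deceased", "n_partial", "n_nonworking", "n_other")
  expect_equal(rowSums(led[, stage_cols]), led$n_usable,
               ignore_attr = TRUE)
  expect_true(all(led$n_completed <= led$n_usable))
  expect_true(all(led$n_usable <= led$n_candidates))

  # all-success configuration: everyone completes
  fun <- default_funnel()
  fun$survivor$stages <- c(completed = 1)
  fun$survivor$n_not_used <- 0
  cfg <- cohort_config(funnel = fun)
  led2 <- generate_recruitment_ledger(cfg, seed = 1)
  srow <- led2[led2$arm == "survivor", ]
  expect_equal(srow$n_completed, srow$n_candidates)
  expect_equal(srow$n_refused + srow$n_callback + srow$n_other, 0)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(peer_nomination_prob = 1.2),
               class = "matchqual_config_error")
  expect_error(cohort_config(n_survivors = 0),
               class = "matchqual_config_error")
  expect_error(cohort_config(listed_age_window = 0),
               class = "matchqual_config_error")
  fun <- default_funnel()
  fun$peer$stages <- c(completed = 0.9, refused = 0.3)
  expect_error(generate_recruitment_ledger(cohort_config(funnel = fun), seed = 1),
               class = "matchqual_config_error")
})
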