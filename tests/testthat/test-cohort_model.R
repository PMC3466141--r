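test_that("smoking duration follows the first/last-cigarette rule", {
  expect_equal(derive_smoking_duration(18, 50, 64, FALSE), 32)
  expect_equal(derive_smoking_duration(20, NA, 60, TRUE), 40)
  expect_true(is.na(derive_smoking_duration(NA, NA, 70, FALSE)))
  # former smoker with unknown quit age: undefined
  expect_true(is.na(derive_smoking_duration(18, NA, 70, FALSE)))
  # vectorised
  expect_equal(
    derive_smoking_duration(c(18, 20, NA), c(50, NA, NA), c(64, 60, 70),
                            c(FALSE, TRUE, FALSE)),
    c(32, 40, NA))
  expect_error(derive_smoking_duration(50, 18, 64, FALSE),
               class = "matchqual_data_error")
})

test_that("a minimal well-formed CSV reads into one matched set", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- dplyr::bind_rows(
    blank_participant_row("S1", "survivor", "S1"),
    blank_participant_row("P1", "peer", "S1"),
    blank_participant_row("L1", "listed", "S1"))
  readr::write_csv(df, path)
  cohort <- read_cohort(path)
  expect_s3_class(cohort, "cohort")
  expect_equal(nrow(cohort$matched_sets), 1)
  expect_equal(cohort$matched_sets$peer_ids[[1]], "P1")
  expect_equal(cohort$matched_sets$listed_id, "L1")
})

test_that("comparison subjects with a cancer history are screened out", {
  df <- dplyr::bind_rows(
    blank_participant_row("S1", "survivor", "S1"),
    blank_participant_row("P1", "peer", "S1", cancer_history = TRUE),
    blank_participant_row("L1", "listed", "S1"))
  expect_message(cohort <- as_cohort(df), "P1")
  expect_false("P1" %in% cohort$participants$subject_id)
  expect_equal(attr(cohort, "excluded")$subject_id, "P1")
  # the filter never leaves an ineligible comparison subject behind
  p <- cohort$participants
  expect_false(any(p$cancer_history[p$group != "survivor"]))
})

test_that("dangling and overfull links are linkage errors naming the culprit", {
  df <- dplyr::bind_rows(
    blank_participant_row("S1", "survivor", "S1"),
    blank_participant_row("L9", "listed", "S404"))
  expect_error(as_cohort(df), "L9", class = "matchqual_linkage_error")

  three_peers <- dplyr::bind_rows(
    blank_participant_row("S1", "survivor", "S1"),
    purrr::map_dfr(1:3, function(i) {
      blank_participant_row(sprintf("P%d", i), "peer", "S1")
    }))
  expect_error(as_cohort(three_peers), "S1",
               class = "matchqual_linkage_error")

  two_listed <- dplyr::bind_rows(
    blank_participant_row("S1", "survivor", "S1"),
    blank_participant_row("L1", "listed", "S1"),
    blank_participant_row("L2", "listed", "S1"))
  expect_error(as_cohort(two_listed), "S1",
               class = "matchqual_linkage_error")
})

test_that("schema and row-level validation errors are specific", {
  df <- blank_participant_row("S1", "survivor", "S1")
  expect_error(as_cohort(df[, setdiff(names(df), "sex")]),
               "sex", class = "matchqual_schema_error")
  bad_age <- blank_participant_row("S1", "survivor", "S1", age = -3)
  expect_error(as_cohort(bad_age), class = "matchqual_validation_error")
  bad_days <- blank_participant_row("S1", "survivor", "S1", days_smoked_30 = 45)
  expect_error(as_cohort(bad_days), class = "matchqual_validation_error")

  path <- withr::local_tempfile(fileext = ".csv")
  txt <- paste(paste(names(df), collapse = ","),
               "S1,survivor,S1,M,white,not-a-number,post-HS,retired,0,,,FALSE,1,1,0,TRUE",
               sep = "\n")
  writeLines(txt, path)
  expect_error(read_cohort(path), "row", class = "matchqual_validation_error")
})

test_that("matched sets are order-independent and handle missing matches", {
  df <- dplyr::bind_rows(
    blank_participant_row("S1", "survivor", "S1"),
    blank_participant_row("S2", "survivor", "S2"),
    blank_participant_row("P1", "peer", "S1"))
  sets <- build_matched_sets(df)
  expect_equal(nrow(sets), 2)
  expect_equal(lengths(sets$peer_ids), c(1L, 0L))
  expect_true(all(is.na(sets$listed_id)))

  shuffled <- df[c(3, 1, 2), ]
  expect_identical(build_matched_sets(shuffled), sets)

  empty <- df[0, ]
  expect_equal(nrow(build_matched_sets(empty)), 0)
})

test_that("write/read round-trip reproduces the cohort field-identically", {
  cohort <- generate_cohort(cohort_config(n_survivors = 15), seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(back$participants, cohort$participants, tolerance = 1e-12)
  expect_equal(back$matched_sets, cohort$matched_sets)
})

test_that("varspec YAML round-trips including ordinal level order", {
  specs <- default_varspecs()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_varspecs(specs, path)
  back <- read_varspecs(path)
  expect_equal(back, specs)
  expect_error(varspec("education", "ordinal", levels = c("a", "a")),
               class = "matchqual_spec_error")
})
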