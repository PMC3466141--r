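# Programmatic fixtures: minimal participant tables built in code.

blank_participant_row <- function(subject_id, group, survivor_link,
                                  age = 60, sex = "M", race = "white",
                                  education = "post-HS",
                                  employment = "retired",
                                  days_smoked_30 = 0,
                                  age_first_cig = NA_real_,
                                  age_last_cig = NA_real_,
                                  is_current_smoker = FALSE,
                                  alc_freq_month = 1,
                                  alc_typical = 1,
                                  alc_six_freq = 0,
                                  cancer_history = group == "survivor") {
  tibble::tibble(
    subject_id = subject_id, group = group, survivor_link = survivor_link,
    sex = sex, race = race, age = age, education = education,
    employment = employment, days_smoked_30 = days_smoked_30,
    age_first_cig = age_first_cig, age_last_cig = age_last_cig,
    is_current_smoker = is_current_smoker, alc_freq_month = alc_freq_month,
    alc_typical = alc_typical, alc_six_freq = alc_six_freq,
    cancer_history = cancer_history)
}

# the cautionary 4-pair example: survivor ages (1,10,1,10), matched listed
# ages (10,1,10,1) — equal marginal means, every pair distance 9
toy_counterexample_cohort <- function() {
  ages_s <- c(1, 10, 1, 10)
  ages_l <- c(10, 1, 10, 1)
  dplyr::bind_rows(
    purrr::map_dfr(1:4, function(i) {
      blank_participant_row(sprintf("S%d", i), "survivor", sprintf("S%d", i),
                            age = ages_s[i])
    }),
    purrr::map_dfr(1:4, function(i) {
      blank_participant_row(sprintf("L%d", i), "listed", sprintf("S%d", i),
                            age = ages_l[i])
    }))
}

# fully paired cohort with peer distances 0 and listed distances 5 on age
four_pair_separated_cohort <- function() {
  dplyr::bind_rows(
    purrr::map_dfr(1:4, function(i) {
      blank_participant_row(sprintf("S%d", i), "survivor", sprintf("S%d", i),
                            age = 60 + i)
    }),
    purrr::map_dfr(1:4, function(i) {
      blank_participant_row(sprintf("P%d", i), "peer", sprintf("S%d", i),
                            age = 60 + i)
    }),
    purrr::map_dfr(1:4, function(i) {
      blank_participant_row(sprintf("L%d", i), "listed", sprintf("S%d", i),
                            age = 65 + i)
    }))
}

age_only_varspec <- function() default_varspecs()[default_varspecs()$name == "age", ]

# pull one variable's distances as the named vectors the test functions take
distance_vectors <- function(cohort, spec) {
  d <- pair_distances(cohort, spec)
  d <- d[!is.na(d$distance), , drop = FALSE]
  list(
    peer = stats::setNames(d$distance[d$group == "peer"],
                           d$survivor_id[d$group == "peer"]),
    listed = stats::setNames(d$distance[d$group == "listed"],
                             d$survivor_id[d$group == "listed"]))
}
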