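#' Derive lifetime smoking duration
#'
#' Duration of smoking in years: age at last cigarette minus age at first
#' cigarette, with current age standing in for the age at last cigarette in
#' current smokers. Never-smokers (missing age at first cigarette) get a
#' missing duration, as do former smokers whose age at last cigarette is
#' unknown. Vectorised.
#'
#' @param age_first_cig,age_last_cig Ages in years (may be `NA`).
#' @param current_age Current age in years.
#' @param is_current_smoker Logical.
#' @return Numeric vector of durations in years (`NA` where undefined).
#' @examples
#' derive_smoking_duration(18, 50, 64, FALSE) # 32
#' derive_smoking_duration(20, NA, 60, TRUE)  # 40
#' derive_smoking_duration(NA, NA, 70, FALSE) # NA (never-smoker)
#' @export
derive_smoking_duration <- function(age_first_cig, age_last_cig,
                                    current_age, is_current_smoker) {
  last <- ifelse(!is.na(is_current_smoker) & is_current_smoker,
                 current_age, age_last_cig)
  dur <- last - age_first_cig
  neg <- !is.na(dur) & dur < 0
  if (any(neg)) {
    mq_abort(sprintf(
      "negative smoking duration at position(s) %s (age at first cigarette exceeds last)",
      paste(which(neg), collapse = ", ")),
      class = "matchqual_data_error")
  }
  dur
}

cohort_columns <- function() {
  c("subject_id", "group", "survivor_link", "sex", "race", "age",
    "education", "employment", "days_smoked_30", "age_first_cig",
    "age_last_cig", "is_current_smoker", "alc_freq_month", "alc_typical",
    "alc_six_freq", "cancer_history")
}

#' Build matched sets from a participant table
#'
#' One matched set per survivor: the survivor plus the peer(s) and listed
#' subject linked to it through `survivor_link`. Survivors with no completed
#' comparison subject yield sets with empty match slots. Deterministic and
#' independent of input row order (peers are ordered by subject identifier).
#'
#' @param participants A participant tibble (see [read_cohort()] for columns).
#' @return A tibble with columns `survivor_id`, `peer_ids` (list-column,
#'   0-2 identifiers each), `listed_id` (`NA` when absent).
#' @export
build_matched_sets <- function(participants) {
  if (nrow(participants) == 0) {
    return(tibble::tibble(survivor_id = character(),
                          peer_ids = list(), listed_id = character()))
  }
  survivors <- participants$subject_id[participants$group == "survivor"]
  link_check(participants, survivors)

  comparisons <- participants[participants$group != "survivor", , drop = FALSE]
  sets <- tibble::tibble(survivor_id = sort(survivors))
  peers <- comparisons[comparisons$group == "peer", , drop = FALSE]
  listed <- comparisons[comparisons$group == "listed", , drop = FALSE]

  peer_map <- split(sort(peers$subject_id),
                    factor(peers$survivor_link[order(peers$subject_id)],
                           levels = sets$survivor_id))
  n_peers <- lengths(peer_map)
  if (any(n_peers > 2)) {
    mq_abort(sprintf("survivor(s) %s linked to more than two peers",
                     paste(names(n_peers)[n_peers > 2], collapse = ", ")),
             class = "matchqual_linkage_error")
  }
  listed_tab <- table(factor(listed$survivor_link, levels = sets$survivor_id))
  if (any(listed_tab > 1)) {
    mq_abort(sprintf("survivor(s) %s linked to more than one listed subject",
                     paste(names(listed_tab)[listed_tab > 1], collapse = ", ")),
             class = "matchqual_linkage_error")
  }
  listed_map <- stats::setNames(listed$subject_id, listed$survivor_link)

  sets$peer_ids <- unname(peer_map[sets$survivor_id])
  sets$listed_id <- unname(listed_map[sets$survivor_id])
  sets$listed_id[is.na(sets$listed_id)] <- NA_character_
  sets
}

link_check <- function(participants, survivors) {
  cmp <- participants[participants$group != "survivor", , drop = FALSE]
  dangling <- is.na(cmp$survivor_link) | !cmp$survivor_link %in% survivors
  if (any(dangling)) {
    mq_abort(sprintf(
      "comparison subject(s) %s link to no existing survivor",
      paste(cmp$subject_id[dangling], collapse = ", ")),
      class = "matchqual_linkage_error")
  }
  invisible(TRUE)
}

#' Assemble and validate a cohort
#'
#' Validates a participant table against the cohort schema, applies the
#' eligibility screen (comparison-group subjects reporting a cancer history
#' are excluded, mirroring the study's telephone screen), derives lifetime
#' smoking duration, and builds the matched sets. The result is a `cohort`
#' object: a list with tibbles `participants` and `matched_sets`.
#'
#' @param participants A data frame with the columns listed under
#'   [read_cohort()].
#' @param varspecs Variable specifications; used to check that declared
#'   variables are present.
#' @return A `cohort` object. Excluded rows (failed eligibility) are kept in
#'   `attr(cohort, "excluded")`.
#' @export
as_cohort <- function(participants, varspecs = default_varspecs()) {
  if (inherits(participants, "cohort")) {
    return(participants)
  }
  validate_varspecs(varspecs)
  participants <- tibble::as_tibble(participants)

  required <- c("subject_id", "group", "survivor_link",
                setdiff(varspecs$name, "smoking_duration"))
  required <- union(required, c("age_first_cig", "age_last_cig",
                                "is_current_smoker", "cancer_history"))
  missing_cols <- setdiff(required, names(participants))
  if (length(missing_cols)) {
    mq_abort(sprintf("missing required column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             class = "matchqual_schema_error")
  }
  if (anyDuplicated(participants$subject_id)) {
    mq_abort("duplicate subject_id values", class = "matchqual_schema_error")
  }
  bad_group <- !participants$group %in% c("survivor", "peer", "listed")
  if (any(bad_group)) {
    mq_abort(sprintf("invalid group label in row(s) %s",
                     paste(which(bad_group), collapse = ", ")),
             class = "matchqual_schema_error")
  }
  bad_age <- !is.na(participants$age) & participants$age <= 0
  bad_days <- !is.na(participants$days_smoked_30) &
    (participants$days_smoked_30 < 0 | participants$days_smoked_30 > 30)
  if (any(bad_age) || any(bad_days)) {
    mq_abort(sprintf(
      "row-level validation failed: age must be positive (rows %s); days_smoked_30 must lie in [0, 30] (rows %s)",
      paste(which(bad_age), collapse = ", ") %|e|% "none",
      paste(which(bad_days), collapse = ", ") %|e|% "none"),
      class = "matchqual_validation_error")
  }

  # eligibility screen: comparison subjects must be cancer-free
  ineligible <- participants$group != "survivor" &
    !is.na(participants$cancer_history) & participants$cancer_history
  excluded <- participants[ineligible, , drop = FALSE]
  if (nrow(excluded)) {
    rlang::inform(sprintf(
      "excluded %d comparison-group subject(s) with a cancer history: %s",
      nrow(excluded), paste(excluded$subject_id, collapse = ", ")))
    participants <- participants[!ineligible, , drop = FALSE]
  }

  # survivors link to themselves
  is_surv <- participants$group == "survivor"
  participants$survivor_link[is_surv] <- participants$subject_id[is_surv]

  participants$smoking_duration <- derive_smoking_duration(
    participants$age_first_cig, participants$age_last_cig,
    participants$age, participants$is_current_smoker)

  sets <- build_matched_sets(participants)
  structure(list(participants = participants, matched_sets = sets),
            class = "cohort", excluded = excluded)
}

`%|e|%` <- function(x, y) if (identical(x, "")) y else x

#' Read a cohort from CSV
#'
#' Reads a long-format participant table (one row per subject; survivors,
#' peer-nominated and listed-sample subjects distinguished by `group`),
#' validates it, applies the cancer-history eligibility screen for
#' comparison subjects, and assembles matched sets. Missing values are empty
#' cells and propagate as `NA`; they are never imputed — downstream analyses
#' use per-variable complete cases.
#'
#' Expected columns: `subject_id`, `group` (survivor | peer | listed),
#' `survivor_link` (identifier of the survivor a comparison subject is
#' matched to), `sex`, `race`, `age`, `education`, `employment`,
#' `days_smoked_30`, `age_first_cig`, `age_last_cig`, `is_current_smoker`,
#' `alc_freq_month`, `alc_typical`, `alc_six_freq`, `cancer_history`.
#'
#' @param path CSV file path (UTF-8, header required).
#' @param varspecs Variable specifications (see [default_varspecs()]).
#' @return A `cohort` object.
#' @export
read_cohort <- function(path, varspecs = default_varspecs()) {
  if (!file.exists(path)) {
    mq_abort(sprintf("cohort file '%s' not found", path),
             class = "matchqual_io_error")
  }
  # parse problems surface as a structured validation error below
  raw <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    group = readr::col_character(),
    survivor_link = readr::col_character(),
    sex = readr::col_character(),
    race = readr::col_character(),
    age = readr::col_double(),
    education = readr::col_character(),
    employment = readr::col_character(),
    days_smoked_30 = readr::col_double(),
    age_first_cig = readr::col_double(),
    age_last_cig = readr::col_double(),
    is_current_smoker = readr::col_logical(),
    alc_freq_month = readr::col_double(),
    alc_typical = readr::col_double(),
    alc_six_freq = readr::col_double(),
    cancer_history = readr::col_logical()
  ), progress = FALSE, show_col_types = FALSE))
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    mq_abort(sprintf(
      "unparseable value(s) in row(s) %s of '%s'",
      paste(unique(probs$row), collapse = ", "), path),
      class = "matchqual_validation_error")
  }
  as_cohort(raw, varspecs = varspecs)
}

#' Write a cohort back to CSV
#'
#' Writes the participant table (original columns only; derived variables
#' such as smoking duration are recomputed on read, so a write/read
#' round-trip reproduces the cohort exactly).
#'
#' @param cohort A `cohort` object.
#' @param path Output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  readr::write_csv(cohort$participants[, cohort_columns()], path, progress = FALSE)
  invisible(path)
}

#' @export
print.cohort <- function(x, ...) {
  p <- x$participants
  n <- table(factor(p$group, levels = c("survivor", "peer", "listed")))
  cat("<cohort>", nrow(p), "participants:",
      n[["survivor"]], "survivors,", n[["peer"]], "peers,",
      n[["listed"]], "listed\n")
  n_excl <- nrow(attr(x, "excluded") %||% data.frame())
  if (n_excl) cat("  ", n_excl, "subject(s) excluded at eligibility screen\n")
  invisible(x)
}
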