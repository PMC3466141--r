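#' Run the full comparison-group study analysis
#'
#' One call composes the two analytic strategies — marginal-distribution
#' tests and pair-level match-quality tests — with the recruitment
#' accounting, on a cohort plus an optional recruitment ledger, and returns
#' a single study report. Deterministic given the seed.
#'
#' @param cohort A `cohort` object, participant data frame, or path to a
#'   cohort CSV.
#' @param varspecs A varspec tibble or path to a YAML varspec config.
#' @param ledger Optional ledger tibble or CSV path; when absent the
#'   accounting section of the report is marked absent.
#' @inheritParams match_quality_report
#' @param hourly_rate Optional hourly-rate override for the accounting
#'   table.
#' @return A `study_report` object: list with elements `metadata`,
#'   `marginal`, `quality`, `accounting` (`NULL` when no ledger), and a
#'   `warnings` tibble with machine-readable codes.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_survivors = 25), seed = 7)
#' ledger <- generate_recruitment_ledger(seed = 7)
#' report <- run_study(cohort, ledger = ledger, n_permutations = 200, seed = 7)
#' report
#' @export
run_study <- function(cohort, varspecs = default_varspecs(), ledger = NULL,
                      n_permutations = 2000L, seed = NULL,
                      method = c("auto", "exact_enumeration", "monte_carlo"),
                      peer_rule = c("first", "mean"), hourly_rate = NULL,
                      exact_cap = 1e6) {
  method <- match.arg(method)
  peer_rule <- match.arg(peer_rule)
  if (is.character(varspecs)) varspecs <- read_varspecs(varspecs)
  if (is.character(cohort)) cohort <- read_cohort(cohort, varspecs)
  cohort <- as_cohort(cohort, varspecs)
  if (is.character(ledger)) ledger <- read_ledger(ledger)

  marginal <- marginal_report(cohort, varspecs,
                              n_permutations = n_permutations, seed = seed,
                              method = method, exact_cap = exact_cap)
  quality <- match_quality_report(cohort, varspecs,
                                  n_permutations = n_permutations, seed = seed,
                                  method = method, peer_rule = peer_rule,
                                  exact_cap = exact_cap)
  accounting <- if (!is.null(ledger)) {
    accounting_report(ledger, hourly_rate = hourly_rate)
  }

  warnings <- dplyr::bind_rows(
    if (is.null(ledger)) {
      tibble::tibble(code = "no_ledger",
                     message = "no recruitment ledger supplied; accounting section absent")
    },
    {
      small <- quality[!is.na(quality$n_peer) &
                         (quality$n_peer < 10 | quality$n_listed < 10), ]
      if (nrow(small)) {
        tibble::tibble(code = "small_n",
                       message = sprintf(
                         "fewer than 10 usable distances for variable '%s'",
                         small$variable))
      }
    },
    {
      flagged <- quality[!is.na(quality$note), ]
      if (nrow(flagged)) {
        tibble::tibble(code = "no_distances",
                       message = sprintf("variable '%s': %s",
                                         flagged$variable, flagged$note))
      }
    })
  if (is.null(warnings)) {
    warnings <- tibble::tibble(code = character(), message = character())
  }

  structure(list(
    metadata = list(
      package = "matchqual",
      version = as.character(utils::packageVersion("matchqual")),
      seed = seed,
      n_permutations = as.integer(n_permutations),
      method = method,
      peer_rule = peer_rule,
      n_participants = nrow(cohort$participants),
      n_survivors = sum(cohort$participants$group == "survivor")),
    marginal = marginal,
    quality = quality,
    accounting = accounting,
    warnings = warnings), class = "study_report")
}

#' Write a study report to disk
#'
#' Writes `report.json` (the full report; list-column summaries included)
#' and flat TSV tables `marginal.tsv`, `quality.tsv`, and `costs.tsv` (the
#' latter only when accounting is present). No timestamps are embedded, so
#' re-running with identical inputs and seed reproduces the files
#' byte-identically.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(
    report_to_list(report), file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  marg <- report$marginal
  marg$summary_index <- vapply(marg$summary_index, summarise_inline, character(1))
  marg$summary_comparison <- vapply(marg$summary_comparison, summarise_inline,
                                    character(1))
  readr::write_tsv(marg, file.path(dir, "marginal.tsv"), progress = FALSE)
  readr::write_tsv(report$quality, file.path(dir, "quality.tsv"), progress = FALSE)
  if (!is.null(report$accounting)) {
    readr::write_tsv(report$accounting, file.path(dir, "costs.tsv"),
                     progress = FALSE)
  }
  invisible(dir)
}

summarise_inline <- function(s) {
  if (is.null(s)) return(NA_character_)
  paste(sprintf("%s=%.4g", names(s), as.numeric(s)), collapse = "; ")
}

report_to_list <- function(report) {
  out <- unclass(report)
  out$marginal <- lapply(seq_len(nrow(report$marginal)), function(i) {
    row <- as.list(report$marginal[i, ])
    row$summary_index <- as.list(row$summary_index[[1]])
    row$summary_comparison <- as.list(row$summary_comparison[[1]])
    row
  })
  out
}

#' Read a study report back from its JSON serialization
#'
#' @param path Path to a `report.json` written by [write_study_report()].
#' @return A list mirroring the report structure (tables as tibbles).
#' @export
read_study_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  raw
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", x$metadata$n_survivors, "survivors,",
      x$metadata$n_participants, "participants\n")
  cat("  seed:", x$metadata$seed %||% "none",
      " permutations:", x$metadata$n_permutations, "\n")
  cat("-- match quality (one-sided p; small = peer matching better) --\n")
  print(x$quality, n = Inf)
  cat("-- marginal tests (two-sided p) --\n")
  print(dplyr::select(x$marginal, -dplyr::any_of(c("summary_index",
                                                   "summary_comparison"))),
        n = Inf)
  if (!is.null(x$accounting)) {
    cat("-- recruitment accounting --\n")
    print(x$accounting)
  }
  if (nrow(x$warnings)) {
    cat("-- warnings --\n")
    print(x$warnings)
  }
  invisible(x)
}
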