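# Deterministic recruitment-funnel and interviewing-cost arithmetic.

round_to <- function(x, digits, rounding = c("truncate", "half_up")) {
  rounding <- match.arg(rounding)
  f <- 10^digits
  if (rounding == "truncate") {
    floor(x * f + 1e-9) / f
  } else {
    floor(x * f + 0.5 + 1e-9) / f
  }
}

#' Recruitment yield
#'
#' Completed interviews as a percentage of an arm-specific denominator
#' (usable telephone numbers, nominees, or numbers dialed). The published
#' funnel figures mix display conventions, so both the number of digits and
#' the rounding mode are explicit: the default (one decimal, truncation)
#' reproduces a peer-arm yield of 44/91 = 48.3%, while integer half-up
#' rounding reproduces 100/372 = 27% and 101/544 = 19%.
#'
#' @param n_completed Completed interviews.
#' @param n_denominator Arm-specific denominator (> 0, at least
#'   `n_completed`).
#' @param digits Decimal places of the reported percentage.
#' @param rounding `"truncate"` or `"half_up"`.
#' @return Percentage on the 0-100 scale.
#' @examples
#' yield_rate(44, 91)                                        # 48.3
#' yield_rate(100, 372, digits = 0, rounding = "half_up")    # 27
#' @export
yield_rate <- function(n_completed, n_denominator, digits = 1,
                       rounding = c("truncate", "half_up")) {
  rounding <- match.arg(rounding)
  if (any(n_denominator <= 0)) {
    mq_abort("yield denominator must be positive", class = "matchqual_domain_error")
  }
  if (any(n_completed < 0) || any(n_completed > n_denominator)) {
    mq_abort("n_completed must lie in [0, n_denominator]",
             class = "matchqual_domain_error")
  }
  round_to(100 * n_completed / n_denominator, digits, rounding)
}

#' Cost per completed interview
#'
#' The call-center hourly rate divided by the completes-per-hour
#' productivity, reported in currency rounded to cents. The published cost
#' table implies truncation at cents ($25/0.60 is printed as $41.66, not
#' $41.67), so truncation is the default; half-up rounding is available.
#'
#' @param hourly_rate Currency per interviewer hour (e.g. 25).
#' @param completes_per_hour Completed interviews per hour (> 0).
#' @param rounding `"truncate"` (default, reproduces the published table) or
#'   `"half_up"`.
#' @return Cost per completed interview, exact to cents.
#' @examples
#' cost_per_complete(25, 0.65) # 38.46
#' cost_per_complete(25, 0.40) # 62.50
#' cost_per_complete(25, 0.60) # 41.66 under truncation
#' @export
cost_per_complete <- function(hourly_rate, completes_per_hour,
                              rounding = c("truncate", "half_up")) {
  rounding <- match.arg(rounding)
  if (any(completes_per_hour <= 0)) {
    mq_abort("completes_per_hour must be positive", class = "matchqual_domain_error")
  }
  if (any(hourly_rate < 0)) {
    mq_abort("hourly_rate must be non-negative", class = "matchqual_domain_error")
  }
  round_to(hourly_rate / completes_per_hour, 2, rounding)
}

#' Total interviewing cost for an arm
#'
#' Cost per completed interview times the number of completions, rounded
#' half-up to cents.
#'
#' @param cost_per_complete Currency per completed interview.
#' @param n_completed Number of completed interviews.
#' @return Total cost, exact to cents.
#' @examples
#' total_cost(62.50, 44)  # 2750
#' total_cost(41.66, 101) # 4207.66
#' @export
total_cost <- function(cost_per_complete, n_completed) {
  if (any(cost_per_complete < 0) || any(n_completed < 0)) {
    mq_abort("inputs must be non-negative", class = "matchqual_domain_error")
  }
  round_to(cost_per_complete * n_completed, 2, "half_up")
}

ledger_stage_columns <- function() {
  c("n_refused", "n_callback", "n_ineligible", "n_deceased", "n_partial",
    "n_nonworking", "n_other")
}

#' Validate a recruitment ledger
#'
#' A ledger has one row per recruitment arm with funnel counts
#' (`n_candidates` entering, `n_usable` after dropping bad numbers,
#' `n_completed` interviews, stage counts), the productivity rate
#' `completes_per_hour`, `hourly_rate`, and `yield_denom`
#' (`"usable"` or `"candidates"`): which count the arm's published yield is
#' taken over (nominee lists use candidates, telephone lists use usable
#' numbers).
#'
#' @param ledger A ledger data frame.
#' @return The ledger, invisibly, after checking count consistency
#'   (`n_completed <= n_usable <= n_candidates`, non-negative counts, stage
#'   counts summing to at most the candidates).
#' @export
validate_ledger <- function(ledger) {
  required <- c("arm", "n_candidates", "n_usable", "n_completed",
                "completes_per_hour", "hourly_rate", "yield_denom")
  missing_cols <- setdiff(required, names(ledger))
  if (length(missing_cols)) {
    mq_abort(sprintf("ledger missing column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             class = "matchqual_schema_error")
  }
  if (anyDuplicated(ledger$arm)) {
    mq_abort("duplicate recruitment arm in ledger",
             class = "matchqual_schema_error")
  }
  counts <- c("n_candidates", "n_usable", "n_completed",
              intersect(ledger_stage_columns(), names(ledger)))
  for (cc in counts) {
    if (any(ledger[[cc]] < 0, na.rm = TRUE)) {
      mq_abort(sprintf("negative count in '%s'", cc),
               class = "matchqual_validation_error")
    }
  }
  with(ledger, {
    if (any(n_completed > n_usable) || any(n_usable > n_candidates)) {
      mq_abort("require n_completed <= n_usable <= n_candidates",
               class = "matchqual_validation_error")
    }
  })
  stage_cols <- intersect(ledger_stage_columns(), names(ledger))
  if (length(stage_cols)) {
    stage_sum <- rowSums(ledger[, stage_cols, drop = FALSE], na.rm = TRUE) +
      ledger$n_completed
    if (any(stage_sum > ledger$n_candidates)) {
      mq_abort("stage counts plus completions exceed candidates",
               class = "matchqual_validation_error")
    }
  }
  invisible(ledger)
}

#' Read a recruitment ledger from CSV
#'
#' @param path CSV path; one row per arm with the columns described in
#'   [validate_ledger()].
#' @return A validated ledger tibble.
#' @export
read_ledger <- function(path) {
  if (!file.exists(path)) {
    mq_abort(sprintf("ledger file '%s' not found", path),
             class = "matchqual_io_error")
  }
  ledger <- readr::read_csv(path, progress = FALSE, show_col_types = FALSE)
  validate_ledger(ledger)
  ledger
}

#' Recruitment accounting report
#'
#' One row per recruitment arm: productivity, cost per completed interview,
#' total interviewing cost, and yield, with the funnel stage counts echoed
#' for audit. Yield is reported at integer precision (half-up), matching the
#' published funnel summaries; cost rounding follows `rounding`.
#'
#' @param ledgers A recruitment ledger (see [validate_ledger()]), e.g. from
#'   [read_ledger()] or [generate_recruitment_ledger()].
#' @param hourly_rate Optional currency-per-hour override; defaults to the
#'   ledger's own `hourly_rate` column.
#' @param rounding Cent-rounding mode for [cost_per_complete()].
#' @param yield_digits Decimal places for the yield column.
#' @param yield_rounding Rounding mode for the yield column.
#' @return A tibble of class `mq_accounting_report`.
#' @export
accounting_report <- function(ledgers, hourly_rate = NULL,
                              rounding = c("truncate", "half_up"),
                              yield_digits = 0,
                              yield_rounding = c("half_up", "truncate")) {
  rounding <- match.arg(rounding)
  yield_rounding <- match.arg(yield_rounding)
  if (nrow(ledgers) == 0) {
    out <- tibble::tibble(arm = character(), n_candidates = numeric(),
                          n_usable = numeric(), n_completed = numeric(),
                          completes_per_hour = numeric(), yield_pct = numeric(),
                          cost_per_complete = numeric(), total_cost = numeric())
    class(out) <- c("mq_accounting_report", class(out))
    return(out)
  }
  validate_ledger(ledgers)
  rate <- hourly_rate %||% ledgers$hourly_rate
  denom <- ifelse(ledgers$yield_denom == "candidates",
                  ledgers$n_candidates, ledgers$n_usable)
  cpc <- cost_per_complete(rate, ledgers$completes_per_hour, rounding)
  out <- tibble::tibble(
    arm = ledgers$arm,
    n_candidates = ledgers$n_candidates,
    n_usable = ledgers$n_usable,
    n_completed = ledgers$n_completed,
    completes_per_hour = ledgers$completes_per_hour,
    yield_pct = yield_rate(ledgers$n_completed, denom,
                           digits = yield_digits, rounding = yield_rounding),
    cost_per_complete = cpc,
    total_cost = total_cost(cpc, ledgers$n_completed))
  stage_cols <- intersect(ledger_stage_columns(), names(ledgers))
  out <- dplyr::bind_cols(out, ledgers[, stage_cols, drop = FALSE])
  class(out) <- c("mq_accounting_report", class(out))
  out
}
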