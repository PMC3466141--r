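# Synthetic survivor / peer / listed cohorts and recruitment funnels with the
# statistical structure the analysis assumes: survivors drawn from population
# marginals, peers generated conditionally on their survivor (match fidelity),
# listed subjects hard-matched on sex and age window, and a null mode in which
# both comparison groups share one conditional law given the survivor (the
# exchangeability null of the match-quality test).

#' Population marginal parameters for the synthetic generator
#'
#' Means, standard deviations and category proportions of the survivor
#' population the generator draws from: age 64.9 (SD 10.1) years, 72% men,
#' mostly white, three education levels, 60% ever-smokers with 15% current
#' smokers, and zero-inflated monthly alcohol quantities. Smoking and alcohol
#' variables are generated as a point mass at zero plus a truncated normal,
#' so that population means well below their standard deviations (e.g.
#' 30-day smoking mean 4.25, SD 10.3) are attainable.
#'
#' @return A named list of marginal parameters; override entries to change
#'   the population.
#' @export
default_marginals <- function() {
  list(
    age = c(mean = 64.9, sd = 10.09), age_min = 30,
    p_male = 0.72,
    race = c(white = 0.94, black = 0.02, other = 0.04),
    education = c(`less-than-HS` = 0.07, `HS-grad` = 0.213, `post-HS` = 0.717),
    employment = c(employed = 0.32, retired = 0.66, other = 0.02),
    p_ever_smoker = 0.60, p_current_smoker = 0.15,
    age_first_cig = c(mean = 18, sd = 4),
    smoke_duration = c(mean = 36.6, sd = 15),
    days_smoked_current = c(mean = 28, sd = 4),
    alc_freq_month = list(p_zero = 0.35, mean = 2.3, sd = 1.5),
    alc_typical = list(p_zero = 0.35, mean = 1.0, sd = 0.6),
    alc_six_freq = list(p_zero = 0.50, mean = 1.56, sd = 0.9)
  )
}

#' Match-fidelity parameters for peer generation
#'
#' Controls how close each generated peer is to its survivor. Continuous
#' variables get a location shift and a noise SD (peer value = survivor value
#' + shift + noise); categorical variables are copied with probability
#' `agree` and otherwise drawn from an alternative distribution (`alt`, or
#' the population marginal when `NULL`). The defaults emulate the observed
#' peer pattern: peers about 7.5 years younger with extra age dispersion,
#' sex matched only partially (survivor instructions did not require
#' same-sex nominees), education well matched, and slightly heavier smoking
#' and drinking.
#'
#' `perfect_fidelity()` sets every shift and SD to zero and every agreement
#' probability to one, so each peer equals its survivor exactly.
#' `null_fidelity()` is the symmetric variant used for null cohorts: no
#' shifts, moderate noise, identical for both comparison groups.
#'
#' @return A named list of per-variable fidelity parameters.
#' @export
default_fidelity <- function() {
  list(
    age = list(shift = -7.5, sd = 9.5),
    sex = list(agree = 0.5, alt = c(M = 0.14, F = 0.86)),
    race = list(agree = 0.9, alt = NULL),
    education = list(agree = 0.7, alt = NULL),
    employment = list(agree = 0.5, alt = NULL),
    smoking_status = list(agree = 0.8),
    age_first_cig = list(sd = 3),
    age_last_cig = list(sd = 4),
    days_smoked_30 = list(shift = 2, sd = 6),
    alc_freq_month = list(shift = 0, sd = 0.8),
    alc_typical = list(shift = 0.3, sd = 0.5),
    alc_six_freq = list(shift = 0.2, sd = 0.7)
  )
}

#' @rdname default_fidelity
#' @export
perfect_fidelity <- function() {
  f <- default_fidelity()
  lapply(f, function(v) {
    if (!is.null(v$shift)) v$shift <- 0
    if (!is.null(v$sd)) v$sd <- 0
    if (!is.null(v$agree)) v$agree <- 1
    v
  })
}

#' @rdname default_fidelity
#' @export
null_fidelity <- function() {
  list(
    age = list(shift = 0, sd = 5),
    sex = list(agree = 0.8, alt = NULL),
    race = list(agree = 0.9, alt = NULL),
    education = list(agree = 0.7, alt = NULL),
    employment = list(agree = 0.6, alt = NULL),
    smoking_status = list(agree = 0.8),
    age_first_cig = list(sd = 3),
    age_last_cig = list(sd = 4),
    days_smoked_30 = list(shift = 0, sd = 6),
    alc_freq_month = list(shift = 0, sd = 0.8),
    alc_typical = list(shift = 0, sd = 0.5),
    alc_six_freq = list(shift = 0, sd = 0.7)
  )
}

#' Recruitment-funnel parameters
#'
#' Per-arm candidate counts, deterministic not-used counts, stage
#' probabilities (remainder goes to an `other` bucket), productivity rates
#' and the call-center hourly rate, calibrated to the study funnels:
#' survivors 100 completions of 372 usable numbers at 0.65/hour, peers 44 of
#' 91 nominees at 0.40/hour, listed sample 101 of 544 dialed numbers at
#' 0.60/hour.
#'
#' @return Named list with entries `survivor`, `peer`, `listed`,
#'   `hourly_rate`.
#' @export
default_funnel <- function() {
  list(
    hourly_rate = 25,
    survivor = list(
      n_candidates = 378, n_not_used = 6, completes_per_hour = 0.65,
      yield_denom = "usable",
      stages = c(completed = 100, refused = 20, callback = 83,
                 ineligible = 14, deceased = 6, partial = 4) / 372),
    peer = list(
      n_candidates = 91, n_not_used = 0, completes_per_hour = 0.40,
      yield_denom = "candidates",
      stages = c(completed = 44, refused = 12, nonworking = 6,
                 ineligible = 14, callback = 15) / 91),
    listed = list(
      n_candidates = 980, n_not_used = 436, completes_per_hour = 0.60,
      yield_denom = "usable",
      stages = c(completed = 101, refused = 117, callback = 188) / 544)
  )
}

#' Generator configuration for synthetic cohorts
#'
#' Bundles every tunable of the synthetic-cohort generator. Defaults encode
#' the study design: 100 survivors; 61% nominate at least one peer, 30 of 61
#' nominators name two, and each nominee completes with probability 0.483;
#' 96% of survivors obtain a listed match constrained to the same sex and an
#' age within +/- 5 years.
#'
#' @param n_survivors Number of survivors (index subjects).
#' @param peer_nomination_prob Probability a survivor nominates at least one
#'   peer.
#' @param two_peer_prob Probability a nominating survivor names two peers.
#' @param peer_contact_success Probability a nominee completes the
#'   interview.
#' @param listed_completion_prob Probability a survivor obtains a completed
#'   listed match.
#' @param listed_age_window Half-width (years) of the listed-sample age
#'   matching window.
#' @param shift_variable Variable whose listed-group match distances are
#'   inflated by [generate_shifted_cohort()].
#' @param marginals Population marginals, see [default_marginals()].
#' @param fidelity Peer match-fidelity parameters, see
#'   [default_fidelity()].
#' @param missing_rate Per-cell missingness rate applied to the education,
#'   employment and alcohol items (sex, age and the structural fields stay
#'   complete so that hard matching constraints remain checkable).
#' @param funnel Recruitment-funnel parameters, see [default_funnel()].
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_survivors = 100,
                          peer_nomination_prob = 0.61,
                          two_peer_prob = 30 / 61,
                          peer_contact_success = 0.483,
                          listed_completion_prob = 0.96,
                          listed_age_window = 5,
                          shift_variable = "age",
                          marginals = default_marginals(),
                          fidelity = default_fidelity(),
                          missing_rate = 0.02,
                          funnel = default_funnel()) {
  probs <- c(peer_nomination_prob, two_peer_prob, peer_contact_success,
             listed_completion_prob, missing_rate)
  if (any(probs < 0 | probs > 1)) {
    mq_abort("probabilities must lie in [0, 1]", class = "matchqual_config_error")
  }
  if (n_survivors < 1) {
    mq_abort("n_survivors must be at least 1", class = "matchqual_config_error")
  }
  if (listed_age_window <= 0) {
    mq_abort("listed_age_window must be positive for a continuous age match",
             class = "matchqual_config_error")
  }
  structure(list(
    n_survivors = as.integer(n_survivors),
    peer_nomination_prob = peer_nomination_prob,
    two_peer_prob = two_peer_prob,
    peer_contact_success = peer_contact_success,
    listed_completion_prob = listed_completion_prob,
    listed_age_window = listed_age_window,
    shift_variable = shift_variable,
    marginals = marginals,
    fidelity = fidelity,
    missing_rate = missing_rate,
    funnel = funnel), class = "cohort_config")
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

zif_draw <- function(n, par) {
  zero <- stats::runif(n) < par$p_zero
  pos <- rtrunc_norm(n, par$mean, par$sd, lower = 0.05)
  ifelse(zero, 0, pos)
}

draw_smoking <- function(n, age, m) {
  ever <- stats::runif(n) < m$p_ever_smoker
  current <- ever & (stats::runif(n) < m$p_current_smoker / m$p_ever_smoker)
  first <- rtrunc_norm(n, m$age_first_cig[["mean"]], m$age_first_cig[["sd"]],
                       lower = 8)
  first <- pmin(first, age - 1)
  dur <- rtrunc_norm(n, m$smoke_duration[["mean"]], m$smoke_duration[["sd"]],
                     lower = 1)
  last <- pmin(first + dur, age)
  days <- round(rtrunc_norm(n, m$days_smoked_current[["mean"]],
                            m$days_smoked_current[["sd"]], lower = 1, upper = 30))
  tibble::tibble(
    age_first_cig = ifelse(ever, first, NA_real_),
    age_last_cig = ifelse(ever & !current, last, NA_real_),
    is_current_smoker = current,
    days_smoked_30 = ifelse(current, days, 0))
}

draw_population <- function(n, m) {
  sex <- sample(c("M", "F"), n, replace = TRUE,
                prob = c(m$p_male, 1 - m$p_male))
  age <- rtrunc_norm(n, m$age[["mean"]], m$age[["sd"]], lower = m$age_min)
  tibble::tibble(
    sex = sex,
    race = sample(names(m$race), n, replace = TRUE, prob = m$race),
    age = age,
    education = sample(names(m$education), n, replace = TRUE,
                       prob = m$education),
    employment = sample(names(m$employment), n, replace = TRUE,
                        prob = m$employment),
    draw_smoking(n, age, m),
    alc_freq_month = zif_draw(n, m$alc_freq_month),
    alc_typical = zif_draw(n, m$alc_typical),
    alc_six_freq = zif_draw(n, m$alc_six_freq))
}

copy_categorical <- function(x, fid, marg_probs) {
  n <- length(x)
  keep <- stats::runif(n) < fid$agree
  probs <- fid$alt %||% marg_probs
  alt <- sample(names(probs), n, replace = TRUE, prob = probs)
  ifelse(keep, x, alt)
}

# survivor value + shift + noise; an extra `shift_abs` inflates the absolute
# deviation from the survivor (used by the shifted generator)
perturb_continuous <- function(x, shift, sd, shift_abs = 0,
                               lower = -Inf, upper = Inf) {
  e <- stats::rnorm(length(x), 0, max(sd, 0))
  if (shift_abs > 0) e <- sign(e) * (abs(e) + shift_abs)
  pmin(pmax(x + shift + e, lower), upper)
}

# generate comparison subjects conditionally on their survivors
perturb_from <- function(surv, fid, m, shift_abs = 0, shift_variable = "age") {
  n <- nrow(surv)
  sa <- function(var) if (shift_variable == var) shift_abs else 0
  age <- perturb_continuous(surv$age, fid$age$shift, fid$age$sd,
                            shift_abs = sa("age"), lower = 18)
  keep_status <- stats::runif(n) < fid$smoking_status$agree
  fresh <- draw_smoking(n, age, m)
  first <- ifelse(is.na(surv$age_first_cig), NA_real_,
                  perturb_continuous(surv$age_first_cig, 0,
                                     fid$age_first_cig$sd, lower = 8))
  first <- pmin(first, age - 1)
  last <- ifelse(is.na(surv$age_last_cig), NA_real_,
                 perturb_continuous(surv$age_last_cig, 0,
                                    fid$age_last_cig$sd))
  last <- pmin(pmax(last, first), age)
  days <- ifelse(surv$days_smoked_30 > 0,
                 round(perturb_continuous(surv$days_smoked_30,
                                          fid$days_smoked_30$shift,
                                          fid$days_smoked_30$sd,
                                          shift_abs = sa("days_smoked_30"),
                                          lower = 1, upper = 30)),
                 0)
  zif_copy <- function(var) {
    f <- fid[[var]]
    ifelse(surv[[var]] > 0,
           perturb_continuous(surv[[var]], f$shift, f$sd,
                              shift_abs = sa(var), lower = 0),
           0)
  }
  tibble::tibble(
    sex = copy_categorical(surv$sex, fid$sex,
                           c(M = m$p_male, F = 1 - m$p_male)),
    race = copy_categorical(surv$race, fid$race, m$race),
    age = age,
    education = copy_categorical(surv$education, fid$education, m$education),
    employment = copy_categorical(surv$employment, fid$employment,
                                  m$employment),
    age_first_cig = ifelse(keep_status, first, fresh$age_first_cig),
    age_last_cig = ifelse(keep_status, last, fresh$age_last_cig),
    is_current_smoker = ifelse(keep_status, surv$is_current_smoker,
                               fresh$is_current_smoker),
    days_smoked_30 = ifelse(keep_status, days, fresh$days_smoked_30),
    alc_freq_month = zif_copy("alc_freq_month"),
    alc_typical = zif_copy("alc_typical"),
    alc_six_freq = zif_copy("alc_six_freq"))
}

apply_missingness <- function(tbl, rate) {
  if (rate <= 0) return(tbl)
  for (var in c("education", "employment", "alc_freq_month", "alc_typical",
                "alc_six_freq")) {
    mask <- stats::runif(nrow(tbl)) < rate
    tbl[[var]][mask] <- NA
  }
  tbl
}

generate_cohort_impl <- function(config, seed, mode, shift) {
  stopifnot(inherits(config, "cohort_config"))
  m <- config$marginals
  with_local_seed(seed, {
    n <- config$n_survivors
    surv <- draw_population(n, m)
    surv <- dplyr::bind_cols(
      tibble::tibble(subject_id = sprintf("S%04d", seq_len(n)),
                     group = "survivor",
                     survivor_link = sprintf("S%04d", seq_len(n))),
      surv)
    surv$cancer_history <- TRUE

    # peer nomination funnel: 0-2 nominees, each completing independently
    nominates <- stats::runif(n) < config$peer_nomination_prob
    n_nom <- ifelse(nominates,
                    1L + (stats::runif(n) < config$two_peer_prob), 0L)
    n_peer <- stats::rbinom(n, n_nom, config$peer_contact_success)
    peer_parent <- rep(seq_len(n), n_peer)
    fid_peer <- if (mode == "study") config$fidelity else null_fidelity()
    peers <- perturb_from(surv[peer_parent, , drop = FALSE], fid_peer, m)
    peers <- dplyr::bind_cols(
      tibble::tibble(subject_id = sprintf("P%04d", seq_along(peer_parent)),
                     group = "peer",
                     survivor_link = surv$subject_id[peer_parent]),
      peers)
    peers$cancer_history <- FALSE

    # listed sample: hard sex/age match in study mode, peer-identical
    # conditional law in null mode
    has_listed <- stats::runif(n) < config$listed_completion_prob
    listed_parent <- which(has_listed)
    sl <- surv[listed_parent, , drop = FALSE]
    if (mode == "study") {
      w <- config$listed_age_window
      listed <- draw_population(length(listed_parent), m)
      listed$sex <- sl$sex
      listed$age <- sl$age + stats::runif(length(listed_parent), -w, w)
    } else {
      listed <- perturb_from(sl, fid_peer, m, shift_abs = shift,
                             shift_variable = config$shift_variable)
    }
    listed <- dplyr::bind_cols(
      tibble::tibble(subject_id = sprintf("L%04d", seq_along(listed_parent)),
                     group = "listed",
                     survivor_link = sl$subject_id),
      listed)
    listed$cancer_history <- FALSE

    participants <- dplyr::bind_rows(surv, peers, listed)
    participants <- apply_missingness(participants, config$missing_rate)
    cohort <- as_cohort(participants[, cohort_columns()])
    # nomination funnel audit trail (nominees who never completed are not
    # participants, so the funnel is recorded alongside the cohort)
    attr(cohort, "nominations") <- tibble::tibble(
      survivor_id = surv$subject_id, n_nominees = as.integer(n_nom),
      n_completed_peers = n_peer)
    cohort
  })
}

#' Generate a synthetic survivor/peer/listed cohort
#'
#' Draws survivors from the configured population marginals, attaches 0-2
#' completed peers per survivor via the nomination/contact funnel, generates
#' peer variables conditionally on the survivor per the match-fidelity
#' parameters, and attaches a listed-sample match hard-constrained to the
#' survivor's sex and an age within the matching window, with its remaining
#' variables drawn independently from the population.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the same config and seed reproduce the cohort
#'   exactly.
#' @return A validated `cohort` object. The per-survivor nomination funnel
#'   (nominees and completed peers, including nominees who never completed
#'   and so are absent from the participant table) is attached as the
#'   `"nominations"` attribute.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_survivors = 20), seed = 1)
#' cohort
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  generate_cohort_impl(config, seed, mode = "study", shift = 0)
}

#' Generate a cohort under the match-quality null
#'
#' Both comparison groups are generated from one shared conditional law
#' given the survivor (identical fidelity parameters, no hard constraints),
#' while the realistic partially paired missingness pattern — 0-2 peers per
#' survivor via the nomination funnel, one listed match for most survivors —
#' is preserved. Match distances are then exchangeable between the groups,
#' which is the null hypothesis of [permutation_test_partially_paired()].
#'
#' @inheritParams generate_cohort
#' @return A validated `cohort` object.
#' @export
generate_null_cohort <- function(config = cohort_config(), seed = NULL) {
  generate_shifted_cohort(config, shift = 0, seed = seed)
}

#' Generate a cohort with inflated listed-group match distances
#'
#' Identical to [generate_null_cohort()] except that on the configured
#' `shift_variable` the listed subject's absolute deviation from its
#' survivor is inflated by `shift` (the deviation magnitude gains a constant,
#' so listed distances are stochastically larger by exactly that amount).
#' `shift = 0` reduces to the null generator, draw for draw.
#'
#' @inheritParams generate_cohort
#' @param shift Non-negative amount (units of the shifted variable) added to
#'   every listed-group deviation.
#' @return A validated `cohort` object.
#' @export
generate_shifted_cohort <- function(config = cohort_config(), shift = 0,
                                    seed = NULL) {
  if (shift < 0) {
    mq_abort("shift must be non-negative", class = "matchqual_config_error")
  }
  generate_cohort_impl(config, seed, mode = "null", shift = shift)
}

#' Generate synthetic recruitment ledgers
#'
#' Allocates each arm's usable candidates across funnel stages by a
#' multinomial draw with the configured stage probabilities (remainder mass
#' goes to an `other` stage), so stage counts always sum exactly to the
#' usable candidates. Candidate and not-used counts, productivity and the
#' hourly rate are taken from the funnel configuration.
#'
#' @inheritParams generate_cohort
#' @return A validated ledger tibble, one row per arm (see
#'   [validate_ledger()]).
#' @examples
#' generate_recruitment_ledger(cohort_config(), seed = 1)
#' @export
generate_recruitment_ledger <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  fun <- config$funnel
  with_local_seed(seed, {
    rows <- purrr::map_dfr(c("survivor", "peer", "listed"), function(arm) {
      f <- fun[[arm]]
      usable <- f$n_candidates - f$n_not_used
      p_other <- 1 - sum(f$stages)
      if (p_other < -1e-9) {
        mq_abort(sprintf("stage probabilities for arm '%s' sum to more than 1", arm),
                 class = "matchqual_config_error")
      }
      probs <- c(f$stages, other = max(p_other, 0))
      counts <- stats::rmultinom(1, usable, probs)[, 1]
      all_stages <- c("completed", "refused", "callback", "ineligible",
                      "deceased", "partial", "nonworking", "other")
      full <- stats::setNames(rep(0, length(all_stages)), all_stages)
      full[names(counts)] <- counts
      tibble::tibble(
        arm = arm,
        n_candidates = f$n_candidates,
        n_usable = usable,
        n_completed = unname(full[["completed"]]),
        n_refused = unname(full[["refused"]]),
        n_callback = unname(full[["callback"]]),
        n_ineligible = unname(full[["ineligible"]]),
        n_deceased = unname(full[["deceased"]]),
        n_partial = unname(full[["partial"]]),
        n_nonworking = unname(full[["nonworking"]]),
        n_other = unname(full[["other"]]),
        completes_per_hour = f$completes_per_hour,
        hourly_rate = fun$hourly_rate,
        yield_denom = f$yield_denom)
    })
    validate_ledger(rows)
    rows
  })
}
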