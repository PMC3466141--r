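#' Matching-variable specifications
#'
#' A variable specification declares how one matching variable enters the
#' pair-distance computation: its name, measurement scale, and (for ordinal
#' variables) the ordered category levels. Specifications are stored as a
#' tibble with one row per variable and a list-column of ordinal levels.
#'
#' @param name Variable name (a participant-table column).
#' @param scale One of `"continuous"`, `"binary"`, `"ordinal"`, `"nominal"`.
#' @param levels Ordered character vector of category labels; required for
#'   ordinal variables, ignored otherwise.
#' @return A one-row varspec tibble; combine with [dplyr::bind_rows()].
#' @export
varspec <- function(name, scale = c("continuous", "binary", "ordinal", "nominal"),
                    levels = NULL) {
  scale <- match.arg(scale)
  if (scale == "ordinal") {
    if (is.null(levels) || length(levels) == 0 || anyDuplicated(levels)) {
      mq_abort(sprintf(
        "ordinal variable '%s' needs a non-empty, duplicate-free level order", name),
        class = "matchqual_spec_error")
    }
  }
  tibble::tibble(name = name, scale = scale,
                 levels = list(if (scale == "ordinal") as.character(levels) else NULL))
}

#' Default variable specifications for the survivor matching variables
#'
#' Covers the study's matching variables: sex, race, age, education (ordinal
#' with three levels: less than high school < high-school graduate < post
#' high school), employment, 30-day smoking, derived lifetime smoking
#' duration, and the three alcohol-use quantities (occasions per month,
#' drinks per typical drinking day, days per month with at least six drinks).
#'
#' @return A varspec tibble, one row per variable.
#' @export
default_varspecs <- function() {
  dplyr::bind_rows(
    varspec("sex", "binary"),
    varspec("race", "nominal"),
    varspec("age", "continuous"),
    varspec("education", "ordinal",
            levels = c("less-than-HS", "HS-grad", "post-HS")),
    varspec("employment", "nominal"),
    varspec("days_smoked_30", "continuous"),
    varspec("smoking_duration", "continuous"),
    varspec("alc_freq_month", "continuous"),
    varspec("alc_typical", "continuous"),
    varspec("alc_six_freq", "continuous")
  )
}

#' Read / write variable specifications as YAML
#'
#' The config file has a top-level `variables:` list; each entry has `name`,
#' `scale`, and for ordinal variables an ordered `levels` list.
#'
#' @param path File path.
#' @return `read_varspecs()` returns a varspec tibble.
#' @export
read_varspecs <- function(path) {
  if (!file.exists(path)) {
    mq_abort(sprintf("varspec config '%s' not found", path),
             class = "matchqual_io_error")
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$variables)) {
    mq_abort("varspec config must have a top-level 'variables' list",
             class = "matchqual_spec_error")
  }
  dplyr::bind_rows(lapply(cfg$variables, function(v) {
    varspec(v$name, v$scale, levels = v$levels)
  }))
}

#' @rdname read_varspecs
#' @param varspecs A varspec tibble.
#' @export
write_varspecs <- function(varspecs, path) {
  vars <- lapply(seq_len(nrow(varspecs)), function(i) {
    v <- list(name = varspecs$name[i], scale = varspecs$scale[i])
    if (varspecs$scale[i] == "ordinal") v$levels <- varspecs$levels[[i]]
    v
  })
  yaml::write_yaml(list(variables = vars), path)
  invisible(path)
}

validate_varspecs <- function(varspecs) {
  stopifnot(is.data.frame(varspecs),
            all(c("name", "scale", "levels") %in% names(varspecs)))
  bad <- !varspecs$scale %in% c("continuous", "binary", "ordinal", "nominal")
  if (any(bad)) {
    mq_abort(sprintf("unknown scale(s): %s",
                     paste(unique(varspecs$scale[bad]), collapse = ", ")),
             class = "matchqual_spec_error")
  }
  invisible(varspecs)
}
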