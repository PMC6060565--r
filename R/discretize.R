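#' Round a sleep report to whole hours
#'
#' Survey sleep reports are collected in whole hours; reports carrying 30
#' minutes or more round up to the next hour, reports with 29 minutes or
#' fewer round down (so 6h45 becomes 7 and 6h05 becomes 6). `strict_drop`
#' instead drops (returns `NA` for) reports with a 1-29 minute remainder,
#' for analyses that exclude rather than round them.
#'
#' @param hours Nonnegative integer vector of whole hours.
#' @param minutes Integer vector in 0-59 (default 0).
#' @param strict_drop If `TRUE`, a nonzero remainder below 30 minutes
#'   yields `NA` instead of rounding down.
#' @return Integer vector of whole hours. Monotone nondecreasing in
#'   (hours, minutes) when `strict_drop = FALSE`.
#' @export
round_sleep_report <- function(hours, minutes = 0, strict_drop = FALSE) {
  if (any(hours < 0, na.rm = TRUE)) stop("hours must be nonnegative")
  if (any(minutes < 0 | minutes > 59, na.rm = TRUE))
    stop("minutes must lie in 0-59")
  out <- ifelse(minutes >= 30, hours + 1L, hours)
  if (strict_drop) out[minutes >= 1 & minutes <= 29] <- NA_integer_
  as.integer(out)
}

#' Bin whole sleep hours into short / average / long
#'
#' Short is under 7 hours, average 7-8 hours, long 9 hours or more
#' (equivalently over 8, since hours are whole after rounding).
#'
#' @param whole_hours Nonnegative integer vector.
#' @return Character vector over `{"short","average","long"}`; `NA` in,
#'   `NA` out.
#' @export
bin_sleep <- function(whole_hours) {
  if (any(whole_hours < 0, na.rm = TRUE)) stop("hours must be nonnegative")
  out <- ifelse(whole_hours < 7, "short",
                ifelse(whole_hours <= 8, "average", "long"))
  as.character(out)
}

#' Bin per-session physical-activity duration (minutes)
#'
#' Boundaries at 10, 30 and 60 minutes; boundary values belong to the bin
#' whose printed label contains them ("10-30" includes both 10 and 30,
#' "31-60" includes 60).
#'
#' @param minutes Nonnegative numeric vector.
#' @return Character vector over `{"<10","10-30","31-60",">60"}`.
#' @export
bin_pa_duration <- function(minutes) {
  if (any(minutes < 0, na.rm = TRUE)) stop("minutes must be nonnegative")
  out <- ifelse(minutes < 10, "<10",
                ifelse(minutes <= 30, "10-30",
                       ifelse(minutes <= 60, "31-60", ">60")))
  as.character(out)
}

#' Bin adult age in years into the three study age groups
#'
#' @param years Integer vector, at least 18 (the survey covers adults
#'   only; younger ages are an error).
#' @return Character vector over `{"18-45","46-65","66+"}`.
#' @export
bin_age <- function(years) {
  if (any(years < 18, na.rm = TRUE))
    stop("age below 18: the survey covers adults only")
  out <- ifelse(years <= 45, "18-45", ifelse(years <= 65, "46-65", "66+"))
  as.character(out)
}

#' Declare a binning rule for one raw numeric column
#'
#' Bins are right-closed intervals `(lower, upper]` by default except that
#' each bin's bounds are taken verbatim: a value falls in the first bin
#' whose `lower <= value <= upper`. Bins must not overlap and must cover
#' the declared domain.
#'
#' @param variable Column name the rule applies to.
#' @param labels Unique bin labels, in canonical state order.
#' @param lower,upper Numeric vectors of inclusive bounds, same length as
#'   `labels`; use `-Inf`/`Inf` for open ends.
#' @return Object of class `bbn_bin_rule`.
#' @export
bin_rule <- function(variable, labels, lower, upper) {
  stopifnot(length(labels) == length(lower), length(labels) == length(upper))
  if (anyDuplicated(labels)) stop("bin labels must be unique")
  if (any(lower > upper)) stop("bin lower bound exceeds upper bound")
  o <- order(lower)
  if (any(utils::head(upper[o], -1) >= utils::tail(lower[o], -1)))
    stop("bins overlap")
  structure(list(variable = variable, labels = as.character(labels),
                 lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "bbn_bin_rule")
}

apply_bin_rule <- function(rule, values) {
  out <- rep(NA_character_, length(values))
  for (i in seq_along(rule$labels)) {
    hit <- !is.na(values) & values >= rule$lower[i] & values <= rule$upper[i]
    out[hit] <- rule$labels[i]
  }
  unbinned <- which(!is.na(values) & is.na(out))
  if (length(unbinned))
    stop("value ", values[unbinned[1]], " in row ", unbinned[1],
         " of variable '", rule$variable, "' falls outside every bin")
  out
}

#' Discretize a raw survey table into a categorical dataset
#'
#' Numeric columns with a [bin_rule()] are binned; all other columns must
#' already hold state labels of the supplied (or derived) schema. Missing
#' raw cells propagate to missing dataset cells; already-binned columns
#' pass through unchanged, so discretization is idempotent.
#'
#' @param raw data.frame of raw responses (numeric and/or categorical
#'   columns).
#' @param rules List of [bin_rule()]s (possibly empty).
#' @param schema Optional [bn_schema()]; if omitted, one is derived (rule
#'   labels in rule order; factor levels; otherwise sorted unique labels).
#' @return A [bn_dataset()].
#' @export
discretize_table <- function(raw, rules = list(), schema = NULL) {
  stopifnot(is.data.frame(raw))
  if (inherits(rules, "bbn_bin_rule")) rules <- list(rules)
  names(rules) <- vapply(rules, `[[`, character(1), "variable")
  unknown <- setdiff(names(rules), names(raw))
  if (length(unknown))
    stop("bin rules name columns absent from the data: ",
         paste(unknown, collapse = ", "))
  out <- raw
  for (v in names(raw)) {
    if (!is.null(rules[[v]]) && is.numeric(raw[[v]]))
      out[[v]] <- apply_bin_rule(rules[[v]], raw[[v]])
    else if (is.factor(raw[[v]])) out[[v]] <- as.character(raw[[v]])
    else out[[v]] <- as.character(raw[[v]])
  }
  if (is.null(schema)) {
    specs <- lapply(names(out), function(v) {
      states <- if (!is.null(rules[[v]])) rules[[v]]$labels
      else if (is.factor(raw[[v]])) levels(raw[[v]])
      else sort(unique(out[[v]][!is.na(out[[v]])]))
      variable_spec(v, states)
    })
    schema <- bn_schema(specs)
  }
  bn_dataset(schema, out)
}

#' Read bin rules from a YAML schema file
#'
#' Expected layout: a top-level `bins` list of entries with `variable`,
#' and `bins` as a list of `{label, lower, upper}` mappings.
#'
#' @param path YAML file path.
#' @return Named list of [bin_rule()]s.
#' @export
read_bin_rules <- function(path) {
  doc <- yaml::read_yaml(path)
  rules <- lapply(doc$bins, function(b) {
    bin_rule(b$variable,
             vapply(b$bins, `[[`, character(1), "label"),
             vapply(b$bins, function(x) as.numeric(x$lower %||% -Inf), numeric(1)),
             vapply(b$bins, function(x) as.numeric(x$upper %||% Inf), numeric(1)))
  })
  names(rules) <- vapply(rules, `[[`, character(1), "variable")
  rules
}
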