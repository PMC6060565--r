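#' One dimension of a profile grid from a variable's states
#'
#' @param var Schema variable name.
#' @param states State labels to enumerate (default: all of them when the
#'   grid is built against a network).
#' @return Named list of single-variable evidence choices, usable as a
#'   grid dimension in [enumerate_profiles()].
#' @export
state_dimension <- function(var, states) {
  choices <- lapply(states, function(s) stats::setNames(list(s), var))
  names(choices) <- states
  choices
}

#' A compound physical-activity choice (intensity + duration + frequency)
#'
#' Bundles the evidence of one activity regimen with the display labels
#' used in the profile report.
#'
#' @param label Choice label (unique within its dimension).
#' @param evidence Named list mapping variables to states, e.g.
#'   `list(VIG10DMIN = "31-60", VIG10FWK = "6")`.
#' @param activity,frequency Display strings for the report's "Physical
#'   activity" and "Frequency of PA" columns.
#' @return A grid choice.
#' @export
pa_choice <- function(label, evidence, activity = label, frequency = "") {
  structure(evidence, label = label, activity = activity,
            frequency = frequency)
}

#' The default 36-cell profile grid
#'
#' Age (3) x sex (2) x activity regimen (2: moderate 31-60 min five
#' times/week, vigorous 31-60 min six times/week) x sleep duration (3) —
#' the 36 sleep-by-activity profiles of the study design.
#'
#' @return Named list of grid dimensions for [enumerate_profiles()].
#' @export
default_profile_grid <- function() {
  list(
    Age = state_dimension("AGE", c("18-45", "46-65", "66+")),
    Sex = state_dimension("SEX", c("male", "female")),
    PA = list(
      moderate = pa_choice("moderate",
                           list(MOD10DMIN = "31-60", MOD10FWK = "5"),
                           activity = "Moderate activity (31-60 min)",
                           frequency = "5 times/week"),
      vigorous = pa_choice("vigorous",
                           list(VIG10DMIN = "31-60", VIG10FWK = "6"),
                           activity = "Vigorous activity (31-60 min)",
                           frequency = "6 times/week")),
    Sleep = state_dimension("HRSLEEP", c("short", "average", "long"))
  )
}

#' Enumerate evidence profiles and their target prevalence
#'
#' Runs one [observational_query()] per cell of the Cartesian product of
#' the grid dimensions and reports the positive-target prevalence as a
#' percentage, flagging cells strictly below `threshold_pct`. In fixed
#' mode the baseline Monte-Carlo sample (when sampling is needed) is drawn
#' once from the seed and shared across cells, which is identical to
#' calling [observational_query()] per cell with the same seed.
#'
#' @param net A valid `bbn_net`.
#' @param grid Named list of dimensions; each dimension is a named list of
#'   evidence choices (see [state_dimension()], [pa_choice()],
#'   [default_profile_grid()]).
#' @param target Target variable (default the schema's target role).
#' @param mode `"fixed"` (default, the conservative standardized estimate)
#'   or `"dynamic"`.
#' @param threshold_pct Prevalence threshold in percent (default 3.07, the
#'   national-average self-reported stroke rate).
#' @param positive Positive target state (default: last state).
#' @param mc_samples,seed,enum_limit Passed to [observational_query()].
#' @return data.frame of class `bbn_profiles`: one row per cell with the
#'   dimension labels, `prevalence_pct`, `mode`, `below_threshold`;
#'   attributes keep the net, grid, and query settings for
#'   [render_profile_report()].
#' @export
enumerate_profiles <- function(net, grid = default_profile_grid(),
                               target = NULL, mode = c("fixed", "dynamic"),
                               threshold_pct = 3.07, positive = NULL,
                               mc_samples = 1e5, seed = NULL,
                               enum_limit = 1e6) {
  mode <- match.arg(mode)
  assert_valid_net(net)
  target <- target %||% schema_target(net$schema)
  stopifnot(length(target) == 1L)
  states <- schema_states(net$schema, target)
  positive <- positive %||% states[length(states)]
  stopifnot(!is.null(names(grid)), all(nzchar(names(grid))))

  cards <- schema_cards(net$schema)
  needs_mc <- mode == "fixed" &&
    prod(cards) / cards[[target]] > enum_limit   # conservative: reuse draw
  baseline_x <- if (needs_mc)
    forward_sample(net, mc_samples, seed = seed)$x else NULL

  labels <- lapply(grid, names)
  cells <- expand.grid(labels, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  prev <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    evidence <- list()
    for (d in names(grid)) {
      choice <- grid[[d]][[cells[i, d]]]
      evidence <- c(evidence, as.list(unclass(choice)))
    }
    q <- observational_query(net, target, evidence, mode = mode,
                             mc_samples = mc_samples, seed = seed,
                             enum_limit = enum_limit,
                             baseline_x = baseline_x)
    prev[i] <- 100 * q$dist$p[[positive]]
  }
  out <- cbind(cells,
               data.frame(prevalence_pct = prev, mode = mode,
                          below_threshold = prev < threshold_pct,
                          stringsAsFactors = FALSE))
  attr(out, "net") <- net
  attr(out, "grid") <- grid
  attr(out, "target") <- target
  attr(out, "positive") <- positive
  attr(out, "threshold_pct") <- threshold_pct
  attr(out, "query") <- list(mode = mode, mc_samples = mc_samples,
                             seed = seed, enum_limit = enum_limit)
  attr(out, "baseline_x") <- baseline_x
  class(out) <- c("bbn_profiles", class(out))
  out
}

#' Flag profiles strictly below a prevalence threshold
#'
#' @param results A `bbn_profiles` data.frame.
#' @param threshold_pct Threshold in percent; the comparison is strict
#'   (`prevalence < threshold`), so cells exactly at the threshold are not
#'   flagged.
#' @return The rows of `results` whose prevalence is strictly below the
#'   threshold, with `below_threshold` refreshed on the full input as an
#'   attribute-preserving side effect of the returned subset.
#' @export
flag_below_threshold <- function(results, threshold_pct) {
  stopifnot(threshold_pct >= 0)
  results$below_threshold <- results$prevalence_pct < threshold_pct
  results[results$below_threshold, , drop = FALSE]
}

#' Render the sleep-by-activity profile report
#'
#' Produces the seven-column report: Age, Sex, Physical activity,
#' Frequency of PA, Stroke % (PA only), Sleep duration, Stroke % (PA and
#' sleep). The "PA only" column is recomputed with the sleep evidence
#' omitted (same mode, samples and seed). Rows are ordered age, then sex,
#' then activity regimen, then sleep duration, following the grid's label
#' order.
#'
#' @param results A nonempty `bbn_profiles` built over a grid with `Age`,
#'   `Sex`, `PA` and `Sleep` dimensions.
#' @return data.frame with the seven report columns.
#' @export
render_profile_report <- function(results) {
  if (!inherits(results, "bbn_profiles") || nrow(results) == 0L)
    stop("results must be a nonempty profile enumeration")
  need <- c("Age", "Sex", "PA", "Sleep")
  if (!all(need %in% names(results)))
    stop("profile grid must have Age, Sex, PA and Sleep dimensions")
  net <- attr(results, "net")
  grid <- attr(results, "grid")
  target <- attr(results, "target")
  positive <- attr(results, "positive")
  qs <- attr(results, "query")
  baseline_x <- attr(results, "baseline_x")

  # PA-only prevalence per (Age, Sex, PA) stratum: drop the sleep evidence.
  strata <- unique(results[, c("Age", "Sex", "PA")])
  pa_only <- numeric(nrow(strata))
  for (i in seq_len(nrow(strata))) {
    evidence <- c(as.list(unclass(grid$Age[[strata$Age[i]]])),
                  as.list(unclass(grid$Sex[[strata$Sex[i]]])),
                  as.list(unclass(grid$PA[[strata$PA[i]]])))
    q <- observational_query(net, target, evidence, mode = qs$mode,
                             mc_samples = qs$mc_samples, seed = qs$seed,
                             enum_limit = qs$enum_limit,
                             baseline_x = baseline_x)
    pa_only[i] <- 100 * q$dist$p[[positive]]
  }
  key <- function(df) paste(df$Age, df$Sex, df$PA, sep = "\r")
  pa_map <- stats::setNames(pa_only, key(strata))

  ord <- order(match(results$Age, names(grid$Age)),
               match(results$Sex, names(grid$Sex)),
               match(results$PA, names(grid$PA)),
               match(results$Sleep, names(grid$Sleep)))
  res <- results[ord, , drop = FALSE]
  pa_choices <- grid$PA[res$PA]
  data.frame(
    Age = res$Age,
    Sex = res$Sex,
    `Physical activity` = vapply(pa_choices, function(ch)
      attr(ch, "activity") %||% "", character(1)),
    `Frequency of PA` = vapply(pa_choices, function(ch)
      attr(ch, "frequency") %||% "", character(1)),
    `Stroke % (PA only)` = unname(pa_map[key(res)]),
    `Sleep duration` = res$Sleep,
    `Stroke % (PA and sleep)` = res$prevalence_pct,
    check.names = FALSE, stringsAsFactors = FALSE, row.names = NULL)
}
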