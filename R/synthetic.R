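#' NHIS-like schema of 34 stroke correlates plus a binary target
#'
#' Returns the survey schema used throughout: 34 categorical correlates
#' (cardinalities matching the degrees of freedom each variable carries
#' against a binary outcome, i.e. states = df + 1) plus the binary
#' `STROKE` target. Sleep duration, the four physical-activity variables,
#' age and sex carry meaningful state labels; the remaining covariates use
#' generic level labels.
#'
#' @return A [bn_schema()] of 35 variables (34 correlates + `STROKE`).
#' @export
default_nhis_schema <- function() {
  lev <- function(k) paste0("l", seq_len(k))
  freq_week <- as.character(1:7)
  pa_bins <- c("<10", "10-30", "31-60", ">60")
  specs <- list(
    variable_spec("HEALTH",      lev(5)),
    variable_spec("AGE",         c("18-45", "46-65", "66+"), role = "profile"),
    variable_spec("EMPSTATWKYR", lev(4)),
    variable_spec("HYPERTENEV",  c("no", "yes")),
    variable_spec("CHEARTDIEV",  c("no", "yes")),
    variable_spec("HEARTATTEV",  c("no", "yes")),
    variable_spec("MARSTAT",     lev(5)),
    variable_spec("HEARTCONEV",  c("no", "yes")),
    variable_spec("DIABETICEV",  lev(3)),
    variable_spec("VIG10DMIN",   pa_bins, role = "profile"),
    variable_spec("ANGIPECEV",   c("no", "yes")),
    variable_spec("ALCSTAT1",    lev(3)),
    variable_spec("ALCSTAT2",    lev(7)),
    variable_spec("INCFAM97ON2", lev(3)),
    variable_spec("KIDNEYWKYR",  c("no", "yes")),
    variable_spec("HRSLEEP",     c("short", "average", "long"), role = "profile"),
    variable_spec("EMPHYSEMEV",  c("no", "yes")),
    variable_spec("EDUCREC1",    lev(4)),
    variable_spec("MOD10DMIN",   pa_bins, role = "profile"),
    variable_spec("USUALPL",     lev(3)),
    variable_spec("EMODISTRESS", c("no", "yes")),
    variable_spec("WORKEV",      c("no", "yes")),
    variable_spec("POORYN",      c("no", "yes")),
    variable_spec("SMOKEV",      c("no", "yes")),
    variable_spec("MOD10FWK",    freq_week, role = "profile"),
    variable_spec("LIVERCONYR",  c("no", "yes")),
    variable_spec("RACEA",       lev(4)),
    variable_spec("HISPETH",     c("no", "yes")),
    variable_spec("VIG10FWK",    freq_week, role = "profile"),
    variable_spec("HEIGHT",      lev(4)),
    variable_spec("BMICALC",     lev(4)),
    variable_spec("REGION",      lev(4)),
    variable_spec("WEIGHT",      lev(4)),
    variable_spec("SEX",         c("male", "female"), role = "profile"),
    variable_spec("STROKE",      c("no", "yes"), role = "target")
  )
  bn_schema(specs)
}

#' Configuration of the synthetic ground-truth generator
#'
#' Describes a tree-augmented naive Bayes (TAN) ground truth: the target is
#' a parent of every feature and the features form a seeded random spanning
#' tree among themselves. Dependence strength is parameterized as
#' total-variation (TV) distance between conditional rows, which directly
#' controls the conditional mutual information the learner must detect.
#'
#' @param prevalence Marginal probability of the positive target state
#'   (default 0.0307, the national-average self-reported stroke rate the
#'   study sample exhibits).
#' @param schema Schema to generate under; default [default_nhis_schema()].
#' @param target Target variable name (default the schema's `target` role).
#' @param effect_target TV distance between a feature's conditional rows
#'   for the two target states (scalar or named per-feature vector; 0 makes
#'   features independent of the target).
#' @param effect_tree TV distance injected between conditional rows across
#'   tree-parent states (scalar or named per-feature vector).
#' @param missingness MCAR cell-masking rate per variable (scalar or named
#'   vector, in `[0,1)`); the target defaults to 0 so outcomes stay
#'   observed.
#' @param jshape_sleep If `TRUE`, `HRSLEEP` stands outside the feature
#'   tree (target parent only) and its conditional rows are calibrated so the posterior
#'   P(target | sleep) is J-shaped (average < short < long), emulating the
#'   reported sleep composition of stroke cases (30.4% short, 20.7% long
#'   sleepers among cases vs 29% / 8.7% overall).
#' @param base_concentration Dirichlet concentration of the baseline state
#'   distributions (larger = closer to uniform).
#' @param tree_edges Optional two-column matrix of feature-tree edges to
#'   use instead of a random spanning tree.
#' @param seed Integer seed making the ground truth reproducible.
#' @return Object of class `bbn_generator_config`.
#' @export
generator_config <- function(prevalence = 0.0307,
                             schema = default_nhis_schema(),
                             target = NULL,
                             effect_target = 0.15,
                             effect_tree = 0.25,
                             missingness = 0.02,
                             jshape_sleep = FALSE,
                             base_concentration = 5,
                             tree_edges = NULL,
                             seed = 1L) {
  target <- target %||% schema_target(schema)
  if (length(target) != 1L || !target %in% schema_names(schema))
    stop("config needs exactly one target variable present in the schema")
  if (!(prevalence > 0 && prevalence < 1))
    stop("prevalence must lie in (0, 1)")
  features <- setdiff(schema_names(schema), target)
  norm_rates <- function(r, default_target = 0) {
    if (is.null(names(r))) r <- stats::setNames(rep_len(r, length(features)), features)
    full <- stats::setNames(rep(0, length(schema)), schema_names(schema))
    full[names(r)] <- r
    if (!target %in% names(r)) full[target] <- default_target
    full
  }
  miss <- norm_rates(missingness)
  if (any(miss < 0 | miss >= 1)) stop("missingness rates must lie in [0, 1)")
  expand <- function(x) {
    if (is.null(names(x))) stats::setNames(rep_len(x, length(features)), features)
    else stats::setNames(x[features], features)
  }
  structure(list(prevalence = prevalence, schema = schema, target = target,
                 effect_target = expand(effect_target),
                 effect_tree = expand(effect_tree),
                 missingness = miss, jshape_sleep = jshape_sleep,
                 base_concentration = base_concentration,
                 tree_edges = tree_edges, seed = as.integer(seed)),
            class = "bbn_generator_config")
}

# Shift distribution `p` toward state `k` by exact total-variation `d`:
# p' = (1-lambda) p + lambda e_k with lambda = d / (1 - p[k]).
shift_toward <- function(p, d, k) {
  if (d <= 0) return(p)
  room <- 1 - p[k]
  lambda <- min(d / room, 0.95)
  p2 <- (1 - lambda) * p
  p2[k] <- p2[k] + lambda
  p2
}

#' Build the synthetic TAN ground truth
#'
#' The target node is a root whose marginal equals the configured
#' prevalence exactly. Each feature is conditioned on the target and (bar
#' the tree root) one other feature; its conditional rows are the feature's
#' baseline Dirichlet draw shifted by the configured total-variation effect
#' sizes, in state directions that differ across conditioning states so
#' the rows are distinguishable.
#'
#' @param config A [generator_config()].
#' @return A valid `bbn_net`, deterministic given `config$seed`.
#' @export
build_ground_truth <- function(config) {
  stopifnot(inherits(config, "bbn_generator_config"))
  schema <- config$schema
  target <- config$target
  cards <- schema_cards(schema)
  features <- setdiff(schema_names(schema), target)
  local_seed(config$seed, {
    # Feature tree: each later feature attaches to a uniformly chosen
    # earlier one.
    # With the J-shape option the sleep variable stands outside the feature
    # tree (target parent only): its calibrated likelihood ratio then shifts
    # the posterior identically under any covariate profile, so the
    # J-shaped ordering holds within every stratum, not just marginally.
    ord <- features
    if (config$jshape_sleep && "HRSLEEP" %in% features)
      ord <- setdiff(features, "HRSLEEP")
    if (!is.null(config$tree_edges)) {
      tree <- matrix(as.character(config$tree_edges), ncol = 2)
    } else if (length(ord) >= 2) {
      anc <- vapply(2:length(ord), function(i)
        ord[sample.int(i - 1L, 1L)], character(1))
      tree <- cbind(anc, ord[-1])
    } else tree <- matrix(character(0), 0, 2)

    tables <- list()
    tables[[target]] <- cpt_table(target, character(0),
                                  matrix(c(1 - config$prevalence,
                                           config$prevalence), 1))
    tree_parent <- stats::setNames(rep(NA_character_, length(features)), features)
    if (nrow(tree)) tree_parent[tree[, 2]] <- tree[, 1]

    for (f in features) {
      r <- cards[[f]]
      p0 <- stats::rgamma(r, shape = config$base_concentration)
      p0 <- p0 / sum(p0)
      dT <- config$effect_target[[f]]
      dU <- config$effect_tree[[f]]
      dirT <- sample.int(r, 1L)
      offs <- sample.int(r, 1L)
      u_parent <- tree_parent[[f]]
      parents <- c(target, if (!is.na(u_parent)) u_parent)
      m <- if (is.na(u_parent)) 1L else cards[[u_parent]]
      if (config$jshape_sleep && f == "HRSLEEP") {
        prob <- rbind(c(0.290, 0.623, 0.087),   # target = no
                      c(0.304, 0.489, 0.207))   # target = yes
        tables[[f]] <- cpt_table(f, target, prob)
        next
      }
      grid <- config_grid(c(cards[target], if (!is.na(u_parent)) m))
      prob <- matrix(NA_real_, nrow(grid), r)
      for (i in seq_len(nrow(grid))) {
        t_state <- grid[i, 1]
        p <- p0
        if (t_state == 2L) p <- shift_toward(p, dT, dirT)
        if (!is.na(u_parent)) {
          u <- grid[i, 2]
          if (u >= 2L) p <- shift_toward(p, dU, ((u - 2L + offs) %% r) + 1L)
        }
        prob[i, ] <- p
      }
      tables[[f]] <- cpt_table(f, parents, prob)
    }
    edges <- rbind(cbind(target, features), tree)
    net <- bayes_net(schema, edges, tables[schema_names(schema)])
    marg <- posterior(net, target, list())
    if (abs(marg$p[2] - config$prevalence) > 1e-6)
      stop("infeasible configuration: target marginal ",
           format(marg$p[2]), " != requested prevalence")
    net
  })
}

#' Mask cells completely at random
#'
#' Each cell of each variable is independently replaced by the missing
#' marker with that variable's rate (MCAR). A rate of 0 (the target's
#' default) leaves a variable fully observed.
#'
#' @param ds A `bbn_dataset`.
#' @param rates Scalar or named per-variable rates in `[0,1)`; unnamed
#'   scalars apply to every variable.
#' @param seed Integer seed.
#' @return A `bbn_dataset` with the same records, weights and schema.
#' @export
inject_missingness <- function(ds, rates, seed = NULL) {
  vars <- schema_names(ds$schema)
  if (is.null(names(rates)))
    rates <- stats::setNames(rep_len(as.numeric(rates), length(vars)), vars)
  else {
    full <- stats::setNames(rep(0, length(vars)), vars)
    full[names(rates)] <- rates
    rates <- full
  }
  if (any(rates < 0 | rates >= 1)) stop("missingness rates must lie in [0, 1)")
  x <- ds$x
  local_seed(seed, {
    for (v in vars) {
      if (rates[[v]] <= 0) next
      mask <- stats::runif(nrow(x)) < rates[[v]]
      x[mask, v] <- NA_integer_
    }
  })
  bn_dataset(ds$schema, x, ds$weights)
}

#' Split records into learning and test sets
#'
#' A seeded shuffle assigns `floor(n * test_fraction)` records to the test
#' set and the rest to the learning set; the two are disjoint and
#' exhaustive. A 288,888-record dataset at fraction 0.2 yields the
#' 231,111 / 57,777 learning/test sizes of the study design.
#'
#' @param ds A `bbn_dataset` (nonempty).
#' @param test_fraction In (0, 1); default 0.2.
#' @param seed Integer seed.
#' @return List with elements `train` and `test` (both `bbn_dataset`).
#' @export
train_test_split <- function(ds, test_fraction = 0.2, seed = NULL) {
  n <- n_records(ds)
  if (n == 0L) stop("cannot split an empty dataset")
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("test_fraction must lie in (0, 1)")
  n_test <- floor(n * test_fraction)
  idx <- local_seed(seed, sample.int(n))
  test_idx <- sort(idx[seq_len(n_test)])
  train_idx <- sort(idx[-seq_len(n_test)])
  list(train = bn_dataset(ds$schema, ds$x[train_idx, , drop = FALSE],
                          ds$weights[train_idx]),
       test = bn_dataset(ds$schema, ds$x[test_idx, , drop = FALSE],
                         ds$weights[test_idx]))
}

#' Generate a synthetic survey dataset
#'
#' Convenience wrapper: builds the ground truth from `config`, forward
#' samples `n` records, and applies the configured MCAR missingness.
#'
#' @param config A [generator_config()].
#' @param n Number of records.
#' @param seed Sampling seed (independent of the structural
#'   `config$seed`).
#' @return List with `net` (the ground truth) and `data` (a
#'   `bbn_dataset`).
#' @export
simulate_survey <- function(config, n, seed = NULL) {
  net <- build_ground_truth(config)
  ds <- forward_sample(net, n, seed = seed)
  if (any(config$missingness > 0))
    ds <- inject_missingness(ds, config$missingness,
                             seed = if (is.null(seed)) NULL else seed + 1L)
  list(net = net, data = ds)
}

#' Write a dataset as CSV (labels, empty cell = missing)
#'
#' @param ds A `bbn_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(ds, path) {
  df <- dataset_labels(ds)
  data.table::fwrite(df, path, na = "", quote = FALSE)
  invisible(path)
}
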