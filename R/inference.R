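new_distribution <- function(states, p) {
  p <- as.numeric(p)
  if (abs(sum(p) - 1) > 1e-9)
    stop("distribution does not sum to 1 (sum = ", format(sum(p)), ")")
  structure(list(states = states, p = stats::setNames(p, states)),
            class = "bbn_distribution")
}

#' @export
print.bbn_distribution <- function(x, ...) {
  cat("<bbn_distribution>\n")
  print(round(x$p, 6))
  invisible(x)
}

#' Exact posterior distribution of a target variable
#'
#' Computes `P(target | evidence)` by variable elimination with a
#' min-degree elimination heuristic. With empty evidence this is the
#' exact prior marginal.
#'
#' @param net A valid `bbn_net`.
#' @param target Variable whose posterior is required.
#' @param evidence Named list/vector mapping variables to observed state
#'   labels (or 1-based indices); must not include `target` and must have
#'   nonzero probability.
#' @return A `bbn_distribution` over the target's states.
#' @export
posterior <- function(net, target, evidence = list()) {
  assert_valid_net(net)
  if (!target %in% schema_names(net$schema))
    stop("unknown target '", target, "'")
  ev <- as_evidence(net$schema, evidence)
  if (target %in% names(ev))
    stop("evidence must not include the target variable")
  factors <- lapply(schema_names(net$schema), cpt_factor, net = net)
  for (v in names(ev))
    factors <- lapply(factors, factor_reduce, var = v, state = ev[[v]])
  elim <- setdiff(schema_names(net$schema), c(target, names(ev)))
  while (length(elim)) {
    # min-degree: eliminate the variable whose combined factor is smallest
    sizes <- vapply(elim, function(v) {
      involved <- factors[vapply(factors, function(f) v %in% f$vars, logical(1))]
      length(unique(unlist(lapply(involved, `[[`, "vars"))))
    }, numeric(1))
    v <- elim[order(sizes, elim)][1]
    elim <- setdiff(elim, v)
    has_v <- vapply(factors, function(f) v %in% f$vars, logical(1))
    prod_f <- Reduce(factor_product, factors[has_v])
    factors <- c(factors[!has_v], list(factor_marginalize(prod_f, v)))
  }
  f <- Reduce(factor_product, factors)
  stopifnot(identical(f$vars, target))
  z <- sum(f$val)
  if (z <= 0)
    stop("evidence {", paste(names(ev), unlist(evidence), sep = "=",
                             collapse = ", "),
         "} has probability zero under the model")
  new_distribution(schema_states(net$schema, target), f$val / z)
}

#' Brute-force posterior by full joint enumeration
#'
#' Independent oracle for [posterior()]: materializes the full joint
#' table, slices the evidence, and marginalizes. Refuses joint state
#' spaces above `max_cells` configurations.
#'
#' @inheritParams posterior
#' @param max_cells Enumeration guard (default 1e7).
#' @return A `bbn_distribution`.
#' @export
brute_force_posterior <- function(net, target, evidence = list(),
                                  max_cells = 1e7) {
  assert_valid_net(net)
  ev <- as_evidence(net$schema, evidence)
  if (target %in% names(ev))
    stop("evidence must not include the target variable")
  joint <- joint_table(net, max_cells = max_cells)
  vars <- schema_names(net$schema)
  f <- new_factor(vars, schema_cards(net$schema), as.numeric(joint))
  for (v in names(ev)) f <- factor_reduce(f, v, ev[[v]])
  for (v in setdiff(f$vars, target)) f <- factor_marginalize(f, v)
  z <- sum(f$val)
  if (z <= 0) stop("evidence has probability zero under the model")
  new_distribution(schema_states(net$schema, target), f$val / z)
}

#' Fixed- or dynamic-mode observational query
#'
#' Dynamic mode is ordinary probabilistic conditioning and returns exactly
#' [posterior()] (all covariates update with the evidence). Fixed mode
#' holds every variable outside the target and the evidence at its
#' baseline (no-evidence) joint distribution and standardizes over it:
#' with fixed set Z,
#' \deqn{P_{fixed}(t \mid e) = \sum_z P(Z = z)\, P(t \mid e, z)}
#' restricted (renormalized) to the `z` compatible with the evidence.
#' This is a covariate-standardization reading of "fixing probabilities"
#' to control confounding; it is computed by exact enumeration when the
#' fixed set's state space is small and otherwise by seeded Monte-Carlo
#' (forward-sampling z from the baseline network, averaging the
#' conditional, skipping zero-probability combinations).
#'
#' @inheritParams posterior
#' @param mode `"fixed"` or `"dynamic"`.
#' @param mc_samples Monte-Carlo sample count for the sampling path
#'   (default 1e5).
#' @param seed Seed for the sampling path.
#' @param enum_limit Enumerate exactly when `prod(cards[Z])` is at most
#'   this and the full joint fits the enumeration guard.
#' @param baseline_x Optional pre-drawn baseline sample matrix (internal
#'   reuse across profile cells); must come from [forward_sample()] of
#'   `net`.
#' @return Object of class `bbn_obs_result`: `dist`, `mode`, `evidence`,
#'   and `diagnostics` (method, samples used, skipped count, seed).
#' @export
observational_query <- function(net, target, evidence = list(),
                                mode = c("fixed", "dynamic"),
                                mc_samples = 1e5, seed = NULL,
                                enum_limit = 1e6, baseline_x = NULL) {
  mode <- match.arg(mode)
  assert_valid_net(net)
  ev <- as_evidence(net$schema, evidence)
  if (target %in% names(ev))
    stop("evidence must not include the target variable")
  diagnostics <- list(method = "enumeration", samples = NA_integer_,
                      skipped = 0L, seed = seed)
  if (mode == "dynamic") {
    dist <- posterior(net, target, evidence)
    return(structure(list(dist = dist, mode = mode, evidence = evidence,
                          diagnostics = diagnostics),
                     class = "bbn_obs_result"))
  }
  cards <- schema_cards(net$schema)
  zvars <- setdiff(schema_names(net$schema), c(target, names(ev)))
  if (prod(cards[zvars]) <= enum_limit && prod(cards) <= 1e7) {
    dist <- fixed_mode_enumeration(net, target, ev, zvars)
  } else {
    res <- fixed_mode_mc(net, target, ev, mc_samples, seed, baseline_x)
    dist <- res$dist
    diagnostics$method <- "monte-carlo"
    diagnostics$samples <- res$samples
    diagnostics$skipped <- res$skipped
  }
  structure(list(dist = dist, mode = mode, evidence = evidence,
                 diagnostics = diagnostics),
            class = "bbn_obs_result")
}

#' @export
print.bbn_obs_result <- function(x, ...) {
  cat("<bbn_obs_result> mode =", x$mode, "(", x$diagnostics$method, ")\n")
  print(round(x$dist$p, 6))
  invisible(x)
}

fixed_mode_enumeration <- function(net, target, ev, zvars) {
  vars <- schema_names(net$schema)
  cards <- schema_cards(net$schema)
  joint <- new_factor(vars, cards, as.numeric(joint_table(net)))
  # Baseline P(Z): marginalize target and evidence variables from the
  # untouched joint.
  pz <- joint
  for (v in setdiff(vars, zvars)) pz <- factor_marginalize(pz, v)
  # P(t, e, z): slice the evidence.
  fe <- joint
  for (v in names(ev)) fe <- factor_reduce(fe, v, ev[[v]])
  for (v in setdiff(fe$vars, c(target, zvars))) fe <- factor_marginalize(fe, v)
  if (length(zvars) == 0L) {
    z <- sum(fe$val)
    if (z <= 0) stop("evidence has probability zero under the model")
    return(new_distribution(schema_states(net$schema, target), fe$val / z))
  }
  # Align fe over (target, Z) with pz over Z.
  tcard <- cards[[target]]
  zcards <- pz$card
  idx_t <- factor_map_index(fe$vars, fe$card, target, tcard)
  idx_z <- factor_map_index(fe$vars, fe$card, pz$vars, zcards)
  joint_tz <- matrix(0, tcard, prod(zcards))
  joint_tz[cbind(idx_t, idx_z)] <- fe$val
  pe_z <- colSums(joint_tz)            # P(e, z) up to the evidence slice
  valid <- pe_z > 0
  if (!any(valid)) stop("evidence has probability zero under the model")
  wz <- pz$val[valid] / sum(pz$val[valid])
  cond <- joint_tz[, valid, drop = FALSE] /
    matrix(pe_z[valid], tcard, sum(valid), byrow = TRUE)
  new_distribution(schema_states(net$schema, target),
                   as.numeric(cond %*% wz))
}

fixed_mode_mc <- function(net, target, ev, mc_samples, seed, baseline_x) {
  cards <- schema_cards(net$schema)
  x <- if (is.null(baseline_x))
    forward_sample(net, mc_samples, seed = seed)$x
  else baseline_x
  m <- nrow(x)
  for (v in names(ev)) x[, v] <- ev[[v]]
  tcard <- cards[[target]]
  lp <- matrix(NA_real_, m, tcard)
  for (t in seq_len(tcard)) {
    x[, target] <- t
    lp[, t] <- log2_joint_records(net, x)
  }
  pj <- 2^(lp - apply(lp, 1, max))
  pj[!is.finite(pj)] <- 0
  tot <- rowSums(pj)
  valid <- tot > 0
  if (!any(valid))
    stop("all Monte-Carlo samples were incompatible with the evidence")
  cond <- pj[valid, , drop = FALSE] / tot[valid]
  list(dist = new_distribution(schema_states(net$schema, target),
                               colMeans(cond)),
       samples = m, skipped = as.integer(m - sum(valid)))
}
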