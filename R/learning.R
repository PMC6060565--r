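#' Weighted cross-tabulation over complete cases
#'
#' Counts records that are fully observed on `vars`, accumulating record
#' weights. Cells are laid out with the first variable varying fastest.
#'
#' @param ds A `bbn_dataset`.
#' @param vars Character vector of schema variables.
#' @return Object of class `bbn_contingency`: `vars`, `cards`, `counts`
#'   (vector over the joint state space) and total weight `n`.
#' @export
contingency_counts <- function(ds, vars) {
  unknown <- setdiff(vars, schema_names(ds$schema))
  if (length(unknown))
    stop("unknown variables: ", paste(unknown, collapse = ", "))
  cards <- schema_cards(ds$schema)[vars]
  x <- ds$x[, vars, drop = FALSE]
  keep <- stats::complete.cases(x)
  counts <- numeric(prod(cards))
  if (any(keep)) {
    idx <- config_index(x[keep, , drop = FALSE], cards)
    agg <- rowsum(ds$weights[keep], idx)
    counts[as.integer(rownames(agg))] <- agg[, 1]
  }
  structure(list(vars = vars, cards = cards, counts = counts,
                 n = sum(counts)),
            class = "bbn_contingency")
}

ct_array <- function(ct) array(ct$counts, dim = ct$cards)

#' Mutual information of a two-way contingency table, in bits
#'
#' \eqn{I(X;Y) = \sum \hat p(x,y) \log_2 \frac{\hat p(x,y)}{\hat p(x)\hat p(y)}}
#' with the convention \eqn{0 \log 0 = 0}. Always nonnegative and
#' symmetric.
#'
#' @param ct A [contingency_counts()] over exactly two variables.
#' @return MI in bits.
#' @export
mutual_information <- function(ct) {
  stopifnot(inherits(ct, "bbn_contingency"), length(ct$vars) == 2L)
  if (ct$n <= 0) stop("empty contingency table")
  p <- ct_array(ct) / ct$n
  px <- rowSums(p)
  py <- colSums(p)
  ratio <- p / outer(px, py)
  terms <- p * log2(ratio)
  max(sum(terms[p > 0]), 0)
}

entropy_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Conditional mutual information I(X;Y | C), in bits
#'
#' Weighted average over the conditioning variable's states of the
#' within-slice mutual information, using complete cases of the triple.
#'
#' @param ds A `bbn_dataset`.
#' @param xi,xj,cond Variable names.
#' @return CMI in bits (nonnegative).
#' @export
conditional_mutual_information <- function(ds, xi, xj, cond) {
  ct <- contingency_counts(ds, c(xi, xj, cond))
  if (ct$n <= 0) stop("no complete cases for (", xi, ", ", xj, ", ", cond, ")")
  arr <- ct_array(ct)
  cmi <- 0
  for (k in seq_len(dim(arr)[3])) {
    slice <- arr[, , k]
    nk <- sum(slice)
    if (nk <= 0) next
    sub <- structure(list(vars = c(xi, xj), cards = ct$cards[1:2],
                          counts = as.numeric(slice), n = nk),
                     class = "bbn_contingency")
    cmi <- cmi + (nk / ct$n) * mutual_information(sub)
  }
  max(cmi, 0)
}

nb_structure <- function(schema, target) {
  features <- setdiff(schema_names(schema), target)
  cbind(parent = rep(target, length(features)), child = features)
}

#' Learn a naive Bayes network
#'
#' Fixed topology (target is the sole parent of every feature) with CPTs
#' estimated by [fit_cpts()].
#'
#' @param ds A `bbn_dataset` (nonempty).
#' @param target Target variable name.
#' @param alpha Laplace smoothing pseudo-count (default 1).
#' @return A valid `bbn_net`.
#' @export
learn_naive_bayes <- function(ds, target, alpha = 1) {
  if (n_records(ds) == 0L) stop("empty dataset")
  fit_cpts(nb_structure(ds$schema, target), ds, alpha, schema = ds$schema)
}

# Maximum-weight spanning tree (Kruskal). `edges` is a data.frame with
# columns a, b, w; ties broken by lexicographic (a, b) order so repeated
# runs are identical.
max_spanning_tree <- function(nodes, edges) {
  if (length(nodes) <= 1L) return(matrix(character(0), 0, 2))
  ord <- order(-edges$w, edges$a, edges$b)
  edges <- edges[ord, , drop = FALSE]
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  chosen <- matrix(character(0), 0, 2)
  for (k in seq_len(nrow(edges))) {
    ra <- find(match(edges$a[k], nodes))
    rb <- find(match(edges$b[k], nodes))
    if (ra != rb) {
      parent[ra] <- rb
      chosen <- rbind(chosen, c(edges$a[k], edges$b[k]))
      if (nrow(chosen) == length(nodes) - 1L) break
    }
  }
  chosen
}

#' Learn a tree-augmented naive Bayes (TAN) network
#'
#' Chow-Liu construction: weight every feature pair by its conditional
#' mutual information given the target, take the maximum-weight spanning
#' tree, orient it outward from the lexicographically first feature, and
#' add the naive Bayes target-to-feature edges. Every feature ends up with
#' the target plus at most one feature parent. Feature pairs with no
#' complete-case overlap get weight 0; CMI ties break lexicographically.
#'
#' @inheritParams learn_naive_bayes
#' @return A valid `bbn_net`.
#' @export
learn_tan <- function(ds, target, alpha = 1) {
  features <- setdiff(schema_names(ds$schema), target)
  if (length(features) < 2L) stop("TAN needs at least 2 features")
  pairs <- utils::combn(sort(features), 2)
  w <- apply(pairs, 2, function(pr) {
    tryCatch(conditional_mutual_information(ds, pr[1], pr[2], target),
             error = function(e) 0)
  })
  tree <- max_spanning_tree(sort(features),
                            data.frame(a = pairs[1, ], b = pairs[2, ], w = w,
                                       stringsAsFactors = FALSE))
  # Orient outward from the lexicographically first feature (BFS).
  root <- sort(features)[1]
  adj <- split(c(tree[, 2], tree[, 1]), c(tree[, 1], tree[, 2]))
  oriented <- matrix(character(0), 0, 2)
  visited <- root
  queue <- root
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    for (u in sort(adj[[v]] %||% character(0))) {
      if (u %in% visited) next
      oriented <- rbind(oriented, c(v, u))
      visited <- c(visited, u)
      queue <- c(queue, u)
    }
  }
  structure_edges <- rbind(nb_structure(ds$schema, target),
                           unname(cbind(oriented[, 1], oriented[, 2])))
  fit_cpts(structure_edges, ds, alpha, schema = ds$schema)
}

#' Fit conditional probability tables on a fixed structure
#'
#' Each row of a child's table is `(count + alpha) / (total + alpha *
#' r_child)`, with counts taken over records fully observed on the child
#' and its parents (pairwise deletion per family). `alpha = 0` gives exact
#' empirical frequencies and errors on empty rows; `alpha = 1` (Laplace)
#' maps never-seen parent configurations to a uniform row.
#'
#' @param structure A `bbn_net` (its edges are reused) or a two-column
#'   parent/child edge matrix.
#' @param ds A `bbn_dataset`.
#' @param alpha Smoothing pseudo-count, `>= 0`.
#' @param schema Schema (defaults to `ds$schema`).
#' @return A valid `bbn_net`.
#' @export
fit_cpts <- function(structure, ds, alpha = 1, schema = NULL) {
  schema <- schema %||% ds$schema
  if (alpha < 0) stop("alpha must be nonnegative")
  edges <- if (inherits(structure, "bbn_net")) structure$edges
  else matrix(as.character(structure), ncol = 2)
  cards <- schema_cards(schema)
  tables <- lapply(schema_names(schema), function(v) {
    parents <- sort(unname(edges[edges[, 2] == v, 1]))
    ct <- contingency_counts(ds, c(parents, v))
    counts <- matrix(ct$counts, nrow = prod(c(1, cards[parents])),
                     ncol = cards[[v]])
    tot <- rowSums(counts)
    if (alpha == 0 && any(tot == 0))
      stop("empty count row for '", v,
           "' with alpha = 0; use alpha > 0 for smoothing")
    prob <- (counts + alpha) / (tot + alpha * cards[[v]])
    cpt_table(v, parents, prob)
  })
  names(tables) <- schema_names(schema)
  bayes_net(schema, edges, tables)
}

#' Minimum description length score of a network on data
#'
#' Data description length is the code length of the complete-case records
#' under the network, \eqn{\sum_i w_i \cdot (-\log_2 P(x_i))} bits; model
#' description length is the BIC-style parameter cost
#' \eqn{(K/2)\log_2 N} with \eqn{K = \sum_v (r_v - 1)\prod_{p \in pa(v)} r_p}.
#' Only score *rankings* across candidate structures are meaningful.
#'
#' @param net A valid `bbn_net` (CPTs as fitted).
#' @param ds A `bbn_dataset`; records with missing cells are excluded from
#'   scoring.
#' @return Object of class `bbn_score`: `model_dl`, `data_dl`, `total`
#'   (all bits), parameter count `k`, and `n` (total scored weight).
#' @export
mdl_score <- function(net, ds) {
  assert_valid_net(net)
  keep <- stats::complete.cases(ds$x)
  x <- ds$x[keep, , drop = FALSE]
  w <- ds$weights[keep]
  if (nrow(x) == 0L) stop("no complete cases to score")
  lp <- log2_joint_records(net, x)
  if (any(!is.finite(lp)))
    stop("a record has probability 0 under the model; refit with alpha > 0")
  data_dl <- -sum(w * lp)
  cards <- schema_cards(net$schema)
  k <- sum(vapply(net$tables, function(tab)
    (cards[[tab$child]] - 1) * prod(c(1, cards[tab$parents])), numeric(1)))
  model_dl <- k / 2 * log2(sum(w))
  structure(list(model_dl = model_dl, data_dl = data_dl,
                 total = model_dl + data_dl, k = k, n = sum(w)),
            class = "bbn_score")
}

#' @export
print.bbn_score <- function(x, ...) {
  cat(sprintf("<bbn_score> total %.1f bits (model %.1f + data %.1f), K = %d\n",
              x$total, x$model_dl, x$data_dl, as.integer(x$k)))
  invisible(x)
}

#' Select the structure with the best (lowest) total MDL
#'
#' @param ds A `bbn_dataset`.
#' @param target Target variable name.
#' @param candidates Named list of learner functions with signature
#'   `function(ds, target, alpha)`; defaults to naive Bayes and TAN.
#' @param alpha Smoothing passed to each learner and used when scoring.
#' @return List with `best` (name), `net` (winning network) and `scores`
#'   (data.frame of per-candidate description lengths).
#' @export
select_structure <- function(ds, target,
                             candidates = list(nb = learn_naive_bayes,
                                               tan = learn_tan),
                             alpha = 1) {
  stopifnot(length(candidates) >= 1L, !is.null(names(candidates)))
  nets <- lapply(candidates, function(f) f(ds, target, alpha))
  scores <- lapply(nets, mdl_score, ds = ds)
  tab <- data.frame(candidate = names(candidates),
                    model_dl = vapply(scores, `[[`, numeric(1), "model_dl"),
                    data_dl = vapply(scores, `[[`, numeric(1), "data_dl"),
                    total_mdl = vapply(scores, `[[`, numeric(1), "total"),
                    k = vapply(scores, `[[`, numeric(1), "k"),
                    row.names = NULL)
  best <- names(candidates)[which.min(tab$total_mdl)]
  list(best = best, net = nets[[best]], scores = tab)
}

# Exact prior marginal mode of every variable (used for all-missing
# records and as the baseline imputer).
marginal_modes <- function(net) {
  vapply(schema_names(net$schema), function(v) {
    p <- posterior(net, v, list())$p
    which.max(p)
  }, integer(1))
}

#' Impute missing cells by per-record posterior mode
#'
#' Every missing cell is replaced by the state maximizing its exact
#' posterior given the record's observed cells under `net`. Records are
#' grouped by missingness pattern and each pattern's joint completions are
#' enumerated (vectorized over the pattern's records); a record whose
#' completion space exceeds `max_combos` falls back to deterministic
#' iterative conditional modes (initialized at prior marginal modes) and
#' is counted in the diagnostics. Records with every cell missing are
#' filled from the prior marginal modes and flagged. With `passes > 1`,
#' CPTs are refit on the completed data between passes and the original
#' missing cells re-imputed under the refit model.
#'
#' @param ds A `bbn_dataset`.
#' @param net A valid `bbn_net` over the dataset's schema.
#' @param passes Number of impute/refit passes (default 1).
#' @param alpha Smoothing used for between-pass refits.
#' @param max_combos Cap on a record's enumerated completion space.
#' @return A complete `bbn_dataset`; attribute `diagnostics` reports
#'   `cells_imputed`, `records_all_missing` and `records_fallback`.
#' @export
impute_missing <- function(ds, net, passes = 1, alpha = 1, max_combos = 1e4) {
  assert_valid_net(net)
  stopifnot(passes >= 1)
  miss <- is.na(ds$x)
  diag <- list(cells_imputed = sum(miss),
               records_all_missing = 0L, records_fallback = 0L)
  x <- ds$x
  for (pass in seq_len(passes)) {
    res <- impute_once(ds$x, net, max_combos)
    x <- res$x
    diag$records_all_missing <- res$all_missing
    diag$records_fallback <- res$fallback
    if (pass < passes)
      net <- fit_cpts(net$edges, bn_dataset(ds$schema, x, ds$weights),
                      alpha, schema = ds$schema)
  }
  out <- bn_dataset(ds$schema, x, ds$weights)
  attr(out, "diagnostics") <- diag
  out
}

impute_once <- function(x, net, max_combos) {
  schema <- net$schema
  cards <- schema_cards(schema)
  vars <- schema_names(schema)
  modes <- marginal_modes(net)
  miss <- is.na(x)
  need <- which(rowSums(miss) > 0L)
  all_missing <- 0L
  fallback <- 0L
  if (!length(need)) return(list(x = x, all_missing = 0L, fallback = 0L))

  pattern <- apply(miss[need, , drop = FALSE], 1, function(m)
    paste(which(m), collapse = ","))
  for (key in unique(pattern)) {
    rows <- need[pattern == key]
    mvars <- vars[as.integer(strsplit(key, ",")[[1]])]
    if (length(mvars) == length(vars)) {
      x[rows, ] <- matrix(modes, length(rows), length(vars), byrow = TRUE)
      all_missing <- all_missing + length(rows)
      next
    }
    n_comb <- prod(cards[mvars])
    if (n_comb <= max_combos) {
      x[rows, ] <- impute_pattern_exact(x[rows, , drop = FALSE], net,
                                        mvars, cards)
    } else {
      fallback <- fallback + length(rows)
      x[rows, ] <- impute_pattern_icm(x[rows, , drop = FALSE], net,
                                      mvars, cards, modes)
    }
  }
  list(x = x, all_missing = all_missing, fallback = fallback)
}

# Exact posterior-mode imputation for a block of records sharing one
# missingness pattern: enumerate joint completions of the missing set,
# evaluate each completion's log joint (only the families touching a
# missing variable vary across completions), and take each variable's
# posterior-marginal argmax.
impute_pattern_exact <- function(xb, net, mvars, cards) {
  vars <- schema_names(net$schema)
  touched <- vars[vapply(vars, function(v) {
    tab <- net$tables[[v]]
    v %in% mvars || any(tab$parents %in% mvars)
  }, logical(1))]
  base_nodes <- setdiff(vars, touched)
  nb <- nrow(xb)
  grid <- config_grid(cards[mvars])
  n_comb <- nrow(grid)

  lp <- matrix(0, nb, n_comb)
  xfill <- xb
  for (ci in seq_len(n_comb)) {
    xfill[, mvars] <- matrix(grid[ci, ], nb, length(mvars), byrow = TRUE)
    l <- numeric(nb)
    for (v in touched) {
      tab <- net$tables[[v]]
      rows <- config_index(xfill[, tab$parents, drop = FALSE],
                           cards[tab$parents])
      l <- l + log2(tab$prob[cbind(rows, xfill[, v])])
    }
    lp[, ci] <- l
  }
  # Posterior over completions per record (base-node terms cancel).
  mx <- apply(lp, 1, max)
  w <- 2^(lp - mx)
  for (j in seq_along(mvars)) {
    v <- mvars[j]
    post <- rowsum(t(w), grid[, j])    # states x records
    xb[, v] <- as.integer(apply(post, 2, which.max))
  }
  xb
}

# Deterministic iterative conditional modes for oversized patterns: start
# at prior marginal modes, then repeatedly set each missing cell to the
# mode of its full conditional given every other (current) cell.
impute_pattern_icm <- function(xb, net, mvars, cards, modes, sweeps = 2L) {
  vars <- schema_names(net$schema)
  for (v in mvars) xb[, v] <- modes[[v]]
  for (s in seq_len(sweeps)) {
    for (v in mvars) {
      lp <- matrix(0, nrow(xb), cards[[v]])
      fam <- vars[vapply(vars, function(u)
        u == v || v %in% net$tables[[u]]$parents, logical(1))]
      for (state in seq_len(cards[[v]])) {
        xb[, v] <- state
        l <- numeric(nrow(xb))
        for (u in fam) {
          tab <- net$tables[[u]]
          rows <- config_index(xb[, tab$parents, drop = FALSE],
                               cards[tab$parents])
          l <- l + log2(tab$prob[cbind(rows, xb[, u])])
        }
        lp[, state] <- l
      }
      xb[, v] <- max.col(lp, ties.method = "first")
    }
  }
  xb
}
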