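#' Conditional probability table for one network node
#'
#' Rows index parent-state combinations (first parent varying fastest, the
#' `expand.grid()` convention); columns index child states. A parentless
#' node has a single row holding its marginal distribution.
#'
#' @param child Child variable name.
#' @param parents Character vector of parent names (possibly empty), in the
#'   order used for row indexing.
#' @param prob Numeric matrix, `prod(parent cards)` rows by `r_child`
#'   columns; every row must sum to 1 within 1e-9.
#' @return Object of class `bbn_cpt`.
#' @export
cpt_table <- function(child, parents = character(0), prob) {
  prob <- as.matrix(prob)
  structure(list(child = child, parents = as.character(parents), prob = prob),
            class = "bbn_cpt")
}

#' Construct a discrete Bayesian network
#'
#' A directed acyclic graph over the schema's variables plus one
#' conditional probability table per variable. Use [validate_network()] to
#' list invariant violations; consumer operations require a valid network.
#'
#' @param schema A [bn_schema()].
#' @param edges Two-column character matrix (parent, child); may have zero
#'   rows. If `NULL`, edges are reconstructed from the tables' parent sets.
#' @param tables Named list of [cpt_table()]s, one per schema variable.
#' @param check If `TRUE` (default) stop on any invariant violation.
#' @return Object of class `bbn_net`.
#' @seealso [joint_probability()], [forward_sample()], [posterior()]
#' @export
bayes_net <- function(schema, edges = NULL, tables, check = TRUE) {
  stopifnot(inherits(schema, "bbn_schema"))
  if (is.null(edges)) {
    ep <- do.call(rbind, lapply(tables, function(t)
      if (length(t$parents)) cbind(t$parents, t$child) else NULL))
    edges <- if (is.null(ep)) matrix(character(0), 0, 2) else ep
  }
  edges <- matrix(as.character(edges), ncol = 2)
  colnames(edges) <- c("parent", "child")
  net <- structure(list(schema = schema, edges = edges, tables = tables),
                   class = "bbn_net")
  if (check) {
    bad <- validate_network(net)
    if (length(bad)) stop("invalid network:\n  ", paste(bad, collapse = "\n  "))
  }
  net
}

#' List invariant violations of a network
#'
#' Checks structural invariants (acyclicity, one table per variable, table
#' parents equal to in-edges) and numeric ones (row normalization within
#' 1e-9, nonnegative entries, row counts matching parent cardinalities).
#' Violations are returned, not raised, so callers can report them all.
#'
#' @param net A `bbn_net` (built with `check = FALSE` if possibly broken).
#' @return Character vector of violation descriptions; empty iff valid.
#' @export
validate_network <- function(net) {
  out <- character(0)
  schema <- net$schema
  vars <- schema_names(schema)
  cards <- schema_cards(schema)
  for (v in vars) {
    if (is.null(net$tables[[v]])) {
      out <- c(out, paste0(v, ": no conditional table"))
      next
    }
    tab <- net$tables[[v]]
    inpar <- sort(unname(net$edges[net$edges[, 2] == v, 1]))
    if (!identical(sort(tab$parents), inpar))
      out <- c(out, paste0(v, ": table parents (",
                           paste(tab$parents, collapse = ","),
                           ") do not match in-edges (",
                           paste(inpar, collapse = ","), ")"))
    if (!all(tab$parents %in% vars)) {
      out <- c(out, paste0(v, ": unknown parent variable"))
      next
    }
    expect_rows <- prod(c(1, cards[tab$parents]))
    if (nrow(tab$prob) != expect_rows || ncol(tab$prob) != cards[v]) {
      out <- c(out, paste0(v, ": table dimensions ", nrow(tab$prob), "x",
                           ncol(tab$prob), " do not match cardinalities"))
      next
    }
    if (any(tab$prob < -1e-12))
      out <- c(out, paste0(v, ": negative probability entry"))
    rs <- rowSums(tab$prob)
    if (any(abs(rs - 1) > 1e-9))
      out <- c(out, paste0(v, ": row not normalized (max deviation ",
                           format(max(abs(rs - 1))), ")"))
  }
  extra <- setdiff(names(net$tables), vars)
  if (length(extra))
    out <- c(out, paste0(paste(extra, collapse = ","),
                         ": table for variable not in schema"))
  if (is.null(topo_order_or_null(net)))
    out <- c(out, "cycle: edge set is not acyclic")
  out
}

topo_order_or_null <- function(net) {
  vars <- schema_names(net$schema)
  edges <- net$edges[net$edges[, 1] %in% vars & net$edges[, 2] %in% vars, ,
                     drop = FALSE]
  indeg <- table(factor(edges[, 2], levels = vars))
  order <- character(0)
  avail <- vars[indeg == 0]
  indeg <- as.integer(indeg)
  names(indeg) <- vars
  while (length(avail)) {
    v <- avail[1]
    avail <- avail[-1]
    order <- c(order, v)
    ch <- edges[edges[, 1] == v, 2]
    for (c in ch) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) avail <- c(avail, c)
    }
  }
  if (length(order) == length(vars)) order else NULL
}

assert_valid_net <- function(net) {
  stopifnot(inherits(net, "bbn_net"))
  bad <- validate_network(net)
  if (length(bad))
    stop("invalid network:\n  ", paste(bad, collapse = "\n  "))
  invisible(net)
}

#' @export
print.bbn_net <- function(x, ...) {
  cat("<bbn_net> ", length(x$schema), " variables, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Joint probability of a complete assignment
#'
#' Evaluates the factorized joint \eqn{P(x) = \prod_v P(x_v \mid pa(x_v))}.
#' The product is accumulated in log space so 30+ variable networks do not
#' underflow.
#'
#' @param net A valid `bbn_net`.
#' @param assignment Named character vector (state labels) or named integer
#'   vector (1-based state indices) covering every schema variable.
#' @return A single probability.
#' @export
joint_probability <- function(net, assignment) {
  assert_valid_net(net)
  vars <- schema_names(net$schema)
  missing <- setdiff(vars, names(assignment))
  if (length(missing))
    stop("assignment is missing variables: ", paste(missing, collapse = ", "))
  idx <- vapply(vars, function(v) {
    a <- assignment[[v]]
    if (is.character(a) || is.factor(a)) state_index(net$schema, v, as.character(a))
    else as.integer(a)
  }, integer(1))
  cards <- schema_cards(net$schema)
  if (any(idx < 1L | idx > cards[vars]))
    stop("state index out of range in assignment")
  lp <- 0
  for (v in vars) {
    tab <- net$tables[[v]]
    row <- config_index(matrix(idx[tab$parents], nrow = 1), cards[tab$parents])
    lp <- lp + log2(tab$prob[row, idx[[v]]])
  }
  2^lp
}

# Vectorized log2 joint probability of complete integer-coded records.
log2_joint_records <- function(net, x) {
  cards <- schema_cards(net$schema)
  lp <- numeric(nrow(x))
  for (v in schema_names(net$schema)) {
    tab <- net$tables[[v]]
    rows <- config_index(x[, tab$parents, drop = FALSE], cards[tab$parents])
    lp <- lp + log2(tab$prob[cbind(rows, x[, v])])
  }
  lp
}

#' Draw complete records by ancestral (forward) sampling
#'
#' @param net A valid `bbn_net`.
#' @param n Number of records (`n >= 0`).
#' @param seed Integer seed; identical seeds give identical datasets. The
#'   caller's RNG stream is left untouched.
#' @return A [bn_dataset()] of `n` complete records with unit weights.
#' @export
forward_sample <- function(net, n, seed = NULL) {
  assert_valid_net(net)
  stopifnot(n >= 0)
  vars <- schema_names(net$schema)
  cards <- schema_cards(net$schema)
  x <- matrix(NA_integer_, nrow = n, ncol = length(vars),
              dimnames = list(NULL, vars))
  if (n > 0) local_seed(seed, {
    for (v in topo_order_or_null(net)) {
      tab <- net$tables[[v]]
      rows <- config_index(x[, tab$parents, drop = FALSE], cards[tab$parents])
      x[, v] <- sample_categorical_rows(tab$prob, rows)
    }
  })
  bn_dataset(net$schema, x)
}

# Sample one categorical draw per record, record i using row rows[i] of the
# probability matrix. Vectorized via the inverse-CDF over row cumsums.
sample_categorical_rows <- function(prob, rows) {
  cm <- t(apply(prob, 1, cumsum))
  if (ncol(prob) == 1L) cm <- matrix(cm, ncol = 1L)
  u <- stats::runif(length(rows))
  as.integer(rowSums(cm[rows, , drop = FALSE] < u) + 1L)
}

#' Dataset of integer-coded survey records
#'
#' Records hold 1-based state indices per variable; `NA` is the
#' distinguished missing marker (never a state). Each record carries a
#' nonnegative weight, defaulting to 1, which all counting operations
#' respect.
#'
#' @param schema A [bn_schema()].
#' @param x Integer matrix of state indices (columns named by variable) or
#'   a data.frame of state labels/factors.
#' @param weights Nonnegative numeric vector, recycled length-1 default 1.
#' @return Object of class `bbn_dataset` with elements `schema`, `x`,
#'   `weights`.
#' @export
bn_dataset <- function(schema, x, weights = 1) {
  stopifnot(inherits(schema, "bbn_schema"))
  vars <- schema_names(schema)
  if (is.data.frame(x)) {
    m <- matrix(NA_integer_, nrow(x), length(vars), dimnames = list(NULL, vars))
    missing_cols <- setdiff(vars, names(x))
    if (length(missing_cols))
      stop("data is missing columns: ", paste(missing_cols, collapse = ", "))
    for (v in vars) m[, v] <- state_index(schema, v, as.character(x[[v]]))
    x <- m
  } else {
    x <- as.matrix(x)
    storage.mode(x) <- "integer"
    if (is.null(colnames(x)) && ncol(x) == length(vars)) colnames(x) <- vars
    x <- x[, vars, drop = FALSE]
  }
  cards <- schema_cards(schema)
  for (v in vars) {
    bad <- !is.na(x[, v]) & (x[, v] < 1L | x[, v] > cards[[v]])
    if (any(bad)) stop("state index out of range for variable '", v, "'")
  }
  weights <- rep_len(as.numeric(weights), nrow(x))
  if (any(weights < 0)) stop("record weights must be nonnegative")
  structure(list(schema = schema, x = x, weights = weights),
            class = "bbn_dataset")
}

#' @export
print.bbn_dataset <- function(x, ...) {
  cat("<bbn_dataset> ", nrow(x$x), " records x ", ncol(x$x), " variables (",
      sum(is.na(x$x)), " missing cells)\n", sep = "")
  invisible(x)
}

#' Number of records in a dataset
#' @param ds A `bbn_dataset`.
#' @return Integer record count.
#' @export
n_records <- function(ds) nrow(ds$x)

#' Convert a dataset to a data.frame of state labels
#'
#' @param ds A `bbn_dataset`.
#' @return data.frame with one character column per variable; missing cells
#'   are `NA`.
#' @export
dataset_labels <- function(ds) {
  out <- as.data.frame(lapply(schema_names(ds$schema), function(v)
    schema_states(ds$schema, v)[ds$x[, v]]), stringsAsFactors = FALSE)
  names(out) <- schema_names(ds$schema)
  out
}

as_evidence <- function(schema, evidence) {
  if (length(evidence) == 0L) return(integer(0))
  ev <- unlist(evidence)
  vars <- names(ev)
  if (is.null(vars) || any(!nzchar(vars)))
    stop("evidence must be a named variable -> state mapping")
  if (anyDuplicated(vars))
    stop("evidence names a variable more than once")
  unknown <- setdiff(vars, schema_names(schema))
  if (length(unknown))
    stop("evidence names unknown variables: ", paste(unknown, collapse = ", "))
  idx <- vapply(vars, function(v) {
    a <- ev[[v]]
    if (is.character(a) || is.factor(a)) state_index(schema, v, as.character(a))
    else as.integer(a)
  }, integer(1))
  cards <- schema_cards(schema)
  if (any(idx < 1L | idx > cards[vars]))
    stop("evidence state out of range")
  idx
}

#' Serialize a network to JSON
#'
#' Writes `{variables, edges, tables}` with CPT rows listed per parent
#' configuration (`given` = parent state labels, `p` = child distribution).
#' Round-trips losslessly through [read_bn_json()].
#'
#' @param net A valid `bbn_net`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bn_json <- function(net, path) {
  assert_valid_net(net)
  cards <- schema_cards(net$schema)
  doc <- list(
    variables = lapply(unname(net$schema), function(v)
      list(name = v$name, states = v$states, role = v$role)),
    edges = apply(net$edges, 1, function(e) as.list(unname(e)),
                  simplify = FALSE),
    tables = lapply(net$tables, function(tab) {
      grid <- config_grid(cards[tab$parents])
      rows <- lapply(seq_len(nrow(tab$prob)), function(i) {
        given <- if (length(tab$parents))
          mapply(function(v, s) schema_states(net$schema, v)[s],
                 tab$parents, grid[i, ]) else character(0)
        list(given = as.list(unname(given)), p = unname(tab$prob[i, ]))
      })
      list(parents = as.list(tab$parents), rows = rows)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a network from its JSON serialization
#'
#' @param path File written by [write_bn_json()].
#' @return A valid `bbn_net`.
#' @export
read_bn_json <- function(path) {
  doc <- jsonlite::read_json(path)
  schema <- bn_schema(lapply(doc$variables, function(v)
    variable_spec(v$name, unlist(v$states), v$role)))
  cards <- schema_cards(schema)
  tables <- lapply(names(doc$tables), function(child) {
    td <- doc$tables[[child]]
    parents <- as.character(unlist(td$parents))
    nr <- prod(c(1, cards[parents]))
    prob <- matrix(NA_real_, nr, cards[[child]])
    grid <- config_grid(cards[parents])
    key <- config_index(grid, cards[parents])
    for (row in td$rows) {
      given <- as.character(unlist(row$given))
      gi <- if (length(parents))
        mapply(function(v, s) state_index(schema, v, s), parents, given)
      else integer(0)
      prob[config_index(matrix(gi, nrow = 1), cards[parents]), ] <-
        as.numeric(unlist(row$p))
    }
    cpt_table(child, parents, prob)
  })
  names(tables) <- names(doc$tables)
  edges <- if (length(doc$edges))
    do.call(rbind, lapply(doc$edges, function(e) unlist(e)))
  else matrix(character(0), 0, 2)
  bayes_net(schema, edges, tables[schema_names(schema)])
}
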