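# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no binary fixtures.

# Generic k-feature schema with a binary class variable C.
toy_schema <- function(k, cards = rep(3, k)) {
  specs <- lapply(seq_len(k), function(i)
    variable_spec(sprintf("f%02d", i), paste0("s", seq_len(cards[i]))))
  specs <- c(specs, list(variable_spec("C", c("no", "yes"), role = "target")))
  bn_schema(specs)
}

# Two-node chain A -> B with P(A=1)=pa, P(B=1|A=0)=pb0, P(B=1|A=1)=pb1.
chain_net <- function(pa = 0.5, pb0 = 0.1, pb1 = 0.8) {
  sch <- bn_schema(list(variable_spec("A", c("0", "1")),
                        variable_spec("B", c("0", "1"))))
  bayes_net(sch, tables = list(
    A = cpt_table("A", character(0), matrix(c(1 - pa, pa), 1)),
    B = cpt_table("B", "A", rbind(c(1 - pb0, pb0), c(1 - pb1, pb1)))))
}

# Confounded triangle Z -> E, Z -> T, E -> T with a strong common cause:
# evidence E=e2 is mostly a proxy for Z=z2, so plain conditioning inflates
# the target response relative to standardization over the baseline P(Z).
confounded_net <- function() {
  sch <- bn_schema(list(variable_spec("Z", c("z1", "z2")),
                        variable_spec("E", c("e1", "e2")),
                        variable_spec("T", c("no", "yes"), role = "target")))
  bayes_net(sch, tables = list(
    Z = cpt_table("Z", character(0), matrix(c(0.7, 0.3), 1)),
    E = cpt_table("E", "Z", rbind(c(0.9, 0.1), c(0.2, 0.8))),
    # rows over (E, Z), first parent fastest: (e1,z1) (e2,z1) (e1,z2) (e2,z2)
    T = cpt_table("T", c("E", "Z"), rbind(c(0.95, 0.05), c(0.90, 0.10),
                                          c(0.55, 0.45), c(0.50, 0.50)))))
}

# Random DAG with random positive CPTs; deterministic in `seed`.
random_net <- function(seed, max_nodes = 8, max_card = 3, edge_prob = 0.4) {
  set.seed(seed)
  k <- sample(3:max_nodes, 1)
  cards <- sample(2:max_card, k, replace = TRUE)
  nm <- sprintf("v%02d", seq_len(k))
  specs <- lapply(seq_len(k), function(i)
    variable_spec(nm[i], paste0("s", seq_len(cards[i]))))
  sch <- bn_schema(specs)
  tables <- list()
  edges <- NULL
  for (i in seq_len(k)) {
    pool <- seq_len(i - 1)
    pa <- pool[stats::runif(length(pool)) < edge_prob]
    if (length(pa) > 3) pa <- sample(pa, 3)
    nr <- prod(c(1, cards[pa]))
    m <- matrix(stats::rgamma(nr * cards[i], 1) + 0.05, nr)
    tables[[nm[i]]] <- cpt_table(nm[i], nm[pa], m / rowSums(m))
    if (length(pa)) edges <- rbind(edges, cbind(nm[pa], nm[i]))
  }
  if (is.null(edges)) edges <- matrix(character(0), 0, 2)
  bayes_net(sch, edges, tables)
}

# Random evidence on `nev` non-target variables of a net.
random_evidence <- function(net, target, nev, seed) {
  set.seed(seed)
  ev <- list()
  if (nev > 0) {
    vars <- sample(setdiff(schema_names(net$schema), target), nev)
    for (v in vars) ev[[v]] <- sample(schema_states(net$schema, v), 1)
  }
  ev
}

# Undirected edge key set (for skeleton comparison).
undirected_key <- function(edges) {
  if (nrow(edges) == 0) return(character(0))
  e <- t(apply(edges, 1, sort))
  sort(paste(e[, 1], e[, 2]))
}

feature_tree <- function(net, target) {
  net$edges[net$edges[, 1] != target, , drop = FALSE]
}

# Independent oracle for fixed-mode standardization: flatten the full
# joint and average the target conditional over the baseline P(Z).
standardize_oracle <- function(net, target, evidence) {
  vars <- schema_names(net$schema)
  J <- strokebbn:::joint_table(net)
  grid <- expand.grid(lapply(vars, function(v) schema_states(net$schema, v)),
                      stringsAsFactors = FALSE)
  names(grid) <- vars
  pj <- as.numeric(J)
  ev <- lapply(evidence, as.character)
  zv <- setdiff(vars, c(target, names(ev)))
  keep <- rep(TRUE, nrow(grid))
  for (v in names(ev)) keep <- keep & grid[[v]] == ev[[v]]
  states <- schema_states(net$schema, target)
  if (!length(zv)) {
    out <- vapply(states, function(t) sum(pj[keep & grid[[target]] == t]),
                  numeric(1))
    return(out / sum(out))
  }
  zkey <- do.call(paste, c(grid[zv], sep = "\r"))
  pz <- tapply(pj, zkey, sum)
  pe_z <- tapply(pj * keep, zkey, sum)
  num <- tapply(pj * keep, paste(zkey, grid[[target]], sep = "\f"), sum)
  acc <- stats::setNames(numeric(length(states)), states)
  tot <- 0
  for (z in names(pz)) {
    if (pe_z[[z]] <= 0) next
    cond <- vapply(states, function(t) num[[paste(z, t, sep = "\f")]],
                   numeric(1)) / pe_z[[z]]
    acc <- acc + pz[[z]] * cond
    tot <- tot + pz[[z]]
  }
  acc / tot
}
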