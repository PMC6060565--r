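# Internal discrete-factor algebra used by exact inference.
#
# A factor is a list(vars, card, val): `vars` is a character vector,
# `card` the matching cardinalities, and `val` a numeric vector over all
# joint states with the FIRST variable varying fastest (expand.grid order).

new_factor <- function(vars, card, val) {
  stopifnot(length(vars) == length(card),
            length(val) == prod(c(1, card)))
  list(vars = vars, card = as.integer(card), val = as.numeric(val))
}

# Index map from the cells of a factor over (vars, card) into a sub-factor
# over a subset of those variables.
factor_map_index <- function(vars, card, sub_vars, sub_card) {
  n <- prod(c(1, card))
  if (length(sub_vars) == 0L) return(rep(1L, n))
  idx <- rep(1, n)
  stride_sub <- cumprod(c(1, sub_card))[seq_along(sub_card)]
  stride_res <- cumprod(c(1, card))[seq_along(card)]
  cells <- seq_len(n) - 1L
  for (j in seq_along(sub_vars)) {
    pos <- match(sub_vars[j], vars)
    state <- (cells %/% stride_res[pos]) %% card[pos]
    idx <- idx + state * stride_sub[j]
  }
  as.integer(idx)
}

factor_product <- function(a, b) {
  vars <- union(a$vars, b$vars)
  card <- integer(length(vars))
  card[match(a$vars, vars)] <- a$card
  card[match(b$vars, vars)] <- b$card
  ia <- factor_map_index(vars, card, a$vars, a$card)
  ib <- factor_map_index(vars, card, b$vars, b$card)
  new_factor(vars, card, a$val[ia] * b$val[ib])
}

factor_marginalize <- function(f, var) {
  keep <- setdiff(f$vars, var)
  if (length(keep) == 0L)
    return(new_factor(character(0), integer(0), sum(f$val)))
  kcard <- f$card[match(keep, f$vars)]
  idx <- factor_map_index(f$vars, f$card, keep, kcard)
  val <- numeric(prod(kcard))
  agg <- rowsum(f$val, idx)
  val[as.integer(rownames(agg))] <- agg[, 1]
  new_factor(keep, kcard, val)
}

# Fix `var` to 1-based state `state` (drops the variable).
factor_reduce <- function(f, var, state) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  keep_cells <- ((seq_along(f$val) - 1L) %/%
                   cumprod(c(1L, f$card))[pos]) %% f$card[pos] == state - 1L
  new_factor(f$vars[-pos], f$card[-pos], f$val[keep_cells])
}

# CPT of `child` as a factor over (parents..., child); the CPT matrix is
# (parent configs x child states) with the first parent fastest, so its
# column-major vector already matches factor cell order.
cpt_factor <- function(net, child) {
  tab <- net$tables[[child]]
  cards <- schema_cards(net$schema)
  vars <- c(tab$parents, child)
  new_factor(vars, cards[vars], as.numeric(tab$prob))
}

# Full joint distribution as a named-dim array in schema order.
joint_table <- function(net, max_cells = 1e7) {
  cards <- schema_cards(net$schema)
  if (prod(cards) > max_cells)
    stop("joint state space has ", format(prod(cards), big.mark = ","),
         " configurations; refusing (limit ", format(max_cells), ")")
  f <- new_factor(character(0), integer(0), 1)
  for (v in schema_names(net$schema))
    f <- factor_product(f, cpt_factor(net, v))
  ord <- match(schema_names(net$schema), f$vars)
  arr <- array(f$val, dim = f$card,
               dimnames = lapply(f$vars, function(v) schema_states(net$schema, v)))
  aperm(arr, ord)
}
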