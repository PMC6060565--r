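#' Declare a categorical survey variable
#'
#' A variable specification names an ordered set of discrete states and a
#' role in the analysis. State order is the canonical integer coding used
#' everywhere downstream (including the ordinal codes behind Pearson
#' correlations in the association table), so ordered variables should list
#' their states in their natural order.
#'
#' @param name Variable name (non-empty string, unique within a schema).
#' @param states Character vector of at least two unique state labels, in
#'   canonical order.
#' @param role One of `"covariate"`, `"target"`, `"profile"`. `"target"`
#'   marks the outcome variable; `"profile"` marks variables used as
#'   evidence dimensions in profile enumeration; everything else is a
#'   plain covariate.
#' @return An object of class `bbn_variable`.
#' @examples
#' variable_spec("HRSLEEP", c("short", "average", "long"), role = "profile")
#' @export
variable_spec <- function(name, states, role = c("covariate", "target", "profile")) {
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("variable name must be a non-empty string")
  states <- as.character(states)
  if (length(states) < 2L)
    stop("variable '", name, "' needs at least 2 states")
  if (anyDuplicated(states))
    stop("variable '", name, "' has duplicated state labels")
  structure(list(name = name, states = states, role = role),
            class = "bbn_variable")
}

#' Assemble a schema from variable specifications
#'
#' @param specs A list of [variable_spec()] objects. Load order is the
#'   canonical schema order.
#' @return A named list of `bbn_variable` objects with class `bbn_schema`.
#' @export
bn_schema <- function(specs) {
  if (inherits(specs, "bbn_variable")) specs <- list(specs)
  stopifnot(is.list(specs), length(specs) > 0L)
  ok <- vapply(specs, inherits, logical(1), "bbn_variable")
  if (!all(ok)) stop("all schema entries must be variable_spec() objects")
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicated variable names in schema: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(specs) <- nms
  structure(specs, class = "bbn_schema")
}

#' Schema accessors
#'
#' `schema_names()` returns the variable names in canonical order;
#' `schema_cards()` the per-variable state counts; `schema_states()` one
#' variable's ordered state labels; `schema_target()` the names of
#' variables with the `target` role.
#'
#' @param schema A [bn_schema()].
#' @param var Variable name.
#' @return Character vector, named integer vector, character vector, and
#'   character vector respectively.
#' @export
schema_names <- function(schema) names(schema)

#' @rdname schema_names
#' @export
schema_cards <- function(schema) {
  vapply(schema, function(v) length(v$states), integer(1))
}

#' @rdname schema_names
#' @export
schema_states <- function(schema, var) {
  if (!var %in% names(schema)) stop("unknown variable '", var, "'")
  schema[[var]]$states
}

#' @rdname schema_names
#' @export
schema_target <- function(schema) {
  roles <- vapply(schema, `[[`, character(1), "role")
  names(schema)[roles == "target"]
}

state_index <- function(schema, var, labels) {
  states <- schema_states(schema, var)
  idx <- match(labels, states)
  bad <- !is.na(labels) & is.na(idx)
  if (any(bad))
    stop("unknown state '", labels[bad][1], "' for variable '", var, "'")
  idx
}

#' @export
print.bbn_schema <- function(x, ...) {
  cat("<bbn_schema> ", length(x), " variables\n", sep = "")
  for (v in x)
    cat(sprintf("  %-14s [%s] %s\n", v$name, v$role,
                paste(v$states, collapse = ", ")))
  invisible(x)
}
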