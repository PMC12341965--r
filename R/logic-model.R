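#' Standalone logic equation
#'
#' One node's update rule in the standardized link-operator family: the
#' activators are OR-joined into `Act`, the inhibitors OR-joined into `Inh`,
#' and the two groups are connected by the link operator:
#' `Act AND-NOT Inh = Act & !Inh` (default, less permissive) or
#' `Act OR-NOT Inh = Act | !Inh` (more permissive). Equations with only one
#' regulator class carry no link operator (`NONE`).
#'
#' @param target node name.
#' @param activators,inhibitors character vectors of regulator names; at
#'   least one of the two must be non-empty.
#' @param link_operator `"AND-NOT"`, `"OR-NOT"`, or `"NONE"`. Must be `NONE`
#'   exactly when one regulator class is empty.
#' @return object of class `logic_equation`.
#' @export
logic_equation <- function(target, activators = character(),
                           inhibitors = character(),
                           link_operator = if (length(activators) > 0 &&
                                               length(inhibitors) > 0)
                             "AND-NOT" else "NONE") {
  activators <- as.character(activators)
  inhibitors <- as.character(inhibitors)
  if (length(activators) == 0 && length(inhibitors) == 0) {
    stop("equation for ", target, " has no regulators")
  }
  both <- length(activators) > 0 && length(inhibitors) > 0
  if (both && link_operator == "NONE") {
    stop("equation for ", target,
         " has both regulator classes and needs a link operator")
  }
  if (!both && link_operator != "NONE") {
    stop("equation for ", target,
         " has a single regulator class; link operator must be NONE")
  }
  structure(list(target = target, activators = activators,
                 inhibitors = inhibitors, link_operator = link_operator),
            class = "logic_equation")
}

#' @export
print.logic_equation <- function(x, ...) {
  cat(format_equation(x), "\n")
  invisible(x)
}

#' Evaluate a logic equation under a full state assignment
#'
#' Computes the target's next-step value: `Act & !Inh` for AND-NOT,
#' `Act | !Inh` for OR-NOT, and plain `Act` or `!Inh` when only one
#' regulator class is present.
#'
#' @param eq a [logic_equation()].
#' @param state named 0/1 vector assigning every regulator.
#' @return 0 or 1.
#' @export
evaluate_equation <- function(eq, state) {
  regs <- c(eq$activators, eq$inhibitors)
  missing <- setdiff(regs, names(state))
  if (length(missing) > 0) {
    stop("state does not assign regulator(s): ", paste(missing, collapse = ", "))
  }
  act <- length(eq$activators) > 0 && any(state[eq$activators] == 1)
  inh <- length(eq$inhibitors) > 0 && any(state[eq$inhibitors] == 1)
  val <- if (length(eq$inhibitors) == 0) act
  else if (length(eq$activators) == 0) !inh
  else if (eq$link_operator == "AND-NOT") act && !inh
  else act || !inh
  as.integer(val)
}

# internal constructor: index-based representation for speed.
# act/inh: lists of integer vectors (indices into nodes); op: 0/1/2 codes;
# last_op: operator memory used when topology mutation refills a class;
# fixed: -1 free, 0/1 clamped by a perturbation.
.new_boolean_model <- function(nodes, act, inh, op, last_op = NULL,
                               fixed = NULL, fitness = NA_real_,
                               provenance = list()) {
  structure(list(nodes = nodes, act = act, inh = inh, op = as.integer(op),
                 last_op = as.integer(last_op %||% pmax(op, .OP_AND_NOT)),
                 fixed = as.integer(fixed %||% rep(-1L, length(nodes))),
                 fitness = fitness, provenance = provenance),
            class = "boolean_model")
}

#' Assemble the default logic model from a prior-knowledge network
#'
#' Every node gets one standardized equation: positive regulators are
#' OR-joined as activators, negative regulators OR-joined as inhibitors, and
#' nodes with both classes get the default AND-NOT link operator (activation
#' required and absence of inhibition required).
#'
#' @param network a [pkn()].
#' @return object of class `boolean_model` with one equation per node, in
#'   network node order.
#' @export
assemble_default_model <- function(network) {
  stopifnot(inherits(network, "pkn"))
  regs <- .regulators(network)
  idx <- function(x) match(x, network$nodes)
  act <- lapply(regs, function(r) as.integer(idx(r$activators)))
  inh <- lapply(regs, function(r) as.integer(idx(r$inhibitors)))
  if (any(vapply(act, anyNA, logical(1))) || any(vapply(inh, anyNA, logical(1)))) {
    stop("regulator refers to a node outside the network")
  }
  nreg <- lengths(act) + lengths(inh)
  if (any(nreg == 0)) {
    stop("network is not self-contained: node(s) without regulator: ",
         paste(network$nodes[nreg == 0], collapse = ", "))
  }
  op <- ifelse(lengths(act) > 0 & lengths(inh) > 0, .OP_AND_NOT, .OP_NONE)
  .new_boolean_model(network$nodes, unname(act), unname(inh), op,
                     provenance = list(origin = "default-assembly",
                                       link_mutations = 0L,
                                       topology_mutations = 0L))
}

#' Extract one node's equation from a model
#'
#' @param model a `boolean_model`.
#' @param node node name.
#' @return a [logic_equation()] (or a constant pseudo-equation description if
#'   the node is clamped by a perturbation).
#' @export
model_equation <- function(model, node) {
  v <- match(node, model$nodes)
  if (is.na(v)) stop("node not in model: ", node)
  if (model$fixed[v] >= 0L) {
    return(structure(list(target = node, constant = model$fixed[v]),
                     class = c("constant_equation", "logic_equation")))
  }
  logic_equation(node,
                 activators = model$nodes[model$act[[v]]],
                 inhibitors = model$nodes[model$inh[[v]]],
                 link_operator = .op_label(model$op[v]))
}

#' Number of link-operator-bearing equations in a model
#' @param model a `boolean_model`.
#' @return integer count (the GA parameterization space has size `2^n`).
#' @export
n_link_operators <- function(model) sum(model$op != .OP_NONE & model$fixed < 0L)

#' @export
print.boolean_model <- function(x, ...) {
  cat("Boolean model:", length(x$nodes), "nodes,", n_link_operators(x),
      "link-operator equations")
  if (!is.na(x$fitness)) cat(", fitness", format(x$fitness, digits = 4))
  if (any(x$fixed >= 0L)) cat(",", sum(x$fixed >= 0L), "clamped node(s)")
  cat("\n")
  invisible(x)
}

# textual form, shared by print and the .bnm on-disk dialect
format_equation <- function(eq) {
  if (inherits(eq, "constant_equation")) {
    return(paste0(eq$target, " *= ", eq$constant))
  }
  grp <- function(x) paste0("(", paste0("(", x, ")", collapse = " or "), ")")
  rhs <- if (length(eq$inhibitors) == 0) grp(eq$activators)
  else if (length(eq$activators) == 0) paste0("not ", grp(eq$inhibitors))
  else paste0(grp(eq$activators),
              if (eq$link_operator == "AND-NOT") " and not " else " or not ",
              grp(eq$inhibitors))
  paste0(eq$target, " *= ", rhs)
}

#' All equations of a model as text lines
#' @param model a `boolean_model`.
#' @return character vector, one equation per node in model order.
#' @export
model_equations_text <- function(model) {
  vapply(model$nodes, function(v) format_equation(model_equation(model, v)),
         character(1))
}

# full synchronous update image for a 0/1 state matrix (rows = states,
# columns in model node order)
.model_update <- function(model, states) {
  .fp_update_cpp(model$act, model$inh, model$op, model$fixed,
                 matrix(as.integer(states), nrow = nrow(states)))
}
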