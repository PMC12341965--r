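#' Enumerate the fixed points (stable states) of a Boolean model
#'
#' Solves `x = f(x)` exactly by depth-first search with unit propagation over
#' the link-operator update rules, independent of any update scheme. A model
#' may legitimately have no fixed point (only complex attractors); `n = 0`
#' is then returned and downstream fitness treats it as zero.
#'
#' @param model a `boolean_model`.
#' @param max_fixed_points enumeration cap; exceeding it raises an error
#'   rather than silently truncating.
#' @param node_guard refuse models larger than this many nodes.
#' @return object of class `attractor_set`: list with `fixed_points` (0/1
#'   matrix, one row per stable state, columns named by node, rows sorted
#'   lexicographically in node order) and `n`.
#' @export
fixed_points <- function(model, max_fixed_points = 64L, node_guard = 4096L) {
  stopifnot(inherits(model, "boolean_model"))
  nn <- length(model$nodes)
  if (nn > node_guard) {
    stop("model has ", nn, " nodes, exceeding the capacity guard (",
         node_guard, ")")
  }
  res <- .fp_enumerate_cpp(model$act, model$inh, model$op, model$fixed,
                           as.integer(max_fixed_points))
  if (isTRUE(res$overflow)) {
    stop("more than ", max_fixed_points,
         " fixed points; raise max_fixed_points to enumerate them all")
  }
  fp <- res$fixed_points
  colnames(fp) <- model$nodes
  if (nrow(fp) > 1) {
    fp <- fp[do.call(order, as.data.frame(fp)), , drop = FALSE]
  }
  structure(list(fixed_points = fp, n = nrow(fp)), class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  cat("Attractor set:", x$n, "fixed point(s)\n")
  if (x$n > 0 && x$n <= 8) print(x$fixed_points)
  invisible(x)
}

#' Write fixed points as a TSV table
#' @param attractors an [fixed_points()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_attractors <- function(attractors, path) {
  utils::write.table(attractors$fixed_points, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
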