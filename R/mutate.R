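#' Flip link operators at random (parameterization mutation)
#'
#' Draws `k` equations uniformly with replacement from the subset bearing a
#' link operator and flips each draw AND-NOT <-> OR-NOT. Drawing with
#' replacement means two draws may hit the same equation and cancel;
#' equations without a link operator never change. The input model is left
#' untouched (value semantics), so GA parents survive mutation of their
#' offspring. Uses the current R random-number stream.
#'
#' @param model a `boolean_model`.
#' @param k number of mutation draws (`k >= 0`).
#' @return a new `boolean_model`.
#' @export
mutate_link_operators <- function(model, k) {
  stopifnot(k >= 0)
  if (k == 0) return(model)
  eligible <- which(model$op != .OP_NONE & model$fixed < 0L)
  if (length(eligible) == 0) {
    warning("model has no link-operator equations; mutation is a no-op")
    return(model)
  }
  draws <- eligible[sample.int(length(eligible), k, replace = TRUE)]
  nflip <- tabulate(draws, nbins = length(model$nodes))
  flip <- nflip %% 2L == 1L
  model$op[flip] <- 3L - model$op[flip]
  model$last_op[flip] <- model$op[flip]
  model$fitness <- NA_real_
  model$provenance$link_mutations <-
    (model$provenance$link_mutations %||% 0L) + as.integer(k)
  model
}

#' Topology mutation: blacklist/whitelist regulators
#'
#' Applies `k` edge mutations, each drawn uniformly over the interactions of
#' the originating network: an edge currently present in the model is
#' removed (blacklisted), an edge currently absent is restored
#' (whitelisted). Restoration can only bring back edges of the original
#' network. A removal that would leave its target without any regulator is
#' rejected and redrawn, preserving self-containedness. When a mutation
#' empties one regulator class the link operator becomes NONE; when both
#' classes are non-empty again the equation's last-used operator is
#' restored (AND-NOT for equations never mutated). Regulator lists keep the
#' network's original ordering, so removing and restoring the same edge is
#' an exact inverse.
#'
#' @param model a `boolean_model` derived from `network`.
#' @param network the originating [pkn()].
#' @param k number of mutations.
#' @return a new `boolean_model`.
#' @export
mutate_topology <- function(model, network, k) {
  stopifnot(k >= 0)
  if (k == 0) return(model)
  ints <- network$interactions
  src <- match(ints$source, model$nodes)
  tgt <- match(ints$target, model$nodes)
  if (anyNA(src) || anyNA(tgt)) stop("model was not derived from this network")
  ne <- nrow(ints)
  # original per-target regulator order, for canonical re-insertion
  ref <- .regulators(network)
  ref_act <- lapply(ref, function(r) match(r$activators, model$nodes))
  ref_inh <- lapply(ref, function(r) match(r$inhibitors, model$nodes))

  applied <- 0L
  tries <- 0L
  max_tries <- max(200L, 50L * k)
  while (applied < k && tries < max_tries) {
    tries <- tries + 1L
    e <- sample.int(ne, 1L)
    v <- tgt[e]
    s <- src[e]
    lst <- if (ints$sign[e] == 1L) "act" else "inh"
    regs <- model[[lst]][[v]]
    if (s %in% regs) {
      # removal: reject if the target would lose its last regulator
      if (length(model$act[[v]]) + length(model$inh[[v]]) <= 1L) next
      model[[lst]][[v]] <- regs[regs != s]
    } else {
      # restore, keeping the network's original regulator order
      refv <- if (lst == "act") ref_act[[v]] else ref_inh[[v]]
      keep <- union(regs, s)
      model[[lst]][[v]] <- refv[refv %in% keep]
    }
    model$op[v] <- if (length(model$act[[v]]) > 0 &&
                       length(model$inh[[v]]) > 0) model$last_op[v] else .OP_NONE
    applied <- applied + 1L
  }
  if (applied < k) {
    warning("only ", applied, " of ", k,
            " topology mutations could be applied (no legal moves left)")
  }
  model$fitness <- NA_real_
  model$provenance$topology_mutations <-
    (model$provenance$topology_mutations %||% 0L) + applied
  model
}
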