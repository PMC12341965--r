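#' Prior-knowledge network constructor
#'
#' A prior-knowledge network (PKN) is a signed, directed graph of causal
#' molecular interactions: the raw material from which logic models are
#' assembled. Node order is the order of first appearance and is preserved
#' through every downstream operation, so results are reproducible
#' byte-for-byte.
#'
#' @param interactions data frame with columns `source`, `target` (character)
#'   and `sign` (+1 activation, -1 inhibition).
#' @param nodes optional character vector fixing node order; defaults to
#'   first-appearance order over `source`/`target`.
#' @param validate check self-containedness (every node has at least one
#'   regulator) and reject duplicate (source, target, sign) triples.
#' @param auto_self_regulate if `TRUE`, a node without any regulator gets a
#'   positive self-loop (logged via `message()`) instead of raising an error.
#'   Intended for user-supplied networks that are not self-contained.
#' @return object of class `pkn` with elements `nodes` and `interactions`.
#' @export
pkn <- function(interactions, nodes = NULL, validate = TRUE,
                auto_self_regulate = FALSE) {
  stopifnot(is.data.frame(interactions),
            all(c("source", "target", "sign") %in% names(interactions)))
  interactions$source <- as.character(interactions$source)
  interactions$target <- as.character(interactions$target)
  interactions$sign <- as.integer(interactions$sign)
  if (any(!nzchar(interactions$source)) || any(!nzchar(interactions$target))) {
    stop("interaction with empty source or target node")
  }
  if (!all(interactions$sign %in% c(1L, -1L))) {
    stop("interaction sign must be +1 (activation) or -1 (inhibition)")
  }
  if (is.null(nodes)) {
    nodes <- unique(as.vector(t(as.matrix(interactions[, c("source", "target")]))))
  }
  if (validate) {
    key <- paste(interactions$source, interactions$target, interactions$sign)
    if (anyDuplicated(key)) {
      dup <- unique(key[duplicated(key)])
      message("dropping ", length(dup), " duplicate interaction(s)")
      interactions <- interactions[!duplicated(key), , drop = FALSE]
    }
    orphan <- setdiff(nodes, interactions$target)
    if (length(orphan) > 0) {
      if (auto_self_regulate) {
        message("adding positive self-loop to unregulated node(s): ",
                paste(orphan, collapse = ", "))
        interactions <- rbind(interactions,
                              data.frame(source = orphan, target = orphan,
                                         sign = 1L, stringsAsFactors = FALSE))
      } else {
        stop("network is not self-contained: node(s) without regulator: ",
             paste(orphan, collapse = ", "))
      }
    }
  }
  rownames(interactions) <- NULL
  structure(list(nodes = nodes, interactions = interactions), class = "pkn")
}

#' @export
print.pkn <- function(x, ...) {
  cat("Prior-knowledge network:", length(x$nodes), "nodes,",
      nrow(x$interactions), "signed interactions\n")
  cat("  activations:", sum(x$interactions$sign == 1L),
      " inhibitions:", sum(x$interactions$sign == -1L), "\n")
  invisible(x)
}

# ordered regulator lists per target, in interaction-file order, deduplicated
.regulators <- function(network) {
  ints <- network$interactions
  out <- lapply(network$nodes, function(v) {
    rows <- ints[ints$target == v, , drop = FALSE]
    list(activators = unique(rows$source[rows$sign == 1L]),
         inhibitors = unique(rows$source[rows$sign == -1L]))
  })
  names(out) <- network$nodes
  out
}
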