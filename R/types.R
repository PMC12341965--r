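#' Calibration profile (partial steady-state observation)
#'
#' Observed activities of signaling entities in unperturbed cells: each node
#' is active (1), inactive (0) or unspecified (`NA`). Model fitness is the
#' fraction of specified entries matched by a model's stable states.
#'
#' @param x named vector with values in `{0, 1, NA}`; names are node
#'   identifiers. Nodes absent from `x` are implicitly unspecified.
#' @param network optional [pkn()]; if given, every named node must belong
#'   to it.
#' @param require_specified if `TRUE` (default), at least one entry must be
#'   specified (`m >= 1`), as required for a training profile.
#' @return named integer vector of class `calibration_profile`.
#' @export
calibration_profile <- function(x, network = NULL, require_specified = TRUE) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("calibration profile entries must be named by node")
  }
  vals <- suppressWarnings(as.integer(x))
  bad <- !is.na(x) & (is.na(vals) | !(vals %in% c(0L, 1L)))
  if (any(bad)) {
    stop("calibration value outside {0, 1, -} for node(s): ",
         paste(names(x)[bad], collapse = ", "))
  }
  if (!is.null(network)) {
    unknown <- setdiff(names(x), network$nodes)
    if (length(unknown) > 0) {
      stop("calibration profile names node(s) not in the network: ",
           paste(unknown, collapse = ", "))
    }
  }
  if (require_specified && sum(!is.na(vals)) < 1) {
    stop("calibration profile must specify at least one node (m >= 1 required)")
  }
  structure(setNames(vals, names(x)), class = "calibration_profile")
}

#' Number of specified (0/1) entries in a calibration profile
#' @param profile a [calibration_profile()].
#' @return integer `m`.
#' @export
m_specified <- function(profile) sum(!is.na(profile))

#' @export
print.calibration_profile <- function(x, ...) {
  cat("Calibration profile:", m_specified(x), "specified of", length(x),
      "listed nodes\n")
  invisible(x)
}

#' Output-node specification for the global "growth" readout
#'
#' Designated phenotypic output nodes with signed weights: pro-survival
#' nodes carry positive weight, anti-survival nodes negative weight. The raw
#' weighted sum of output-node states is scaled affinely to `[0, 1]` using
#' the theoretical minimum (sum of negative weights) and maximum (sum of
#' positive weights).
#'
#' @param weights named numeric vector of non-zero weights; at least one
#'   positive and one negative weight are required, otherwise the scaling
#'   degenerates.
#' @return object of class `output_spec` with `weights`, `theoretical_min`,
#'   `theoretical_max`.
#' @export
output_spec <- function(weights) {
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("output weights must be named by node")
  }
  weights <- setNames(as.numeric(weights), names(weights))
  if (any(weights == 0) || anyNA(weights)) stop("output weights must be non-zero")
  if (!any(weights > 0) || !any(weights < 0)) {
    stop("output spec needs at least one positive and one negative weight")
  }
  structure(list(weights = weights,
                 theoretical_min = sum(weights[weights < 0]),
                 theoretical_max = sum(weights[weights > 0])),
            class = "output_spec")
}

#' @export
print.output_spec <- function(x, ...) {
  cat("Output spec:", length(x$weights), "nodes, raw range [",
      x$theoretical_min, ",", x$theoretical_max, "]\n")
  invisible(x)
}

#' Drug panel
#'
#' Maps each drug to its target node(s) and its effect: an inhibiting drug
#' clamps its targets to 0 during simulation, an activating drug clamps
#' them to 1.
#'
#' @param entries named list: drug name to `list(effect, targets)` with
#'   `effect` in `{"inhibits", "activates"}` and `targets` a non-empty
#'   character vector.
#' @return object of class `drug_panel`.
#' @export
drug_panel <- function(entries) {
  if (is.null(names(entries)) || anyDuplicated(names(entries))) {
    stop("drug names must be present and unique")
  }
  if (any(grepl("-", names(entries), fixed = TRUE))) {
    stop("drug names must not contain '-' (reserved as the pair separator)")
  }
  for (d in names(entries)) {
    e <- entries[[d]]
    if (!e$effect %in% c("inhibits", "activates")) {
      stop("drug ", d, ": effect must be 'inhibits' or 'activates'")
    }
    if (length(e$targets) == 0) stop("drug ", d, " has no target nodes")
  }
  structure(list(entries = entries), class = "drug_panel")
}

#' @export
print.drug_panel <- function(x, ...) {
  cat("Drug panel:", length(x$entries), "drugs\n")
  invisible(x)
}

#' Canonical drug-pair key
#'
#' Pairs are unordered; the key joins the two sorted drug names with "-" so
#' that scores, gold-standard labels and reports agree on naming.
#'
#' @param a,b drug names (vectorized).
#' @return character vector of keys.
#' @export
pair_key <- function(a, b) {
  mapply(function(x, y) paste(sort(c(x, y)), collapse = "-"), a, b,
         USE.NAMES = FALSE)
}
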