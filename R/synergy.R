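#' Apply a drug perturbation to a model
#'
#' Each targeted node's equation is replaced by a constant: 0 for an
#' inhibiting drug, 1 for an activating drug. All other equations are left
#' untouched and the input model is not modified. For a drug pair both
#' drugs' target sets are clamped; the order of the two drugs is irrelevant.
#'
#' @param model a `boolean_model`.
#' @param perturbation character vector of 1 or 2 drug names.
#' @param panel a [drug_panel()].
#' @return a new `boolean_model` with clamped target nodes.
#' @export
apply_perturbation <- function(model, perturbation, panel) {
  stopifnot(length(perturbation) %in% 1:2)
  for (drug in perturbation) {
    entry <- panel$entries[[drug]]
    if (is.null(entry)) stop("drug not in panel: ", drug)
    value <- if (entry$effect == "inhibits") 0L else 1L
    idx <- match(entry$targets, model$nodes)
    if (anyNA(idx)) {
      stop("drug ", drug, " targets node(s) absent from the model: ",
           paste(entry$targets[is.na(idx)], collapse = ", "))
    }
    model$fixed[idx] <- value
  }
  model$fitness <- NA_real_
  model
}

#' Scaled global output ("growth") of a single model
#'
#' For each fixed point the raw output is the weighted sum of output-node
#' states; it is scaled affinely to `[0, 1]` by the theoretical minimum
#' (sum of negative weights) and maximum (sum of positive weights), and the
#' scaled values are averaged over all fixed points. A model without a
#' fixed point has undefined growth (`NA`): growth is a property of stable
#' behavior. Because the scaling is affine, scaling then averaging equals
#' averaging then scaling.
#'
#' @param model a `boolean_model` (typically perturbed).
#' @param outputs an [output_spec()].
#' @param attractors optional precomputed [fixed_points()] result.
#' @return growth in `[0, 1]`, or `NA` when no fixed point exists.
#' @export
model_growth <- function(model, outputs, attractors = NULL) {
  att <- attractors %||% fixed_points(model)
  if (att$n == 0) return(NA_real_)
  nodes <- names(outputs$weights)
  missing <- setdiff(nodes, colnames(att$fixed_points))
  if (length(missing) > 0) {
    stop("output node(s) absent from the model: ",
         paste(missing, collapse = ", "))
  }
  raw <- att$fixed_points[, nodes, drop = FALSE] %*% outputs$weights
  scaled <- (raw - outputs$theoretical_min) /
    (outputs$theoretical_max - outputs$theoretical_min)
  mean(scaled)
}

#' Ensemble-averaged growth under one perturbation
#'
#' Growth is the arithmetic mean of [model_growth()] over the ensemble
#' members whose perturbed version retains at least one fixed point; members
#' without a fixed point are excluded (their growth is undefined) and
#' counted, keeping the exclusion auditable.
#'
#' @param ensemble a [evolve()] result or list of models.
#' @param perturbation character vector of 0, 1 or 2 drug names (empty =
#'   unperturbed baseline).
#' @param panel a [drug_panel()].
#' @param outputs an [output_spec()].
#' @return list with `growth` (`NA` when all members are excluded),
#'   `models_used`, `models_excluded`.
#' @export
ensemble_growth <- function(ensemble, perturbation, panel, outputs) {
  models <- if (inherits(ensemble, "model_ensemble")) ensemble$models else ensemble
  stopifnot(length(models) >= 1)
  growths <- vapply(models, function(m) {
    pm <- if (length(perturbation) > 0) {
      apply_perturbation(m, perturbation, panel)
    } else m
    model_growth(pm, outputs)
  }, numeric(1))
  used <- sum(!is.na(growths))
  list(growth = if (used > 0) mean(growths, na.rm = TRUE) else NA_real_,
       models_used = used, models_excluded = length(models) - used)
}

#' Simulate an ensemble over a perturbation list
#'
#' @param ensemble a [evolve()] result or list of models.
#' @param perturbations list of character vectors (1 or 2 drugs each), e.g.
#'   from [read_perturbations()] or [all_perturbations()].
#' @param panel a [drug_panel()].
#' @param outputs an [output_spec()].
#' @return data frame with columns `perturbation` (canonical key),
#'   `n_drugs`, `growth`, `models_used`, `models_excluded`.
#' @export
simulate_ensemble <- function(ensemble, perturbations, panel, outputs) {
  rows <- lapply(perturbations, function(p) {
    r <- ensemble_growth(ensemble, p, panel, outputs)
    data.frame(perturbation = paste(sort(p), collapse = "-"),
               n_drugs = length(p), growth = r$growth,
               models_used = r$models_used,
               models_excluded = r$models_excluded,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' All single-drug and pairwise perturbations of a panel
#' @param panel a [drug_panel()].
#' @return list of character vectors: every single drug followed by every
#'   unordered pair.
#' @export
all_perturbations <- function(panel) {
  drugs <- names(panel$entries)
  singles <- as.list(drugs)
  pairs <- if (length(drugs) >= 2) {
    combn(drugs, 2, simplify = FALSE)
  } else list()
  c(singles, pairs)
}

#' Bliss-style synergy decomposition for one drug pair
#'
#' The observed combination effect `E(a,b) = growth(a,b)` is decomposed as
#' `E = A + S` with the expected effect `A(a,b) = growth(a) * growth(b)`
#' (Bliss independence) and the excess `S = E - A`. A combination with
#' `growth(a,b) < growth(a) * growth(b)` (`S < 0`) is called synergistic,
#' `S > 0` antagonistic, `S = 0` neither. Symmetric in the two drugs.
#'
#' @param growth_a,growth_b single-drug ensemble growths in `[0, 1]`.
#' @param growth_ab pair growth in `[0, 1]`.
#' @return list with `observed`, `expected`, `excess`, `call` (one of
#'   `"synergy"`, `"antagonism"`, `"none"`, or `"not-available"` when any
#'   input growth is undefined).
#' @export
score_synergy <- function(growth_a, growth_b, growth_ab) {
  if (anyNA(c(growth_a, growth_b, growth_ab))) {
    return(list(observed = NA_real_, expected = NA_real_, excess = NA_real_,
                call = "not-available"))
  }
  expected <- growth_a * growth_b
  excess <- growth_ab - expected
  call <- if (excess < 0) "synergy" else if (excess > 0) "antagonism" else "none"
  list(observed = growth_ab, expected = expected, excess = excess, call = call)
}

#' Per-pair synergy table from an ensemble response table
#'
#' @param responses a [simulate_ensemble()] data frame containing every
#'   single drug and every scored pair.
#' @return data frame with one row per pair: `pair`, `drug_a`, `drug_b`,
#'   `observed`, `expected`, `excess`, `call`.
#' @export
synergy_table <- function(responses) {
  singles <- responses[responses$n_drugs == 1, ]
  g1 <- setNames(singles$growth, singles$perturbation)
  pairs <- responses[responses$n_drugs == 2, ]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    drugs <- strsplit(pairs$perturbation[i], "-", fixed = TRUE)[[1]]
    if (!all(drugs %in% names(g1))) {
      stop("missing single-drug response for pair ", pairs$perturbation[i])
    }
    s <- score_synergy(g1[[drugs[1]]], g1[[drugs[2]]], pairs$growth[i])
    data.frame(pair = pairs$perturbation[i], drug_a = drugs[1],
               drug_b = drugs[2], observed = s$observed,
               expected = s$expected, excess = s$excess, call = s$call,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Normalize calibrated synergies against a random-proliferative baseline
#'
#' The normalized score is the exponential fold change
#' `exp(S_calibrated - S_random)` per pair, comparing the calibrated
#' ensemble's excess effect to that of an ensemble trained to a random yet
#' proliferative phenotype. Values below 1 lean synergistic relative to the
#' baseline; ranking for ROC/PR uses the normalized score ascending. Pairs
#' with an unavailable excess in either ensemble are excluded (with a
#' message) and reported with `NA`.
#'
#' @param calibrated,random [synergy_table()] data frames covering the same
#'   pairs.
#' @return the `calibrated` table with extra columns `excess_random` and
#'   `normalized`.
#' @export
normalize_synergies <- function(calibrated, random) {
  i <- match(calibrated$pair, random$pair)
  if (anyNA(i)) {
    stop("baseline table is missing pair(s): ",
         paste(calibrated$pair[is.na(i)], collapse = ", "))
  }
  out <- calibrated
  out$excess_random <- random$excess[i]
  out$normalized <- exp(out$excess - out$excess_random)
  dropped <- is.na(out$normalized)
  if (any(dropped)) {
    message("normalization unavailable for ", sum(dropped), " pair(s): ",
            paste(out$pair[dropped], collapse = ", "))
  }
  out
}

#' Sample a random proliferative calibration profile
#'
#' Emulates a cell with all anti-survival signals inactivated and at least
#' one pro-survival signal active: every negative-weight output node is set
#' to 0 and the positive-weight output nodes get independent uniform bits,
#' redrawn until at least one is 1. All other nodes are unspecified. Used
#' to train baseline ensembles for normalization. Uses the current R
#' random-number stream.
#'
#' @param outputs an [output_spec()].
#' @return a [calibration_profile()] over the output nodes.
#' @export
sample_proliferative_profile <- function(outputs) {
  w <- outputs$weights
  pos <- names(w)[w > 0]
  neg <- names(w)[w < 0]
  repeat {
    bits <- rbinom(length(pos), 1L, 0.5)
    if (any(bits == 1L)) break
  }
  calibration_profile(setNames(c(bits, rep(0L, length(neg))), c(pos, neg)))
}
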