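#' Generate a synthetic self-contained system with planted ground truth
#'
#' Emulates the pipeline's real inputs end-to-end: a random signed, directed
#' self-contained network; a planted "truth" model (one specific
#' link-operator assignment, redrawn until it has a stable state — by
#' default a *unique* one, so the planted profile identifies it); a
#' calibration profile read off a verified fixed point of the truth model
#' (optionally masked); output nodes split into positive and negative
#' weights; an inhibitor drug panel; and gold-standard synergy labels
#' computed by exhaustively simulating every drug pair on the truth model
#' (Bliss excess `S < 0` strictly; pairs with undefined growth are labeled
#' negative and flagged). Drug target assignments are redrawn until the gold
#' standard contains at least one positive and one negative label, since a
#' benchmark is undefined otherwise. Uses the current R random-number
#' stream; call `set.seed()` first for a reproducible system.
#'
#' @param n_nodes,n_edges network size (`n_edges >= n_nodes` so every node
#'   can have a regulator).
#' @param n_outputs number of output nodes (>= 2; split positive/negative).
#' @param n_drugs number of single-target inhibitor drugs.
#' @param mask_fraction fraction of profile entries set to unspecified
#'   (`ceiling(mask_fraction * n_nodes)` entries masked).
#' @param unique_fixed_point require the truth model to have exactly one
#'   stable state (default) rather than at least one.
#' @param max_tries retry budget for finding a stable truth assignment.
#' @return object of class `planted_system`: `network`, `truth_model`,
#'   `truth_profile`, `outputs`, `panel`, `gold` (data frame `pair`,
#'   `drug_a`, `drug_b`, `label`, `flagged`), `perturbations`.
#' @export
generate_planted_system <- function(n_nodes = 15L, n_edges = 25L,
                                    n_outputs = 4L, n_drugs = 6L,
                                    mask_fraction = 0.2,
                                    unique_fixed_point = TRUE,
                                    max_tries = 500L) {
  stopifnot(n_edges >= n_nodes, n_outputs >= 2L, n_drugs >= 2L,
            n_nodes > n_outputs)
  nodes <- sprintf("n%02d", seq_len(n_nodes))

  draw_network <- function() {
    # one incoming edge per node guarantees self-containedness
    src <- vapply(seq_len(n_nodes), function(v) {
      sample(setdiff(seq_len(n_nodes), v), 1L)
    }, integer(1))
    edges <- data.frame(source = nodes[src], target = nodes,
                        sign = sample(c(1L, -1L), n_nodes, replace = TRUE),
                        stringsAsFactors = FALSE)
    key <- function(e) paste(e$source, e$target, e$sign)
    seen <- key(edges)
    while (nrow(edges) < n_edges) {
      st <- sample.int(n_nodes, 2L, replace = FALSE)
      cand <- data.frame(source = nodes[st[1]], target = nodes[st[2]],
                         sign = sample(c(1L, -1L), 1L),
                         stringsAsFactors = FALSE)
      if (key(cand) %in% seen) next
      edges <- rbind(edges, cand)
      seen <- c(seen, key(cand))
    }
    pkn(edges)   # canonical first-appearance node order, as read_sif uses
  }

  # a stable (by default uniquely stable) link-operator assignment on a
  # fresh random topology; errors when the retry budget is exhausted
  draw_truth <- function() {
    network <- draw_network()
    base <- assemble_default_model(network)
    for (try in seq_len(max_tries)) {
      cand <- base
      lo <- which(cand$op != .OP_NONE)
      if (length(lo) > 0) {
        cand$op[lo] <- sample(c(.OP_AND_NOT, .OP_OR_NOT), length(lo),
                              replace = TRUE)
        cand$last_op[lo] <- cand$op[lo]
      }
      att <- fixed_points(cand)
      ok <- if (unique_fixed_point) att$n == 1 else att$n >= 1
      if (ok) {
        return(list(network = network, truth = cand, att = att))
      }
      if (try %% 50L == 0L) {   # refresh topology if assignments keep failing
        network <- draw_network()
        base <- assemble_default_model(network)
      }
    }
    stop("no stable truth parameterization found within ", max_tries,
         " tries; increase max_tries")
  }

  drug_names <- sprintf("d%d", seq_len(n_drugs))

  gold_for <- function(truth, panel, outputs) {
    g1 <- setNames(vapply(drug_names, function(d) {
      model_growth(apply_perturbation(truth, d, panel), outputs)
    }, numeric(1)), drug_names)
    pairs <- combn(drug_names, 2, simplify = FALSE)
    rows <- lapply(pairs, function(p) {
      gab <- model_growth(apply_perturbation(truth, p, panel), outputs)
      s <- score_synergy(g1[[p[1]]], g1[[p[2]]], gab)
      data.frame(pair = pair_key(p[1], p[2]), drug_a = sort(p)[1],
                 drug_b = sort(p)[2],
                 label = as.integer(identical(s$call, "synergy")),
                 flagged = identical(s$call, "not-available"),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }

  # search jointly over systems, output choices and drug panels for a gold
  # standard with both classes present (a benchmark needs both)
  for (sys_try in seq_len(25L)) {
    drawn <- draw_truth()
    network <- drawn$network
    truth <- drawn$truth
    for (out_try in seq_len(5L)) {
      out_nodes <- sample(nodes, n_outputs)
      n_pos_w <- ceiling(n_outputs / 2)
      outputs <- output_spec(setNames(c(rep(1, n_pos_w),
                                        rep(-1, n_outputs - n_pos_w)),
                                      out_nodes))
      candidates <- setdiff(nodes, out_nodes)
      stopifnot(length(candidates) >= n_drugs)
      for (panel_try in seq_len(20L)) {
        targets <- sample(candidates, n_drugs)
        panel <- drug_panel(setNames(lapply(targets, function(t) {
          list(effect = "inhibits", targets = t)
        }), drug_names))
        gold <- gold_for(truth, panel, outputs)
        if (any(gold$label == 1L) && any(gold$label == 0L)) {
          full_profile <- calibration_profile(drawn$att$fixed_points[1, ])
          n_mask <- ceiling(mask_fraction * n_nodes)
          profile <- full_profile
          if (n_mask > 0) {
            profile[sample(seq_along(profile), n_mask)] <- NA_integer_
          }
          profile <- calibration_profile(profile)
          return(structure(list(network = network, truth_model = truth,
                                truth_profile = profile,
                                full_profile = full_profile,
                                outputs = outputs, panel = panel, gold = gold,
                                perturbations = all_perturbations(panel)),
                           class = "planted_system"))
        }
      }
    }
  }
  stop("could not find a drug panel with a mixed gold standard; ",
       "try different system dimensions")
}

#' @export
print.planted_system <- function(x, ...) {
  cat("Planted system:", length(x$network$nodes), "nodes,",
      nrow(x$network$interactions), "edges,",
      length(x$outputs$weights), "outputs,",
      length(x$panel$entries), "drugs;",
      sum(x$gold$label), "of", nrow(x$gold), "pairs synergistic\n")
  invisible(x)
}

#' Write all system artifacts to a directory
#'
#' Produces `network.sif`, `steadystate.tab`, `drugpanel.tab`,
#' `modeloutputs.tab`, `perturbations.tab`, `gold.tsv` and
#' `truth_model.bnm`, each readable by the corresponding reader.
#'
#' @param system a [generate_planted_system()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_planted_system <- function(system, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sif(system$network, file.path(dir, "network.sif"))
  write_calibration(system$truth_profile, file.path(dir, "steadystate.tab"))
  write_drug_panel(system$panel, file.path(dir, "drugpanel.tab"))
  write_output_spec(system$outputs, file.path(dir, "modeloutputs.tab"))
  write_perturbations(system$perturbations, file.path(dir, "perturbations.tab"))
  utils::write.table(system$gold, file.path(dir, "gold.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_model(system$truth_model, file.path(dir, "truth_model.bnm"))
  invisible(dir)
}

#' Corrupt a calibration profile by flipping specified bits
#'
#' Exactly `round(fraction * m)` of the `m` specified entries, chosen
#' uniformly without replacement, have their bit flipped; unspecified
#' entries are untouched. At fraction 1 the operation is an involution
#' (applying it twice restores the original profile). Uses the current R
#' random-number stream.
#'
#' @param profile a [calibration_profile()].
#' @param fraction fraction of specified entries to flip, in `[0, 1]`.
#' @return a corrupted [calibration_profile()].
#' @export
corrupt_profile <- function(profile, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  spec <- which(!is.na(profile))
  k <- round(fraction * length(spec))
  if (k > 0) {
    idx <- spec[sample.int(length(spec), k)]
    profile[idx] <- 1L - profile[idx]
  }
  calibration_profile(unclass(profile))
}

#' Scramble network topology (robustness experiment)
#'
#' Modifies `round(fraction * n_edges)` interactions, chosen uniformly
#' without replacement. Modes: `source` exchanges the source of each chosen
#' interaction with the source of another uniformly chosen interaction
#' (pairwise swap); `target` likewise for targets; `sign` inverts the
#' activation/inhibition annotation; `all` applies each of the three to its
#' own independently sampled subset. Pairwise swaps permute the endpoint
#' multiset among edges, so node set, edge count and per-node degrees are
#' preserved and the network stays self-contained; should a node
#' nevertheless end up unregulated, a positive self-loop is added (with a
#' message). Scrambling may create duplicate interactions; they are kept so
#' that the edge count is preserved (duplicates collapse at model assembly).
#' Uses the current R random-number stream.
#'
#' @param network a [pkn()].
#' @param mode one of `"source"`, `"target"`, `"sign"`, `"all"`.
#' @param fraction fraction of interactions to modify, in `[0, 1]`.
#' @return a scrambled [pkn()].
#' @export
scramble_topology <- function(network, mode = c("source", "target", "sign", "all"),
                              fraction = 1) {
  mode <- match.arg(mode)
  stopifnot(fraction >= 0, fraction <= 1)
  ints <- network$interactions
  ne <- nrow(ints)
  pick <- function() {
    k <- round(fraction * ne)
    if (k > 0) sample.int(ne, k) else integer()
  }
  swap_col <- function(ints, col, sel) {
    for (i in sel) {
      j <- sample.int(ne, 1L)
      tmp <- ints[[col]][i]
      ints[[col]][i] <- ints[[col]][j]
      ints[[col]][j] <- tmp
    }
    ints
  }
  if (mode %in% c("source", "all")) ints <- swap_col(ints, "source", pick())
  if (mode %in% c("target", "all")) ints <- swap_col(ints, "target", pick())
  if (mode %in% c("sign", "all")) {
    sel <- pick()
    ints$sign[sel] <- -ints$sign[sel]
  }
  orphan <- setdiff(network$nodes, ints$target)
  if (length(orphan) > 0) {
    message("self-containedness repair: positive self-loop added to ",
            paste(orphan, collapse = ", "))
    ints <- rbind(ints, data.frame(source = orphan, target = orphan,
                                   sign = 1L, stringsAsFactors = FALSE))
  }
  pkn(ints, nodes = network$nodes, validate = FALSE)
}

#' Input-degradation experiment: corruption / scrambling vs performance
#'
#' For each degradation fraction and replicate: derive the degraded input
#' (flipped calibration bits for `mode = "profile"`, a scrambled topology
#' otherwise), train a calibrated ensemble on it, train a matched baseline
#' ensemble against random proliferative profiles, simulate all
#' perturbations with both, normalize, and benchmark the normalized scores
#' against the system's planted gold standard. At fraction 0 the run
#' reproduces the clean-system benchmark for that replicate (seeds depend
#' only on the replicate). For `mode = "profile"` the baseline is shared
#' across fractions (the network is unchanged); for topology modes it is
#' retrained on each scrambled network so that normalization mirrors the
#' calibrated pipeline.
#'
#' @param system a [generate_planted_system()] result.
#' @param fractions degradation fractions to sweep.
#' @param mode `"profile"` (calibration corruption) or a
#'   [scramble_topology()] mode.
#' @param config a [ga_config()]; its `seed` is ignored in favor of derived
#'   per-replicate seeds.
#' @param replicates independent replicates per fraction.
#' @param seed master seed for the experiment.
#' @return data frame `mode`, `fraction`, `replicate`, `seed`, `roc_auc`,
#'   `pr_auc`, `mean_fitness` (AUCs are `NA` when too few scored pairs
#'   remain to benchmark).
#' @export
degradation_experiment <- function(system, fractions = seq(0, 1, by = 0.1),
                                   mode = c("profile", "source", "target",
                                            "sign", "all"),
                                   config = ga_config(evolutions = 5L),
                                   replicates = 10L, seed = 1L) {
  mode <- match.arg(mode)
  rows <- list()
  for (r in seq_len(replicates)) {
    rep_seed <- .derive_seed(seed, 10000 * r)
    baseline <- NULL
    if (mode == "profile") {
      baseline <- .train_baseline(system$network, system$outputs, config,
                                  .derive_seed(rep_seed, 5000))
    }
    for (f in fractions) {
      set.seed(.derive_seed(rep_seed, round(1000 * f)))
      if (mode == "profile") {
        net <- system$network
        prof <- corrupt_profile(system$truth_profile, f)
        base <- baseline
      } else {
        net <- scramble_topology(system$network, mode, f)
        prof <- system$truth_profile
        base <- .train_baseline(net, system$outputs, config,
                                .derive_seed(rep_seed, 5000))
      }
      cal_config <- config
      cal_config$seed <- rep_seed
      cal <- evolve(net, prof, cal_config)
      resp_cal <- simulate_ensemble(cal, system$perturbations, system$panel,
                                    system$outputs)
      resp_base <- simulate_ensemble(base, system$perturbations, system$panel,
                                     system$outputs)
      syn <- suppressMessages(
        normalize_synergies(synergy_table(resp_cal), synergy_table(resp_base)))
      bench <- tryCatch(benchmark_synergies(syn, system$gold),
                        error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, fraction = f, replicate = r, seed = rep_seed,
        roc_auc = if (is.null(bench)) NA_real_ else bench$roc_auc,
        pr_auc = if (is.null(bench)) NA_real_ else bench$pr_auc,
        mean_fitness = mean(ensemble_fitness(cal)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# baseline ensemble trained to a fresh random proliferative profile per
# evolution, mirroring the calibrated runs' configuration
.train_baseline <- function(network, outputs, config, seed) {
  base_config <- config
  base_config$seed <- seed
  evolve(network, function(e) sample_proliferative_profile(outputs),
         base_config)
}
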