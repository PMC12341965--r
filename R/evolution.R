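#' Fitness of a model's stable states against a calibration profile
#'
#' With `n` fixed points and `m` specified profile entries the fitness is
#' the average match fraction
#' `sum_i sum_j 1[fix_ij == ss_j] / (m * n)`,
#' i.e. the fraction of specified calibration entries matched, averaged over
#' all of the model's fixed points. Models with several stable states are
#' thereby penalized unless every stable state matches. A model without any
#' fixed point (only complex attractors) gets fitness 0.
#'
#' @param attractors a [fixed_points()] result.
#' @param profile a [calibration_profile()] with `m >= 1` specified entries.
#' @return fitness in `[0, 1]`.
#' @export
compute_fitness <- function(attractors, profile) {
  m <- m_specified(profile)
  stopifnot(m >= 1)
  if (attractors$n == 0) return(0)
  nodes <- names(profile)[!is.na(profile)]
  missing <- setdiff(nodes, colnames(attractors$fixed_points))
  if (length(missing) > 0) {
    stop("profile specifies node(s) absent from the model: ",
         paste(missing, collapse = ", "))
  }
  fp <- attractors$fixed_points[, nodes, drop = FALSE]
  target <- as.integer(profile[nodes])
  matches <- sum(t(fp) == target)
  matches / (m * attractors$n)
}

#' Genetic-algorithm configuration
#'
#' Defaults follow the published calibration schedule: populations of 20
#' models, the best 3 selected per generation, 3 link-operator mutations per
#' offspring multiplied by 1000 during the initial burst phase (before any
#' population member has a stable state), halting at a minimum-top-3 fitness
#' of 0.99 or after 20 generations, with 50 independent evolutions pooling
#' 3 x 50 = 150 models. Topology mode applies 50 edge mutations per
#' offspring during the burst and 10 afterwards.
#'
#' @param population models per generation.
#' @param generations_max generation cap per evolution.
#' @param selection_count models kept per generation (and per evolution).
#' @param mutations_per_model link-operator mutation draws per offspring.
#' @param burst_multiplier factor applied to `mutations_per_model` while the
#'   burst phase is active; the burst ends permanently in the first
#'   generation in which any population member has a fixed point.
#' @param topology_mutations_init,topology_mutations_after edge mutations
#'   per offspring during/after the burst phase (topology modes).
#' @param fitness_threshold halt an evolution when the minimum fitness among
#'   the selected models reaches this value.
#' @param evolutions number of independent evolutions pooled into the
#'   ensemble.
#' @param mutation_mode `"parameterization"`, `"topology"`, or `"both"`
#'   (topology mutations are applied before link-operator mutations).
#' @param crossover `"uniform"` (each equation independently from either
#'   parent) or `"single-point"`.
#' @param elitism carry the selected parents into the next generation's
#'   scored pool so the best fitness never regresses.
#' @param seed master seed; evolution `e` uses stream seed `seed + e`.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(population = 20L, generations_max = 20L,
                      selection_count = 3L, mutations_per_model = 3L,
                      burst_multiplier = 1000L,
                      topology_mutations_init = 50L,
                      topology_mutations_after = 10L,
                      fitness_threshold = 0.99, evolutions = 50L,
                      mutation_mode = c("parameterization", "topology", "both"),
                      crossover = c("uniform", "single-point"),
                      elitism = TRUE, seed = 42L) {
  mutation_mode <- match.arg(mutation_mode)
  crossover <- match.arg(crossover)
  stopifnot(selection_count <= population, selection_count >= 1,
            fitness_threshold > 0, fitness_threshold <= 1,
            population >= 1, generations_max >= 1, evolutions >= 1)
  structure(list(population = as.integer(population),
                 generations_max = as.integer(generations_max),
                 selection_count = as.integer(selection_count),
                 mutations_per_model = as.integer(mutations_per_model),
                 burst_multiplier = as.integer(burst_multiplier),
                 topology_mutations_init = as.integer(topology_mutations_init),
                 topology_mutations_after = as.integer(topology_mutations_after),
                 fitness_threshold = fitness_threshold,
                 evolutions = as.integer(evolutions),
                 mutation_mode = mutation_mode, crossover = crossover,
                 elitism = elitism, seed = as.integer(seed)),
            class = "ga_config")
}

.crossover <- function(p1, p2, type) {
  nn <- length(p1$nodes)
  from1 <- if (type == "uniform") {
    sample(c(TRUE, FALSE), nn, replace = TRUE)
  } else {
    cut <- sample.int(nn, 1L)
    seq_len(nn) <= cut
  }
  child <- p1
  child$act[!from1] <- p2$act[!from1]
  child$inh[!from1] <- p2$inh[!from1]
  child$op[!from1] <- p2$op[!from1]
  child$last_op[!from1] <- p2$last_op[!from1]
  child$fitness <- NA_real_
  child
}

.mutate_offspring <- function(child, network, config, burst) {
  if (config$mutation_mode %in% c("topology", "both")) {
    k <- if (burst) config$topology_mutations_init else config$topology_mutations_after
    child <- mutate_topology(child, network, k)
  }
  if (config$mutation_mode %in% c("parameterization", "both")) {
    k <- config$mutations_per_model * (if (burst) config$burst_multiplier else 1L)
    # an even burst budget would fix the parity of flipped equations; one
    # extra coin-flip mutation makes the burst phase cover the whole
    # parameterization space
    if (burst) k <- k + sample(0:1, 1L)
    child <- suppressWarnings(mutate_link_operators(child, k))
  }
  child
}

#' Produce one generation of offspring from selected parents
#'
#' Each offspring is built by crossover of two parents drawn uniformly with
#' replacement from `parents` (a parent may be drawn twice: asexual
#' reproduction), then mutated according to the configuration and the burst
#' state. Uses the current R random-number stream.
#'
#' @param parents non-empty list of `boolean_model` parents.
#' @param config a [ga_config()].
#' @param network the originating [pkn()] (needed for topology mutations).
#' @param burst whether the burst phase is active.
#' @return list of `config$population` offspring models.
#' @export
next_generation <- function(parents, config, network, burst = FALSE) {
  stopifnot(length(parents) >= 1)
  lapply(seq_len(config$population), function(j) {
    pick <- sample.int(length(parents), 2L, replace = TRUE)
    child <- .crossover(parents[[pick[1]]], parents[[pick[2]]], config$crossover)
    .mutate_offspring(child, network, config, burst)
  })
}

# score a model in place: enumerate fixed points, attach fitness
.score_model <- function(model, profile, max_fixed_points) {
  att <- fixed_points(model, max_fixed_points = max_fixed_points)
  model$fitness <- compute_fitness(att, profile)
  model$n_fixed_points <- att$n
  model
}

# one complete evolution: burst-phase initialization, selection, halting
.run_evolution <- function(base_model, network, profile, config,
                           max_fixed_points) {
  burst <- TRUE
  creation <- 0L
  new_pop <- function(parents, burst) {
    pop <- next_generation(parents, config, network, burst)
    for (j in seq_along(pop)) {
      creation <<- creation + 1L
      pop[[j]]$creation <- creation
    }
    pop
  }
  pop <- new_pop(list(base_model), burst)
  parents <- list()
  log <- list()
  for (gen in seq_len(config$generations_max)) {
    pop <- lapply(pop, .score_model, profile = profile,
                  max_fixed_points = max_fixed_points)
    if (burst && any(vapply(pop, `[[`, integer(1), "n_fixed_points") > 0)) {
      burst <- FALSE
    }
    pool <- c(parents, pop)
    fit <- vapply(pool, `[[`, numeric(1), "fitness")
    born <- vapply(pool, `[[`, integer(1), "creation")
    top <- pool[order(-fit, born)][seq_len(min(config$selection_count,
                                               length(pool)))]
    top_fit <- vapply(top, `[[`, numeric(1), "fitness")
    log[[gen]] <- data.frame(generation = gen, best = max(fit),
                             min_top = min(top_fit),
                             mean = mean(fit), sd = sd(fit), burst = burst)
    if (min(top_fit) >= config$fitness_threshold) break
    if (gen == config$generations_max) break
    parents <- if (config$elitism) top else list()
    pop <- new_pop(top, burst)
  }
  list(kept = top, log = do.call(rbind, log))
}

#' Calibrate an ensemble of Boolean models with the genetic algorithm
#'
#' Runs `config$evolutions` independent evolutions. Each starts from the
#' default-assembled model, explores parameterizations with heavily mutated
#' (burst-phase) offspring until stable states appear, then refines by
#' selection, crossover and mutation, halting when the minimum fitness among
#' the selected models reaches the threshold or the generation cap. The
#' selected models of every evolution are pooled, giving
#' `selection_count * evolutions` models in the final ensemble.
#'
#' Evolution `e` is driven by seed `config$seed + e`, so evolutions are
#' individually reproducible.
#'
#' @param network a [pkn()].
#' @param profile a [calibration_profile()], or a function of the evolution
#'   index returning one (used e.g. to train random-proliferative baseline
#'   ensembles on a fresh profile per evolution).
#' @param config a [ga_config()].
#' @param max_fixed_points per-model enumeration cap (see [fixed_points()]).
#' @return object of class `model_ensemble`: list with `models` (each with
#'   attached `fitness`), `config`, `calibration`, and a per-generation
#'   training `log` (evolution, generation, best/min-top/mean/sd fitness).
#' @export
evolve <- function(network, profile, config = ga_config(),
                   max_fixed_points = 64L) {
  stopifnot(inherits(network, "pkn"))
  if (!is.function(profile)) {
    unknown <- setdiff(names(profile), network$nodes)
    if (length(unknown) > 0) {
      stop("calibration profile names node(s) not in the network: ",
           paste(unknown, collapse = ", "))
    }
  }
  base_model <- assemble_default_model(network)
  models <- list()
  logs <- list()
  for (e in seq_len(config$evolutions)) {
    set.seed(.derive_seed(config$seed, e))
    prof <- if (is.function(profile)) profile(e) else profile
    res <- .run_evolution(base_model, network, prof, config, max_fixed_points)
    models <- c(models, res$kept)
    res$log$evolution <- e
    logs[[e]] <- res$log
  }
  log <- do.call(rbind, logs)
  structure(list(models = models, config = config,
                 calibration = if (is.function(profile)) "per-evolution draw"
                 else profile,
                 log = log[, c("evolution", "generation", "best", "min_top",
                               "mean", "sd", "burst")]),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  fit <- vapply(x$models, `[[`, numeric(1), "fitness")
  cat("Model ensemble:", length(x$models), "models from",
      x$config$evolutions, "evolutions; fitness",
      sprintf("%.3f (mean), %.3f (min), %.3f (max)",
              mean(fit), min(fit), max(fit)), "\n")
  invisible(x)
}

#' Fitness values of an ensemble
#' @param ensemble a [evolve()] result or list of models.
#' @return numeric vector.
#' @export
ensemble_fitness <- function(ensemble) {
  models <- if (inherits(ensemble, "model_ensemble")) ensemble$models else ensemble
  vapply(models, `[[`, numeric(1), "fitness")
}
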