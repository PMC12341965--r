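make_attractors <- function(rows, nodes) {
  fp <- matrix(as.integer(unlist(rows)), nrow = length(rows), byrow = TRUE,
               dimnames = list(NULL, nodes))
  structure(list(fixed_points = fp, n = nrow(fp)), class = "attractor_set")
}

test_that("fitness is the average match fraction over stable states", {
  prof <- calibration_profile(c(A = 1, B = 0, C = 1))
  none <- structure(list(fixed_points = matrix(integer(), 0, 3), n = 0),
                    class = "attractor_set")
  expect_equal(compute_fitness(none, prof), 0)

  perfect <- make_attractors(list(c(1, 0, 1)), c("A", "B", "C"))
  expect_equal(compute_fitness(perfect, prof), 1)

  # two stable states matching 3 of 3 and 1 of 3 entries: (3+1)/(3*2) = 2/3
  mixed <- make_attractors(list(c(1, 0, 1), c(0, 1, 1)), c("A", "B", "C"))
  expect_equal(compute_fitness(mixed, prof), 2 / 3)

  # unspecified entries are ignored; m counts only 0/1 entries
  partial <- calibration_profile(c(A = 1, B = NA, C = 0))
  half <- make_attractors(list(c(1, 1, 1)), c("A", "B", "C"))
  expect_equal(compute_fitness(half, partial), 1 / 2)
})

test_that("fitness stays within [0, 1] on random attractor sets", {
  set.seed(301)
  for (rep in 1:25) {
    nodes <- sprintf("x%d", 1:6)
    n_fp <- sample(0:4, 1)
    att <- if (n_fp == 0) {
      structure(list(fixed_points = matrix(integer(), 0, 6,
                                           dimnames = list(NULL, nodes)),
                     n = 0), class = "attractor_set")
    } else {
      make_attractors(replicate(n_fp, sample(0:1, 6, TRUE), simplify = FALSE),
                      nodes)
    }
    spec <- sample(c(0L, 1L, NA), 6, TRUE)
    if (all(is.na(spec))) spec[1] <- 1L
    f <- compute_fitness(att, calibration_profile(setNames(spec, nodes)))
    expect_gte(f, 0)
    expect_lte(f, 1)
  }
})

test_that("crossover of a single parent or identical parents clones them", {
  set.seed(302)
  net <- random_test_network(10)
  model <- assemble_default_model(net)
  cfg <- ga_config(population = 6L, mutations_per_model = 0L,
                   burst_multiplier = 1L, seed = 1L)
  # mutation count zero isolates the crossover step
  kids <- suppressWarnings(next_generation(list(model), cfg, net))
  expect_length(kids, 6)
  for (k in kids) {
    expect_identical(model_equations_text(k), model_equations_text(model))
  }
  variant <- mutate_link_operators(model, 1)
  kids2 <- suppressWarnings(next_generation(list(variant, variant), cfg, net))
  for (k in kids2) {
    expect_identical(model_equations_text(k), model_equations_text(variant))
  }
})

test_that("offspring generation is deterministic under a fixed seed", {
  set.seed(303)
  net <- random_test_network(10)
  parents <- list(assemble_default_model(net),
                  mutate_link_operators(assemble_default_model(net), 3))
  cfg <- ga_config(population = 8L, seed = 5L)
  gen <- function() {
    set.seed(99)
    lapply(next_generation(parents, cfg, net, burst = TRUE),
           model_equations_text)
  }
  expect_identical(gen(), gen())
})

test_that("the ensemble pools selection_count models per evolution", {
  set.seed(304)
  sys <- generate_planted_system(n_nodes = 10, n_edges = 17, n_outputs = 2,
                                 n_drugs = 3)
  cfg <- ga_config(evolutions = 4L, selection_count = 3L, seed = 9L)
  ens <- evolve(sys$network, sys$truth_profile, cfg)
  expect_length(ens$models, 4 * 3)
  expect_true(all(ensemble_fitness(ens) >= 0 & ensemble_fitness(ens) <= 1))
})

test_that("the kept minimum fitness never decreases within an evolution", {
  set.seed(305)
  sys <- generate_planted_system(n_nodes = 12, n_edges = 20, n_outputs = 2,
                                 n_drugs = 3)
  cfg <- ga_config(evolutions = 3L, fitness_threshold = 1, seed = 21L)
  ens <- evolve(sys$network, sys$truth_profile, cfg)
  for (e in unique(ens$log$evolution)) {
    top <- ens$log$min_top[ens$log$evolution == e]
    expect_true(all(diff(top) >= -1e-12))
  }
})

test_that("evolve is reproducible and validates profile nodes", {
  set.seed(306)
  sys <- generate_planted_system(n_nodes = 10, n_edges = 17, n_outputs = 2,
                                 n_drugs = 3)
  cfg <- ga_config(evolutions = 2L, seed = 13L)
  e1 <- evolve(sys$network, sys$truth_profile, cfg)
  e2 <- evolve(sys$network, sys$truth_profile, cfg)
  expect_identical(lapply(e1$models, model_equations_text),
                   lapply(e2$models, model_equations_text))
  expect_identical(ensemble_fitness(e1), ensemble_fitness(e2))
  expect_identical(e1$log, e2$log)

  bad <- calibration_profile(c(zz = 1))
  expect_error(evolve(sys$network, bad, cfg), "zz")
})

test_that("burst-phase initial models sample parameterizations near-uniformly", {
  set.seed(307)
  net <- random_test_network(8)
  model <- assemble_default_model(net)
  lo <- which(model$op != 0L)
  n <- length(lo)
  expect_gte(n, 2)
  cfg <- ga_config(population = 1L, selection_count = 1L,
                   mutations_per_model = 3L, burst_multiplier = 1000L,
                   seed = 1L)
  draws <- replicate(max(600, 40 * 2^n), {
    kid <- next_generation(list(model), cfg, net, burst = TRUE)[[1]]
    paste(kid$op[lo], collapse = "")
  })
  counts <- table(factor(draws, levels = apply(
    expand.grid(rep(list(1:2), n)), 1, paste, collapse = "")))
  expect_equal(length(counts), 2^n)
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.001)
})

test_that("average fitness rises then plateaus across generations", {
  set.seed(308)
  sys <- generate_planted_system(n_nodes = 12, n_edges = 20, n_outputs = 2,
                                 n_drugs = 3, mask_fraction = 0)
  # a partially inconsistent profile keeps perfect fitness out of reach, so
  # every evolution spans the full generation budget and the population-mean
  # trajectory is comparable across evolutions
  hard <- corrupt_profile(sys$full_profile, 0.25)
  cfg <- ga_config(evolutions = 6L, generations_max = 12L,
                   fitness_threshold = 1, seed = 31L)
  ens <- evolve(sys$network, hard, cfg)
  log <- ens$log
  n_gen <- min(tapply(log$generation, log$evolution, max))
  expect_gte(n_gen, 6)
  log <- log[log$generation <= n_gen, ]
  gen_mean <- tapply(log$mean, log$generation, mean)
  early <- gen_mean[[1]]
  late <- mean(gen_mean[(n_gen - 1):n_gen])
  expect_gt(late, early)                       # overall rise
  # plateau: the late gain is small next to the initial climb
  mid <- gen_mean[[ceiling(n_gen / 2)]]
  expect_lt(abs(late - mid), max(0.1, 0.5 * (mid - early)))
})

test_that("topology-mode offspring always satisfy the one-regulator floor", {
  set.seed(309)
  net <- random_test_network(10)
  model <- assemble_default_model(net)
  cfg <- ga_config(population = 10L, mutation_mode = "topology", seed = 3L)
  kids <- suppressWarnings(next_generation(list(model), cfg, net, burst = TRUE))
  for (k in kids) {
    expect_true(all(lengths(k$act) + lengths(k$inh) >= 1))
  }
})
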