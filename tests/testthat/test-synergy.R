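# small deterministic system reused across blocks:
# S -> P (activation chain), S -| Q; outputs P (+1), Q (-1)
chain_system <- function() {
  net <- pkn(data.frame(source = c("S", "S", "S", "P", "Q"),
                        target = c("P", "Q", "S", "S", "P"),
                        sign = c(1L, -1L, 1L, 1L, -1L),
                        stringsAsFactors = FALSE))
  model <- assemble_default_model(net)
  list(net = net, model = model,
       outputs = output_spec(c(P = 1, Q = -1)),
       panel = drug_panel(list(
         ds = list(effect = "inhibits", targets = "S"),
         dp = list(effect = "inhibits", targets = "P"),
         da = list(effect = "activates", targets = "Q"))))
}

test_that("perturbations clamp targets and leave the input model untouched", {
  cs <- chain_system()
  pm <- apply_perturbation(cs$model, "ds", cs$panel)
  expect_equal(pm$fixed[match("S", pm$nodes)], 0L)
  expect_true(all(cs$model$fixed == -1L))

  act <- apply_perturbation(cs$model, "da", cs$panel)
  expect_equal(act$fixed[match("Q", act$nodes)], 1L)

  ab <- apply_perturbation(cs$model, c("ds", "dp"), cs$panel)
  ba <- apply_perturbation(cs$model, c("dp", "ds"), cs$panel)
  expect_identical(ab$fixed, ba$fixed)

  expect_error(apply_perturbation(cs$model, "nope", cs$panel), "nope")
  foreign <- drug_panel(list(dz = list(effect = "inhibits", targets = "ZZ")))
  expect_error(apply_perturbation(cs$model, "dz", foreign), "dz.*ZZ")
})

test_that("growth scales the weighted output sum to [0, 1]", {
  # two outputs of weight +1 and -1 both active: raw 0 in range [-1, 1],
  # scaled global output 0.5
  att <- structure(list(fixed_points = matrix(c(1L, 1L), 1,
                                              dimnames = list(NULL, c("P", "Q"))),
                        n = 1), class = "attractor_set")
  outputs <- output_spec(c(P = 1, Q = -1))
  model_stub <- structure(list(nodes = c("P", "Q")), class = "boolean_model")
  expect_equal(model_growth(model_stub, outputs, attractors = att), 0.5)

  # all positive-weight nodes on, all negative off: maximal growth 1
  best <- structure(list(fixed_points = matrix(c(1L, 0L), 1,
                                               dimnames = list(NULL, c("P", "Q"))),
                         n = 1), class = "attractor_set")
  expect_equal(model_growth(model_stub, outputs, attractors = best), 1)
})

test_that("growth is undefined without a fixed point", {
  osc <- pkn(data.frame(source = c("A", "B"), target = c("B", "A"),
                        sign = c(-1L, 1L)), validate = FALSE)
  m <- assemble_default_model(osc)
  expect_equal(fixed_points(m)$n, 0)
  expect_true(is.na(model_growth(m, output_spec(c(A = 1, B = -1)))))
})

test_that("per-fixed-point scaling then averaging equals averaging then scaling", {
  set.seed(501)
  for (rep in 1:10) {
    model <- random_test_model(9)
    att <- fixed_points(model)
    if (att$n == 0) next
    w <- setNames(c(1, 1, -1, -1), sample(model$nodes, 4))
    outputs <- output_spec(w)
    g <- model_growth(model, outputs, attractors = att)
    raw_mean <- mean(att$fixed_points[, names(w), drop = FALSE] %*% w)
    expect_equal(g, (raw_mean - outputs$theoretical_min) /
                   (outputs$theoretical_max - outputs$theoretical_min))
    expect_gte(g, 0)
    expect_lte(g, 1)
  }
})

test_that("ensemble growth averages member growths and audits exclusions", {
  cs <- chain_system()
  # two models differing in one link operator yield different growths
  m1 <- cs$model
  att1 <- fixed_points(m1)
  g1 <- model_growth(m1, cs$outputs)
  # stub ensemble mixing a model that loses its fixed points under 'da'
  osc_net <- pkn(data.frame(source = c("S", "P", "Q", "P"),
                            target = c("P", "S", "P", "Q"),
                            sign = c(1L, 1L, -1L, -1L)), validate = FALSE)
  m2 <- assemble_default_model(osc_net)
  r <- ensemble_growth(list(m1, m1), character(), cs$panel, cs$outputs)
  expect_equal(r$growth, g1)
  expect_equal(r$models_used, 2)

  # hand-built growths 0.4 / 0.6 average to 0.5 via the same code path
  resp <- simulate_ensemble(list(m1), list("ds", "dp", c("ds", "dp")),
                            cs$panel, cs$outputs)
  expect_equal(nrow(resp), 3)
  expect_true(all(resp$models_used + resp$models_excluded == 1))
})

test_that("synergy decomposition follows Bliss independence exactly", {
  s <- score_synergy(0.5, 0.5, 0.20)
  expect_equal(s$expected, 0.25)
  expect_equal(s$excess, -0.05)
  expect_equal(s$call, "synergy")
  expect_equal(s$observed, s$expected + s$excess)  # E = A + S

  expect_equal(score_synergy(0.5, 0.5, 0.25)$call, "none")
  expect_equal(score_synergy(0.5, 0.5, 0.30)$call, "antagonism")
  expect_identical(score_synergy(0.4, 0.7, 0.2), score_synergy(0.7, 0.4, 0.2))
  expect_equal(score_synergy(NA, 0.5, 0.2)$call, "not-available")
})

test_that("E = A + S holds to machine precision on random growth triples", {
  set.seed(502)
  for (rep in 1:200) {
    g <- runif(3)
    s <- score_synergy(g[1], g[2], g[3])
    expect_identical(s$observed, s$expected + s$excess)
  }
})

test_that("normalization is the exponential fold change over the baseline", {
  tab <- function(S) data.frame(pair = "a-b", drug_a = "a", drug_b = "b",
                                observed = 0.2, expected = 0.2 - S,
                                excess = S, call = "synergy",
                                stringsAsFactors = FALSE)
  expect_equal(normalize_synergies(tab(-0.1), tab(-0.1))$normalized, 1)
  expect_equal(normalize_synergies(tab(-0.2), tab(-0.1))$normalized,
               exp(-0.1))
  expect_equal(normalize_synergies(tab(0), tab(-0.1))$normalized, exp(0.1))
  # unavailable baseline scores are flagged, not silently dropped
  na_tab <- tab(NA_real_)
  expect_message(out <- normalize_synergies(tab(-0.1), na_tab), "unavailable")
  expect_true(is.na(out$normalized))
})

test_that("random proliferative profiles obey the phenotype constraints", {
  outputs <- output_spec(c(P1 = 1, P2 = 1, A1 = -1, A2 = -1))
  set.seed(503)
  for (rep in 1:50) {
    prof <- sample_proliferative_profile(outputs)
    expect_equal(unname(prof[c("A1", "A2")]), c(0L, 0L))
    expect_gte(sum(prof[c("P1", "P2")]), 1)
  }
  set.seed(42)
  a <- replicate(10, sample_proliferative_profile(outputs)[["P1"]])
  set.seed(42)
  b <- replicate(10, sample_proliferative_profile(outputs)[["P1"]])
  expect_identical(a, b)
})

test_that("perturbing nodes with no path to the outputs leaves growth unchanged", {
  skip_if_not_installed("igraph")
  set.seed(504)
  checked <- 0
  for (rep in 1:30) {
    sys <- tryCatch(generate_planted_system(n_nodes = 10, n_edges = 17,
                                            n_outputs = 2, n_drugs = 3),
                    error = function(e) NULL)
    if (is.null(sys)) next
    g <- igraph::graph_from_data_frame(
      sys$network$interactions[, c("source", "target")],
      vertices = sys$network$nodes)
    out_nodes <- names(sys$outputs$weights)
    for (d in names(sys$panel$entries)) {
      tgt <- sys$panel$entries[[d]]$targets
      reach <- igraph::as_ids(igraph::subcomponent(g, tgt, mode = "out"))
      if (any(out_nodes %in% reach)) next
      g0 <- model_growth(sys$truth_model, sys$outputs)
      g1 <- model_growth(apply_perturbation(sys$truth_model, d, sys$panel),
                         sys$outputs)
      if (is.na(g1)) next  # perturbation removed the stable state entirely
      expect_equal(g1, g0)
      checked <- checked + 1
    }
    if (checked >= 3) break
  }
  expect_gte(checked, 1)
})
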