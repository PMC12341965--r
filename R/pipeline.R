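#' Run the full train / simulate / score / evaluate pipeline
#'
#' Orchestrates, from a single configuration: calibrated ensemble training,
#' random-proliferative baseline training, simulation of every listed
#' perturbation with both ensembles, Bliss-style synergy scoring with
#' exponential fold-change normalization, and (when a gold standard is
#' configured) ROC/PR benchmarking. All randomness derives from the master
#' seed, so two runs with identical configuration and seed produce
#' byte-identical outputs. A machine-readable `manifest.json` records the
#' configuration snapshot, seed, input checksums, package version and
#' per-stage timings.
#'
#' @param config path to a YAML file or an equivalent named list with
#'   entries `network`, `calibration`, `drug_panel`, `perturbations`,
#'   `model_outputs`, optional `gold`, `out_dir`, `seed`, and an optional
#'   `ga` section overriding [ga_config()] defaults.
#' @return the output directory, invisibly. Writes
#'   `models_calibrated/`, `models_random/`, `responses_calibrated.tsv`,
#'   `responses_random.tsv`, `synergies.tsv`, optional `aucs.tsv` and
#'   `curves.tsv`, plus `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("network", "calibration", "drug_panel", "perturbations",
                "model_outputs", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    stop("pipeline config is missing: ", paste(missing, collapse = ", "))
  }
  inputs <- unlist(config[c("network", "calibration", "drug_panel",
                            "perturbations", "model_outputs",
                            if (!is.null(config$gold)) "gold")])
  absent <- inputs[!file.exists(inputs)]
  if (length(absent) > 0) {
    stop("pipeline input file(s) not found: ", paste(absent, collapse = ", "))
  }
  seed <- as.integer(config$seed %||% 42L)
  ga_args <- config$ga %||% list()
  ga_args$seed <- NULL
  ga <- do.call(ga_config, c(ga_args, list(seed = seed)))

  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  network <- stage("read-inputs", {
    read_sif(config$network)
  })
  profile <- read_calibration(config$calibration, network)
  panel <- read_drug_panel(config$drug_panel, network)
  perturbations <- read_perturbations(config$perturbations, panel)
  outputs <- read_output_spec(config$model_outputs, network)
  gold <- if (!is.null(config$gold)) {
    utils::read.delim(config$gold, stringsAsFactors = FALSE)
  }

  calibrated <- stage("train-calibrated", evolve(network, profile, ga))
  base_ga <- ga
  base_ga$seed <- .derive_seed(seed, 990000)
  random <- stage("train-random", {
    evolve(network, function(e) sample_proliferative_profile(outputs), base_ga)
  })
  write_ensemble(calibrated, file.path(out_dir, "models_calibrated"))
  write_ensemble(random, file.path(out_dir, "models_random"))

  resp_cal <- stage("simulate-calibrated", {
    simulate_ensemble(calibrated, perturbations, panel, outputs)
  })
  resp_rand <- stage("simulate-random", {
    simulate_ensemble(random, perturbations, panel, outputs)
  })
  tsv <- function(x, name) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tsv(resp_cal, "responses_calibrated.tsv")
  tsv(resp_rand, "responses_random.tsv")

  synergies <- stage("score", {
    normalize_synergies(synergy_table(resp_cal), synergy_table(resp_rand))
  })
  tsv(synergies, "synergies.tsv")

  bench <- NULL
  if (!is.null(gold)) {
    bench <- stage("evaluate", benchmark_synergies(synergies, gold))
    tsv(data.frame(metric = c("roc_auc", "pr_auc"),
                   value = c(bench$roc_auc, bench$pr_auc),
                   n_pos = bench$n_pos, n_neg = bench$n_neg), "aucs.tsv")
    curves <- rbind(
      data.frame(curve = "roc", x = bench$roc_points$fpr,
                 y = bench$roc_points$tpr),
      data.frame(curve = "pr", x = bench$pr_points$recall,
                 y = bench$pr_points$precision))
    tsv(curves, "curves.tsv")
  }

  manifest <- list(
    package = "synlogic",
    version = as.character(packageVersion("synlogic")),
    seed = seed,
    config = config,
    ga = unclass(ga),
    input_checksums = as.list(tools::md5sum(inputs)),
    counts = list(models_calibrated = length(calibrated$models),
                  models_random = length(random$models),
                  perturbations = length(perturbations),
                  pairs_scored = nrow(synergies)),
    aucs = if (!is.null(bench)) {
      list(roc_auc = bench$roc_auc, pr_auc = bench$pr_auc)
    },
    timings_sec = timings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
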