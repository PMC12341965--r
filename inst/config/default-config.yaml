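# Template configuration for `run_pipeline()` / `synlogic.R run --config ...`
# The ga section lists the package defaults explicitly so every knob of the
# calibration schedule is visible and versioned alongside a run.

network: network.sif
calibration: steadystate.tab
drug_panel: drugpanel.tab
perturbations: perturbations.tab
model_outputs: modeloutputs.tab
# gold: gold.tsv            # optional: enables ROC/PR benchmarking
out_dir: out
seed: 42

ga:
  population: 20
  generations_max: 20
  selection_count: 3
  mutations_per_model: 3
  burst_multiplier: 1000
  topology_mutations_init: 50
  topology_mutations_after: 10
  fitness_threshold: 0.99
  evolutions: 50
  mutation_mode: parameterization   # parameterization | topology | both
  crossover: uniform                # uniform | single-point
  elitism: true
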