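---
title: "Ensemble Boolean logic models for drug synergy prediction: methods"
author: "synlogic authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble Boolean logic models for drug synergy prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synlogic)
```

## The modeling problem

Targeted cancer drugs are rarely effective alone; combinations can be, but
the space of pairs is too large to screen exhaustively. `synlogic`
implements an ensemble-modeling strategy for prioritizing drug pairs: build
executable Boolean models of a cell line's signaling network from a curated
prior-knowledge network (PKN), calibrate them against observed baseline
signaling activity, simulate drug perturbations in silico, and rank pairs
by a Bliss-style synergy score. Because calibration uses only unperturbed
(steady-state) biomarker data, the drug-response predictions are genuinely
out-of-sample with respect to perturbation experiments.

## The model family

A PKN is a signed, directed graph of causal interactions. It must be
*self-contained*: every node has at least one regulator inside the network,
so there are no free inputs. Each node `T` gets one standardized
*link-operator* equation,

```
T *= (A or B or ...) LINK not (C or D or ...)
```

where the activators are OR-joined into `Act`, the inhibitors OR-joined
into `Inh`, and `LINK` is either `and` (AND-NOT: activation present *and*
inhibition absent — the default, less permissive) or `or` (OR-NOT:
activation present *or* inhibition absent — more permissive). Nodes with a
single regulator class carry no link operator. The inline notation is
ambiguous on paper; this package fixes the grouping to
`(A∨B∨...) LINK ¬(C∨D∨...)` throughout, which is the only semantics the
link-operator concept supports (one connective joining the OR-combined
activator group to the OR-combined inhibitor group). With `n`
link-operator equations, the parameterization space has exactly `2^n`
members; those operator choices are the genetic algorithm's genotype.

## Stable states

The only attractors used anywhere are *fixed points*, states `x` with
`f(x) = x`, which are update-scheme independent. The solver translates the
fixed-point condition into a constraint problem and enumerates all
solutions by depth-first search with unit propagation (implemented in
C++); a plain `2^N` state sweep written independently in R serves as the
brute-force oracle in the test suite. Models whose only attractors are
complex (cyclic) are reported as having zero fixed points — they are never
characterized further, and downstream stages treat them as "no stable
behavior". Two guards fail loudly rather than truncate: a node-count cap
(default 4096) and a fixed-point enumeration cap (default 64).

## Calibration: fitness and the genetic algorithm

A calibration profile assigns 0, 1 or *unspecified* to each node
(typically from baseline biomarker annotation of proliferating cells).
With `m` specified nodes and `n` fixed points, fitness is

```
fitness = sum_i sum_j 1[fix_ij == ss_j] / (m * n)
```

the fraction of specified entries matched, averaged over all fixed points;
multi-stable models are thereby penalized unless every stable state
matches, and models with no fixed point score 0.

`ga_config()` defaults encode the calibration schedule the platform was
designed around: populations of 20 models, the best 3 selected per
generation, 3 link-operator mutation draws per offspring, a burst factor of
1000, halting at min-top-3 fitness 0.99 or 20 generations, and 50
independent evolutions pooling `3 × 50 = 150` models. Topology mode
blacklists/whitelists PKN edges instead (50 mutations per offspring during
the burst, 10 after), always preserving at least one regulator per target.

Choices the schedule leaves open, fixed here as package behavior:

* **Crossover** is uniform per equation (each equation independently from
  either of two parents drawn with replacement — a parent drawn twice
  reproduces asexually). Single-point crossover is available via
  `crossover = "single-point"`.
* **Elitism**: the selected parents re-enter the next generation's scored
  pool, so the kept minimum fitness never regresses (`elitism = FALSE`
  restores pure generational replacement).
* **Ties** in fitness break by model creation order (older first), making
  selection deterministic.
* **Burst exit** is population-wide and permanent: the burst ends in the
  first generation in which *any* population member has a fixed point.
* **Burst parity**: mutation draws flip equations with replacement, so an
  even burst budget (3 × 1000) can only reach parameterizations differing
  from the start model in an *even* number of operators. One extra
  coin-flip mutation per burst offspring removes this parity invariant, so
  the burst phase samples all `2^n` parameterizations near-uniformly (the
  test suite checks this with a chi-square test).
* **Reproducibility**: evolution `e` runs on seed `seed + e`, so
  evolutions are independently reproducible and the whole run is
  deterministic under the master seed.
* **Restored operators**: when a topology mutation empties one regulator
  class the link operator becomes `NONE`; if the class refills later the
  equation's last-used operator is restored (AND-NOT if never mutated).
  The alternative — always resetting to the default — is not remembered by
  any published description; remembering the last operator makes
  removal/restore an exact inverse.

## Simulation and synergy

A drug clamps its target nodes to 0 (inhibitor) or 1 (activator). For each
perturbed model, the global output "growth" is the weighted sum of output
node states (positive weights for pro-survival outputs, negative for
anti-survival), scaled affinely to `[0, 1]` by the theoretical minimum and
maximum of the weighted sum, and averaged over the model's fixed points
(uniform weighting; the scaling is affine, so scaling and averaging
commute). For example, with outputs weighted +1 and −1 and both nodes
active, the raw output 0 in the range `[−1, 1]` scales to growth 0.5.

Growth is undefined for a model without fixed points; such models are
*excluded* from the ensemble mean for that perturbation (and counted),
rather than scored 0 — a non-converging model is not evidence of cell
death. The ensemble responds with the arithmetic mean of member growths
(ensemble-level aggregation, before synergy scoring).

Synergy per pair uses the Bliss-independence decomposition
`E(a,b) = A(a,b) + S(a,b)` with `A(a,b) = growth(a) · growth(b)` and
excess `S = E − A`; `S < 0` is called synergy, `S > 0` antagonism.
Normalization compares each pair's excess to that of a *baseline* ensemble
trained to a random-yet-proliferative phenotype (all anti-survival outputs
0, at least one pro-survival output 1, one fresh draw per evolution):

```
normalized = exp(S_calibrated − S_random)
```

Values below 1 lean synergistic; ranking for ROC/PR uses the normalized
score ascending.

## Benchmarking conventions

* ROC AUC is computed by the rank-sum (Mann–Whitney) identity with tied
  scores receiving average ranks — identical to trapezoidal integration of
  the ROC curve.
* PR AUC is average precision (step-wise; linear PR interpolation is
  known-biased), computed tie-aware: all items sharing a score form one
  threshold block and each positive contributes the block-end precision.
  The PR baseline of an uninformative ranker is the prevalence
  `n_pos/(n_pos + n_neg)`, and a constant-score ranker attains exactly
  that value. Note a statistical subtlety the test suite pins down: the
  *mean* average precision of continuous random scores overshoots the
  prevalence when positives are very few (at 6 positives of 153 the mean
  is ≈ 0.068 against a baseline of 0.039), so random-classifier baselines
  are quoted as the prevalence, not as an average over random-score draws.
* The bootstrap AUC comparison is paired and stratified (positives and
  negatives resampled separately, so no resample is degenerate) and
  reports the one-sided `p = P[AUC(A) ≤ AUC(B)]` for ROC and PR
  separately.
* The agreement statistic reports, per link-operator node, the percentage
  of (model, fixed point) observations where OR-NOT co-occurs with state 1
  or AND-NOT with state 0.

## The synthetic laboratory

`generate_planted_system()` builds a fully self-contained test bed: a
random signed digraph (every node receives at least one edge; defaults 15
nodes, 25 edges — desk-scale counterparts of curated networks an order of
magnitude larger), a planted *truth* parameterization redrawn until it has
a stable state, a calibration profile read off that verified fixed point
(default 20% of entries masked as unspecified), outputs split into
positive and negative weights, a panel of single-target inhibitors, and
gold-standard labels computed by exhaustively simulating every pair on the
truth model (`S < 0` strictly; pairs with undefined growth are labeled
negative and flagged).

Two constructive guarantees are worth spelling out:

* The truth model is required to have a *unique* fixed point by default,
  so the planted profile identifies the planted parameterization and
  recovery experiments are well-posed.
* Gold labels come from a single deterministic model, and most random
  (system, outputs, panel) draws contain no strictly synergistic pair; the
  generator therefore searches jointly over systems, output choices and
  drug panels until the gold standard contains at least one positive and
  one negative label — without both classes a benchmark is undefined.

What the generator does *not* emulate: scale-free or biologically motivated
degree distributions, pathway structure, literature-curation noise, or
partial drug efficacy. Passing tests on planted systems therefore
demonstrate the machinery's correctness and the recoverability of planted
signal — not predictive performance on real cell-line data.

`corrupt_profile()` flips exactly `round(fraction · m)` specified entries
(an involution at fraction 1). `scramble_topology()` modifies
`round(fraction · |E|)` edges: source/target scrambling is implemented as
pairwise exchanges between edges, which preserves node set, edge count and
per-node degrees (hence self-containedness) in every mode; a positive
self-loop repair for orphaned nodes is kept as a guarded fallback.
Duplicate edges arising from swaps are retained so the edge count is
preserved; they collapse at model assembly.

`degradation_experiment()` sweeps a fraction grid with replicate seeds
derived only from the replicate index, so the fraction-0 cell reproduces
the clean benchmark exactly. For profile corruption the baseline ensemble
is shared across fractions (the network is unchanged); for topology modes
it is retrained per scrambled network so normalization mirrors the
calibrated pipeline.

## Problem sizes used by the test suite

The packaged tests and acceptance checks run at deliberately desk-scale
sizes chosen as the smallest systems that exercise every code path with
non-trivial signal: solver-vs-oracle equivalence on 200 random models of
4–12 nodes; parameter recovery on a 20-node, 34-edge planted system with
the full 50-evolution schedule; degradation and scrambling on the default
15-node system with a reduced schedule (population 12, 8 generations, 4
evolutions, 10 replicates). The qualitative outcomes — recovery of planted
operators, monotone loss of PR AUC under profile corruption, collapse of
ROC AUC to the random floor under full topology scrambling — are the
package-scale analogues of the corresponding full-scale experiments.

## Known limitations

* Only the standardized link-operator family is expressible — no nested
  Boolean expressions, XOR, or threshold rules — and only fixed points are
  analyzed (no trap spaces, no asynchronous state-transition graphs, no
  cycle enumeration).
* Drugs are all-or-nothing node clamps; no dose–response surfaces, partial
  inhibition, or Loewe/HSA reference models.
* The GA optimizes a single objective (stable-state match); there is no
  multi-objective or annealing variant.
* SBML-qual/GINsim/BoolNet import-export is not provided; the on-disk
  formats are the tab-delimited dialects documented in the reader
  functions.
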