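---
title: "Methods: scoring metabolic-model essentiality predictions against mutant fitness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring metabolic-model essentiality predictions against mutant fitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models, parameters and design
choices. It states no empirical numbers beyond what the test suite and
`scripts/acceptance.R` compute.

## The simulation model

A metabolic model is a stoichiometric matrix $S$ (metabolites × reactions),
flux bounds $l \le v \le u$ in mmol/(gdw·h), and Boolean
gene–protein–reaction (GPR) rules. Flux balance analysis solves

$$\max_v \; v_{\text{bio}} \quad \text{s.t.} \quad S v = 0,\; l \le v \le u,$$

and the growth call is $v_{\text{bio}} \ge c$ with $c = 0.001$ 1/h by
default. The cutoff is compared inclusively, so a biomass flux exactly at
the cutoff counts as growth. A gene knockout zeroes both bounds of every
reaction whose GPR evaluates FALSE with the knocked-out genes FALSE and all
others TRUE; zeroing rather than deleting keeps the reaction index stable
across simulations, which the flux-matrix stage requires. Knockout LPs that
become infeasible are recorded as biomass 0 / no-growth rather than errors:
an infeasible program is the model's way of saying the mutant cannot
satisfy its constraints.

Parsimonious FBA re-solves with the biomass flux pinned at its optimum and
minimizes $\sum_i |v_i|$ by splitting each reaction into non-negative
forward and reverse parts. Direction variables are created only where the
bounds allow the direction, which keeps the second-stage LP near size $n$
for largely irreversible networks.

### The LP solver

No linear-programming package is available in the package's dependency
environment, so the solver is part of the package: a dense two-phase primal
simplex with explicit bounded variables (nonbasic variables sit at either
bound), Dantzig pricing with a Bland's-rule fallback against cycling,
periodic basis refactorization, and a $10^{-9}$ pivot tolerance. Every
optimum the tests rely on is cross-checked against an independent
vertex-enumeration oracle (fix $n - \mathrm{rank}(S)$ variables at bounds,
solve the rest, take the best feasible vertex) on hundreds of random
networks with at most 8 reactions; agreement is required to $10^{-6}$. The
solver requires finite bounds on all variables — metabolic models use
±1000 as "unbounded" by convention — and an unbounded objective is
reported as an error naming a culprit column, since it indicates a missing
bound rather than a meaningful optimum.

## Environments and corrections

A medium closes every exchange reaction (lower bound 0), opens the listed
non-carbon components to −1000, and opens the carbon source's exchange to
−10. When the carbon source collides with a base component the carbon bound
wins, because carbon limitation is the experimentally meaningful
constraint. Exchange reactions are recognized as single-metabolite
reactions on the extracellular side (or with the conventional `EX_`
prefix); the restriction to the boundary side matters because the package
also supports forced intracellular drains that must not be mistaken for
exchanges.

The three correction classes mirror the recurring failure modes of
genome-scale models evaluated against pooled fitness assays:

- **Supplements.** Vitamins and cofactors present in the assay medium or
  carried over from rich pre-culture mask biosynthesis knockouts.
  Extracellular mode opens the existing exchange to −1000; intracellular
  mode creates a new uptake-only exchange, bounds (−1000, 0), directly on
  the cytoplasmic species. Uptake-only is deliberate: a reversible
  artificial exchange would let the model earn parsimony or yield credit by
  secreting the supplement. The upper bound of 0 is a design choice the
  data cannot pin down; it is the conservative end.
- **Irreversibilization.** A reaction whose reverse direction does not
  operate in vivo can rescue a biosynthesis pathway in silico. The fix sets
  the lower bound to 0 and leaves everything else alone. An
  already-irreversible reaction is untouched (the operation never relaxes a
  positive lower bound).
- **Isoenzyme reassignment.** An OR-partner that is regulatorily silent
  under the assay conditions rescues knockouts in silico. The fix rewrites
  the reaction's GPR to the single responsible gene.

Scenario application orders the edits (strain gene removal, isoenzyme
reassignment, irreversibilization, medium, supplements, fixed fluxes); the
edits are independent, and applying a scenario twice yields an identical
model — re-application intentionally re-opens supplement uptakes that the
medium reset closed. Strain gene removal deletes orphaned reactions
outright (a permanent strain difference) whereas knockouts zero bounds (a
per-simulation perturbation).

Unconditionally essential genes — those whose knockout abolishes growth
even with every exchange opened to −1000 — are excluded from
condition-specific evaluation by default, because pooled transposon assays
cannot phenotype genes that never tolerate insertion.

## Evaluation

The positive class is simulated essentiality (model no-growth) and the
sliding score is the fitness value: at threshold $t$ an experiment is
called experimentally essential when fitness $\le t$ (ties on the
inclusive side; for continuous fitness the choice is immaterial to the
area). Thresholds enumerate the unique fitness values; precision is the
fraction of called experiments that the model predicts essential, recall
the fraction of model-essential experiments called. The area is integrated
by trapezoid with the conventional (recall 0, precision 1) anchor.
Undefined metrics (no model-essential rows, or an empty class) are NaN with
a warning, never a silent 0.

The fixed-threshold metrics (confusion matrix, balanced and overall
accuracy) label an experiment as experimental no-growth when fitness is
strictly below −2, matching the labeling rule of the misprediction
classifier. Null padding appends nonfunctional-gene rows (fitness exactly
0, predicted growth) up to a target experiment count; the tests assert the
defining robustness property — padding moves the overall and balanced
accuracies more than it moves the PR-AUC.

## Network distance

The model becomes a bipartite graph with one node per metabolite and per
reaction and an edge for every nonzero stoichiometric coefficient. Nodes
with more than 50 connections (currency metabolites, the biomass reaction)
are removed, except nodes in a keep list — a carbon source must survive
even when it is a hub, so the carbon metabolites under analysis are always
kept. All edges have unit weight, so shortest paths are breadth-first
search. The distance from a carbon source to a gene is reported as the
number of reactions traversed *before* the nearest reaction the gene's
knockout removes: a metabolite-to-reaction path of $2k+1$ edges contains
$k+1$ reaction nodes and is reported as $k$, which makes a reaction
directly consuming the carbon metabolite distance 0. Unreachable genes are
excluded from subset means rather than assigned a sentinel that would skew
them. Experiments enter the distance table only when the gene disrupts at
least one reaction; a lone member of an isoenzyme OR pair disrupts nothing
and is absent. The carbon-specific no-growth subset keeps no-growth
experiments of genes that show no-growth in at most 80% of their carbons.

## Flux-space analysis

Growth-predicted knockouts (and per-carbon wild types) contribute their
parsimonious flux vectors to a samples × reactions matrix. Columns with
variance below $10^{-7}$ are dropped; the rest are clustered by
single-linkage connected components over $|r| > 0.99$ Pearson correlation.
The absolute value is deliberate — a reaction and an exactly
counter-running partner covary perfectly — and the cluster representative
is the lowest-index column, a deterministic rule where any member would do.

The classifier labels growth-predicted samples as false positives when
fitness is strictly below −2 (a −1 sensitivity run is a parameter change;
the tests assert the feature-importance rankings are rank-correlated above
0.8 across the two thresholds). It is a gradient-boosted tree ensemble:
100 trees, at most 5 leaves per tree, learning rate 0.1, no subsampling,
single-threaded and seeded for determinism. Train/test splits draw a
uniform random 80% of carbons and 80% of genes (floor rounding, minimum 1);
training rows need both, the full test set is everything else, and the
unseen test set is the subset whose gene and carbon both never appear in
training. The 100-split harness uses split seeds 0–99.

Shapley attribution uses the exact tree-path algorithm with node covers as
background weights. Two engines implement it: the booster's built-in
contribution pass (fast, single-precision output) drives the 100-split
averages, and a double-precision re-evaluation from the dumped tree
structure backs the additivity guarantee — bias plus per-feature
contributions reconstruct each sample's margin to round-off. The engines
are cross-checked against each other at single-precision tolerance; inputs
are rounded to single precision before tree traversal so that
threshold-adjacent samples route exactly as the booster routes them.
Attributions are reported for the true-positive class (the negated
false-positive contributions), and features are ranked by mean absolute
Shapley value per split and on the split average.

The permuted baseline re-scores the full test set against permuted labels.
Its split-mean is compared with the false-positive base rate against twice
the binomial standard error of that base rate at the test-set size — the
appropriate yardstick because each test set's positive count is a binomial
draw, while the trapezoidal PR-AUC of an uninformative ranking carries a
small positive finite-sample offset that vanishes only slowly with size.

## The synthetic study conditions

The toy-GEM generator builds, per carbon source, an exchange, a
gene-bearing transporter and a linear catabolic chain into a shared central
metabolite, so catabolic knockouts are essential exactly on their own
carbon. Onto this it grafts the three error motifs: vitamin biosynthesis
chains whose product is a biomass precursor, importable through an
exchange-plus-transporter pair (knockouts are model-essential everywhere
but experimentally silent — the carry-over false negatives); isoenzyme OR
pairs on the central pathway whose second member is regulatorily silent
(experimentally essential, model-rescued false positives); and a
reversible bypass that rescues a two-gene biosynthesis pathway only when
run backwards. Yield motifs — an efficient route beside a wasteful
(higher-carbon) alternative — give knockouts that lower the growth yield
instead of abolishing growth. Ground truth is written down constructively
and then verified by exhaustive single-knockout FBA on every carbon;
generation fails rather than returning an inconsistent fixture.

Fitness values are Normal(−4, 0.5) for experimentally essential
gene–carbon pairs and Normal(0, 0.5) otherwise, in duplicate, seeded. Real
fitness distributions are heavy-tailed; a Gaussian with class-dependent
means is enough here because every statistic the package computes from
fitness is ordinal in the scores. That is also the main caveat: passing
tests on these conditions demonstrates the machinery, not the noise
robustness or identifier-matching mess of real assay data.

Default sizes are chosen so exhaustive oracles run in seconds: 6 carbons ×
3 chain genes (≈ 50 reactions, 37 genes) for the evaluation and distance
fixtures. The flux-profiling fixture is larger (10 carbons × 5 chain
genes) and switches on a per-gene "expression burden": a small forced
drain on the freely available nutrient, removed by the gene's knockout, so
every knockout's flux vector is distinct — mirroring the fact that real
parsimonious flux profiles never tie exactly, and preventing degenerate
tied-score precision–recall artifacts in the unseen-carbon/gene
cross-validation. The planted-signal experiments attach false-positive
labels through a logistic link on the total-nutrient-uptake flux (slope 3
per standard deviation, base rate 0.3), with per-carbon log-odds offsets of
standard deviation 2 when a carbon-specific component is wanted.

## Numerical choices and limitations

- LP tolerances: $10^{-9}$ pivots, $10^{-6}$ equality assertions in tests;
  fluxes are clamped to bounds after solving to absorb round-off.
- Wild-type solution reuse: when a knockout disables only reactions that
  carry zero flux in the wild-type parsimonious solution, that solution is
  reused unchanged — the shrunken feasible set still contains it and the
  optimum cannot improve. With per-gene burden reactions enabled this
  shortcut never fires, and grids cost one LP per knockout.
- The SBML reader covers Level 3 with flux-bound and GPR (fbc)
  annotations — enough for constraint-based models from the standard
  repositories — and is not a general SBML validator. The JSON dialect
  mirrors the common constraint-based schema and round-trips exactly.
- Carbon-source matching uses the deterministic `X -> X_e` rule with a
  user-supplied override map for irregular names; real datasets matched by
  hand need that map.
- Missing fitness values are dropped and counted, never imputed.
- Genome-scale models run through the same code paths but the dense
  simplex makes them slow; the package's validated scale is the synthetic
  fixture tier.
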