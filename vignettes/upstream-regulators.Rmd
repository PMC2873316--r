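---
title: "Inferring upstream regulators from network topology: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring upstream regulators from network topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netreg)
```

## The model

`netreg` treats a curated interactome as a signed, directed multigraph.
Nodes carry a class (`ligand`, `receptor`, `kinase`,
`transcription_factor`, `generic`); interactions carry an effect
(`activation`, `inhibition`, `unspecified`) and a mechanism
(`transcription_regulation` or `other`). Two counting conventions anchor
everything:

* the universe size `N` is the number of **stored interaction records**
  (parallel edges that differ in sign or mechanism count separately;
  `network_counts()` also reports the unique-pair count so users can
  compare conventions);
* a node's degree counts each stored record once, incoming plus outgoing,
  so that summed degree equals `2N`.

Undirected facts (e.g. complex binding) must be encoded as two reciprocal
records; the package never guesses directionality.

### Overconnectivity

A node `v` with degree `R`, of whose interactions `r` touch the gene set of
interest, is compared against drawing `R` records at random from the `N` in
the database, of which `n` — the summed degree of the set members — touch
the set. The p-value is the hypergeometric tail `P(X >= r)`. Two
subtleties:

* when the set has internal interactions, the summed member degree counts
  them twice and can in principle exceed `N`; the population parameter is
  then capped at `N` (flagged in the parameter list). The permutation-null
  acceptance test uses gene sets without internal edges, where the analytic
  model is exact in distribution.
* when `v` itself belongs to the set its own degree stays inside `n` by
  default (the literal parameter definitions); the
  `exclude_self_from_population` flag implements the alternative.

### Hidden nodes

The multi-step statistic scores candidates by their presence on
*transcription-activation shortest paths*: directed simple paths of at most
`max_len` hops (default 6) whose final edge is a transcription-regulation
edge leaving a transcription-factor node, and whose number of inhibitory
edges has even parity, i.e. net activation. For every ordered
(source, target) pair *all* minimal-hop admissible paths are enumerated;
paths are edge sequences, so parallel edges of different sign are distinct
paths and the parity predicate stays well-defined. The index stores, per
node, the number of paths containing it (source and terminal target
included), per terminal target, and in total; the same hypergeometric tail
is applied to (paths containing `v` and ending in the set, paths ending in
the set, paths containing `v`, all paths).

Design choices worth knowing:

* **Parity default.** Net activation requires an *even* number of
  inhibitory steps; the package defaults to `parity = "even"` and keeps
  `parity = "odd"` available, because the two readings ("activating
  effect" vs "uneven number of inhibiting interactions") conflict and the
  intent — activation — wins.
* Edges with effect `unspecified` count as non-inhibiting by default;
  `exclude_unspecified = TRUE` removes them from admissible paths
  entirely.
* "Preferred" paths in commercial tools rely on curation metadata that
  does not exist outside them; enumerating *all* admissible shortest paths
  per pair is the reproducible substitute.
* `max_len = 6` caps enumeration cost; regulatory cascades of interest
  (ligand → receptor → kinases → TF → target) fit comfortably within it.
* The enumerator (C++) works backwards from each terminal
  transcription-regulation edge, so every prefix of a partial path is
  itself a candidate path from its own source; an R brute-force enumerator
  over all simple paths, kept in the test suite, provides the independent
  oracle on networks of up to 12 nodes.

### Rank aggregation

The two topology rankings (truncated to their top `k = 20`) are merged into
one ordered list of size `k` minimizing the summed weighted Spearman
footrule distance. An element absent from a list takes rank `k + 1`.
Element importance comes from its position in the *reference* list:
`w(j) = 1 - (j - 1)/(k + 1)` for positions `1..k+1`, a linear decay that
keeps even absent elements at positive weight (so disagreements beyond the
list tail still cost); `scheme = "uniform"` gives the plain footrule. The
weights are position-based rather than raw p-value-based because the
topology p-values span hundreds of orders of magnitude, which would let a
single extreme entry dominate the objective.

The optimizer is a genetic algorithm over ordered k-subsets of the
candidate union: population 100 seeded with every input list, tournament
selection, order-preserving crossover (rate 0.8), point mutation swapping a
member against an outside element (rate 0.05), elitism of one, and stop
after 500 generations or 50 without improvement. These hyperparameters are
conventional defaults for this method family — the source procedure does
not state its own — and all are configurable. Input lists are canonicalized
before seeding so the result is invariant to the order in which lists are
supplied; with a fixed seed the run is bit-reproducible. On small universes
the GA provably reaches the exhaustive optimum in ≥ 95% of seeded runs
(acceptance criterion 5).

### Subnetworks

Two constructions, both scored by hypergeometric enrichment of the gene set
over the *node* universe and sorted ascending by p (ties: larger overlap,
then seed id):

* **Receptor series** — for each receptor whose ligand is in the set: all
  directed shortest paths (≤ `max_len` hops) to every TF that directly
  transcriptionally regulates the set, plus those TFs' set-member targets.
  Paths here are not sign-constrained (parity applies only to the
  hidden-nodes statistic), though a parity filter is available.
* **TF expansion** — greedy growth around a TF to a fixed size (default
  50 nodes). The growth priority — set members first, then most links into
  the current subnetwork, then lexicographic id — is an invented,
  deterministic rule: the original "gradually expands" heuristic is
  proprietary and unknowable, and reproducibility was preferred over
  fidelity to it.

### Common TFs and receptor classification

For each data type (transcriptomics DE set, proteomics set) the package
computes both rankings over all TF nodes, aggregates them to `k = 20`, and
intersects the aggregated lists across data types. Aggregation is wired
*per data type, across the two topology methods* (the alternative wiring is
available by calling `aggregate_rankings()` directly). Seeds of the top
TF-expansion subnetworks (per data type, pooled) supplement the
intersection.

Receptors ranked by the hidden-nodes statistic are then filtered:
`hidden_p < 0.05`; own gene or at least one ligand (ligand-class
in-neighbour) overexpressed more than 2.5-fold at the DE q-threshold;
and pathway co-membership with a common TF, operationalized as directed
reachability within `max_len` hops — deliberately permissive, matching the
observation that this criterion should rarely reject anything. Categories
(`receptor_only` / `ligand_only` / `both`) partition the retained set, and
retention is monotone in both cut-offs.

## The differential-expression stage

Intensities are normalized by the per-sample median (every column ends at
median 1), which also removes sample-wide pair effects. The default test is
the standard paired test — a one-sample t-test on per-pair log2 differences
— because "paired Welch" is self-contradictory (Welch's test is unpaired by
definition) and the pairing of lesional with non-lesional biopsies from the
same patient is the design's point; `method = "unpaired_welch"` preserves
the literal alternative. P-values are Benjamini–Hochberg adjusted. The fold
change is the ratio of group means on the normalized linear scale
(`fc_method = "mean_of_ratios"` is the alternative); a gene passes with
fold change strictly above 2.5 *and* q strictly below 0.01. Only
overexpression propagates by default (`direction = "both"` exists); genes
identical in every pair get p = 1; a zero denominator mean yields an `Inf`
fold change with a logged warning, never a silent pass.

## The synthetic world

`simulation_config()` describes the benchmark scenario the package is
validated on: 200 nodes (10% ligands, 15% receptors, 20% kinases, 15% TFs,
40% generic), about 2.5 background edges per node, 20% inhibitory edges, a
planted cascade of 2 ligands → 2 receptors → 2 kinases → 2 TFs → 20 targets,
28 sample pairs, planted target overexpression of mean 2 on the log2 scale
(sd 0.25, clamped above 1), and log2 measurement noise of sd 0.5. Baseline
intensities are log-normal (meanlog log 100, sdlog 1); a pair-level effect
(sd 0.1 log2) emulates array-scale variation and is removed by median
normalization. Where the benchmark scenario fixes a value (node count,
planted counts, pairs, effect size, noise) it is used verbatim; the
remaining defaults are one-time choices of what a curated signalling
network and Affymetrix-era intensities plausibly look like.

Generator design, and why it is shaped this way:

* the background graph is sampled *first* (preferential attachment within
  class-compatibility rules: ligand→receptor, receptor/kinase→kinase/TF,
  TF→generic by transcription regulation) and the planted nodes are chosen
  uniformly afterwards — planting before sampling would let preferential
  attachment turn the cascade into the network's hub system and make
  recovery trivially confounded;
* the cascade is wired bipartitely (every receptor to every planted kinase,
  every kinase to every planted TF), mirroring the redundancy of real
  signalling modules and giving each planted regulator multiple admissible
  routes to every target;
* planted receptors signal *exclusively* through the cascade (their
  background out-edges are removed). This emulates receptors whose
  downstream wiring is their canonical adaptor pathway. Without it the
  planted receptors' path profiles are dominated by arbitrary background
  descendants and the hidden-nodes statistic — correctly — ranks them as
  unremarkable: the benchmark would then measure the background topology,
  not the method.

What a green recovery test establishes: that the pipeline recovers planted
regulators in a world where the cascade is the dominant regulatory program
for its targets. What it does not establish: performance on a real curated
interactome (orders of magnitude larger, with confidence-weighted and
redundant edges), robustness to annotation errors, or any biological claim
about a particular disease.

## Numerical and degenerate-input policy

* `P(X >= r)` is computed by `phyper(r - 1, n, N - n, R, lower.tail =
  FALSE)` and checked against exhaustive enumeration of all `C(N, R)`
  draws for every valid parameter set with `N <= 12` (absolute error
  < 1e-12).
* Isolated candidates (`R = 0`) get p = 1 with a diagnostic attribute; a
  node on no admissible path gets p = 1; an empty path index warns and
  returns p = 1 everywhere.
* Ranked lists break p-value ties by larger `r`, then lexicographic node
  id — rankings, greedy expansions and the GA are fully deterministic given
  a seed, which is what makes the end-to-end byte-identity criterion
  testable.
* Empty gene sets, empty candidate sets, networks with zero interactions,
  fewer than two sample pairs, non-positive sample medians and malformed
  input files all raise typed errors (`netreg_validation_error`,
  `netreg_parse_error`, `netreg_io_error`, `netreg_lookup_error`) rather
  than propagating NaN.

## Known limitations

* The hidden-nodes statistic treats paths as exchangeable draws; paths
  sharing edges are correlated, so its p-values are enrichment scores, not
  calibrated tail probabilities — ranks are meaningful, absolute values
  less so. The same caveat applies to the overconnectivity population when
  a set has internal edges (see the capping rule above).
* Path enumeration is exponential in the worst case; `max_len` bounds it,
  but very dense networks (mean degree far above the benchmark's ~2.7)
  may need a smaller cap.
* No confidence weighting of interactions and no probe-to-gene mapping
  layer: node identifiers are opaque strings, and expression rows must
  already be keyed by them.
* The aggregation weights and GA hyperparameters are method-family
  conventions, not fitted quantities.
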