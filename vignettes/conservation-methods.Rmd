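---
title: "Methods: comparing the evolutionary conservation of gene sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing the evolutionary conservation of gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consurvey)
```

## The question and the procedure

`consurvey` asks whether one gene set is more evolutionarily conserved
than another — canonically, whether human drug-target genes are more
conserved than genes sharing no protein-domain family with any target.
Conservation is measured on two levels:

1. **Per-species evolutionary features** over a 21-species vertebrate
   panel: the evolutionary rate ω = dN/dS of one-to-one orthologs, a
   protein **conservation score** (the optimal local-alignment score of
   the human protein against its species ortholog), and the **ortholog
   percentage** (the fraction of the gene set with a one-to-one ortholog
   in that species).
2. **Network topology** in a human protein–protein interaction network:
   degree, local clustering coefficient, normalized betweenness
   centrality, and per-node average shortest path length (ASPL).

The comparison is two-level. Within each species, the two gene sets'
feature values are compared with a Wilcoxon rank-sum test, and each
group is summarised by median and quartiles. Across species, the 21
paired per-species medians (one pair per species) are compared with a
Wilcoxon signed-rank test. Network metrics are compared once, by
rank-sum tests on the node values of the two sets.

## The control set

Non-targets are derived by family exclusion (`derive_nontargets()`):
starting from a gene → Pfam-family map, every family containing a
target gene is removed wholesale, and the remaining genes — those
sharing *no* family with *any* target — form the control set. Two
points were left open by the procedure this implements and are resolved
here as package policy:

* exclusion is at the *family* level, not the clan (super-family)
  level, and one shared family suffices for exclusion;
* genes with no family annotation are **ineligible** as non-targets:
  their domain dissimilarity cannot be certified. This is the
  conservative choice; it shrinks the control set rather than risking
  contamination.

## Evolutionary rate

Rates are consumed from a BioMart-style ortholog table, not computed
from codon alignments. `evolutionary_rates()` keeps exactly the
one-to-one ortholog records with both dN and dS present, and
additionally requires dS > 0 because ω = dN/dS is undefined there
(dN = 0 with dS > 0 yields ω = 0 and is kept). Exclusion counts by
reason (no record, wrong homology type, missing value, dS = 0) are
attached to the result so filtering is auditable.

The ortholog-percentage denominator is the **full gene set**, not the
subset with orthology data: a gene with no record counts against the
percentage. The alternative (annotated-subset denominator) conflates
ortholog absence with annotation absence; with the full-set convention
the statistic estimates the probability that a set member has a
one-to-one ortholog, which is what the synthetic generator plants.

## Conservation score

The score is the raw optimal **Smith–Waterman local-alignment score**
under BLOSUM62 with affine gaps, computed exactly (Gotoh dynamic
program, in C++). This replaces heuristic BLASTP scoring: it is
deterministic, oracle-verifiable, and by construction never below the
BLAST raw score for the same pair — a systematic, documented difference
from scores obtained with BLASTP. The raw (not bit) score is used; the
published per-species score tables have magnitudes of hundreds to
~1300, consistent with raw scores of proteins a few hundred residues
long.

Numerical conventions:

* gap penalties default to the BLASTP defaults for BLOSUM62, open 11 /
  extend 1, with a gap of length L costing 11 + L (so 12 for a
  length-1 gap);
* the unknown residue X scores 0 against every standard residue and −1
  against X. This keeps self-scores of X-free sequences exact while
  penalising runs of unknowns;
* the empty alignment is admissible, so scores are never negative.

## Network topology

The network is an undirected simple graph (self-loops and duplicate
pairs dropped at load). Metrics follow the standard node-level
definitions:

* degree `k`;
* clustering coefficient `2 e_v / (k (k − 1))`, 0 when `k < 2`, with
  `e_v` the edge count among the `k` neighbours;
* betweenness `B_v = Σ_{i≠j≠v} σ_ivj / σ_ij / ((n − 1)(n − 2))`,
  computed by Brandes' algorithm. The sum runs over **ordered** pairs,
  matching the `(n − 1)(n − 2)` normalisation (each unordered pair is
  counted twice; star centres score exactly 1). The whole-graph `n` is
  used even on disconnected graphs — the formula has a single `n` —
  and unreachable pairs contribute 0;
* ASPL: the mean hop distance from a node to every node *reachable*
  from it, undefined (`NA`, excluded from comparisons) for isolated
  nodes. A looser reading — "the average length of shortest paths
  passing through the node" — would make ASPL a second
  betweenness-flavoured quantity; the distance-to-others definition is
  the standard Cytoscape node metric and is the one that measures how
  tightly a node is connected, so it is what `avg_shortest_path()`
  implements.

## The Wilcoxon machinery

`rank_sum_test()` and `signed_rank_test()` expose exact and
normal-approximation modes with explicit continuity- and
tie-correction flags, because the cross-species result is sensitive to
the exact variant:

* with 21 paired medians all favouring the same group and tie-free
  absolute differences, the **exact** two-sided signed-rank p is the
  closed form `2^(1−21) ≈ 9.54e-07`;
* the **normal approximation with continuity correction and no tie
  correction** gives `≈ 6.41e-05` for the same configuration — the
  variant that reproduces the published cross-species dN/dS value from
  the published median table, and therefore the pipeline default for
  per-species-median tests (`compare_feature()`);
* the published conservation-score p (6.40e-05) differs from the dN/dS
  one (6.41e-05) in the third digit although both tables are unanimous
  in direction, which forces identical signed-rank statistics. The
  printed medians contain tied absolute differences, and the
  tie-corrected variant gives 6.35e-05: the published value sits
  between the corrected and uncorrected variants, consistent with a
  tie correction applied to unrounded medians. It cannot be exactly
  reproduced from the rounded table; the package reproduces it to
  within 1%.

Exact modes evaluate the full enumeration distributions
(`C(n+m, n)` labelings; `2^n` sign assignments) via polynomial
convolution. Under ties the exact distribution is computed
*conditionally on the observed midrank multiset* (using doubled
midranks to keep statistics integral) rather than refusing to run:
the paired ortholog percentages live on a 1/n grid and do tie in
practice, and the conditional distribution is the standard resolution
(it leaves the all-same-sign closed form unchanged). `method = "auto"`
still resolves tied data to the normal approximation. Zero paired
differences are dropped (Wilcoxon's original treatment; the Pratt
variant is not implemented), two-sided p-values are twice the smaller
tail, capped at 1, and fully tied two-sample data hit a zero-variance
guard returning p = 1.

The normal approximation is a central-range tool: in seeded sweeps its
p agrees with the exact p to within a few percent whenever the exact p
is not in the extreme tail (p ≥ 0.05), but relative agreement degrades
in the far tail, which is why the cross-species default is fixed by
the reproduction argument above rather than by asymptotic accuracy.

## The synthetic study generator

No accession-resolvable inputs are available, so `simulate_study()`
generates a complete study with planted group effects; its defaults
*are* the reference conditions used throughout the tests:

| parameter | default | meaning |
|---|---|---|
| `n_targets` / `n_nontargets` | 300 / 900 | genes per group |
| `species` | 21-code panel | per-species features |
| `omega_logmean_*` | log 0.10 / log 0.13 | group median ω |
| `omega_logsd` | 0.9 | log-scale ω spread |
| `ortholog_prob_*` | 0.9 / 0.75 | one-to-one presence |
| `one2many_prob` | 0.05 | decoy homology records |
| `missing_rate` | 0.02 | blanked dN/dS fields |
| `ds_logmean`, `ds_logsd` | log 0.3, 0.5 | synonymous rate dS |
| `seq_len_range` | 80–200 aa | protein lengths |
| `divergence_scale` | 1.0 | ω → per-site substitution prob. |
| `degree_weight_*` | 3 / 1 | expected-degree propensities |
| `mean_degree` | 8 | network average degree |
| `triad_prob` | 0.2 | extra triangle per target node |
| `n_families` | 200 | family pool |
| `family_overlap` | 0.1 | non-targets placed in target families |

Rationale for the main choices: ω medians 0.10 vs 0.13 and presence
probabilities 0.9 vs 0.75 mirror the magnitude of published
target/non-target contrasts; `omega_logsd = 0.9` reproduces the
roughly 3–4× quartile ratio seen in published per-species ω
distributions; dS around 0.3 with moderate spread is typical of
human–mammal comparisons; mean degree 8 matches a ~39 k-edge PPI
network over ~10 k proteins.

Construction decisions that make recovery exact or auditable:

* dN is simulated as ω·dS rather than independently, so the extracted
  ratio recovers the planted ω *exactly*;
* substitutions are uniform over the 19 alternative residues, not
  BLOSUM-biased — simpler, and conservation scores still degrade
  monotonically in divergence on average;
* missing values are written as empty TSV fields, exercising the
  non-null filter;
* every sub-generator (orthology, sequences per species, network,
  families) draws from its own RNG stream derived from the master
  seed, so changing the species list does not perturb the network
  draw; identical configurations are byte-identical on disk;
* the network is a Chung–Lu draw (edge probability
  `min(1, w_i w_j / Σw)`) with a triad-closure pass at target nodes to
  raise their clustering.

What the generator does **not** emulate: phylogenetic structure across
the species panel (species are exchangeable draws, with no tree),
codon-level evolution, indels (substitution-only divergence),
BLOSUM-structured substitution preferences, correlated features (in
real data conserved genes are simultaneously slow-evolving, central,
and ortholog-rich for shared biological reasons; here the four effects
are planted independently), and database artefacts such as identifier
mismatches. Passing tests therefore demonstrate that the pipeline
*recovers planted effects of realistic magnitude from cleanly
formatted inputs* — not that real databases would yield the published
numbers.

## Problem sizes and runtime posture

The reference synthetic study uses the full 300/900 × 21-species
orthology grid, network and family map, but restricts the alignment
stage to the first 5 species with protein lengths ≤ 200 — about five
thousand Smith–Waterman problems — which keeps the full study under a
minute while leaving every stage exercised at realistic per-species
sample sizes. Null-calibration sweeps use 100 seeded replicates of the
orthology stage only. Oracle-equivalence tests run the exhaustive
references on small instances: all-pairs path counting on graphs of up
to 25 nodes, exhaustive alignment enumeration for sequences up to
length 5, and full enumeration of the exact test distributions up to
n = 12 (plus the 2^21 sign enumeration for the 21-species case).

## Known limitations

* Smith–Waterman scores are upper bounds on BLASTP raw scores; absolute
  score levels are not comparable across the two pipelines, only the
  group contrast is.
* The cross-species signed-rank test treats species as independent
  paired observations; real species share phylogeny, so its p-value
  overstates independence (a limitation inherited from the design it
  reproduces).
* The per-species rank-sum tests use the normal approximation
  throughout (group sizes in the hundreds); exact per-species tests
  are not offered.
* `derive_nontargets()` requires family annotations; in a sparsely
  annotated proteome the control set may be small, and the package
  errors rather than silently returning an empty set.
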