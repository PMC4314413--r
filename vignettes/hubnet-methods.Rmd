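---
title: "Methods: cross-study signatures, network topology and hub subnetworks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-study signatures, network topology and hub subnetworks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubnet)
```

`hubnet` chains six stages: cross-study gene scoring, signature
selection, interaction-network topology, MCODE clustering, pathway
enrichment, and hub-subnetwork extraction. This vignette records the
model behind each stage, the tunable parameters and their defaults, the
numerical conventions, and what the synthetic benchmark does — and does
not — establish.

## Cross-study scoring model

Each study contributes a gene-by-sample matrix of log2 expression with
case/control labels. After restricting to the genes present in every
study (a gene absent anywhere is removed; the common list is ordered
lexicographically), study *j* ranks genes by |log2FC| where log2FC is
the case-minus-control mean difference on the log2 scale. Rank ties are
broken by the smaller per-study p-value, then by gene id, so ranks are
always a permutation of 1..m and runs are reproducible.

The per-study rank score is s_ij = -2 ln(r_ij / m): zero at the bottom
of the list, about 19.8 for rank 1 among 20,109 genes, and strictly
decreasing in rank. Scores combine across studies as the weighted sum
S_i = sum_j w_j s_ij with nonnegative weights normalised to one. Equal
weights are the default; weights exist so a user can down-weight, say,
cell-line studies against biopsy studies. Because S_i is a convex
combination, it always lies between the per-study extremes, and
improving any one study's rank strictly increases it.

*Why this functional form*: with five equal weights, a combined score of
about 14 corresponds to a geometric-mean rank near 18 out of ~20,000,
which is the regime where top cross-study genes in published
multi-cohort breast-cancer analyses land; the form rewards consistent
top placement rather than a single extreme study.

Significance is meta-analysed with maxP: the combined p-value is the
maximum of the per-study p-values, the conjunction reading of
significance ("significant in every study"). It is used directly as the
combined p, not transformed through its Beta null distribution. The
per-study test is a two-sided Welch t on the log2 values. A moderated
(empirical-Bayes) test would shrink variances at small n; we
deliberately use the plain Welch test to keep the stage dependency-free,
and absolute p-values will therefore differ from pipelines that use
moderated statistics. With 10 samples per group the difference is
immaterial for the strict double filter used downstream.

The signature filter is |mean log2FC| > 2 and maxP < 0.01, both strict,
with the mean log2FC the unweighted arithmetic mean across studies; a
gene sitting exactly on a threshold is excluded. Sign agreement across
studies is reported (the `direction` column) but not enforced.

Probe-level inputs are collapsed to genes by the per-sample maximum over
a gene's probes; multi-mapped probes contribute to every target gene.

## Network topology

The interaction graph is simple and undirected; confidence scores can
gate edge inclusion (`score_cutoff`) but never weight a path — shortest
paths are unweighted throughout, matching the binary-interaction
reading of curated PPI exports. Analyses run on the giant component
(size ties broken by lexicographically smallest member); nodes outside
it get no centrality values rather than zeros, since closeness is
undefined across components.

All four centralities come from one Brandes-style single-source pass
per node, written in this package: betweenness accumulates the standard
pair dependencies; stress accumulates sigma_sv times the count of
shortest-path continuations from v; closeness uses the BFS distance
sums. Stress counts each unordered source–target pair once by default;
`stress_mode = "ordered"` doubles it for comparison with tools that sum
ordered pairs — the published values we checked against do not state
which convention they use, so both are exposed. Betweenness is
normalised by (N-1)(N-2)/2 (graphs with N < 3 get zeros). Endpoints are
never counted as path interiors. Correctness is established against an
exhaustive oracle that enumerates every shortest path on 200 random
graphs, not against another library.

## MCODE

The clustering stage is a complete re-implementation of molecular
complex detection:

* **Vertex weighting.** weight(v) = k(H) × density(H), where H is the
  highest-k k-core of the subgraph induced by the closed neighbourhood
  N[v]. A node with a single neighbour weighs 1; the centre of K5
  weighs 4. Core numbers come from the standard peeling iteration and
  are oracle-checked.
* **Prediction.** Seeds are processed in descending weight (ties by
  node id); nodes with degree < `degree_cutoff` (default 2) never seed.
  From a seed of weight w0, neighbours join breadth-first while their
  weight strictly exceeds (1 − `node_score_cutoff`) × w0, to
  `max_depth`. A node joins at most one complex. With the default
  cutoff 0.3 a complex keeps nodes within 30% of the seed's weight.
* **Filtering and scoring.** Complexes whose maximum internal core
  number is below `k_core` (default 4) are discarded. Scores are
  density × nodes = 2E/(V−1), so a complete graph on n nodes scores n.
* **Post-processing.** Haircut (default on) trims members with fewer
  than two within-complex neighbours; if trimming splits a complex the
  largest piece is kept, so emitted complexes are always connected with
  minimum internal degree 2. Fluff (default off) adds outside
  neighbours whose closed-neighbourhood density strictly exceeds
  `fluff_density_cutoff` and may create overlaps. Published cluster
  tables we compared against do not print complex membership, so the
  haircut/fluff defaults cannot be validated externally; they follow
  the algorithm's reference defaults.

One reading note: descriptions of this parameterisation sometimes say
"degree cutoff = 0.3". MCODE's degree cutoff is an integer; 0.3 is the
node score cutoff, and the package keeps the two parameters distinct
(0.3 and 2 by default).

## Enrichment

Pathways are plain GMT. The test is the EASE score: the one-sided
Fisher exact p-value of the 2×2 overlap table after jackknifing one
gene out of the overlap (a → a−1 with margins preserved), i.e.
P[X ≥ a−1] for X hypergeometric; an overlap of 0 or 1 scores exactly 1.
This penalises single-gene "enrichments" and is always ≥ the plain
Fisher p, which is reported alongside. The default background is the
union of pathway genes, optionally intersected with the analysis
universe; query genes outside it are dropped with a logged count
(mirroring how online annotation tools report unmapped genes). No
multiplicity correction is applied to the tiers — the fixed 0.05/0.01
tiers are the decision rule, and a Benjamini–Hochberg column is emitted
for information only. Tier thresholds are strict: a published table we
bundle as an example lists rows up to p = 0.0868 under a "P<0.05"
header; with strict thresholds those rows fall in no tier, and the
package documents rather than reproduces that discrepancy.

## Group comparison and hub extraction

Cluster and pathway gene sets are summarised by their members' four
centralities. "One-way ANOVA for multiple pairwise comparisons" is
implemented as a per-pair two-group one-way ANOVA — the only reading
under which each pair gets its own p-value — with F identically the
square of the pooled-variance t; an omnibus F across all groups is also
attached. Zero within-group variance with equal means gives p = 1, with
unequal means p = 0. No correction is applied across pairs, matching
the uncorrected three-star convention (0.05 / 0.01 / 1e-4).

The default selection rule mimics the analysis the pipeline is built
for: the cluster with the highest mean degree that is significant in
degree (p < 0.05) against at least one other cluster, plus the
top-tier (p < 0.01) pathways with the highest mean degree, capped at
two. When only one cluster exists there is nothing to compare against,
and the lone cluster is selected (vacuous significance) — without this
the single-planted-clique benchmark could never produce a hub. The hub
subnetwork is the exact intersection of the selected member sets with
its induced edges; pairwise intersections are reported so near-misses
are visible.

## Synthetic benchmark: what it emulates

`sim_config()` defaults state the benchmark world once:

* 5 studies, 1,000 genes, 10 case + 10 control samples per study.
  (Published multi-cohort designs motivating this pipeline pooled ~280
  cases and ~70 controls over five heterogeneous studies; per-study
  sizes are a free choice here and 10+10 keeps the suite fast while
  leaving the Welch test comfortably powered at effect 3.)
* 20 planted differential genes, log2 shift ±3, Gaussian noise sd 0.5.
  At these values the planted |log2FC| exceeds 2 in every study with
  probability > 0.99, so the strict filter should recover the full
  planted set — that is the point of the recovery criterion.
* Background network: preferential attachment (2 edges per node),
  giving the heavy-tailed degree distribution real PPI networks show;
  planted cliques of sizes 8 and 6 whose members are drawn
  preferentially from the planted genes.
* 20 pathways of 10–40 genes; the planted pathway carries 10 planted
  genes, preferring those inside the first clique and then planted
  genes in no clique. The planted pathway emulates the annotation of
  the top complex; letting it straddle two planted cliques would make
  "hub ⊆ clique1 ∩ pathway" unachievable whenever background edges
  bridge the cliques and MCODE (correctly) merges them.
* One master seed; each generator consumes an arithmetically derived
  substream, so adding a generator call never perturbs earlier outputs
  and a run is byte-reproducible.

Deliberately absent: probe-level structure, batch effects,
normalisation artefacts, gene–gene correlation beyond the planted
cliques, and any dependence between expression and network position
beyond the planted overlap. A green recovery suite therefore
establishes that the algorithms are implemented correctly and the
pipeline is wired correctly — not that the method is robust to the
correlated noise, annotation bias and incomplete interactomes of real
cohorts.

## Numerical conventions

* Strict inequalities at every threshold (fold change, p-values,
  enrichment tiers, MCODE inclusion and fluff).
* All orderings are made deterministic: rank ties by p then id, seed
  ties by id, complex ties by seed id, component ties by smallest
  member, top-k ties lexicographic.
* Welch p-values are clamped to (0, 1]; exact-zero-variance equal-mean
  genes get p = 1.
* The EASE jackknife keeps all margins fixed (b = L−a+1, c = K−a+1,
  d = N−K−L+a−1), giving P[X ≥ a−1]; inconsistent margins error.
* Degenerate graphs: betweenness on N < 3 is all zeros; complexes need
  ≥ 2 nodes to score; empty hub intersections are valid, logged
  results.

## Known limitations

* Pure-R Brandes accumulation is O(VE) per graph; fine for
  signature-scale networks (hundreds of nodes), not for
  interactome-scale graphs.
* The Welch replacement for a moderated t changes absolute p-values at
  very small group sizes.
* The group-selection rule is a configurable heuristic; with no
  significant cluster and no p01 pathway the pipeline correctly emits
  no hub rather than guessing.
* Stress centrality's pair-counting convention differs across published
  tools; both conventions are provided but only the unordered one is
  oracle-locked by default.
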