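---
title: "Median-centrality target screening for multi-herb formulas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Median-centrality target screening for multi-herb formulas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The screening procedure

Network pharmacology asks which proteins a multi-compound herbal formula is
likely to act on in a given disease, using only public resources: compound
databases with ADME annotations, compound–target predictions, case/control
expression cohorts, and a background protein–protein interaction (PPI)
network. `netpharm` implements the standard screening cascade as a tested
pipeline:

1. **Ingredient screen.** A compound is a candidate when its oral
   bioavailability OB ≥ 30% *and* drug-likeness DL ≥ 0.18, or when it
   carries a literature-mined whitelist flag (pharmacologically established
   compounds failing the thresholds). Both cut-offs are inclusive — the
   conventional "≥" reading — and both are exposed
   (`screen_ingredients(ob_min =, dl_min =)`).
2. **Drug-side network.** Candidates map to putative protein targets
   (`build_bipartite()`); the union of targets seeds a PPI subnetwork:
   seeds plus their direct interactors with all induced edges
   (`expand_seed_network()`, `depth = 1` by default, matching the usual
   "add neighbours and edges" expansion; deeper expansions are a flag).
3. **Disease-side network.** Differentially expressed genes are called per
   cohort and intersected across cohorts, then expanded the same way.
4. **Merge-intersection.** The drug and disease networks intersect with
   network-merge semantics: a node or edge survives only if present in
   *both* networks (`intersect_networks()`), not the induced-subgraph
   alternative — intersection of edge sets is what makes the merged network
   sparser than either parent.
5. **Two-stage median-centrality screen** (`screen_topology()`):
   - *Stage 1*: keep nodes with degree DC ≥ 2 × median(DC) of the merged
     network (inclusive; comparator switchable via `stage1_cmp`).
   - *Stage 2*: recompute DC, betweenness BC and closeness CC *on the
     stage-1 network* and keep nodes strictly above all three medians
     ("higher than" read as `>`; switchable via `stage2_cmp`). Recomputing
     the medians on the screened network, rather than inheriting them,
     follows the stagewise narrative of the original tools.
   - *Hubs*: over the core-target network, rank nodes by each metric and
     intersect the three top-`k` lists (`k = 10`). Ties at the k-th value
     are all kept — a deterministic, order-independent rule — rather than
     broken arbitrarily.
6. **Enrichment** of the core targets by hypergeometric over-representation
   with Benjamini–Hochberg control (`enrich()`).
7. **Docking-energy ranking** of a precomputed ligand × receptor matrix
   (`rank_pairs()`): ascending by energy (kcal/mol; more negative =
   stronger), plus the total over all pairs. The docking engine itself is
   out of scope; the package consumes its per-pair best energies.

`run_pipeline()` executes 1–7 from a single `pipeline_config()`; the
`analysis/` scripts in the repository run the same stages as a narrated
workflow writing `results/`.

## Statistics

**Differential expression.** Per gene, a Welch two-sample t-test on log2
values, tumor vs normal, with BH adjustment across the dataset's genes; a
gene is called at `q < alpha` (default 0.05) and `|log2FC| ≥ lfc_min`
(default 1). Source studies of this kind rarely state their DE method; the
Welch/BH/fold-change combination is the most common two-group convention
for array-style matrices, and both knobs are exposed. Degenerate genes are
kept with a stated convention: both variances zero and equal means → p = 1;
both zero and different means → p = 0 (forced separation). Direction is
ignored when intersecting cohorts unless
`require_concordant_sign = TRUE`.

**Centralities.** DC(v) is the neighbour count; BC(v) the unnormalized
Brandes sum of geodesic fractions; CC(v) = (n−1)/Σ distances. All three are
computed on the largest connected component, since closeness is undefined
across components; excluded nodes are reported. Because every downstream
decision is a median or rank comparison, any positive rescaling of BC or CC
leaves all screen outputs unchanged (a tested property). Medians of
even-length vectors are the mean of the two middle values.

**Enrichment.** The upper-tail hypergeometric probability P(X ≥ k) is
evaluated in log-space via the distribution function and verified in the
tests against exhaustive combinatorial enumeration for all parameter
triples with N ≤ 25. The background universe defaults to the union of the
collection's members, overridable by an explicit universe. Significance is
flagged on BH-adjusted q < 0.05 by default; `adjust = FALSE` flags on raw p,
the behaviour of classical enrichment web tools. Note that the
hypergeometric test is *discrete*: under null queries its attained size is
below the nominal level (roughly 0.02–0.03 at a 0.05 threshold for
realistic query and term sizes), which is conservative validity, not
miscalibration — the continuous Welch test, by contrast, attains ≈ 0.05
under the null, and the test suite asserts exactly these two properties.

## The synthetic generators

All inputs can be simulated from one `sim_config()` seed; sub-streams are
derived deterministically from (seed, generator-name), so adding one
generator call never perturbs another, and every generator is
byte-reproducible under the same config.

- **Interactome**: preferential attachment (Barabási–Albert, via igraph),
  because real PPI networks are heavy-tailed and the median-based filters
  exploit exactly that; the generated max degree exceeds the median many
  fold. Defaults (500 nodes, 3 edges per new node) give a connected simple
  graph of realistic sparsity at desk scale — no attempt is made to match
  the ~5,000-node/110,000-edge networks that full database builds produce.
  `n_module` optionally wires the top-degree nodes into a clique as planted
  high-centrality ground truth.
- **Compound table**: OB uniform on (0, 100) and DL uniform on (0, 1), so
  the 30%/0.18 thresholds are exercised on both sides; whitelist flags are
  Bernoulli(`whitelist_rate`, default 0.2 — roughly the share of
  literature-rescued compounds in published candidate lists).
- **Expression**: `n_cohorts = 3` cohorts share one planted DE gene list
  (default 50 of 2000 genes) shifted by ±2 log2 units in tumor samples
  under N(0, 1) noise, 20 vs 20 samples — conditions under which a
  well-powered two-group design should recover nearly all planted genes.
  The planted list and per-gene directions are returned explicitly, never
  inferred. Real microarray features deliberately *not* modelled:
  normalization artefacts, probe-level structure, correlated genes,
  batch effects. Passing tests therefore demonstrate correctness of the
  screening logic, not robustness to those artefacts.
- **Gene sets**: uniform draws from the universe with sizes in
  `term_size_range`; an optional spiked term equal to a caller-supplied
  list supports power tests.
- **Target map**: each compound receives `targets_per_compound` random
  targets; `must_include` guarantees coverage of a planted module so the
  drug side can reach it.

`n_module` and `targets_per_compound` are generator knobs beyond the
minimal input contract: the first creates the recoverable ground truth that
the end-to-end tests measure, the second sets the bipartite density the
pipeline needs.

## Problem sizes used by the tests

The test-suite and acceptance checks run at deliberately desk-scale sizes,
chosen once as the package's study conditions: centrality oracles on random
connected graphs of up to 60 nodes; screen nesting on 100 random
interactomes of 30–120 nodes; DE recovery on 20 replicate three-cohort
simulations at the defaults above; end-to-end recovery on ten 300-node
pipelines with a 12-node planted module overlapping 40 planted DE genes.
At these conditions the three-cohort intersection recovers ≳ 95% of planted
genes with essentially no contamination, and ≥ 80% of planted-module genes
reach the core-target set.

## Known limitations

- Node identity is upper-cased symbol equality; no identifier mapping.
- The real databases behind such screens (compound ADME tables, target
  predictors, curated interactomes, GEO cohorts, GO/KEGG annotation) are
  deliberately replaced by fixtures and generators; published headline
  counts that depend on specific 2020 database versions are treated as
  qualitative references, not reproduction targets.
- The packaged docking fixture follows its source's printed table; the
  source's own text swaps the two best MCM2 energies between ligands, a
  discrepancy the table resolves in favour of ferulic acid (−7.44).
- Kappa-style term grouping of enrichment results, eigenvector/subgraph
  centralities, and any visualization layout are out of scope.
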