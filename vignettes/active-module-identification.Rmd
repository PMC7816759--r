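---
title: "Active module identification and empirical validation with dominoR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active module identification and empirical validation with dominoR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dominoR)
```

## The problem

Active module identification (AMI) takes an undirected gene interaction
network and per-gene *activity scores* — p/q-values from a differential
expression analysis or gene-level GWAS association — and looks for
connected subnetworks in which high-activity ("active") genes are
over-represented. Such modules are then read as the condition-specific
biological processes behind the measured signal, usually by GO-term
enrichment analysis of each module.

A known failure mode of this enrichment read-out is that many reported GO
terms are not specific to the measured condition at all: run the same AMI
algorithm on a randomly permuted score vector and many of the same terms
come back enriched, driven by network topology and algorithmic bias rather
than biology. `dominoR` implements two complementary answers to this
problem in one package:

1. **DOMINO**, a detection algorithm built to produce modules whose
   enrichments survive permutation testing, and
2. the **empirical pipeline (EMP)**, a permutation-based validation layer
   that works for any solution, plus five evaluation criteria built on it.

## The detection algorithm

The pipeline has four stages, each exposed as an exported function and
composed by `run_domino()`. All statistical thresholds in the package are
inclusive (`<=`); the source conventions mix strict and non-strict
inequalities, and one uniform convention keeps every boundary case
predictable.

**Step 0 — slicing** (`build_slices()`). The network is partitioned once
into disjoint, highly connected *slices* with Louvain community detection
under a generalized modularity objective whose resolution parameter
multiplies the expected-edge (null-model) term. The default resolution is
0.15; low resolution yields large, well-separated communities. Each
community's induced subgraph is split into connected components, and
components with more than three nodes become slices (the component
decomposition guarantees the connectivity invariant even when
resolution-parameterized Louvain emits a disconnected community). Slicing
ignores edge weights — weights only matter as a confidence filter at read
time (`read_network(min_edge_weight = )`, which keeps strictly greater
weights). The partition is cached to a text file whose header records the
network fingerprint, the seed and the resolution, so one slicing serves
every dataset analyzed on that network.

**Step 1 — relevant slices** (`detect_relevant_slices()`). Slices with too
little activity would only dilute the multiple-testing correction, so a
slice is *testable* only if it contains at least 10% of all network-active
genes, or its internal active fraction reaches

\[
\alpha = \min\!\left(0.7,\; \frac{a}{n}\left(1 + \frac{100}{n}\right)\right),
\]

with \(a\) active genes among \(n\) network nodes. Testable slices get a
hypergeometric upper-tail p-value (population = network nodes, successes =
active genes, draws = slice size), BH correction across testable slices
only, and a lenient relevance cutoff `q <= 0.3`.

**Step 2a — PCST refinement** (`propagate_influence()`,
`build_pcst_instance()`, `solve_pcst()`). Each relevant slice is reduced to
the single connected component that captures most of its activity by
solving a prize-collecting Steiner tree instance. Prizes come from linear
threshold influence propagation inside the slice: a node with degree `k`
exerts influence `1/k` on each neighbor, and an inactive node activates at
the first synchronous iteration where the summed influence of its active
neighbors strictly exceeds `theta = 0.5`. A node activated at iteration
\(l\) receives prize \(\beta^l\), where
\(\beta = \max(0, 1 - 3a/n)\) — so seeds (iteration 0) are worth 1 and
propagation-activated nodes decay geometrically; datasets where more than a
third of the network is active give no credit to propagation at all. Edges
incident to an input-active node are free; all others cost
\(1-\varepsilon\) with \(\varepsilon = 10^{-4}\). The "active node" in the
penalty rule is read as *input-active* (seed), not propagation-activated:
the source text uses "active nodes" for the input set throughout, and the
free-edge region should not grow with propagation depth.

**Step 2b — repartition** (`ng_partition()`). A sub-slice with more than 10
nodes that fails a lenient over-representation check (raw hypergeometric
`p <= 0.05`; the mid-pipeline gate is deliberately uncorrected, the strict
correction comes at step 3) is split with the Girvan–Newman algorithm:
repeatedly delete the edge of maximum betweenness (recomputed each
removal, ties broken by lexicographic edge order for determinism) until the
modularity \(M_i\) of the current component partition — always evaluated on
the original sub-slice graph — satisfies
\(\log(n_\text{sub-slice}) / \log(n_\text{network}) \le M_i\). If every
edge is removed without meeting the criterion (e.g. when the sub-slice is
nearly the whole network and the threshold approaches the modularity upper
bound of 1), the singleton partition is returned and logged.

**Step 3 — final modules.** All sub-slices of at most 10 nodes,
over-represented larger sub-slices, and Girvan–Newman parts become
*putative modules*. Each is tested for active-gene over-representation and
Bonferroni-corrected with family size equal to the number of putative
modules in this solution; modules with `q <= 0.05` are final, reported
sorted by q, then decreasing size, then lexicographically. Disjointness is
inherited from the slice partition; connectivity from the PCST/partition
construction; both are re-assertable post hoc and covered by tests.

### The PCST solver

No exact polynomial algorithm exists (the problem is NP-hard), so
`solve_pcst()` is a two-regime solver built around one observation: with
non-negative prizes, zero-cost edges can always be contracted — any
solution touching a free component may absorb all of it without loss. After
contraction every remaining edge costs \(1-\varepsilon\), and supernodes
carry summed prizes. If at most 12 supernodes remain, the solver runs an
exact branch-and-bound enumeration of connected supernode subsets
(canonical minimum-index enumeration; the admissible bound adds each
remaining supernode's prize net of the cheapest edge cost under uniform
costs, and the raw prize otherwise, since with general costs a new node can
lower the spanning cost of the current set). Above 12 supernodes a greedy
heuristic repeatedly merges the pair of adjacent candidate trees whose
cheapest connecting edge gives the largest positive objective improvement,
and returns the best tree (never worse than the best single node). On the
pipeline's instances the contracted graphs are small — free edges blanket
every seed neighborhood — so the exact regime handles the bulk of real
calls. The suite validates the solver against an independent brute-force
oracle (exhaustive connected-subset enumeration over the raw graph) on 200
random instances of up to 12 nodes and on general-cost instances at
tiny size.

## GO enrichment

`load_ontology()` ingests OBO 1.2 + GAF 2.x text, keeps the Biological
Process namespace, drops NOT-qualified lines and annotations with evidence
codes IPI, IEP, IGI, IMP, HMP, HGI and HEP (annotations inferred from
physical interaction, expression, genetic interaction or mutant phenotype
would leak the very signals the network analysis is meant to find), and
up-propagates annotations along is_a and — by default, toggleable —
part_of edges. *Usable* terms have 5–500 annotated genes; the size filter
is evaluated on the full annotation corpus after exclusion and
propagation, not on the network intersection, keeping term usability
dataset-independent. Term information content is
\(\mathrm{IC}(t) = -\ln(n_t / n_\text{corpus})\) in nats, so the root has
IC 0, and Resnik similarity of two terms is the IC of their most
informative common ancestor.

`module_enrichment()` runs the hypergeometric test for every usable term
with the network's gene set as background and BH correction across terms
within each module; whether the correction should instead pool the whole
solution is genuinely open, so it is per-module here (one module's term
family does not change when another module grows) and composable by the
caller. `solution_term_scores()` lifts per-module results to the solution:
each term's score is its maximal \(-\log_{10}(p)\) over modules, and terms
reported by no module score 0 rather than being omitted — that convention
makes the permutation null below well defined for every term.

## The empirical pipeline

`build_null()` repeats `n_permutations` times: reassign the (p, q) score
records to gene ids uniformly at random over *all* scored genes
(`permute_profile()`), rerun detection and enrichment, and record each
term's solution score. Permuting dataset-wide means the number of active
genes landing on the network varies across permutations — intended, since
scores are shuffled in the dataset, not on the network. Each permutation
derives its own seed from the master seed and its index, so the null store
is reproducible regardless of execution order or worker count.

The empirical significance of a term with real score \(s\) against its
null \(F_t\) is \(e(t) = 1 - F_t(s)\), estimated as the fraction of null
scores \(\ge s\): ties count as extreme, the conservative reading of a
right tail, and an optional add-one estimator \((1+\text{count})/(n+1)\)
avoids exact zeros. A term is an **HG term** if its best BH q-value on the
real data is at most 0.05, and an **EV term** (empirically validated) if
additionally \(e(t) \le 0.05\). The **EHR** (empirical-to-hypergeometric
ratio) of a solution is \(|EV|/|HG|\), reported as missing — not 0 — when
no term passes the HG test. The reference protocol uses 5000 permutations;
the tests and the acceptance script run 100, which is enough to resolve
\(e(t)\) at the 0.05 level on the synthetic fixtures.

## Evaluation criteria

- **mEHR** (`module_ehr()`, `mehr_top_k()`): per-module EV/HG ratio
  (missing when a module has no HG terms), summarized as the mean over the
  top-`min(k, n)` modules for `k = 1..20`.
- **Biological richness** (`reduce_redundant()`,
  `biological_richness()`): the number of non-redundant EV terms after a
  greedy dispensability-style reduction — while any pair of survivors has
  Resnik similarity above the cutoff, drop the worse-p member of the most
  similar pair (at equal p the lower-IC, more general term goes). Swept
  over cutoffs 1.0–4.0; lower cutoffs merge more, so richness is
  non-decreasing in the cutoff.
- **Intra-module homogeneity** (`intra_module_homogeneity()`): build the
  complete Resnik-weighted graph on the solution's EV terms, delete edges
  below the cutoff, and score each module by its edge density relative to
  the solution's. Modules or solutions with fewer than two EV terms, or a
  solution with no surviving edges, score 0 by convention.
- **Robustness** (`robustness()`): retain a uniform random fraction
  (0.6–0.9) of the scored genes, rerun detection and enrichment, and
  compare that run's HG terms against the full run's EV terms; precision,
  recall and F1 are averaged over iterations, and AUPR is computed
  step-wise over terms ranked by detection frequency. The predicted set is
  deliberately the subsampled run's *HG* terms, not a per-subsample EMP
  validation: the gold standard is the full run's EV set, and running a
  full permutation pipeline inside each of 400 subsample iterations would
  multiply the cost by orders of magnitude without changing what is being
  measured (stability of the reported term set). The run also reports the
  fraction of non-empty predictions, since many empty solutions can
  inflate AUPR.

## Synthetic fixtures and what they do (not) show

`make_planted_fixture()` builds the reference test-bed: a 500-node
stochastic-block-model network of 25 communities of 20 nodes
(`p_in = 0.3`, `p_out = 0.001`), one planted community whose genes carry
activity signal at rate 0.8 (signal q-values uniform on (0, 0.01)) against
a 5% active background, and a toy BP-style ontology (root, two branches,
one leaf per community covering 90% of its genes plus noise, five random
background terms). `p_out` was chosen analytically so that
resolution-0.15 Louvain keeps blocks separate: the generalized-modularity
gain of merging two blocks is negative once expected between-block edges
fall below the scaled null-model term. The fixture pins seed 42; every
generator takes explicit seeds and is deterministic given them.

The SBM emulates community structure and activity contrast, not the
degree heterogeneity, clustering spectrum or annotation depth of real
interactomes and the real Gene Ontology. Passing tests on these fixtures
demonstrates algorithmic correctness (recovery of planted structure,
calibration of the empirical filter, determinism), not field performance
on DIP/HuRI/STRING-scale data — reference-scale results additionally need
thousands of permutations and real annotation corpora.

Problem sizes used by the shipped checks, chosen to keep a full run on one
CPU in minutes: 200 random PCST instances of 6–12 nodes; the complete
hypergeometric grid up to population 25; 100-permutation EMP runs and a
100-permutation null-calibration run on the 500-node fixtures; 20
subsample iterations at fraction 0.8.

## Numerical and degenerate-input choices

- Activation uses strict `>` on `theta`; a boundary influence sum of
  exactly 0.5 does not activate.
- `beta^0 = 1` even when `beta = 0`: seeds always keep full prize.
- Zero active genes, zero testable or relevant slices, and empty putative
  sets all produce a valid empty solution, never an error.
- Empty enrichment: a module disjoint from every term has `p = 1`
  everywhere; an empty module yields an empty record table.
- EHR with no HG terms, mEHR with no module HG terms, and robustness with
  an empty positive set are reported missing (`NA`), never coerced to 0.
- Betweenness ties, equal-p redundancy ties and equal-similarity pair
  ties all break lexicographically so repeated runs are byte-identical.

## Limitations

- The PCST heuristic above 12 contracted supernodes has no optimality
  guarantee (the exact regime and the test oracle bound it below).
- Identifier namespaces are never converted; network, scores and GAF must
  share one namespace, and the overlap is only logged.
- Only undirected, single-layer networks; no GSEA-style continuous
  enrichment; no cross-algorithm benchmark harness.
- Slicing quality degrades on networks without community structure; the
  pipeline then reports few or no slices and an empty solution, which is
  the designed behavior, not a failure.
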