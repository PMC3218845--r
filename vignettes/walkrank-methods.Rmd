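---
title: "Accessibility-corrected random walks for knowledge-graph prioritization"
author: "walkrank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accessibility-corrected random walks for knowledge-graph prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkrank)
```

## The model

`walkrank` ranks target concepts (typically genes) against a source
concept (typically a disease) in an undirected heterogeneous knowledge
graph whose nodes are typed biomedical concepts and whose edges are
curated relations carrying a semantic type, a database of origin and
literature references.

Three quantities drive everything:

1. **Prior accessibility.** The stationary distribution of the uniform
   random walk. On a connected undirected graph this has the closed form
   $\pi(v) = \deg(v)/2m$ (with $m$ the number of distinct edges), which
   `compute_prior()` uses as its reference semantics. It measures pure
   global centrality: hubs such as ubiquitous compounds and generic
   annotation terms carry large prior mass.
2. **Posterior accessibility.** The stationary distribution of the walk
   with restart at the source $s$: at each step the walker jumps back to
   $s$ with probability $c$ and otherwise moves to a uniformly random
   neighbor, the fixed point of
   $p = c\,e_s + (1-c)\,T\,p$, where $T_{vu} = 1/\deg(u)$ for $u \sim v$.
   It measures proximity to the source, but is confounded by hubness.
3. **Rank score.** $\mathrm{score}(v \mid s) = p(v \mid s)/\sqrt{\pi(v)}$.
   Dividing by the square root of the prior removes enough of the
   centrality confound that specific indirect evidence beats
   hub-mediated reachability, without over-penalizing well-studied
   concepts the way full division would. The hub-hazard behaviour is
   reproducible on `hub_hazard_fixture()`: the hub adjacent to the
   source wins on raw posterior but loses to a specific two-hop gene on
   score.

### Assumptions

* **Edges are undirected and equally weighted.** Curated relations
  (gene–disease association, protein interaction, annotation) have no
  walk-relevant direction, and weighting by database multiplicity would
  silently distort transition probabilities — hence parallel relations
  between the same concept pair collapse to a single walk edge, with all
  provenance retained on the relation records.
* **The analysis graph is the 2-core of the largest component.**
  `sanitize()` keeps the largest connected component and iteratively
  prunes degree-1 concepts to a fixed point (removing a dangling concept
  can expose new ones). Degree-1 concepts carry no cycle evidence and
  only dilute the walk. The walk operators themselves accept any
  connected graph without isolated concepts, because the benchmark
  removes relations *without* re-sanitizing (see below) and can leave
  degree-1 concepts behind.
* **One restart source.** Restart mass is injected at a single source
  concept; that is the query model throughout.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `restart_prob` (c) | 0.25 | restart probability per step; fixes the locality scale of the posterior walk |
| `tol` | 1e-10 | L1 fixed-point tolerance; rankings must be stable to solver noise, and at desk scale tighter tolerances are cheap |
| `max_iter` | 10 000 | iteration cap; the posterior iteration contracts at rate $(1-c)$, so the cap binds only for vanishing restart probabilities |
| `k` | 10 | number of path hypotheses returned |
| `beam_width` | 1000 | frontier cap of the backtracking search |
| `max_length` | 6 | maximum edges per hypothesis path; informative biomedical hypotheses are short, and simple-path counts explode beyond this |

The prior's power-iteration variant uses the *lazy* walk (stay put with
probability 1/2): it has the same stationary distribution but also
converges on bipartite, i.e. periodic, graphs, which the plain iteration
does not. A PageRank-style damping/teleportation factor is deliberately
not part of the prior: the prior is the pure walk limit, and the
degree/(2m) closed form is exact for it. The posterior solver is the
fixed-point iteration; `solve_posterior_exact()` provides the dense
linear solve $p = c\,(I - (1-c)T)^{-1} e_s$ as an independent oracle for
graphs up to 5000 concepts.

## Path hypotheses

A hypothesis is a simple (cycle-free) path from source to target. Its
probability is the chance that a restart-surviving walker follows
exactly that node sequence:
$\prod_{i=1}^{L} (1-c)/\deg(u_i)$ over the traversed steps, taken at the
node each step leaves from. This is the natural walk semantics; it is
the package's reference definition and `path_probability()` implements
it verbatim.

`backtrack_paths()` grows partial paths backward from the target,
expanding through neighbors considered in order of their accessibility
with respect to the source (posterior by default; the corrected rank
score behind a flag). A partial path is scored by the walk probability
of its suffix as if walked from its current head. Since every backward
extension multiplies that score by $(1-c)/\deg < 1$, expanding the
currently best partial first makes complete paths emerge in
non-increasing probability order; the search can therefore stop as soon
as $k$ paths have been found, and with an unbounded beam the result
equals the exhaustive top-$k$ exactly (set and order) — the test suite
checks this equivalence against brute-force enumeration on random
graphs. Beam pruning to the `beam_width` most probable partials is the
only approximation. Ties are broken lexicographically by node sequence;
emitted probabilities are recomputed in canonical source-to-target
factor order so that ties sort identically in the heuristic and in the
enumeration oracle. Duplicate paths cannot arise because each partial is
a distinct node sequence.

`hypothesis_subnetwork()` merges the $k$ paths into one annotated graph;
each edge carries its provenance, the best probability of any path using
it, and an importance tier in 1–3 (thirds of the distinct
best-probability values, mirroring solid/dashed/dotted rendering).

## Leave-one-out benchmark protocol

To test whether a *known* disease–gene association could have been
recovered from indirect evidence alone, `loo_benchmark()`:

1. removes every direct relation between the disease and the gene;
2. identifies *related* diseases — those with a name or synonym that
   contains the query disease's name as a case-insensitive substring
   after whitespace normalization (e.g. "Charcot-Marie-Tooth disease,
   type 4C" for "Charcot-Marie-Tooth") — and removes the relations
   between the *gene* and each of them (relations among the diseases
   themselves are kept: only gene-side shortcuts leak information);
3. recomputes the prior on the modified graph (edge removal changes
   degrees; reusing the unmodified prior is an explicit speed option,
   off by default), computes the posterior from the disease, ranks all
   concepts of the target category, and records the held-out gene's
   rank, candidate count and percentile.

No re-sanitization happens after removal: the benchmark compares
rankings over a fixed candidate set, and pruning would change that set
between queries.

AUC is computed two ways. `roc_auc()` takes the positive ranks of *one*
ranking and returns the Mann–Whitney probability that a random positive
outranks a random negative (mid-rank ties; equal to the trapezoidal area
under the rank-threshold ROC sweep — asserted against a brute-force
pairwise oracle in the tests). Benchmark *records*, in contrast, come
from separate genome-wide rankings, one positive each, so
`summarize_benchmark()` pools them on the percentile scale: a record
with rank $r$ among $n$ candidates contributes the pair-win fraction
$(n-r)/(n-1)$; `pooled_auc` is the mean over records and `mean_auc`
averages within diseases first. With equal candidate counts the pooled
value is exactly the all-pairs Mann–Whitney statistic.

## The synthetic fixture generator

`generate_fixture()` emulates the structural features that make this
ranking problem hard, without emulating any particular database:

* category-stratified Erdős–Rényi background edges within plausible
  category pairs (gene–gene protein interactions, gene–annotation,
  gene–pathway, compound–gene, compound–disease, disease–disease
  family) — the simplest background that gives heterogeneous
  multi-category paths;
* hub nodes wired to a large random fraction of all other nodes — the
  ubiquitous-connector hazard;
* planted disease–gene associations: an indirect evidence chain of
  `path_length` heterogeneous edges through non-hub intermediates,
  optionally plus the direct relation that the leave-one-out protocol
  then removes.

The default study conditions — 200 concepts (80 genes, 20 diseases, 30
pathways, 40 annotations, 28 compounds, 2 hubs), background edge
probability 0.01, hub attachment probability 0.6, planted chains of
length 2 — were fixed once as a desk-scale caricature of a curated
network: background density low enough that indirect evidence is sparse,
hubs dense enough to dominate raw proximity (hub degree is an order of
magnitude above the median), and two-step chains because a single shared
intermediate (a compound affecting both the disease and the gene, a
common pathway) is the canonical unit of indirect biomedical evidence.
A single integer seed controls all randomness and the generator restores
global RNG state, so identical specs yield byte-identical TSVs.

What passing the planted-retrieval tests shows — and does not show: the
generator produces homogeneous background densities and clean planted
signal, so retrieval there demonstrates the machinery (protocol, scoring
and solvers) end to end, not performance on real curated networks, whose
degree distributions, category imbalance and literature biases are far
more skewed. Conversely `example_disease_graph()` and
`hub_hazard_fixture()` are deterministic, hand-wired topologies whose
orderings are structural properties, not statistical ones.

## Numerical choices and degenerate inputs

* Fixed-point solvers use L1 change between successive iterates as the
  stopping rule; the posterior error is bounded by the residual divided
  by $c$, so the default `tol` leaves solver noise orders of magnitude
  below any ranking gap the tests rely on.
* Ranking ties (equal scores) break lexicographically by concept id —
  deterministic and order-independent.
* `sanitize()` of a graph with no 2-core returns an empty graph rather
  than erroring; sanitizing an empty graph errors.
* Relations given in either endpoint order are canonicalized (unordered
  pairs); self-loops are dropped with a warning at construction.
* `remove_relations()` for a pair with no connecting relation returns
  the graph unchanged; the benchmark logs (but tolerates) held-out pairs
  with nothing to remove.
* An unreachable target in `backtrack_paths()` yields an empty
  hypothesis set with a notice, not an error — a query outcome, not a
  usage error.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
inputs: 50-concept ring-with-chord graphs for solver agreement, 8–12
concept graphs for exhaustive path enumeration (simple-path counts grow
combinatorially), 200-concept fixtures across 50 seeds for the
planted-retrieval suite, and 10 000 random rankings for AUC calibration.
These sizes make every check rerunnable in seconds on one CPU while
leaving each property's failure modes (solver drift, beam pruning loss,
hub confounding) clearly visible at the tested tolerances.

## Known limitations

* The substring rule for related diseases is intentionally generous;
  short disease names ("Deafness") match many compound phenotype names,
  and systematically generated fixture names can collide the same way.
  That is the intended benchmark behaviour (removing too much is safe;
  removing too little leaks), not a disease-ontology resolver.
* Relation weighting by database quality or literature support is out of
  scope; all relations are equally weighed.
* The CLI is a thin wrapper: it loads, sanitizes, runs one command and
  writes TSV/JSON/GraphML; it does not cache transition operators across
  commands.
* Multi-source restarts and directed/weighted walk variants are not
  implemented.
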