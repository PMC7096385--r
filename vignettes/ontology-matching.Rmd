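---
title: "Ontology-based matching of lipids onto metabolic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-based matching of lipids onto metabolic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chebimap)
```

## The problem

Identifier matching between lipidomics datasets and genome-scale metabolic
networks (GSMNs) fails for most lipids because the two sides annotate at
different levels of precision: analytical platforms often resolve only a
class (a sum composition such as PC(34:1), or "C18:1 n-9"), whereas the
network may carry either one generic class node (phosphatidylcholine) or
several fully specified stereoisomers. `chebimap` links the two by walking
the ChEBI ontology, so a measured class can be matched to a more generic
ancestor or a more specific descendant in the network, with a distance that
records how far and in which direction the match moved.

## The distance model

The ontology is a directed acyclic graph. `is a` edges run from the more
specific child to the more generic parent; conjugate acid/base and tautomer
edges connect functional variants of what an analyst would consider the
same measured compound, and are traversable in both directions.

A legal matching path is: an optional functional step at either endpoint
(at most one per endpoint) around a monotone `is a` chain running entirely
upward or entirely downward. Its signed distance is

$$ d = \mathrm{sign}(h)\,\bigl(|h| + 0.1\,a + 0.01\,t\bigr), $$

with $h$ the hierarchical step count (positive toward ancestors), $a$ the
acid/base steps and $t$ the tautomer steps. The increments are applied once
per functional edge crossed, so they compose additively (a tautomer of a
conjugate base costs 0.11). A path with $h = 0$ is given positive sign: it
is distinct from an exact match ($d = 0$), which arises only when the query
id itself is a target.

Three modelling choices deserve justification, because the distance
definition alone does not force them:

* **No up-then-down paths.** Paths through a common ancestor (up then down)
  are rejected. A signed distance has no well-defined sign for such a path,
  and allowing them would let any two entities in a connected ontology
  match. Matching stays within one lineage plus functional variants.
* **Closest-flag tie-break.** All targets are reported with their
  distances; those at minimal $|d|$ carry `is_closest`. If the minimal
  magnitude is attained with both signs, the negative (more specific)
  targets take the flag — the conservative choice, since a more specific
  network node asserts strictly more chemistry than the query, whereas a
  generic ancestor may pool many unrelated species.
* **Deterministic path reporting.** When several minimal paths reach one
  target, the lexicographically smallest node sequence is reported. This
  has no scientific content; it makes reports byte-reproducible.

Obsolete ontology terms are excluded from traversal entirely, and secondary
(merged) identifiers are remapped to their primary id at load time when the
source provides an `alt_id` table.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `acid_base` | 0.1 | distance increment per conjugate acid/base edge (dimensionless, same unit as one hierarchical step) |
| `tautomer` | 0.01 | increment per tautomer edge |
| `max_up`, `max_down` | 20 | bound on hierarchical steps per direction; effectively unbounded for real ChEBI lineages (typical depth < 15), a guard on pathological graphs |
| `side_compounds` | empty | compounds removed before degree computation in subnetwork extraction |

The defaults reproduce the reference worked distances (−1.1 and +3.1 on the
packaged fixture); raising a penalty above 1 would make a functional hop
cost more than a hierarchical step and is not recommended.

## Matching pipeline

`match_dataset()` runs three passes. The exact-name pass compares
normalized names (case, whitespace, Unicode dashes) against network names
and any declared synonyms — SBML models carry few synonyms, so this pass is
deliberately weak and is expected to find only a handful of matches. The
exact-ChEBI pass compares canonicalized identifiers. The ontology pass then
runs only for entries with a ChEBI id and no exact match: re-running it for
exactly matched entries would report the same compound at distance 0 plus
possibly spurious siblings, and entries without a ChEBI id cannot enter the
ontology at all — they are tallied separately rather than counted as
failures of the method. The counts always reconcile:
matched + unmatched + no-ChEBI = dataset size.

Matching is performed against *unique compounds*: species collapsed over
compartments by stripping the trailing `_<compartment>` token (BiGG/Recon
convention, applied only when the token equals the declared compartment so
unrelated underscores never cause false merges). All compartment copies
inherit the match.

## Subnetwork extraction

Mapped compounds are connected on the undirected bipartite
metabolite–reaction graph, each node weighted by its squared degree
(the classical hub-avoidance heuristic). The extracted subnetwork is the
union over all unordered pairs of mapped compounds of the lightest paths —
paths minimizing the sum of node weights, endpoints included (the inclusive
convention only shifts all path costs by a constant per pair and can change
ties only). Reaction direction is ignored; the bipartite form (rather than
a metabolite-only compound graph) makes the recovered reaction set exact.
Disconnected pairs are reported, never silently dropped. Path search is
Dijkstra under the node-to-edge weight transformation with a fixed
tie-break (weight, then hop count, then node label) so extractions are
deterministic.

## What the generators emulate

`random_ontology()` builds connected `is a` DAGs in topological order with
occasional multiple parenthood and sparse random functional edges —
structurally like a ChEBI fragment, but with none of ChEBI's curation
heterogeneity (real branches differ wildly in depth and detail, which is
precisely what shifts real matching distances). `random_planted_triple()`
derives a network and dataset from such a DAG and computes ground-truth
distances with the independent brute-force path enumerator
(`enumerate_ontology_paths()`), never with the production matcher, so
matcher-vs-truth agreement is a genuine two-route check.
`random_network()` generates small reaction networks with a recorded
compartment-duplication plan for census tests.

Passing tests on these generators therefore demonstrate algorithmic
correctness (distances, tie semantics, path optimality, censuses), not
real-data performance: they do not show how many lipids of a particular
chemical library will match a particular network release, which depends on
annotation coverage and ontology curation depth. The test sizes are chosen
where exhaustive enumeration is still exact: ontologies of ~25 nodes over
200 seeds for the matcher, compound graphs of at most 12 nodes for path
optimality.

## Numerical and degenerate-input choices

Distances are small exact decimals; comparisons use exact equality on the
composed value, and magnitude ties are resolved before sign is attached.
Empty ontologies, empty datasets, empty models, zero search radii, queries
equal to targets, unknown or malformed ChEBI ids, absent targets,
disconnected node pairs and sub-2-node mapped sets all have defined,
non-fatal behavior (errors are reserved for unreadable inputs, cyclic
`is a` subgraphs, duplicate species ids and dangling reaction references).

## Known limitations

* Name matching uses network-declared names and synonyms only; no external
  synonym service is consulted, so it under-matches by design.
* Ontology matching requires the dataset to carry ChEBI ids; no
  cross-database identifier translation is attempted.
* The matcher's distances inherit the ontology's curation unevenness: a
  poorly detailed branch yields large or missing distances regardless of
  chemical similarity.
* Subnetwork extraction returns unions of single lightest paths — not
  k-shortest-path or Steiner variants — and treats all reactions as
  reversible for connectivity purposes.
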