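---
title: "Building, merging and simplifying participatory causal system maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building, merging and simplifying participatory causal system maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sysmapr)
```

## The model

A *causal map* (also called a system map, causal loop diagram, or the
skeleton of a fuzzy cognitive map) is a signed directed graph. Nodes are
concepts; an edge $u \xrightarrow{+} v$ asserts that an increase in $u$
increases $v$, and $u \xrightarrow{-} v$ that it decreases $v$. The sign of
a path is the product of its edge signs, so a directed cycle with positive
product is a *reinforcing* feedback loop and one with negative product a
*balancing* loop. Node roles follow from degrees alone: a **source** has
only outgoing edges (a model parameter), a **receiver** only incoming ones
(an output), a **transmitter** both, and an **isolated** concept neither.
These four roles partition the node set, an identity asserted throughout
the package.

In participatory practice such maps are elicited one interviewee at a
time around a fixed focal problem, transcribed as (cause, effect,
polarity) triples, quality-checked structurally, and then merged across
the panel. sysmapr implements everything downstream of transcription:

1. **Ingest** — signed edge lists or MentalModeler-style signed adjacency
   matrices (`read_edgelist()`, `read_adjacency_matrix()`). Numeric
   weights are collapsed to their sign: elicitation yields a direction of
   influence, not a strength, and pretending otherwise would manufacture
   data.
2. **Structural QC** — `validate_map()` warns when a map has no feedback
   loop, a small diameter, a high fraction of sources, or a high density.
   All four checks are advisory: they flag maps whose elicitation may
   have been shallow, they never reject data.
3. **Canonicalization and aggregation** — `canonicalize()` resolves each
   label through a curated thesaurus; `aggregate_maps()` unions the panel
   into one combined map in which every edge carries the multiset of
   (map, sign) assertions that produced it.
4. **Simplification** — `propose_plan()`, `prune_endpoints()` and
   `contract_chains()` implement endpoint review and sign-preserving
   chain contraction.
5. **Census** — `census()` reports nodes, edges, the role partition,
   density $m/(n(n-1))$, average degree $2m/n$, maximum total degree with
   its argmax concepts, diameter, cycle presence, and degree
   concentration (max degree / edges, a centralization indicator).

## Decisions the formalism forces

**Self-loops.** A one-node loop is uninterpretable in this formalism —
feedback means a multi-node cycle — so self-loop assertions are rejected
at ingest with a warning, and edges that *become* self-loops when two
variants collapse to one concept are dropped and recorded in the merge
report.

**Sign conflicts.** Interviewees can disagree about the direction of an
influence. The package keeps every assertion and derives the edge
polarity by majority; an exact tie marks the edge *conflicted* (polarity
`NA`). Conflicted edges are excluded from sign-dependent operations —
chain contraction skips them — until more evidence or a curator resolves
them. Nothing in the elicitation literature dictates this policy; we
prefer it to first-wins or last-wins because it is order-invariant, which
in turn makes panel aggregation order-invariant (a property the test
suite asserts).

**Label identity.** Concept identity is decided on a normalized form
(trimmed, internal whitespace collapsed, case-folded); the first-seen
casing is kept for display and other spellings accumulate as aliases.
Exact-case matching would silently split concepts on typographic
accidents.

**Contracted-edge polarity.** When `contract_chains()` replaces
$A \xrightarrow{s_1} B \xrightarrow{s_2} C$ by a single edge, the new
polarity is the path product $s_1 s_2$, and the provenance of both edges
is carried along *for audit only* — the polarity of a contracted edge is
deliberately not re-derived from its merged provenance counts, which
describe the original two links rather than the composite. If $A \to C$
already exists with a different sign than the path product, the edge is
flagged conflicted and surfaced instead of silently overwritten; if
$A = C$, the contraction is refused so that elicited 2-node feedback
loops stay intact.

**Diameter convention.** The diameter is the maximum finite shortest-path
length over ordered pairs; unreachable pairs are ignored. The default is
the directed definition, because the quantity is meant to measure how
elaborated the causal chains are, and causal chains are directed. An
undirected mode is provided because published summaries of such maps do
not always state their convention; `census()` records which mode it used.

**Cycle enumeration caps.** Simple-cycle counts grow exponentially, so
`cycle_census()` enumerates vertex-simple cycles only up to a length cap
(default 7) and aborts beyond a count cap (default 10,000) with a
`truncated` flag. The yes/no question "does this map contain feedback?"
is always answered exactly, via strongly connected components, regardless
of the caps.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `diameter_floor` | 5 | QC: warn below this diameter (edges). Individual elicited maps tend to run around 8. |
| `source_fraction_max` | 0.5 | QC: warn when more than half the concepts are pure parameters. |
| `density_max` | 0.05 | QC: elicited maps are very sparse; warn above this. |
| `cycle_max_len` / `cycle_max_count` | 7 / 10000 | enumeration caps, see above. |
| `similarity_floor` | 0.8 | floor for `suggest_aliases()` candidate pairs. |

The three QC thresholds encode qualitative expectations, not published
cutoffs; they are configurable in one place (`pipeline_config()`, or a
YAML file with the same keys, unknown keys rejected).

`suggest_aliases()` ranks cross-map label pairs by the larger of a
normalized Levenshtein ratio and the same ratio after sorting word
tokens, so permutations like "family financial stress" vs "financial
stress (family)" score 1. It never merges anything: resolving two labels
into one concept is an expert judgement, and the thesaurus it feeds is
the curated record of those judgements. A thesaurus is chain-free by
construction (a canonical term may not itself redirect), so one lookup
always lands on a canonical term; redirect chains in an input file are
either fatal or, on request, flattened transitively with a warning.

## The synthetic generator

`generate_sme_map()` and `generate_panel()` exist so that every
downstream stage can be tested against a known ground truth without any
interview data. The generator imitates the *shape* of interview-elicited
maps with a two-phase growth process:

* **Phase 1** builds a star of proximal causes and consequences around
  the focal problem, sized near `max_degree_target` (default 15): the
  focal concept is, by construction, the busiest node, as it tends to be
  in practice.
* **Phase 2** repeatedly elaborates: it deepens upstream and downstream
  chains (new concepts at increasing distance from the focal node, with
  depth caps derived from `target_diameter`), adds forward cross-links
  between levels, and, with probability `p_backedge`, closes a feedback
  loop by linking a downstream concept back to an upstream one. Every
  non-back edge points strictly forward through the levels, so setting
  `p_backedge = 0` yields a DAG, and any positive value guarantees at
  least one loop (the last growth step is forced to be a back-edge if
  none occurred).

Each map has *exactly* `edges_per_map` edges (default 85) and is weakly
connected by construction. Realized diameters run about one edge above
`target_diameter` (empirical mean ≈ 9.4 at the default target of 8 over
100 replicates), because loop-closing back-edges create long finite
geodesics between branches; the calibration checks in the test suite use
a ±2 band around the target. Mean per-map maximum degree sits near 15 by
construction of the phase-1 star, with other nodes degree-capped below
it.

Panels share one canonical concept pool (a qualifier × core-concept
vocabulary of public-health-flavored terms) and one latent sign per
ordered concept pair, so the default panel is conflict-free and
aggregation through the ground-truth thesaurus must reconstruct the
pooled graph *exactly* — node and signed-edge precision and recall of 1,
with per-expert provenance intact. `conflict_rate` flips individual
assertions to exercise the majority policy deliberately rather than by
accident. Lexical variation is injected per map at `alias_rate`
(default 0.3) using deterministic transforms (word reordering,
parenthesization, "level of …", "exposure to …"), each variant recorded
in the ground-truth thesaurus; the focal term is never aliased, as the
interviewer fixes its wording.

What the generator does **not** emulate: the content of real concepts
(its labels are synthetic composites), heterogeneity of expertise across
interviewees, correlated edge endorsement (real experts share many more
edges than independent growth produces), transcription error, and
weighted or temporal relations. Passing the recovery tests therefore
shows that the merge/simplify/census machinery is correct, not that any
particular real panel was elicited well.

## Degenerate inputs and numerical conventions

* Density requires ≥ 2 nodes and diameter ≥ 1 edge; `census()` reports
  `NA` for undefined entries instead of failing, while the standalone
  functions raise errors.
* Degree-maximum ties report *all* argmax concepts, in lexicographic
  order of their normalized labels.
* Average degree and density are kept at full precision internally and
  displayed at 3 decimal places alongside the full value, so a reader
  can tell 5.241 displayed from 5.240 truncated.
* File writes emit concepts and edges in byte-wise lexicographic order
  of normalized labels: two writes of the same map are byte-identical,
  and re-running a pipeline with an identical configuration reproduces
  the artifact directory byte for byte (the run log records the package
  version and a checksum of the configuration, never a timestamp).
* The edge-list format cannot represent isolated concepts (a warning
  says so); GraphML and JSON can. Only JSON round-trips the full
  per-origin provenance; the edge-list and GraphML formats carry the
  `n_pos`/`n_neg` counts, which is sufficient to reconstruct polarity
  and conflict state.

## Validation strategy and problem sizes

The test suite checks diameter, node roles, and the signed simple-cycle
set against independently coded brute-force references (Floyd–Warshall;
exhaustive recursive enumeration) on hundreds of random digraphs of up to
8 nodes, where exhaustive enumeration is cheap; contraction is checked by
comparing multisets of simple-path sign products before and after on the
same scale, plus 100 random signed chains contracted end to end.
Generator calibration uses 100 seeded replicates at the defaults. These
sizes keep the whole suite around a minute while exercising every branch
of the algorithms; the algorithms themselves are size-independent, and
the pipeline comfortably handles panels of 15 maps × 85 edges in seconds.

## Known limitations

* No edge weights, no temporal ordering, no what-if propagation
  dynamics: the package models elicited polarity structure only.
* Cluster decomposition and cross-panel comparison are out of scope.
* `suggest_aliases()` is string-based; it will not notice synonyms with
  no lexical overlap ("poverty" vs "low income") — that remains the
  curator's job.
* The endpoint-pruning step models expert consultation as an explicit
  approval list; it has no notion of which endpoints are substantively
  important.
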