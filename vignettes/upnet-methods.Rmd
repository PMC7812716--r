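---
title: "Methods: upstream network assembly from BioPAX knowledge graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: upstream network assembly from BioPAX knowledge graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upnet)
```

## The reconstruction procedure

`upnet` reconstructs the regulatory or signaling events upstream of a
gene list by breadth-first query rewriting over a BioPAX Level 3 RDF
knowledge graph. The state of the walk is a *frontier* of entity names
not yet queried. Each level:

1. the frontier names are optionally expanded (synonyms from an NCBI
   `gene_info` table, decorated label forms such as
   `expression of <name>`), chunked, and compiled into one of two SPARQL
   patterns;
2. query hits are parsed into raw interactions — controller, product,
   a sign normalized from the BioPAX `controlType` (any subtype
   containing `ACTIVATION` or `INHIBITION` collapses to that sign;
   anything else is `UNKNOWN`), the source database read from the
   statement-level `bp:dataSource` provenance node (`"unspecified"`
   when absent), and the interaction IRI;
3. decorations are stripped from returned names before node creation;
   complex controllers contribute `PART_OF` edges member → complex,
   from explicit `bp:component` links when available, otherwise by
   splitting the label on the configured delimiters;
4. newly seen canonical names that were never enqueued before form the
   next frontier.

The walk stops when the frontier empties or after `max_depth` levels
(input genes are level 0, so `max_depth = N` permits `N` query rounds).
Because each name is enqueued at most once ever (a *global* visited
set), the loop runs at most `min(max_depth, #distinct names)` levels and
always terminates, including on cyclic knowledge content such as
autoregulation. The global (rather than per-level) visited set is a
design choice: it matches the stopping phrase "no new controllers can be
found" and guarantees termination; anyone comparing node counts against
a per-level-visited implementation should expect small differences on
graphs with many convergent paths.

Two result containers are maintained simultaneously. The *influence
graph* is a directed multigraph of typed entities with signed,
provenance-annotated edges; contradictory signs from different databases
are deliberately kept as parallel edges, since merging them is a
modeling decision best left to exporters. The *hypergraph* keeps the
reaction nodes, with typed participation links (`controller-of`,
`product-of`, `left-of`, `right-of`, `member-of`). Complex membership is
represented through a pseudo-reaction node of kind `complex_assembly`
so that the hypergraph stays strictly bipartite;
`to_influence_graph()` compiles these back to `PART_OF` edges.

Left-hand participants of signaling reactions become upstream edges with
sign `UNKNOWN`: they participate in producing the target but the
reaction asserts no causal sign for them, unlike the controller whose
`controlType` is explicit. Consequently the signed-interactions-only
mode (`drop_unknown`, the `-unk` flag) removes them; it is applied while
parsing, so entities reachable only through unsigned interactions are
not explored — "recover only signed interactions" is interpreted as a
property of the whole walk, not a post-filter (the standalone
`filter_unsigned()` post-filter also exists).

## Query expansion and unification

Expansion raises recall at query time; unification normalizes the
finished graph:

* **Complex decomposition** — delimiters default to `/` and `:`; `-` is
  intentionally not a delimiter because hyphens occur inside gene
  symbols (HLA-A). Explicit `bp:component` links are preferred over
  label splitting when the complex IRI is known.
* **Label expansion** — prefix list defaults to `expression of`; suffix
  list to `mutant form`, `phosphorylated`, `protein`, `gene`. Only the
  first two forms are well attested in pathway databases; the rest are
  a configurable starting point (`read_expansion_config()` loads
  JSON/YAML), not a fixed vocabulary. `strip_decorations()` removes at
  most one known prefix and one known suffix and is idempotent, so the
  expand/strip round-trip is the identity — a property the test suite
  checks exhaustively over the configured forms.
* **Synonym expansion** — a name matching several `gene_info` records
  expands over *all* of them (recall-oriented; a warning reports the
  ambiguity). Expansions are applied to every frontier, not only the
  initial input, since upstream entities surface under aliases too.
* **Unification** — performed after assembly on the finished graph, and
  the non-unified graph is always kept alongside. A node is renamed only
  when its name maps to exactly one gene; ambiguous names are reported
  untouched. A merge that would collapse a complex node onto a
  non-complex node is refused (the two cannot denote the same entity);
  this situation cannot arise from the package's own generator but can
  from real knowledge bases. Parallel edges made identical by renaming
  are merged with their provenance sets unioned, so the per-edge-key
  union of provenance is conserved — no source is lost or invented.

## Metrics

Coverage is `S = |ON|/|IG| × 100` with `ON` the input genes present as
graph nodes; when a synonym table is supplied both sides are normalized
to canonical symbols first, otherwise alias spellings would deflate
`ON` arbitrarily. `S` is reported raw and rounded to the nearest
integer.

Topology metrics follow the conventions of signed directed graph
analysis: components on the undirected projection; diameter and
characteristic path length as the maximum and mean of finite *directed*
shortest-path lengths on the largest weakly connected component (a
single number is still meaningful on disconnected graphs that way, and
the choice is stated in the output); "percentage of shortest paths" as
the fraction of ordered node pairs joined by a finite directed path;
clique census on the undirected simple projection; betweenness on the
directed simple projection of the largest component with lexicographic
tie-breaking. The 2-cycle fraction counts *edges* that lie in a mutual
pair (an edge is "in" a 2-cycle), not pairs, and excludes self-loops
and `PART_OF` edges. `motif_census_3()` is a raw census of connected
directed triad classes — a descriptive count, not a motif z-score
analysis against randomized ensembles, and it should not be compared
with one.

Standard graph algorithms come from igraph; the test suite validates
each metric against independent brute force (exhaustive subset
enumeration for cliques, Floyd–Warshall for distances, geodesic
counting via adjacency-matrix powers for betweenness) on all graphs of
at most 12 nodes drawn from 50 seeded fixtures.

## The SPARQL engine and remote endpoints

No RDF or SPARQL infrastructure is assumed on the host: the package
includes a small triple store, readers for Turtle, N-Triples and flat
RDF/XML, and an evaluator for the SPARQL fragment its query builders
emit — basic graph patterns, `UNION`, `OPTIONAL`,
`FILTER (?v [NOT] IN (...))`, `DISTINCT`. Two semantic notes: joins
treat unbound values as matching only unbound (generated queries never
re-join an optionally bound variable), and `NOT IN` keeps rows where
the variable is unbound, which is exactly what source exclusion needs —
statements without provenance are excluded by no one. Name matching is
exact-string and case-sensitive: reproducible, and consistent with the
case-normalized display names of public pathway aggregators.

Remote endpoints are queried over the SPARQL protocol (HTTP POST, JSON
results) with a 60 s timeout and 3 attempts by default — public
endpoints are slow and flaky enough that bounded retries are the
difference between a 10-level run completing or not. The transport is
injectable, which the tests use to serve SPARQL-results JSON from an
in-process graph and verify that the local and remote paths return
identical binding tables. Queries are chunked at 20 names per request
by default: large enough to keep round-trips low, small enough to stay
below typical endpoint query-length limits.

## The synthetic generator and what passing tests mean

`generate_kb()` plants a layered upstream DAG: each node receives
`floor(branching)` new regulators plus one more with probability equal
to the fractional part, so `branching` is the exact mean in-degree from
new nodes and `branching = 1, n_genes = 1` yields a deterministic
chain. Optional shortcut edges (`p_shortcut`) connect regulators to
earlier levels, creating convergent paths that exercise deduplication
and the visited set. Signs are drawn per edge
(`p_inhibition`/`p_unknown`, remainder activation), sources from
`source_names`, and a configurable number of upstream nodes become
complexes (emitted with *both* explicit component links and
delimiter-joined labels so both decomposition paths are exercised),
aliases (display name differs from the canonical symbol; a companion
`gene_info` table records the synonymy) or decorated labels. All
randomness flows from the spec seed through R's RNG; a spec serializes
byte-identically across runs.

`ground_truth_upstream()` is an independent breadth-first closure over
the planted edge list — it never touches RDF, queries or the assembler
— and the central correctness claim of the package is that
`reconstruct()` (with all expansions on, followed by `unify_graph()`,
since alias controllers legitimately surface under their alias until
unification) reproduces that closure *exactly*: node set, edge set,
signs, sources and `PART_OF` edges, across seeds, depths 1–5 and both
network kinds.

The generator emulates the features of real BioPAX exports that the
algorithm must navigate — class typing, controlType subtypes, per-
statement provenance, complexes, aliases, decorations — but not their
statistics: no scale-free degree distributions, no pathway/step
scaffolding beyond what the queries touch, no contradictory signs for
the same pair from different databases, and names are unambiguous by
construction. Passing the recovery tests therefore demonstrates that
the assembly logic is exact on knowledge bases of this structure, not
that any particular public endpoint yields a graph of a particular
size; absolute node/edge counts from live endpoints are
version-dependent by nature.

Test problem sizes — knowledge bases up to a few hundred statements,
metric fixtures of at most 12 nodes, 20–50 seeds per property — were
chosen so the properties are exercised densely while the whole suite
runs in well under a minute per file; the brute-force oracles are
exponential and 12 nodes is where exhaustive clique enumeration stays
trivial.

## Numerical and degenerate-input choices

* All orderings (frontiers, serialized files, SIF lines) are
  lexicographic in the C locale, making outputs byte-stable across
  platforms and runs; assembly involves no randomness at all.
* Entity classes are fixed at first real assignment; `unknown` acts as
  unassigned and may be upgraded (e.g. a node first seen as a product,
  later typed as a complex controller). Conflicting real classes keep
  the first and log the conflict.
* A complex with neither component links nor a splittable label yields
  no membership edges and a warning.
* An empty gene list, empty query-name list, zero chunk size, or
  coverage of an empty input set are usage errors (the last would
  divide by zero); a gene absent from the knowledge base is not an
  error and simply contributes nothing.
* UNKNOWN edges present at signed-network export are an error unless
  explicitly dropped, so sign-consistency inputs can never silently
  contain unsigned rows; `PART_OF` maps to `+` (complex formation as a
  positive influence) or can be dropped entirely for tools that cannot
  handle membership edges.

## Known limitations

* The SPARQL evaluator covers only the emitted fragment; arbitrary
  user queries outside it are rejected with a syntax error rather than
  silently mis-evaluated. Property paths, `Modulation` and
  `PathwayStep` traversal are not part of the signaling pattern.
* Only BioPAX Level 3 classes are recognized; OWL inference is not
  performed — what is not asserted does not exist.
* Downstream (successor) exploration is out of scope; the walk is
  strictly upstream.
* Name matching is exact; no fuzzy or cross-species matching.
* The drug-screening module is designed for DrugBank-like RDF with
  configurable predicate IRIs; counts obtained from live endpoints
  depend on their versions and are not reproduced offline.
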