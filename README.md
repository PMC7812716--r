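# upnet

Assembly of upstream gene regulatory networks (GRNs) and signaling
networks (SNs) from BioPAX-typed RDF knowledge graphs, in R.

## The problem

Pathway aggregators such as PathwayCommons expose millions of curated
interactions as a BioPAX Level 3 knowledge graph behind a SPARQL
endpoint. Given a list of genes of interest (for example the
differentially expressed genes of a tumor cohort), a modeler wants the
*upstream* network that explains them: which transcription factors,
complexes and signaling reactions regulate those genes, which regulate
the regulators, and so on. Doing this by hand is impractical: entity
names differ between source databases, complexes are written as
concatenated labels, and many entities carry decorated labels such as
`expression of MYC`.

`upnet` automates this through recursive query rewriting. Starting from
the input list, it generates one of two SPARQL graph patterns per
exploration level:

* **regulation**: a `TemplateReactionRegulation` whose controlled
  `TemplateReaction` produces an entity named in the current frontier;
* **signaling**: a `Control`/`Catalysis` whose controlled
  `BiochemicalReaction` has a frontier entity among its right-hand
  participants (upstream entities are the controllers and left-hand
  participants).

Hits become signed edges (`ACTIVATION`, `INHIBITION`, `UNKNOWN`, and
`PART_OF` for protein-complex membership, oriented member → complex)
with per-edge data-source provenance, and the newly discovered
controllers form the next frontier, until no new controller is found or
the maximum depth is reached. Three optional expansions raise recall:
complex decomposition (splitting `CDK4/CCND1`-style labels and explicit
`bp:component` links), label expansion (querying decorated forms and
stripping them from results), and synonym expansion through an NCBI
`gene_info` table. Unification then merges synonym nodes onto canonical
symbols; both the unified and non-unified graphs are always produced.

The quality of a reconstruction is summarized by its **coverage**

```
S = |ON| / |IG| × 100
```

where `IG` is the input gene set and `ON ⊆ IG` the input genes present
in the output graph, plus standard topology metrics (components,
diameter, characteristic path length, 2-cycle fraction, clique census,
betweenness ranking).

Because public endpoints drift between versions, the package ships a
seedable synthetic BioPAX generator (`generate_kb()`) that plants an
upstream DAG with known signs, sources, complexes, aliases and
decorated labels, together with a brute-force oracle
(`ground_truth_upstream()`) that the assembler is tested against.

## Worked example

```r
library(upnet)

## a synthetic knowledge base with 1 complex, 1 alias and 1 decorated label
gk <- generate_kb(kb_spec(n_genes = 2, n_levels = 3, branching = 1.2,
                          seed = 7, n_complexes = 1, n_aliases = 1,
                          n_decorated = 1),
                  dir = "demo")

kb  <- load_rdf_graph("demo/kb.ttl")
#> <knowledge_base: local, 145 statements>
syn <- load_synonym_table("demo/gene_info.tsv")

res <- reconstruct(kb, gk$truth$input_genes, "regulation", max_depth = 5,
                   config = expansion_config(use_synonyms = TRUE,
                                             use_complex_decomposition = TRUE,
                                             use_label_expansion = TRUE),
                   synonym_table = syn)
res
#> <upstream network: 19 nodes, 17 edges, 4 level(s) explored>
#>   coverage: 100.00% (2 of 2 input genes in graph)
#>   provenance: ctd=1 panther=7 pid=6

uni <- unify_graph(res$influence_graph, syn)
uni$graph
#> <influence_graph: 19 nodes, 17 edges>
#>   signs: ACTIVATION=13 INHIBITION=1 PART_OF=3
uni$report$merges
#> RG02004ALT
#>  "RG02004"

topology_summary(uni$graph)
#> Topology summary
#>   nodes/edges:            19 / 17
#>   connected components:   2
#>   diameter (largest cmp): 4
#>   char. path length:      2.031
#>   ...
```

Both input genes were recovered (coverage 100%), 17 signed or
membership edges were collected from three simulated source databases,
the alias node `RG02004ALT` was merged onto its canonical symbol, and
the three `PART_OF` edges are the members of the one planted complex.
`export_sif()`, `export_signed_network()` (ACTIVATION → `+`,
INHIBITION → `-`, PART_OF → `+` for sign-consistency tools) and
`export_hypergraph()` write the results to files.

The same run is available from a shell:

```sh
Rscript inst/cli/upnet -reg -md 5 -sy -su -co \
    -f demo/genes.csv --kb demo/kb.ttl --gene-info demo/gene_info.tsv -o out
```

Drug screening against a DrugBank-like RDF source (`screen()`) maps
target genes to approved drugs, augments the target list with depth-1
upstream regulators, and re-queries drugs for the regulators.

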