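Package: upnet
Title: Upstream Regulatory and Signaling Network Assembly from BioPAX
    Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs gene regulatory and signaling networks upstream
    of a list of genes or proteins by recursive, query-rewriting
    exploration of BioPAX Level 3 typed RDF knowledge graphs (local files
    or remote SPARQL endpoints such as PathwayCommons).  Supports complex
    decomposition, label (prefix/suffix) expansion and NCBI gene_info
    synonym expansion, produces signed influence graphs and bipartite
    entity/reaction hypergraphs with per-edge data-source provenance,
    merges synonym nodes into unified graphs, exports SIF and signed
    network tables for sign-consistency modeling tools, computes coverage
    and graph-topology metrics, and screens DrugBank-like RDF sources for
    approved drugs targeting a gene list and its upstream regulators.  A
    seedable synthetic knowledge-base generator with planted ground truth
    supports fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    xml2,
    curl,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
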