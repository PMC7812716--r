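# Unification, hypergraph compilation and output formats.

mk_graph <- function(nodes, edges) {
  influence_graph(
    nodes = data.frame(name = nodes, entity_class = "protein_or_gene",
                       aliases = "", stringsAsFactors = FALSE),
    edges = edges)
}

test_that("synonym nodes merge onto canonical symbols with provenance unioned", {
  tab <- load_synonym_table(gene_info_fixture())
  e <- data.frame(
    source = c("P53", "TP53"), target = c("MYC", "MYC"),
    sign = "ACTIVATION", kind = "transcriptional",
    provenance = c("ctd", "pid"), reaction = c("r1", "r2"),
    stringsAsFactors = FALSE)
  g <- mk_graph(c("P53", "TP53", "MYC"), e)
  out <- unify_graph(g, tab)
  expect_identical(n_nodes(out$graph), 2L)
  expect_identical(out$report$merges, c(P53 = "TP53"))
  expect_identical(out$report$node_count_before, 3L)
  expect_identical(out$report$node_count_after, 2L)
  merged <- out$graph$edges
  expect_identical(nrow(merged), 1L)
  expect_identical(merged$provenance, "ctd|pid")
  # input graph untouched
  expect_identical(n_nodes(g), 3L)

  # provenance conservation: union per merged key preserved
  expect_setequal(unlist(strsplit(merged$provenance, "|", fixed = TRUE)),
                  c("ctd", "pid"))
})

test_that("graphs without synonyms and ambiguous aliases pass through", {
  tab <- load_synonym_table(gene_info_fixture())
  g <- mk_graph(c("FOO", "BAR"), data.frame(
    source = "FOO", target = "BAR", sign = "INHIBITION",
    kind = "transcriptional", provenance = "ctd", reaction = "r1",
    stringsAsFactors = FALSE))
  out <- unify_graph(g, tab)
  expect_identical(out$graph$nodes$name, g$nodes$name)
  expect_identical(length(out$report$merges), 0L)

  amb <- mk_graph(c("SHARED", "X"), data.frame(
    source = "SHARED", target = "X", sign = "ACTIVATION",
    kind = "transcriptional", provenance = "ctd", reaction = "r1",
    stringsAsFactors = FALSE))
  out2 <- unify_graph(amb, tab)
  expect_true("SHARED" %in% out2$graph$nodes$name)  # untouched
  expect_identical(out2$report$ambiguous, "SHARED")
})

test_that("unification never merges a complex onto a protein node", {
  tab <- load_synonym_table(gene_info_fixture())
  nodes <- data.frame(name = c("P53", "TP53"),
                      entity_class = c("complex", "protein_or_gene"),
                      aliases = "", stringsAsFactors = FALSE)
  g <- influence_graph(nodes, upnet:::empty_edges_df())
  out <- unify_graph(g, tab)
  expect_identical(n_nodes(out$graph), 2L)  # merge refused
})

test_that("unified node count never exceeds the original", {
  tab <- load_synonym_table(gene_info_fixture())
  for (seed in 1:5) {
    g <- random_graph(seed)
    out <- unify_graph(g, tab)
    expect_lte(n_nodes(out$graph), n_nodes(g))
  }
})

test_that("hypergraphs compile to influence graphs by the controller-product rule", {
  h <- hypergraph(
    entities = data.frame(name = c("K", "P1", "P2"),
                          entity_class = "protein_or_gene",
                          stringsAsFactors = FALSE),
    reactions = data.frame(id = "r1", kind = "signaling", sign = "ACTIVATION",
                           source = "pid", stringsAsFactors = FALSE),
    participation = data.frame(
      entity = c("K", "P1", "P2"), reaction = "r1",
      role = c("controller-of", "right-of", "right-of"),
      stringsAsFactors = FALSE))
  g <- to_influence_graph(h)
  expect_identical(n_edges(g), 2L)
  expect_true(all(g$edges$source == "K"))
  expect_true(all(g$edges$sign == "ACTIVATION"))

  # reaction with no controller contributes no influence edges
  h0 <- suppressWarnings(hypergraph(
    entities = data.frame(name = "P", entity_class = "protein_or_gene"),
    reactions = data.frame(id = "r1", kind = "signaling", sign = "UNKNOWN",
                           source = ""),
    participation = data.frame(entity = "P", reaction = "r1", role = "right-of")))
  expect_identical(n_edges(to_influence_graph(h0)), 0L)

  # catalysis + 2-member complex assembly: 1 signed + 2 PART_OF edges
  h2 <- hypergraph(
    entities = data.frame(name = c("K", "P", "A", "B", "A/B"),
                          entity_class = c(rep("protein_or_gene", 4), "complex"),
                          stringsAsFactors = FALSE),
    reactions = data.frame(id = c("r1", "asm1"),
                           kind = c("signaling", "complex_assembly"),
                           sign = c("ACTIVATION", "UNKNOWN"),
                           source = c("pid", ""), stringsAsFactors = FALSE),
    participation = data.frame(
      entity = c("K", "P", "A", "B", "A/B"),
      reaction = c("r1", "r1", "asm1", "asm1", "asm1"),
      role = c("controller-of", "right-of", "member-of", "member-of",
               "product-of"),
      stringsAsFactors = FALSE))
  g2 <- to_influence_graph(h2)
  expect_identical(sum(g2$edges$sign == "ACTIVATION"), 1L)
  expect_identical(sum(g2$edges$sign == "PART_OF"), 2L)
  expect_true(all(g2$edges$target[g2$edges$sign == "PART_OF"] == "A/B"))

  # bipartite invariant is enforced
  expect_error(hypergraph(
    entities = data.frame(name = "A", entity_class = "protein_or_gene"),
    reactions = data.frame(id = "r", kind = "signaling", sign = "UNKNOWN",
                           source = ""),
    participation = data.frame(entity = "A", reaction = "r", role = "binds")),
    class = "upnet_usage_error")
})

test_that("hypergraphs with no reaction nodes compile to an isomorphic graph", {
  h <- suppressWarnings(hypergraph(
    entities = data.frame(name = c("A", "B"), entity_class = "protein_or_gene",
                          stringsAsFactors = FALSE),
    reactions = data.frame(id = character(), kind = character(),
                           sign = character(), source = character(),
                           stringsAsFactors = FALSE),
    participation = data.frame(entity = character(), reaction = character(),
                               role = character(), stringsAsFactors = FALSE)))
  g <- to_influence_graph(h)
  expect_identical(g$nodes$name, c("A", "B"))
  expect_identical(n_edges(g), 0L)
})

test_that("SIF export round-trips the edge multiset", {
  g <- mk_graph(c("X", "Y"), data.frame(
    source = c("X", "X"), target = c("Y", "Y"),
    sign = c("ACTIVATION", "INHIBITION"),   # parallel edges preserved
    kind = "transcriptional", provenance = "ctd", reaction = c("r1", "r2"),
    stringsAsFactors = FALSE))
  f <- tempfile(fileext = ".sif")
  export_sif(g, f)
  expect_identical(readLines(f),
                   c("X\tACTIVATION\tY", "X\tINHIBITION\tY"))
  back <- read_sif(f)
  expect_identical(
    sort(paste(back$edges$source, back$edges$sign, back$edges$target)),
    sort(paste(g$edges$source, g$edges$sign, g$edges$target)))
  attrs <- readLines(paste0(f, ".attrs.tsv"))
  expect_identical(attrs[1], "source\trelation\ttarget\tkind\tprovenance")
  expect_identical(length(attrs), 3L)

  fe <- tempfile()
  export_sif(influence_graph(), fe)
  expect_identical(readLines(fe), character())
  expect_identical(length(readLines(paste0(fe, ".attrs.tsv"))), 1L)

  # round-trip property on random graphs
  for (seed in 1:5) {
    rg <- random_graph(seed)
    fr <- tempfile()
    export_sif(rg, fr)
    rt <- read_sif(fr)
    expect_identical(
      sort(paste(rt$edges$source, rt$edges$sign, rt$edges$target)),
      sort(paste(rg$edges$source, rg$edges$sign, rg$edges$target)))
  }

  expect_error(export_sif(g, "/nonexistent-dir/x.sif"),
               class = "upnet_export_error")
})

test_that("signed-network export maps ACTIVATION/INHIBITION/PART_OF to +/-/+", {
  g <- mk_graph(c("A", "B", "C", "M", "K"), data.frame(
    source = c("A", "C", "M"), target = c("B", "B", "K"),
    sign = c("ACTIVATION", "INHIBITION", "PART_OF"),
    kind = c("transcriptional", "transcriptional", "membership"),
    provenance = c("ctd", "ctd", ""), reaction = c("r1", "r2", ""),
    stringsAsFactors = FALSE))
  f <- tempfile()
  export_signed_network(g, f, part_of_sign = "plus")
  lines <- readLines(f)
  expect_identical(lines[1], "source\tsign\ttarget")
  expect_setequal(lines[-1], c("A\t+\tB", "C\t-\tB", "M\t+\tK"))

  f2 <- tempfile()
  export_signed_network(g, f2, part_of_sign = "drop")
  expect_identical(length(readLines(f2)), 3L)

  gu <- mk_graph(c("A", "B"), data.frame(
    source = "A", target = "B", sign = "UNKNOWN", kind = "transcriptional",
    provenance = "ctd", reaction = "r1", stringsAsFactors = FALSE))
  expect_error(export_signed_network(gu, tempfile()),
               class = "upnet_export_error")
  f3 <- tempfile()
  export_signed_network(gu, f3, drop_unknown = TRUE)
  expect_identical(readLines(f3), "source\tsign\ttarget")

  f4 <- tempfile()
  export_signed_network(influence_graph(), f4)
  expect_identical(readLines(f4), "source\tsign\ttarget")
})

test_that("hypergraph export writes participation and entity tables", {
  gk <- generate_kb(kb_spec(n_genes = 2, n_levels = 2, branching = 1,
                            seed = 4, n_complexes = 1))
  res <- reconstruct(gk$kb, gk$truth$input_genes, "regulation", max_depth = 2,
                     config = expansion_config(use_complex_decomposition = TRUE))
  f <- tempfile()
  export_hypergraph(res$hypergraph, f)
  lines <- readLines(f)
  expect_identical(lines[1], "entity\trole\treaction\treaction_kind\tsign\tsource")
  expect_identical(length(lines) - 1L, nrow(res$hypergraph$participation))
  expect_true(file.exists(paste0(f, ".entities.tsv")))
})
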