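# Recursive assembly.

test_that("a planted activation chain is recovered level by level", {
  kb <- kb_from_ttl(fixture_chain)
  res <- reconstruct(kb, "g", "regulation", max_depth = 3)
  g <- res$influence_graph
  expect_identical(n_nodes(g), 4L)
  expect_identical(n_edges(g), 3L)
  expect_true(all(g$edges$sign == "ACTIVATION"))
  expect_identical(res$levels_run, 3L)
  expect_identical(length(res$coverage$ON), 1L)

  shallow <- reconstruct(kb, "g", "regulation", max_depth = 1)
  expect_identical(n_nodes(shallow$influence_graph), 2L)
  expect_identical(n_edges(shallow$influence_graph), 1L)

  absent <- reconstruct(kb, "NOT_IN_KB", "regulation", max_depth = 3)
  expect_identical(n_edges(absent$influence_graph), 0L)
  expect_identical(absent$coverage$S, 0)

  expect_error(reconstruct(kb, character(), "regulation"),
               class = "upnet_usage_error")
  expect_error(reconstruct(kb, "g", "regulation", max_depth = 0),
               class = "upnet_usage_error")
})

test_that("step_frontier enqueues new controllers and respects the visited set", {
  kb <- kb_from_ttl('
kb:g a bp:Protein ; bp:displayName "g" .
kb:x a bp:Protein ; bp:displayName "X" .
kb:y a bp:Protein ; bp:displayName "Y" .
kb:src a bp:Provenance ; bp:displayName "ctd" .
kb:r1 a bp:TemplateReactionRegulation ; bp:controlled kb:t1 ;
  bp:controller kb:x ; bp:controlType "ACTIVATION" ; bp:dataSource kb:src .
kb:t1 a bp:TemplateReaction ; bp:product kb:g .
kb:r2 a bp:TemplateReactionRegulation ; bp:controlled kb:t2 ;
  bp:controller kb:y ; bp:controlType "INHIBITION" ; bp:dataSource kb:src .
kb:t2 a bp:TemplateReaction ; bp:product kb:g .
')
  st <- assembly_state("g")
  st <- step_frontier(st, kb, "regulation")
  expect_identical(st$frontier, c("X", "Y"))
  expect_identical(nrow(st$edges), 2L)
  expect_identical(st$explored, "g")
  expect_identical(st$depth, 1L)
  expect_error(step_frontier(assembly_state("zzz"), kb, "regulation"),
               NA)  # querying an absent name is not an error
})

test_that("autoregulation yields a self-loop and terminates immediately", {
  kb <- kb_from_ttl('
kb:g a bp:Protein ; bp:displayName "g" .
kb:src a bp:Provenance ; bp:displayName "ctd" .
kb:r1 a bp:TemplateReactionRegulation ; bp:controlled kb:t1 ;
  bp:controller kb:g ; bp:controlType "INHIBITION" ; bp:dataSource kb:src .
kb:t1 a bp:TemplateReaction ; bp:product kb:g .
')
  res <- reconstruct(kb, "g", "regulation", max_depth = 5)
  e <- res$influence_graph$edges
  expect_identical(nrow(e), 1L)
  expect_identical(e$source, e$target)
  expect_identical(res$levels_run, 1L)  # g already explored, frontier empties
})

test_that("decorated controller and product names are stripped before node creation", {
  kb <- kb_from_ttl('
kb:myc a bp:Protein ; bp:displayName "expression of MYC" .
kb:tf a bp:Protein ; bp:displayName "TF1" .
kb:src a bp:Provenance ; bp:displayName "pid" .
kb:r1 a bp:TemplateReactionRegulation ; bp:controlled kb:t1 ;
  bp:controller kb:tf ; bp:controlType "ACTIVATION" ; bp:dataSource kb:src .
kb:t1 a bp:TemplateReaction ; bp:product kb:myc .
')
  cfg <- expansion_config(use_label_expansion = TRUE)
  res <- reconstruct(kb, "MYC", "regulation", max_depth = 2, config = cfg)
  expect_setequal(res$influence_graph$nodes$name, c("MYC", "TF1"))
  expect_identical(res$coverage$S, 100)

  # without label expansion the decorated product does not match
  res0 <- reconstruct(kb, "MYC", "regulation", max_depth = 2)
  expect_identical(n_edges(res0$influence_graph), 0L)
})

test_that("complex controllers produce PART_OF edges from explicit components", {
  kb <- kb_from_ttl('
kb:g a bp:Protein ; bp:displayName "g" .
kb:m1 a bp:Protein ; bp:displayName "P1" .
kb:m2 a bp:Protein ; bp:displayName "P2" .
kb:m3 a bp:Protein ; bp:displayName "P3" .
kb:cx a bp:Complex ; bp:displayName "P1/P2/P3" ;
  bp:component kb:m1 ; bp:component kb:m2 ; bp:component kb:m3 .
kb:src a bp:Provenance ; bp:displayName "ctd" .
kb:r1 a bp:TemplateReactionRegulation ; bp:controlled kb:t1 ;
  bp:controller kb:cx ; bp:controlType "ACTIVATION" ; bp:dataSource kb:src .
kb:t1 a bp:TemplateReaction ; bp:product kb:g .
')
  cfg <- expansion_config(use_complex_decomposition = TRUE)
  res <- reconstruct(kb, "g", "regulation", max_depth = 2, config = cfg)
  e <- res$influence_graph$edges
  po <- e[e$sign == "PART_OF", ]
  expect_identical(nrow(po), 3L)
  expect_identical(unique(po$target), "P1/P2/P3")
  expect_setequal(po$source, c("P1", "P2", "P3"))
  # membership edges always point at a complex-classed node
  cls <- res$influence_graph$nodes
  expect_true(all(cls$entity_class[match(po$target, cls$name)] %in%
                    c("complex", "small_molecule_complex")))
})

test_that("label-only complexes decompose syntactically; indivisible ones warn", {
  edges <- upnet:::empty_edges_df()
  cfg <- expansion_config(use_complex_decomposition = TRUE)
  out <- add_complex_membership_edges(
    edges, list(name = "A/B", entity_class = "complex", iri = NA), cfg)
  expect_identical(nrow(out$edges), 2L)
  expect_setequal(out$members, c("A", "B"))
  expect_identical(unique(out$edges$target), "A/B")

  expect_warning(
    deg <- add_complex_membership_edges(
      edges, list(name = "OPAQUE", entity_class = "complex", iri = NA), cfg),
    "no PART_OF")
  expect_identical(nrow(deg$edges), 0L)
  expect_error(add_complex_membership_edges(
    edges, list(name = "X", entity_class = "protein_or_gene", iri = NA), cfg),
    class = "upnet_usage_error")
})

test_that("filter_unsigned drops exactly the UNKNOWN-signed edges", {
  e <- data.frame(
    source = c("A", "B", "C", "M"), target = c("T", "T", "T", "K"),
    sign = c("ACTIVATION", "INHIBITION", "UNKNOWN", "PART_OF"),
    kind = c("transcriptional", "transcriptional", "transcriptional",
             "membership"),
    provenance = c("ctd", "ctd", "ctd", ""), reaction = c("r1", "r2", "r3", ""),
    stringsAsFactors = FALSE)
  kept <- filter_unsigned(e)
  expect_identical(sort(kept$sign), sort(c("ACTIVATION", "INHIBITION", "PART_OF")))
  expect_identical(nrow(filter_unsigned(e[e$sign == "UNKNOWN", ])), 0L)
  expect_identical(nrow(filter_unsigned(upnet:::empty_edges_df())), 0L)

  g <- influence_graph(edges = e)
  expect_identical(n_edges(filter_unsigned(g)), 3L)
})

test_that("deeper exploration only adds edges (depth monotonicity)", {
  for (seed in c(2, 5, 9)) {
    gk <- generate_kb(kb_spec(n_genes = 2, n_levels = 5, branching = 1.2,
                              p_shortcut = 0.3, seed = seed, p_inhibition = 0.3))
    prev <- character()
    for (d in 1:5) {
      res <- reconstruct(gk$kb, gk$truth$input_genes, "regulation",
                         max_depth = d)
      cur <- edge_key(explode_edges(res$influence_graph))
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("assembly terminates on cyclic knowledge bases", {
  kb <- kb_from_ttl('
kb:a a bp:Protein ; bp:displayName "A" .
kb:b a bp:Protein ; bp:displayName "B" .
kb:src a bp:Provenance ; bp:displayName "ctd" .
kb:r1 a bp:TemplateReactionRegulation ; bp:controlled kb:t1 ;
  bp:controller kb:a ; bp:controlType "ACTIVATION" ; bp:dataSource kb:src .
kb:t1 a bp:TemplateReaction ; bp:product kb:b .
kb:r2 a bp:TemplateReactionRegulation ; bp:controlled kb:t2 ;
  bp:controller kb:b ; bp:controlType "INHIBITION" ; bp:dataSource kb:src .
kb:t2 a bp:TemplateReaction ; bp:product kb:a .
')
  res <- reconstruct(kb, "A", "regulation", max_depth = 50)
  expect_lte(res$levels_run, 2L)  # two distinct names bound the loop
  expect_identical(n_edges(res$influence_graph), 2L)
})
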