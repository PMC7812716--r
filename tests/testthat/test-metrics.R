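# Coverage and topology metrics, cross-checked against brute force.

path_graph <- function() {
  influence_graph(edges = data.frame(
    source = c("A", "B"), target = c("B", "C"), sign = "ACTIVATION",
    kind = "transcriptional", provenance = "ctd", reaction = c("r1", "r2"),
    stringsAsFactors = FALSE))
}

test_that("coverage implements S = |ON| / |IG| x 100", {
  genes <- generate_gene_list(910, seed = 1)
  g <- influence_graph(
    nodes = data.frame(name = genes[1:691], entity_class = "protein_or_gene",
                       aliases = "", stringsAsFactors = FALSE))
  cov <- coverage(genes, g)
  expect_equal(cov$S, 691 / 910 * 100, tolerance = 1e-12)
  expect_identical(cov$S_rounded, 76L)
  expect_identical(length(cov$ON), 691L)

  expect_identical(coverage("ZZZ", g)$S, 0)
  expect_identical(coverage(genes[1:10], g)$S, 100)
  expect_error(coverage(character(), g), class = "upnet_usage_error")

  # invariant to edges: same nodes, extra edges, same coverage
  g2 <- influence_graph(
    nodes = g$nodes,
    edges = data.frame(source = genes[1], target = genes[2],
                       sign = "ACTIVATION", kind = "transcriptional",
                       provenance = "ctd", reaction = "r",
                       stringsAsFactors = FALSE))
  expect_identical(coverage(genes, g2)$S, cov$S)
})

test_that("coverage normalizes aliases through the synonym table", {
  tab <- load_synonym_table(gene_info_fixture())
  g <- influence_graph(
    nodes = data.frame(name = "P53", entity_class = "protein_or_gene",
                       aliases = "", stringsAsFactors = FALSE))
  expect_identical(coverage("TP53", g, synonyms = tab)$S, 100)
  expect_identical(coverage("TP53", g)$S, 0)  # without normalization
})

test_that("two-cycle fraction counts edges in mutual pairs", {
  g1 <- influence_graph(edges = data.frame(
    source = c("A", "B"), target = c("B", "A"), sign = "ACTIVATION",
    kind = "transcriptional", provenance = "ctd", reaction = c("r1", "r2"),
    stringsAsFactors = FALSE))
  expect_identical(two_cycle_fraction(g1), 1)
  expect_identical(two_cycle_fraction(path_graph()), 0)

  # self-loops are not 2-cycles; PART_OF edges are excluded
  g2 <- influence_graph(edges = data.frame(
    source = c("A", "M"), target = c("A", "K"),
    sign = c("ACTIVATION", "PART_OF"),
    kind = c("transcriptional", "membership"),
    provenance = c("ctd", ""), reaction = c("r1", ""),
    stringsAsFactors = FALSE))
  expect_identical(two_cycle_fraction(g2), 0)

  # sign-relabeling invariance + brute-force agreement
  for (seed in 1:10) {
    g <- random_graph(seed)
    expect_equal(two_cycle_fraction(g), bf_two_cycle(g))
    g_relab <- g
    g_relab$edges$sign <- ifelse(g_relab$edges$sign == "ACTIVATION",
                                 "INHIBITION", "ACTIVATION")
    expect_equal(two_cycle_fraction(g_relab), two_cycle_fraction(g))
  }
})

test_that("clique census matches closed forms and exhaustive enumeration", {
  tri <- influence_graph(edges = data.frame(
    source = c("A", "B", "C"), target = c("B", "C", "A"), sign = "ACTIVATION",
    kind = "transcriptional", provenance = "ctd",
    reaction = c("r1", "r2", "r3"), stringsAsFactors = FALSE))
  cl <- clique_census(tri, 3)
  expect_identical(cl$counts[["3"]], 1L)
  expect_identical(cl$max_clique_size, 3L)

  # complete graph on 5 nodes: C(5,3)=10, C(5,4)=5, C(5,5)=1
  pairs <- t(utils::combn(LETTERS[1:5], 2))
  k5 <- influence_graph(edges = data.frame(
    source = pairs[, 1], target = pairs[, 2], sign = "ACTIVATION",
    kind = "transcriptional", provenance = "ctd",
    reaction = sprintf("r%d", seq_len(nrow(pairs))), stringsAsFactors = FALSE))
  cl5 <- clique_census(k5, 5)
  expect_identical(unname(cl5$counts), c(10L, 5L, 1L))
  expect_identical(cl5$max_clique_size, 5L)

  edgeless <- influence_graph(
    nodes = data.frame(name = c("A", "B"), entity_class = "unknown",
                       aliases = "", stringsAsFactors = FALSE))
  cl0 <- clique_census(edgeless, 4)
  expect_true(all(cl0$counts == 0L))
  expect_lte(cl0$max_clique_size, 2L)
  expect_error(clique_census(tri, 2), class = "upnet_usage_error")

  for (seed in 11:25) {
    g <- random_graph(seed)
    got <- clique_census(g, 5)
    want <- bf_cliques(g, 5)
    expect_identical(got$counts, want$counts)
    expect_identical(got$max_clique_size, want$max_clique_size)
  }
})

test_that("topology summary matches closed forms on small graphs", {
  ts <- topology_summary(path_graph())
  expect_identical(ts$n_nodes, 3L)
  expect_identical(ts$n_edges, 2L)
  expect_identical(ts$connected_components, 1L)
  expect_identical(ts$diameter, 2L)
  expect_equal(ts$characteristic_path_length, mean(c(1, 1, 2)))
  expect_equal(ts$pct_shortest_paths, 3 / 6)
  expect_identical(ts$self_loops, 0L)

  two <- influence_graph(edges = data.frame(
    source = c("A", "C"), target = c("B", "D"), sign = "ACTIVATION",
    kind = "transcriptional", provenance = "ctd", reaction = c("r1", "r2"),
    stringsAsFactors = FALSE))
  expect_identical(topology_summary(two)$connected_components, 2L)

  multi <- influence_graph(edges = data.frame(
    source = c("A", "B", "A"), target = c("B", "A", "B"),
    sign = c("ACTIVATION", "ACTIVATION", "INHIBITION"),
    kind = "transcriptional", provenance = c("ctd", "ctd", "pid"),
    reaction = c("r1", "r2", "r3"), stringsAsFactors = FALSE))
  mts <- topology_summary(multi)
  expect_identical(mts$multi_edge_pairs, 1L)
  expect_identical(mts$self_loops, 0L)
})

test_that("diameter and characteristic path length match Floyd-Warshall", {
  for (seed in 26:40) {
    g <- random_graph(seed)
    ts <- topology_summary(g)
    D <- bf_distances(g)
    # restrict to the largest weakly connected component, as documented
    comp <- igraph::components(upnet:::simple_directed(g), mode = "weak")
    big <- names(comp$membership[comp$membership == which.max(tabulate(comp$membership))])
    Dc <- D[big, big, drop = FALSE]
    diag(Dc) <- Inf
    fin <- Dc[is.finite(Dc)]
    if (length(fin)) {
      expect_identical(ts$diameter, as.integer(max(fin)))
      expect_equal(ts$characteristic_path_length, mean(fin))
    }
    diag(D) <- Inf
    expect_equal(ts$pct_shortest_paths,
                 sum(is.finite(D)) / (nrow(D) * (nrow(D) - 1)))
  }
})

test_that("betweenness ranking matches the path-counting oracle", {
  # directed star: A->HUB, B->HUB, HUB->A, HUB->B
  star <- influence_graph(edges = data.frame(
    source = c("A", "B", "HUB", "HUB"), target = c("HUB", "HUB", "A", "B"),
    sign = "ACTIVATION", kind = "transcriptional", provenance = "ctd",
    reaction = sprintf("r%d", 1:4), stringsAsFactors = FALSE))
  top <- betweenness_top_k(star, 1)
  expect_identical(top$node, "HUB")

  pathg <- path_graph()
  bt <- betweenness_top_k(pathg, 3)
  expect_identical(bt$node[1], "B")
  expect_true(all(bt$score[-1] == 0))

  for (seed in 41:50) {
    g <- random_graph(seed, n_max = 8L)
    oracle <- bf_betweenness(g)
    comp <- igraph::components(upnet:::simple_directed(g), mode = "weak")
    big <- names(comp$membership[comp$membership ==
                                   which.max(tabulate(comp$membership))])
    oracle <- oracle[big]
    got <- betweenness_top_k(g, length(big))
    expect_setequal(got$node, big)
    expect_equal(got$score, unname(oracle[got$node]), tolerance = 1e-9)
    expect_true(all(diff(got$score) <= 1e-9))
  }
  expect_error(betweenness_top_k(path_graph(), 0), class = "upnet_usage_error")
})

test_that("metrics are independent of node and edge insertion order", {
  g <- random_graph(99)
  perm <- g
  set.seed(1)
  perm$edges <- perm$edges[sample(nrow(perm$edges)), ]
  perm$nodes <- perm$nodes[sample(nrow(perm$nodes)), ]
  perm <- influence_graph(perm$nodes, perm$edges)
  expect_identical(topology_summary(g), topology_summary(perm))
  expect_identical(betweenness_top_k(g, 5), betweenness_top_k(perm, 5))
})

test_that("triad census reports connected three-node subgraph classes", {
  ffl <- influence_graph(edges = data.frame(
    source = c("A", "A", "B"), target = c("B", "C", "C"), sign = "ACTIVATION",
    kind = "transcriptional", provenance = "ctd",
    reaction = c("r1", "r2", "r3"), stringsAsFactors = FALSE))
  cen <- motif_census_3(ffl)
  expect_identical(cen[["030T"]], 1L)   # the feed-forward class
  expect_identical(sum(cen), 1L)
  expect_identical(sum(motif_census_3(influence_graph())), 0L)
})

test_that("topology report writes the TSV property table", {
  f <- tempfile()
  write_topology_tsv(topology_summary(path_graph()), f)
  lines <- readLines(f)
  expect_identical(lines[1], "Property\tValue")
  expect_true(any(grepl("^Network diameter\t2$", lines)))
  expect_true(any(grepl("^N. Nodes\t3$", lines)))
})
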