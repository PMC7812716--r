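# Coverage and graph-topology metrics used to characterize reconstructed
# networks.  All metrics are deterministic and independent of node
# insertion order; igraph provides the standard graph algorithms.

#' Coverage of an input gene list by a graph
#'
#' Computes `S = |ON| / |IG| * 100` where IG is the set of input genes
#' and ON the subset of input genes present as nodes of the graph.  When
#' a synonym table is supplied, both input names and node names are
#' normalized to canonical symbols before matching, so alias spellings do
#' not deflate the count.
#'
#' @param input_genes Character vector (non-empty) of input gene names.
#' @param graph An `influence_graph`.
#' @param synonyms Optional [load_synonym_table()] result.
#' @return A `coverage_report` with fields `IG`, `ON`, `S` (raw
#'   percentage) and `S_rounded` (nearest integer).
#' @examples
#' g <- influence_graph(
#'   nodes = data.frame(name = c("A", "B"), entity_class = "unknown",
#'                      aliases = ""),
#'   edges = data.frame(source = "A", target = "B", sign = "ACTIVATION",
#'                      kind = "transcriptional", provenance = "ctd",
#'                      reaction = "r1"))
#' coverage(c("A", "B", "C", "D"), g)$S   # 50
#' @export
coverage <- function(input_genes, graph, synonyms = NULL) {
  input_genes <- unique(as.character(input_genes))
  input_genes <- input_genes[nzchar(input_genes)]
  if (length(input_genes) == 0L) {
    usage_error("coverage: empty input gene set (division by zero)")
  }
  node_names <- graph$nodes$name
  canon_nodes <- unique(canonicalize_name(node_names, synonyms))
  canon_in <- canonicalize_name(input_genes, synonyms)
  on <- input_genes[canon_in %in% canon_nodes]
  s <- length(on) / length(input_genes) * 100
  structure(list(IG = sort_c(input_genes), ON = sort_c(on),
                 S = s, S_rounded = as.integer(round(s))),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("coverage S = |ON|/|IG| x 100 = %d/%d x 100 = %.2f%% (~%d%%)\n",
              length(x$ON), length(x$IG), x$S, x$S_rounded))
  invisible(x)
}

# Directed simple projection (parallel edges collapsed, loops kept).
simple_directed <- function(graph) {
  igraph::simplify(as_igraph(graph), remove.multiple = TRUE,
                   remove.loops = FALSE)
}

# Undirected simple projection (directions and signs ignored, parallel
# edges collapsed, loops dropped).
simple_undirected <- function(graph) {
  igraph::simplify(igraph::as_undirected(as_igraph(graph), mode = "collapse"),
                   remove.multiple = TRUE, remove.loops = TRUE)
}

#' Fraction of edges belonging to a 2-cycle
#'
#' The fraction of non-membership edges `(u, v)` such that some edge
#' `(v, u)` also exists (the A -> B, B -> A motif).  Self-loops are not
#' counted as 2-cycles.  The value is invariant under sign relabeling.
#'
#' @param graph An `influence_graph`.
#' @return A number in `[0, 1]` (0 for a graph with no non-membership
#'   edges).
#' @export
two_cycle_fraction <- function(graph) {
  e <- graph$edges[graph$edges$sign != "PART_OF", , drop = FALSE]
  if (!nrow(e)) return(0)
  pair <- paste(e$source, e$target, sep = "\r")
  rev <- paste(e$target, e$source, sep = "\r")
  in2 <- (rev %in% pair) & e$source != e$target
  sum(in2) / nrow(e)
}

#' Clique census on the undirected simple projection
#'
#' Counts cliques of each size from 3 to `max_size` (edge directions and
#' signs ignored, parallel edges collapsed) and reports the maximal
#' clique size.
#'
#' @param graph An `influence_graph`.
#' @param max_size Largest clique size to count (>= 3).
#' @return List with `counts` (named integer vector for sizes
#'   `3:max_size`) and `max_clique_size`.
#' @export
clique_census <- function(graph, max_size = 5L) {
  if (max_size < 3L) usage_error("clique_census: max_size must be >= 3")
  g <- simple_undirected(graph)
  counts <- integer(max_size - 2L)
  names(counts) <- as.character(3:max_size)
  if (igraph::vcount(g) >= 3L) {
    cl <- igraph::cliques(g, min = 3L, max = max_size)
    if (length(cl)) {
      tab <- table(lengths(cl))
      counts[names(tab)] <- as.integer(tab)
    }
  }
  maxc <- if (igraph::vcount(g) == 0L) 0L else igraph::clique_num(g)
  list(counts = counts, max_clique_size = as.integer(maxc))
}

#' Topology summary of an influence graph
#'
#' Connected components are counted on the undirected projection.
#' Diameter and characteristic path length are the maximum and mean of
#' finite directed shortest-path lengths, computed on the largest
#' (weakly) connected component when the graph is disconnected.
#' `pct_shortest_paths` is the fraction of ordered node pairs joined by a
#' finite directed path.  `multi_edge_pairs` counts unordered node pairs
#' linked by more than one edge in any direction or sign.
#'
#' @param graph An `influence_graph`.
#' @param max_clique_count_size Largest clique size for the census.
#' @return A `topology_summary` list.
#' @export
topology_summary <- function(graph, max_clique_count_size = 5L) {
  gd <- simple_directed(graph)
  gu <- simple_undirected(graph)
  comp <- if (igraph::vcount(gd)) igraph::components(gd, mode = "weak") else
    list(no = 0L, membership = integer())
  nv <- igraph::vcount(gd)

  # largest weak component for path metrics
  diam <- 0; cpl <- NA_real_
  if (nv > 1L && comp$no >= 1L) {
    big <- which.max(tabulate(comp$membership))
    sub <- igraph::induced_subgraph(gd, which(comp$membership == big))
    d <- igraph::distances(sub, mode = "out")
    diag(d) <- Inf
    fin <- d[is.finite(d)]
    if (length(fin)) { diam <- max(fin); cpl <- mean(fin) }
  }
  pct <- 0
  if (nv > 1L) {
    dall <- igraph::distances(gd, mode = "out")
    diag(dall) <- Inf
    pct <- sum(is.finite(dall)) / (nv * (nv - 1L))
  }
  e <- graph$edges
  self_loops <- sum(e$source == e$target)
  mep <- 0L
  if (nrow(e)) {
    nonloop <- e[e$source != e$target, , drop = FALSE]
    upair <- paste(pmin(nonloop$source, nonloop$target),
                   pmax(nonloop$source, nonloop$target), sep = "\r")
    mep <- sum(table(upair) > 1L)
  }
  cl <- clique_census(graph, max_clique_count_size)
  structure(list(
    n_nodes = n_nodes(graph),
    n_edges = n_edges(graph),
    clustering_coefficient = if (igraph::vcount(gu) >= 3L)
      igraph::transitivity(gu, type = "global") else NA_real_,
    connected_components = as.integer(comp$no),
    diameter = as.integer(diam),
    pct_shortest_paths = pct,
    characteristic_path_length = cpl,
    avg_neighbors = if (nv) mean(igraph::degree(gu)) else NA_real_,
    self_loops = as.integer(self_loops),
    multi_edge_pairs = as.integer(mep),
    two_cycle_fraction = two_cycle_fraction(graph),
    clique_counts = cl$counts,
    max_clique_size = cl$max_clique_size
  ), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat("Topology summary\n")
  cat(sprintf("  nodes/edges:            %d / %d\n", x$n_nodes, x$n_edges))
  cat(sprintf("  connected components:   %d\n", x$connected_components))
  cat(sprintf("  diameter (largest cmp): %d\n", x$diameter))
  cat(sprintf("  char. path length:      %.3f\n", x$characteristic_path_length))
  cat(sprintf("  %% shortest paths:       %.1f%%\n", 100 * x$pct_shortest_paths))
  cat(sprintf("  avg neighbors:          %.2f\n", x$avg_neighbors))
  cat(sprintf("  self-loops:             %d\n", x$self_loops))
  cat(sprintf("  multi-edge node pairs:  %d\n", x$multi_edge_pairs))
  cat(sprintf("  2-cycle edge fraction:  %.3f\n", x$two_cycle_fraction))
  cat(sprintf("  max clique size:        %d\n", x$max_clique_size))
  cat(sprintf("  cliques by size:        %s\n",
              paste(sprintf("%s:%d", names(x$clique_counts), x$clique_counts),
                    collapse = " ")))
  invisible(x)
}

#' Write a topology summary as a TSV report
#'
#' @param x A `topology_summary`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_topology_tsv <- function(x, path) {
  rows <- c(
    sprintf("N. Nodes\t%d", x$n_nodes),
    sprintf("N. Edges\t%d", x$n_edges),
    sprintf("Clustering coefficient\t%.3f", x$clustering_coefficient),
    sprintf("Connected components\t%d", x$connected_components),
    sprintf("Network diameter\t%d", x$diameter),
    sprintf("Percentage of shortest paths\t%.1f%%", 100 * x$pct_shortest_paths),
    sprintf("Characteristic path length\t%.2f", x$characteristic_path_length),
    sprintf("Avg. number of neighbors\t%.2f", x$avg_neighbors),
    sprintf("Self-loops\t%d", x$self_loops),
    sprintf("Multi-edge node pairs\t%d", x$multi_edge_pairs),
    sprintf("Edges in 2-cycles\t%.1f%%", 100 * x$two_cycle_fraction),
    sprintf("Maximal clique size\t%d", x$max_clique_size),
    vapply(names(x$clique_counts), function(k)
      sprintf("Cliques of size %s\t%d", k, x$clique_counts[[k]]), "")
  )
  writeLines(c("Property\tValue", rows), path)
  invisible(path)
}

#' Top-k nodes by betweenness centrality
#'
#' Standard shortest-path betweenness on the largest weakly connected
#' component of the directed simple projection, with lexicographic tie
#' breaking.  Neighbor counts (distinct neighbors, any direction) are
#' reported for centrality-vs-degree scatter plots.
#'
#' @param graph An `influence_graph`.
#' @param k Number of nodes to return (>= 1).
#' @return data.frame with columns `node`, `score`, `neighbor_count`.
#' @export
betweenness_top_k <- function(graph, k = 10L) {
  if (k < 1L) usage_error("betweenness_top_k: k must be >= 1")
  gd <- simple_directed(graph)
  if (igraph::vcount(gd) == 0L) {
    return(data.frame(node = character(), score = numeric(),
                      neighbor_count = integer(), stringsAsFactors = FALSE))
  }
  comp <- igraph::components(gd, mode = "weak")
  big <- which.max(tabulate(comp$membership))
  sub <- igraph::induced_subgraph(gd, which(comp$membership == big))
  sc <- igraph::betweenness(sub, directed = TRUE)
  nb <- igraph::degree(igraph::simplify(igraph::as_undirected(sub, mode = "collapse"),
                                        remove.multiple = TRUE,
                                        remove.loops = TRUE))
  nm <- igraph::V(sub)$name
  ord <- order(-sc, nm, method = "radix")
  out <- data.frame(node = nm[ord], score = unname(sc[ord]),
                    neighbor_count = as.integer(unname(nb[nm[ord]])),
                    stringsAsFactors = FALSE)
  utils::head(out, k)
}

#' Census of connected three-node subgraph types
#'
#' A raw local census of directed triad types (standard triad-census
#' classes restricted to weakly connected triads).  This is a descriptive
#' count, not a motif z-score analysis against randomized ensembles.
#'
#' @param graph An `influence_graph`.
#' @return Named integer vector of connected triad classes.
#' @export
motif_census_3 <- function(graph) {
  gd <- simple_directed(graph)
  labels <- c("003", "012", "102", "021D", "021U", "021C", "111D", "111U",
              "030T", "030C", "201", "120D", "120U", "120C", "210", "300")
  if (igraph::vcount(gd) < 3L) {
    out <- integer(13L)
    names(out) <- labels[-(1:3)]
    return(out)
  }
  cen <- igraph::triad_census(igraph::delete_edges(
    gd, igraph::E(gd)[igraph::which_loop(gd)]))
  names(cen) <- labels
  conn <- setdiff(labels, c("003", "012", "102"))
  out <- as.integer(cen[conn])
  names(out) <- conn
  out
}
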