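# Graph containers.
#
# influence_graph: directed multigraph of typed biological entities with
#   signed, provenance-annotated edges (ACTIVATION/INHIBITION/UNKNOWN/
#   PART_OF).  Edges live in a data.frame (multiset; parallel edges with
#   different signs or provenance are kept).  Provenance is a sorted
#   "|"-joined set of data-source names per edge.
#
# hypergraph: bipartite entity <-> reaction representation retaining the
#   reaction nodes, with typed participation links (controller-of,
#   product-of, left-of, right-of, member-of).  Complex membership is
#   carried by a pseudo reaction node of kind "complex_assembly" so the
#   graph stays strictly bipartite.

PARTICIPATION_ROLES <- c("controller-of", "product-of", "left-of", "right-of",
                         "member-of")

#' Construct an influence graph
#'
#' @param nodes data.frame with columns `name`, `entity_class`, `aliases`.
#' @param edges data.frame with columns `source`, `target`, `sign`,
#'   `kind`, `provenance`, `reaction`.
#' @return An `influence_graph` object.
#' @export
influence_graph <- function(nodes = empty_nodes_df(), edges = empty_edges_df()) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    bad_sign <- setdiff(unique(edges$sign), SIGN_TOKENS)
    if (length(bad_sign)) {
      usage_error(sprintf("influence_graph: invalid edge sign(s): %s",
                          paste(bad_sign, collapse = ", ")))
    }
    missing_ep <- setdiff(unique(c(edges$source, edges$target)), nodes$name)
    if (length(missing_ep)) {
      # tolerate by materializing unknown-class nodes; keeps the container
      # usable on externally read SIF files
      nodes <- rbind(nodes, data.frame(
        name = sort_c(missing_ep), entity_class = "unknown", aliases = "",
        stringsAsFactors = FALSE))
    }
  }
  nodes <- nodes[!duplicated(nodes$name), , drop = FALSE]
  nodes <- nodes[order_c(nodes$name), , drop = FALSE]
  edges <- edges[order_c(edges$source, edges$target, edges$sign,
                         edges$kind, edges$provenance), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "influence_graph")
}

n_nodes <- function(g) nrow(g$nodes)
n_edges <- function(g) nrow(g$edges)

#' @export
print.influence_graph <- function(x, ...) {
  cat(sprintf("<influence_graph: %d nodes, %d edges>\n", n_nodes(x), n_edges(x)))
  if (n_edges(x)) {
    tab <- table(x$edges$sign)
    cat("  signs:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                          collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
summary.influence_graph <- function(object, ...) {
  cls <- table(object$nodes$entity_class)
  cat(sprintf("Influence graph: %d nodes, %d edges\n",
              n_nodes(object), n_edges(object)))
  if (length(cls)) {
    cat("  node classes:", paste(sprintf("%s=%d", names(cls), as.integer(cls)),
                                 collapse = " "), "\n")
  }
  if (n_edges(object)) {
    sg <- table(object$edges$sign)
    cat("  edge signs:  ", paste(sprintf("%s=%d", names(sg), as.integer(sg)),
                                 collapse = " "), "\n")
    src <- provenance_histogram(object)
    cat("  provenance:  ", paste(sprintf("%s=%d", names(src), as.integer(src)),
                                 collapse = " "), "\n")
  }
  invisible(object)
}

#' @export
plot.influence_graph <- function(x, ...) {
  g <- as_igraph(x)
  cols <- c(ACTIVATION = "forestgreen", INHIBITION = "firebrick",
            UNKNOWN = "grey50", PART_OF = "steelblue")
  igraph::plot.igraph(
    g, edge.color = cols[igraph::E(g)$sign],
    vertex.size = 8, vertex.label.cex = 0.7, edge.arrow.size = 0.4, ...)
  invisible(x)
}

# Per-source edge counts over non-membership edges (an edge contributes
# once per data source it carries).
provenance_histogram <- function(graph) {
  e <- graph$edges[graph$edges$sign != "PART_OF", , drop = FALSE]
  if (!nrow(e)) return(integer())
  srcs <- unlist(strsplit(e$provenance, "|", fixed = TRUE), use.names = FALSE)
  tab <- table(srcs)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[sort_c(names(out))]
}

#' Convert an influence graph to an igraph object
#'
#' Edge attributes `sign`, `kind` and `provenance` are preserved.
#'
#' @param graph An `influence_graph`.
#' @return A directed `igraph` graph (possibly with parallel edges).
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "influence_graph"))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = graph$edges$source, to = graph$edges$target,
                   sign = graph$edges$sign, kind = graph$edges$kind,
                   provenance = graph$edges$provenance,
                   stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = graph$nodes$name,
                          entity_class = graph$nodes$entity_class,
                          stringsAsFactors = FALSE)
  )
  g
}

#' Construct a hypergraph
#'
#' @param entities data.frame with columns `name`, `entity_class`.
#' @param reactions data.frame with columns `id`, `kind`
#'   (`transcriptional`/`signaling`/`complex_assembly`), `sign`, `source`.
#' @param participation data.frame with columns `entity`, `reaction`,
#'   `role` (one of controller-of, product-of, left-of, right-of,
#'   member-of).
#' @return A `hypergraph` object.
#' @export
hypergraph <- function(entities, reactions, participation) {
  entities <- as.data.frame(entities, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  participation <- as.data.frame(participation, stringsAsFactors = FALSE)
  bad_role <- setdiff(unique(participation$role), PARTICIPATION_ROLES)
  if (length(bad_role)) {
    usage_error(sprintf("hypergraph: invalid participation role(s): %s",
                        paste(bad_role, collapse = ", ")))
  }
  if (nrow(participation)) {
    if (any(!participation$entity %in% entities$name)) {
      usage_error("hypergraph: participation references unknown entity")
    }
    if (any(!participation$reaction %in% reactions$id)) {
      usage_error("hypergraph: participation references unknown reaction")
    }
  }
  anchored <- unique(participation$reaction[
    participation$role %in% c("controller-of", "product-of")])
  dangling <- setdiff(reactions$id, anchored)
  if (length(dangling)) {
    warning(sprintf("%d reaction node(s) lack controller-of/product-of links",
                    length(dangling)), call. = FALSE)
  }
  entities <- entities[!duplicated(entities$name), , drop = FALSE]
  entities <- entities[order_c(entities$name), , drop = FALSE]
  reactions <- reactions[!duplicated(reactions$id), , drop = FALSE]
  reactions <- reactions[order_c(reactions$id), , drop = FALSE]
  participation <- unique(participation)
  participation <- participation[order_c(participation$reaction,
                                         participation$role,
                                         participation$entity), , drop = FALSE]
  rownames(entities) <- rownames(reactions) <- rownames(participation) <- NULL
  structure(list(entities = entities, reactions = reactions,
                 participation = participation),
            class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf("<hypergraph: %d entities, %d reactions, %d participation links>\n",
              nrow(x$entities), nrow(x$reactions), nrow(x$participation)))
  invisible(x)
}

#' Compile a hypergraph to an influence graph
#'
#' For each reaction node, every controller receives a signed edge (the
#' reaction's control-type sign) to every product/right-hand participant;
#' left-hand participants receive `UNKNOWN` participation edges to the
#' products; `member-of` links of complex-assembly pseudo-reactions become
#' `PART_OF` edges from member to complex.  Reaction nodes disappear.
#'
#' @param h A `hypergraph`.
#' @return An `influence_graph`.
#' @export
to_influence_graph <- function(h) {
  stopifnot(inherits(h, "hypergraph"))
  edges <- empty_edges_df()
  for (i in seq_len(nrow(h$reactions))) {
    rx <- h$reactions[i, ]
    part <- h$participation[h$participation$reaction == rx$id, , drop = FALSE]
    controllers <- part$entity[part$role == "controller-of"]
    products <- part$entity[part$role %in% c("product-of", "right-of")]
    lefts <- part$entity[part$role == "left-of"]
    members <- part$entity[part$role == "member-of"]
    kind <- if (rx$kind == "transcriptional") "transcriptional" else "signaling"
    if (length(controllers) && length(products)) {
      edges <- rbind(edges, expand.grid.df(controllers, products, rx$sign, kind,
                                           rx$source, rx$id))
    }
    if (length(lefts) && length(products)) {
      edges <- rbind(edges, expand.grid.df(lefts, products, "UNKNOWN", kind,
                                           rx$source, rx$id))
    }
    if (length(members) && length(products)) {
      edges <- rbind(edges, expand.grid.df(members, products, "PART_OF",
                                           "membership", "", rx$id))
    }
  }
  if (nrow(edges)) {
    key <- paste(edges$source, edges$target, edges$sign, edges$provenance,
                 edges$reaction, sep = "\r")
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  influence_graph(
    nodes = data.frame(name = h$entities$name,
                       entity_class = h$entities$entity_class,
                       aliases = "", stringsAsFactors = FALSE),
    edges = edges
  )
}

expand.grid.df <- function(sources, targets, sign, kind, provenance, reaction) {
  grid <- expand.grid(source = sources, target = targets,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  data.frame(source = grid$source, target = grid$target, sign = sign,
             kind = kind, provenance = provenance, reaction = reaction,
             stringsAsFactors = FALSE)
}
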