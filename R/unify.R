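# Network unification: merge synonym nodes into canonical-symbol nodes.

#' Unify synonym nodes in an influence graph
#'
#' Nodes whose name is registered as a synonym of exactly one canonical
#' gene symbol are renamed to that symbol.  Parallel edges created by the
#' merge are deduplicated when `(source, target, sign, kind)` coincide,
#' with their provenance sets unioned, so no provenance is lost or
#' invented.  Names matching several genes are left untouched and listed
#' as ambiguous.  A merge that would collapse a complex node onto a
#' protein node (or vice versa) is refused and logged, since the two
#' cannot denote the same entity.  The input graph is not modified; both
#' the unified and the original graph remain available to the caller.
#'
#' @param graph An `influence_graph`.
#' @param table A [load_synonym_table()] result.
#' @return List with `graph` (the unified `influence_graph`) and `report`
#'   (fields `merges`, `ambiguous`, `node_count_before`,
#'   `node_count_after`).
#' @export
unify_graph <- function(graph, table) {
  stopifnot(inherits(graph, "influence_graph"), inherits(table, "synonym_table"))
  before <- n_nodes(graph)
  mapping <- character()      # alias -> canonical
  ambiguous <- character()
  for (nm in graph$nodes$name) {
    ids <- table$index[[nm]] %||% integer()
    if (length(ids) > 1L) {
      ambiguous <- c(ambiguous, nm)
    } else if (length(ids) == 1L) {
      canon <- table$records$symbol[match(ids, table$records$gene_id)]
      if (!is.na(canon) && canon != nm) {
        # class-mismatch guard: never merge a complex with a non-complex
        cls_alias <- graph$nodes$entity_class[match(nm, graph$nodes$name)]
        cls_canon <- graph$nodes$entity_class[match(canon, graph$nodes$name)]
        complexish <- c("complex", "small_molecule_complex")
        if (!is.na(cls_canon) &&
            xor(cls_alias %in% complexish, cls_canon %in% complexish)) {
          up_log("unification refused for %s -> %s: entity class mismatch",
                 nm, canon)
          next
        }
        mapping[[nm]] <- canon
      }
    }
  }
  rename <- function(x) ifelse(x %in% names(mapping), unname(mapping[x]), x)
  nodes <- graph$nodes
  nodes$aliases <- ifelse(nodes$name %in% names(mapping), nodes$name, nodes$aliases)
  nodes$name <- rename(nodes$name)
  # merge node rows sharing a canonical name
  if (anyDuplicated(nodes$name)) {
    nodes <- do.call(rbind, lapply(split(nodes, nodes$name), function(blk) {
      cls <- setdiff(unique(blk$entity_class), "unknown")
      data.frame(name = blk$name[[1L]],
                 entity_class = if (length(cls)) cls[[1L]] else "unknown",
                 aliases = paste(sort_c(setdiff(unique(blk$aliases), "")),
                                 collapse = "|"),
                 stringsAsFactors = FALSE)
    }))
  }
  edges <- graph$edges
  edges$source <- rename(edges$source)
  edges$target <- rename(edges$target)
  # dedupe parallel edges with identical (source, target, sign, kind),
  # unioning provenance
  if (nrow(edges)) {
    key <- paste(edges$source, edges$target, edges$sign, edges$kind, sep = "\r")
    edges <- do.call(rbind, lapply(split(edges, key), function(blk) {
      prov <- sort_c(unique(unlist(strsplit(blk$provenance, "|", fixed = TRUE))))
      blk2 <- blk[1L, , drop = FALSE]
      blk2$provenance <- paste(prov, collapse = "|")
      blk2$reaction <- paste(sort_c(unique(blk$reaction[nzchar(blk$reaction)])),
                             collapse = "|")
      blk2
    }))
  }
  unified <- influence_graph(nodes, edges)
  list(
    graph = unified,
    report = list(
      merges = mapping,
      ambiguous = sort_c(unique(ambiguous)),
      node_count_before = before,
      node_count_after = n_nodes(unified)
    )
  )
}
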