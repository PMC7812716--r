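# Recursive upstream network assembly.
#
# A frontier of unexplored names is queried level by level: names are
# expanded (synonyms, decorated labels) before query generation, query
# hits are parsed into raw interactions, decorated names are stripped
# before node creation, complex controllers are decomposed into PART_OF
# membership edges, and newly seen canonical names (minus the global
# visited set) form the next frontier.  The loop stops when the frontier
# empties or the maximum exploration depth is reached.  Assembly is fully
# deterministic on a local knowledge base: frontiers and outputs are kept
# in lexicographic (C-locale) order and no randomness is involved.

#' Create an empty assembly state
#'
#' @param genes Character vector of input names (level 0 frontier).
#' @return An `assembly_state` list with fields `explored`, `frontier`,
#'   `depth`, `edges`, `nodes`, hypergraph accumulators and a per-level
#'   `log`.
#' @export
assembly_state <- function(genes) {
  genes <- unique(str_trim2(as.character(genes)))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) usage_error("assembly_state: empty gene list")
  structure(list(
    explored = character(),
    frontier = sort_c(genes),
    seen = sort_c(genes),          # global visited set: enqueued at most once ever
    depth = 0L,
    edges = empty_edges_df(),
    nodes = empty_nodes_df(),
    reactions = data.frame(id = character(), kind = character(),
                           sign = character(), source = character(),
                           stringsAsFactors = FALSE),
    participation = data.frame(entity = character(), reaction = character(),
                               role = character(), stringsAsFactors = FALSE),
    log = list()
  ), class = "assembly_state")
}

# Register nodes; entity_class is fixed once assigned ("unknown" counts as
# unassigned and may be upgraded; real-class conflicts keep the first).
state_add_nodes <- function(state, names, classes) {
  keep <- nzchar(names)
  names <- names[keep]; classes <- classes[keep]
  if (!length(names)) return(state)
  first <- !duplicated(names)
  df <- data.frame(name = names[first], entity_class = classes[first],
                   aliases = "", stringsAsFactors = FALSE)
  idx <- match(df$name, state$nodes$name)
  new <- is.na(idx)
  state$nodes <- rbind(state$nodes, df[new, , drop = FALSE])
  for (i in which(!new)) {
    old <- state$nodes$entity_class[idx[i]]
    nw <- df$entity_class[i]
    if (old == "unknown" && nw != "unknown") {
      state$nodes$entity_class[idx[i]] <- nw
    } else if (old != "unknown" && nw != "unknown" && old != nw &&
               !(old == "small_molecule_complex" && nw == "complex")) {
      up_log("entity class conflict for %s: keeping %s, ignoring %s",
             df$name[i], old, nw)
    }
  }
  state
}

state_add_edges <- function(state, edges) {
  if (!nrow(edges)) return(state)
  combined <- rbind(state$edges, edges)
  key <- paste(combined$source, combined$target, combined$sign,
               combined$kind, combined$provenance, combined$reaction,
               sep = "\r")
  state$edges <- combined[!duplicated(key), , drop = FALSE]
  rownames(state$edges) <- NULL
  state
}

#' Advance the assembly one exploration level
#'
#' Expands and queries the current frontier, converts hits into signed
#' edges and hypergraph content, decomposes complex controllers, and
#' computes the next frontier.
#'
#' @param state An `assembly_state` with a non-empty frontier.
#' @param kb A `knowledge_base`.
#' @param network_kind `"regulation"` or `"signaling"`.
#' @param config An [expansion_config()].
#' @param excluded_sources Data sources to exclude.
#' @param synonym_table Optional [load_synonym_table()] result, used when
#'   `config$use_synonyms` is `TRUE`.
#' @param drop_unknown Drop unsigned interactions as they are parsed (the
#'   signed-interactions-only mode).
#' @param chunk_size Names per generated query.
#' @return The updated `assembly_state`.
#' @export
step_frontier <- function(state, kb, network_kind = c("regulation", "signaling"),
                          config = expansion_config(),
                          excluded_sources = character(),
                          synonym_table = NULL, drop_unknown = FALSE,
                          chunk_size = 20L) {
  network_kind <- match.arg(network_kind)
  stopifnot(inherits(state, "assembly_state"))
  if (length(state$frontier) == 0L) usage_error("step_frontier: empty frontier")
  kind <- if (network_kind == "regulation") "transcriptional" else "signaling"

  query_names <- state$frontier
  if (config$use_synonyms && !is.null(synonym_table)) {
    query_names <- suppressWarnings(expand_synonyms(query_names, synonym_table))
  }
  if (config$use_label_expansion) {
    query_names <- expand_labels(query_names, config)
  }
  query_names <- unique(query_names)

  raw <- list()
  for (chunk in chunk_names(query_batch(query_names, chunk_size))) {
    q <- if (network_kind == "regulation") {
      build_regulation_query(chunk, excluded_sources)
    } else {
      build_signaling_query(chunk, excluded_sources)
    }
    rows <- tryCatch(execute_query(kb, q), error = function(e) {
      if (inherits(e, "upnet_transport_error")) {
        transport_error(sprintf("level %d: %s", state$depth + 1L,
                                conditionMessage(e)),
                        level = state$depth + 1L)
      }
      stop(e)
    })
    raw[[length(raw) + 1L]] <- parse_bindings(rows, kind)
  }
  raw <- if (length(raw)) unique(do.call(rbind, raw)) else
    parse_bindings(data.frame(controllerName = character(),
                              targetName = character(),
                              reaction = character(),
                              stringsAsFactors = FALSE), kind)
  if (drop_unknown) {
    raw <- raw[raw$sign_token != "UNKNOWN", , drop = FALSE]
  }

  n_edges_before <- nrow(state$edges)
  n_nodes_before <- nrow(state$nodes)

  ctrl_canon <- strip_decorations(raw$controller_name, config)
  tgt_canon <- strip_decorations(raw$target_name, config)

  state <- state_add_nodes(state, tgt_canon, rep("unknown", length(tgt_canon)))
  state <- state_add_nodes(state, ctrl_canon, raw$controller_class)

  if (nrow(raw)) {
    state <- state_add_edges(state, data.frame(
      source = ctrl_canon, target = tgt_canon, sign = raw$sign_token,
      kind = raw$kind, provenance = raw$source_db, reaction = raw$reaction_id,
      stringsAsFactors = FALSE))
    # hypergraph content
    rx <- data.frame(id = raw$reaction_id, kind = raw$kind,
                     sign = raw$sign_token, source = raw$source_db,
                     stringsAsFactors = FALSE)
    ctl_role <- ifelse(raw$role == "left", "left-of", "controller-of")
    prod_role <- if (kind == "transcriptional") "product-of" else "right-of"
    part <- rbind(
      data.frame(entity = ctrl_canon, reaction = raw$reaction_id,
                 role = ctl_role, stringsAsFactors = FALSE),
      data.frame(entity = tgt_canon, reaction = raw$reaction_id,
                 role = prod_role, stringsAsFactors = FALSE))
    state$reactions <- unique(rbind(state$reactions, rx))
    # controller rows win over left rows for the same (entity, reaction)
    state$reactions <- state$reactions[!duplicated(state$reactions$id), , drop = FALSE]
    state$participation <- unique(rbind(state$participation, part))
  }

  new_names <- unique(ctrl_canon)

  # complex controllers: membership edges + member enqueueing
  if (config$use_complex_decomposition && nrow(raw)) {
    is_cx <- raw$controller_class %in% c("complex", "small_molecule_complex")
    cx <- unique(data.frame(name = ctrl_canon[is_cx],
                            iri = raw$controller_iri[is_cx],
                            stringsAsFactors = FALSE))
    for (i in seq_len(nrow(cx))) {
      res <- add_complex_membership_edges(
        state$edges,
        complex_entity = list(name = cx$name[i], entity_class = "complex",
                              iri = cx$iri[i]),
        config = config, kb = kb)
      state$edges <- res$edges
      if (length(res$members)) {
        state <- state_add_nodes(state, res$members, res$member_classes)
        if (any(res$member_classes == "small_molecule")) {
          j <- match(cx$name[i], state$nodes$name)
          state$nodes$entity_class[j] <- "small_molecule_complex"
        }
        # bipartite hypergraph form: complex-assembly pseudo-reaction
        aid <- paste0("urn:assembly:", cx$name[i])
        state$reactions <- unique(rbind(state$reactions, data.frame(
          id = aid, kind = "complex_assembly", sign = "UNKNOWN", source = "",
          stringsAsFactors = FALSE)))
        state$participation <- unique(rbind(
          state$participation,
          data.frame(entity = res$members, reaction = aid, role = "member-of",
                     stringsAsFactors = FALSE),
          data.frame(entity = cx$name[i], reaction = aid, role = "product-of",
                     stringsAsFactors = FALSE)))
        new_names <- unique(c(new_names, res$members))
      }
    }
  }

  state$explored <- sort_c(unique(c(state$explored, state$frontier)))
  next_frontier <- sort_c(setdiff(new_names, state$seen))
  state$seen <- sort_c(unique(c(state$seen, next_frontier)))
  state$frontier <- next_frontier
  state$depth <- state$depth + 1L
  state$log[[length(state$log) + 1L]] <- data.frame(
    level = state$depth, queried = length(query_names),
    new_edges = nrow(state$edges) - n_edges_before,
    new_nodes = nrow(state$nodes) - n_nodes_before,
    stringsAsFactors = FALSE)
  state
}

#' Add PART_OF membership edges for a complex controller
#'
#' Members come from explicit `bp:component` links when a knowledge base
#' and the complex IRI are available (preferred); otherwise the complex
#' label is decomposed syntactically with the configured delimiters.  One
#' `PART_OF` edge per member, oriented member -> complex, is added.
#'
#' @param edges Current edge data.frame.
#' @param complex_entity List with `name`, `entity_class` and optionally
#'   `iri`.
#' @param config An [expansion_config()].
#' @param kb Optional `knowledge_base` for explicit component lookup.
#' @return List with `edges` (updated), `members` (character) and
#'   `member_classes`.
#' @export
add_complex_membership_edges <- function(edges, complex_entity, config, kb = NULL) {
  if (!complex_entity$entity_class %in% c("complex", "small_molecule_complex")) {
    usage_error("add_complex_membership_edges: entity is not a complex")
  }
  members <- character()
  member_classes <- character()
  if (!is.null(kb) && !is.null(complex_entity$iri) && !is.na(complex_entity$iri)) {
    comp <- execute_query(kb, build_component_query(complex_entity$iri))
    if (nrow(comp)) {
      members <- strip_decorations(comp$memberName, config)
      member_classes <- entity_class_from_iri(comp$memberClass)
      ord <- order_c(members)
      members <- members[ord]; member_classes <- member_classes[ord]
      keep <- !duplicated(members)
      members <- members[keep]; member_classes <- member_classes[keep]
    }
  }
  if (!length(members)) {
    parts <- decompose_complex_label(complex_entity$name, config$complex_delimiters)
    if (length(parts) > 1L) {
      members <- sort_c(unique(parts))
      member_classes <- rep("unknown", length(members))
    } else {
      warning(sprintf(
        "complex %s has no component links and an indivisible label; no PART_OF edges",
        sQuote(complex_entity$name)), call. = FALSE)
      return(list(edges = edges, members = character(), member_classes = character()))
    }
  }
  new_edges <- data.frame(
    source = members, target = complex_entity$name, sign = "PART_OF",
    kind = "membership", provenance = "", reaction = "",
    stringsAsFactors = FALSE)
  combined <- rbind(edges, new_edges)
  key <- paste(combined$source, combined$target, combined$sign, sep = "\r")
  dup <- duplicated(key) & combined$sign == "PART_OF"
  list(edges = combined[!dup, , drop = FALSE],
       members = members, member_classes = member_classes)
}

#' Remove unsigned edges
#'
#' Drops every edge whose sign is `UNKNOWN`; `PART_OF` and signed edges
#' are retained.  Accepts an `influence_graph` or an edge data.frame and
#' returns the same type.
#'
#' @param edges An `influence_graph` or edge data.frame.
#' @return Filtered object of the same type.
#' @export
filter_unsigned <- function(edges) {
  if (inherits(edges, "influence_graph")) {
    kept <- edges$edges[edges$edges$sign != "UNKNOWN", , drop = FALSE]
    return(influence_graph(edges$nodes, kept))
  }
  edges[edges$sign != "UNKNOWN", , drop = FALSE]
}

#' Reconstruct the upstream network of a gene list
#'
#' Runs the recursive exploration until the frontier is exhausted or
#' `max_depth` query rounds have run (input genes are level 0), and
#' returns both graph forms, the coverage of the input list, the
#' per-source provenance histogram and the number of levels actually run.
#'
#' @param kb A `knowledge_base` (local file-backed or remote endpoint).
#' @param genes Character vector of input gene/protein names.
#' @param network_kind `"regulation"` (transcriptional) or `"signaling"`.
#' @param max_depth Maximum number of exploration levels (>= 1).
#' @param config An [expansion_config()].
#' @param excluded_sources Data-source names to exclude
#'   (e.g. `c("mirtarbase", "msigdb")`).
#' @param drop_unknown Keep only signed interactions.
#' @param synonym_table Optional synonym table for expansion and coverage.
#' @param chunk_size Names per generated query.
#' @param quiet Suppress per-level progress messages.
#' @return A `reconstruction_result` with fields `influence_graph`, `hypergraph`,
#'   `coverage`, `provenance_histogram`, `levels_run` and `log`.
#' @examples
#' kb <- generate_kb(kb_spec(n_genes = 1, n_levels = 3, seed = 7))
#' res <- reconstruct(kb$kb, kb$truth$input_genes, max_depth = 3)
#' res
#' @export
reconstruct <- function(kb, genes, network_kind = c("regulation", "signaling"),
                        max_depth = 10L, config = expansion_config(),
                        excluded_sources = character(), drop_unknown = FALSE,
                        synonym_table = NULL, chunk_size = 20L, quiet = TRUE) {
  network_kind <- match.arg(network_kind)
  if (length(genes) == 0L) usage_error("reconstruct: empty gene list")
  if (!is.numeric(max_depth) || max_depth < 1) {
    usage_error("reconstruct: max_depth must be >= 1")
  }
  state <- assembly_state(genes)
  while (length(state$frontier) > 0L && state$depth < max_depth) {
    state <- step_frontier(state, kb, network_kind, config, excluded_sources,
                           synonym_table, drop_unknown, chunk_size)
    lg <- state$log[[length(state$log)]]
    up_log("level %d: queried %d names, +%d edges, +%d nodes",
           lg$level, lg$queried, lg$new_edges, lg$new_nodes, quiet = quiet)
  }
  graph <- influence_graph(state$nodes, state$edges)
  hyper <- suppressWarnings(hypergraph(
    entities = data.frame(name = state$nodes$name,
                          entity_class = state$nodes$entity_class,
                          stringsAsFactors = FALSE),
    reactions = state$reactions, participation = state$participation))
  structure(list(
    influence_graph = graph,
    hypergraph = hyper,
    coverage = coverage(genes, graph, synonyms = synonym_table),
    provenance_histogram = provenance_histogram(graph),
    levels_run = state$depth,
    log = if (length(state$log)) do.call(rbind, state$log) else NULL
  ), class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf("<upstream network: %d nodes, %d edges, %d level(s) explored>\n",
              n_nodes(x$influence_graph), n_edges(x$influence_graph),
              x$levels_run))
  cat(sprintf("  coverage: %.2f%% (%d of %d input genes in graph)\n",
              x$coverage$S, length(x$coverage$ON), length(x$coverage$IG)))
  if (length(x$provenance_histogram)) {
    cat("  provenance:", paste(sprintf("%s=%d", names(x$provenance_histogram),
                                       x$provenance_histogram), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
summary.reconstruction_result <- function(object, ...) {
  print(object)
  if (!is.null(object$log)) {
    cat("  per-level log:\n")
    print(object$log, row.names = FALSE)
  }
  invisible(object)
}
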