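# Output formats: Cytoscape SIF (+ edge/node attribute TSVs), signed
# network tables for sign-consistency tools, hypergraph TSV/GraphML.

#' Export an influence graph as a SIF file
#'
#' Writes one line per edge, `source<TAB>RELATION<TAB>target` with
#' RELATION in ACTIVATION/INHIBITION/UNKNOWN/PART_OF, lexicographically
#' sorted (no header, the Cytoscape simple-interaction dialect).  A
#' companion edge-attribute TSV (`<path>.attrs.tsv` by default) carries
#' kind and provenance per edge.  Parallel edges are preserved as
#' distinct lines.
#'
#' @param graph An `influence_graph`.
#' @param path Output SIF path.
#' @param attrs_path Edge-attribute table path (default `<path>.attrs.tsv`).
#' @return Invisibly, `path`.
#' @export
export_sif <- function(graph, path, attrs_path = paste0(path, ".attrs.tsv")) {
  stopifnot(inherits(graph, "influence_graph"))
  e <- graph$edges
  lines <- if (nrow(e)) sort_c(paste(e$source, e$sign, e$target, sep = "\t")) else character()
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(err) FALSE, warning = function(err) FALSE)
  if (!ok) export_error(sprintf("cannot write SIF file: %s", path))
  attrs <- e[order_c(e$source, e$sign, e$target, e$provenance), , drop = FALSE]
  hdr <- "source\trelation\ttarget\tkind\tprovenance"
  body <- if (nrow(attrs)) paste(attrs$source, attrs$sign, attrs$target,
                                 attrs$kind, attrs$provenance, sep = "\t")
          else character()
  writeLines(c(hdr, body), attrs_path)
  invisible(path)
}

#' Read a SIF file back into an influence graph
#'
#' Inverse of [export_sif()]; node classes are `unknown` unless a
#' companion attribute table is supplied.
#'
#' @param path SIF path.
#' @return An `influence_graph`.
#' @export
read_sif <- function(path) {
  if (!file.exists(path)) input_error(sprintf("SIF file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(influence_graph())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) input_error(sprintf("malformed SIF line %d in %s", bad[1L], path))
  edges <- data.frame(
    source = vapply(parts, `[[`, "", 1L),
    sign = vapply(parts, `[[`, "", 2L),
    target = vapply(parts, `[[`, "", 3L),
    stringsAsFactors = FALSE)
  edges$kind <- ifelse(edges$sign == "PART_OF", "membership", "unknown")
  edges$provenance <- ""
  edges$reaction <- ""
  influence_graph(edges = edges)
}

#' Export a signed network table for sign-consistency tools
#'
#' Writes a three-column TSV (`source`, `sign`, `target`) with signs `+`
#' and `-`: ACTIVATION maps to `+`, INHIBITION to `-`, and PART_OF
#' (protein-complex membership, treated as a positive influence) to `+`
#' when `part_of_sign = "plus"` or is dropped when `part_of_sign =
#' "drop"`.  UNKNOWN edges are omitted when `drop_unknown = TRUE`;
#' otherwise their presence is an error instructing the caller to filter
#' first.
#'
#' @param graph An `influence_graph`.
#' @param part_of_sign `"plus"` or `"drop"`.
#' @param drop_unknown Silently omit UNKNOWN edges.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_signed_network <- function(graph, path, part_of_sign = c("plus", "drop"),
                                  drop_unknown = FALSE) {
  stopifnot(inherits(graph, "influence_graph"))
  part_of_sign <- match.arg(part_of_sign)
  e <- graph$edges
  if (any(e$sign == "UNKNOWN")) {
    if (drop_unknown) {
      e <- e[e$sign != "UNKNOWN", , drop = FALSE]
    } else {
      export_error(paste0(
        "graph contains UNKNOWN-signed edges; filter them first ",
        "(filter_unsigned) or pass drop_unknown = TRUE"))
    }
  }
  if (part_of_sign == "drop") {
    e <- e[e$sign != "PART_OF", , drop = FALSE]
  }
  sign_chr <- c(ACTIVATION = "+", INHIBITION = "-", PART_OF = "+")[e$sign]
  hdr <- "source\tsign\ttarget"
  body <- if (nrow(e)) sort_c(paste(e$source, sign_chr, e$target, sep = "\t"))
          else character()
  ok <- tryCatch({ writeLines(c(hdr, body), path); TRUE },
                 error = function(err) FALSE, warning = function(err) FALSE)
  if (!ok) export_error(sprintf("cannot write signed network file: %s", path))
  invisible(path)
}

#' Export a hypergraph as participation-edge TSV
#'
#' One row per typed participation link (`entity`, `role`, `reaction`,
#' `reaction_kind`, `sign`, `source`), plus an entity table alongside
#' (`<path>.entities.tsv`).
#'
#' @param h A `hypergraph`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_hypergraph <- function(h, path) {
  stopifnot(inherits(h, "hypergraph"))
  p <- h$participation
  i <- match(p$reaction, h$reactions$id)
  hdr <- "entity\trole\treaction\treaction_kind\tsign\tsource"
  body <- if (nrow(p)) paste(p$entity, p$role, p$reaction,
                             h$reactions$kind[i], h$reactions$sign[i],
                             h$reactions$source[i], sep = "\t") else character()
  writeLines(c(hdr, sort_c(body)), path)
  ent <- h$entities
  writeLines(c("name\tentity_class",
               if (nrow(ent)) sort_c(paste(ent$name, ent$entity_class, sep = "\t"))
               else character()),
             paste0(path, ".entities.tsv"))
  invisible(path)
}
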