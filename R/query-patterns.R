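# Generation of the two BioPAX pattern-matching queries (transcriptional
# regulation vs. signaling) for a batch of entity names, and parsing of
# their results into raw interactions.
#
# Regulation pattern:  TemplateReactionRegulation -> controlled
#   TemplateReaction -> product entity whose displayName or additional
#   name is in the batch.
# Signaling pattern:   Control or Catalysis -> controlled
#   BiochemicalReaction with a right-hand participant named in the batch;
#   upstream entities are the controllers plus left-hand participants.

query_prefix <- function() paste0("PREFIX bp: <", BP, ">\n")

quote_lit <- function(x) paste0("\"", escape_literal(x), "\"")

name_filter <- function(var, names) {
  sprintf("  FILTER (?%s IN (%s))\n", var, paste(quote_lit(names), collapse = ", "))
}

exclusion_filter <- function(excluded_sources) {
  if (length(excluded_sources) == 0) return("")
  sprintf("  FILTER (?source NOT IN (%s))\n",
          paste(quote_lit(sort_c(unique(excluded_sources))), collapse = ", "))
}

provenance_block <- function(subject_var) {
  paste0(
    "  OPTIONAL { ?", subject_var, " bp:dataSource ?ds .\n",
    "    { ?ds bp:displayName ?source . } UNION { ?ds bp:name ?source . } }\n"
  )
}

#' Build the transcriptional-regulation query for a batch of names
#'
#' Matches a `bp:TemplateReactionRegulation` whose controlled
#' `bp:TemplateReaction` produces an entity whose display name or
#' additional name is one of `names`, and selects the controller name and
#' class, product name, control type, data source and interaction IRI.
#' Rows whose data source is in `excluded_sources` are filtered out;
#' statements with no data-source annotation are kept.
#'
#' @param names Character vector of entity names (non-empty).
#' @param excluded_sources Character vector of data-source names to
#'   exclude (e.g. `c("mirtarbase", "msigdb")`).
#' @return SPARQL query text.
#' @export
build_regulation_query <- function(names, excluded_sources = character()) {
  if (length(names) == 0) usage_error("build_regulation_query: empty name list")
  paste0(
    query_prefix(),
    "SELECT DISTINCT ?controllerName ?targetName ?controlType ?source ",
    "?reaction ?controllerClass ?controller WHERE {\n",
    "  ?reaction a bp:TemplateReactionRegulation .\n",
    "  ?reaction bp:controlled ?template .\n",
    "  ?template a bp:TemplateReaction .\n",
    "  ?template bp:product ?product .\n",
    "  { ?product bp:displayName ?targetName . } UNION { ?product bp:name ?targetName . }\n",
    name_filter("targetName", names),
    "  ?reaction bp:controller ?controller .\n",
    "  ?controller bp:displayName ?controllerName .\n",
    "  ?controller a ?controllerClass .\n",
    "  OPTIONAL { ?reaction bp:controlType ?controlType . }\n",
    provenance_block("reaction"),
    exclusion_filter(excluded_sources),
    "}"
  )
}

#' Build the signaling query for a batch of names
#'
#' Matches a `bp:Control` or `bp:Catalysis` whose controlled
#' `bp:BiochemicalReaction` has an entity named in `names` among its
#' right-hand participants.  Upstream entities are the controllers plus
#' the reaction's left-hand participants.
#'
#' @inheritParams build_regulation_query
#' @return SPARQL query text.
#' @export
build_signaling_query <- function(names, excluded_sources = character()) {
  if (length(names) == 0) usage_error("build_signaling_query: empty name list")
  paste0(
    query_prefix(),
    "SELECT DISTINCT ?controllerName ?targetName ?controlType ?source ",
    "?reaction ?controllerClass ?controller ?leftName ?leftClass ?leftEnt WHERE {\n",
    "  { ?reaction a bp:Control . } UNION { ?reaction a bp:Catalysis . }\n",
    "  ?reaction bp:controlled ?rxn .\n",
    "  ?rxn a bp:BiochemicalReaction .\n",
    "  ?rxn bp:right ?product .\n",
    "  { ?product bp:displayName ?targetName . } UNION { ?product bp:name ?targetName . }\n",
    name_filter("targetName", names),
    "  ?reaction bp:controller ?controller .\n",
    "  ?controller bp:displayName ?controllerName .\n",
    "  ?controller a ?controllerClass .\n",
    "  OPTIONAL { ?rxn bp:left ?leftEnt .\n",
    "    ?leftEnt bp:displayName ?leftName .\n",
    "    ?leftEnt a ?leftClass . }\n",
    "  OPTIONAL { ?reaction bp:controlType ?controlType . }\n",
    provenance_block("reaction"),
    exclusion_filter(excluded_sources),
    "}"
  )
}

# Components of a complex entity (explicit bp:component links).
build_component_query <- function(complex_iri) {
  paste0(
    query_prefix(),
    "SELECT DISTINCT ?memberName ?memberClass ?member WHERE {\n",
    "  <", complex_iri, "> bp:component ?member .\n",
    "  ?member bp:displayName ?memberName .\n",
    "  ?member a ?memberClass .\n",
    "}"
  )
}

#' Create a query batch
#'
#' @param names Character vector of entity names; duplicates are an error.
#' @param chunk_size Maximum number of names per generated query
#'   (default 20, keeping generated queries below endpoint limits).
#' @return A `query_batch` object.
#' @export
query_batch <- function(names, chunk_size = 20L) {
  if (anyDuplicated(names)) usage_error("query_batch: duplicate names in batch")
  if (!is.numeric(chunk_size) || chunk_size < 1) {
    usage_error("query_batch: chunk_size must be >= 1")
  }
  structure(list(names = as.character(names), chunk_size = as.integer(chunk_size)),
            class = "query_batch")
}

#' Split a batch of names into query-sized chunks
#'
#' Concatenating the chunks reproduces the input order; each chunk has at
#' most `chunk_size` names and the last chunk may be shorter.
#'
#' @param batch A `query_batch` (or a character vector, using the default
#'   chunk size).
#' @return List of character vectors; empty list for zero names.
#' @export
chunk_names <- function(batch) {
  if (is.character(batch)) batch <- query_batch(batch)
  n <- length(batch$names)
  if (n == 0L) return(list())
  unname(split(batch$names, ceiling(seq_len(n) / batch$chunk_size)))
}

#' Parse a bindings table into raw interactions
#'
#' Converts rows returned by the regulation or signaling query into one
#' raw interaction per row.  Control-type literals are normalized by
#' substring (any literal containing `ACTIVATION` or `INHIBITION` maps to
#' that sign; anything else, including absent, maps to `UNKNOWN`).  For
#' signaling rows, left-hand participants yield additional
#' participant interactions with sign `UNKNOWN`.  Duplicate rows (same
#' controller, target, sign, source, reaction) are collapsed.
#'
#' @param rows Bindings data.frame from [execute_query()].
#' @param kind `"transcriptional"` or `"signaling"`.
#' @return A data.frame of raw interactions with columns `controller_name`,
#'   `target_name`, `sign_token`, `kind`, `source_db`, `reaction_id`,
#'   `controller_class`, `controller_iri` and `role` (`"controller"` or
#'   `"left"` for left-hand reaction participants).
#' @export
parse_bindings <- function(rows, kind = c("transcriptional", "signaling")) {
  kind <- match.arg(kind)
  mandatory <- c("controllerName", "targetName", "reaction")
  missing_vars <- setdiff(mandatory, names(rows))
  if (length(missing_vars)) {
    results_error(sprintf("bindings lack mandatory variable(s): %s",
                          paste(missing_vars, collapse = ", ")))
  }
  get <- function(v, default = NA_character_) {
    if (v %in% names(rows)) rows[[v]] else rep(default, nrow(rows))
  }
  base <- data.frame(
    controller_name  = rows$controllerName,
    target_name      = rows$targetName,
    sign_token       = normalize_sign(get("controlType")),
    kind             = rep(kind, nrow(rows)),
    source_db        = ifelse(is.na(get("source")), "unspecified", get("source")),
    reaction_id      = rows$reaction,
    controller_class = entity_class_from_iri(get("controllerClass")),
    controller_iri   = get("controller"),
    role             = rep("controller", nrow(rows)),
    stringsAsFactors = FALSE
  )
  out <- base
  if (kind == "signaling" && "leftName" %in% names(rows)) {
    has_left <- !is.na(rows$leftName)
    if (any(has_left)) {
      left <- data.frame(
        controller_name  = rows$leftName[has_left],
        target_name      = rows$targetName[has_left],
        sign_token       = "UNKNOWN",
        kind             = "signaling",
        source_db        = ifelse(is.na(get("source")[has_left]), "unspecified",
                                  get("source")[has_left]),
        reaction_id      = rows$reaction[has_left],
        controller_class = entity_class_from_iri(get("leftClass")[has_left]),
        controller_iri   = get("leftEnt")[has_left],
        role             = "left",
        stringsAsFactors = FALSE
      )
      out <- rbind(base, left)
    }
  }
  out <- out[!is.na(out$controller_name) & !is.na(out$target_name), , drop = FALSE]
  key <- paste(out$controller_name, out$target_name, out$sign_token,
               out$source_db, out$reaction_id, sep = "\r")
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order_c(out$controller_name, out$target_name, out$sign_token,
                     out$source_db, out$reaction_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
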