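#' Load a BioPAX-typed RDF knowledge base from a local file
#'
#' Parses an RDF file into an in-memory, queryable knowledge base.  The
#' supported serializations are Turtle, RDF/XML and N-Triples.  Only
#' asserted triples are visible: no OWL reasoning is performed.
#'
#' @param path Path to an RDF file.
#' @param serialization One of `"turtle"`, `"rdfxml"`, `"ntriples"`.  When
#'   missing it is inferred from the file extension (`.ttl`, `.rdf`/`.owl`/
#'   `.xml`, `.nt`).
#' @return A `knowledge_base` object in local mode.
#' @examples
#' f <- tempfile(fileext = ".ttl")
#' writeLines(c(
#'   "@prefix bp: <http://www.biopax.org/release/biopax-level3.owl#> .",
#'   "@prefix kb: <http://example.org/kb/> .",
#'   "kb:p1 a bp:Protein ; bp:displayName \"TP53\" ."), f)
#' kb <- load_rdf_graph(f)
#' kb_size(kb)
#' @export
load_rdf_graph <- function(path, serialization = NULL) {
  if (!file.exists(path)) input_error(sprintf("RDF file not found: %s", path))
  if (is.null(serialization)) {
    ext <- tolower(tools::file_ext(path))
    serialization <- switch(ext,
      ttl = "turtle", turtle = "turtle",
      nt = "ntriples", ntriples = "ntriples",
      rdf = "rdfxml", owl = "rdfxml", xml = "rdfxml",
      usage_error(sprintf(
        "cannot infer serialization from extension %s; pass `serialization`",
        sQuote(ext))))
  }
  serialization <- match.arg(serialization, c("turtle", "rdfxml", "ntriples"))
  triples <- switch(serialization,
    turtle   = parse_turtle(paste(readLines(path, warn = FALSE), collapse = "\n"),
                            what = path),
    ntriples = parse_ntriples(paste(readLines(path, warn = FALSE), collapse = "\n"),
                              what = path),
    rdfxml   = parse_rdfxml(path, what = path)
  )
  kb_from_triples(triples)
}

# Build a local knowledge base directly from a triple data.frame.
kb_from_triples <- function(triples) {
  structure(
    list(triples = triples, mode = "local", endpoint = NULL,
         transport = NULL, timeout = 60, retries = 3L),
    class = "knowledge_base"
  )
}

#' Connect to a remote SPARQL endpoint
#'
#' Creates a knowledge base handle that evaluates queries over the SPARQL
#' protocol (HTTP POST, JSON results).  Requests are retried with a bounded
#' retry count before failing with a transport error.
#'
#' @param endpoint Endpoint URL.
#' @param timeout Per-request timeout in seconds (default 60).
#' @param retries Number of attempts before giving up (default 3).
#' @param transport Optional function `function(endpoint, query, timeout)`
#'   returning the response body as a string; used to inject test
#'   transports.  The default posts the query with curl.
#' @return A `knowledge_base` object in remote mode.
#' @export
remote_knowledge_base <- function(endpoint, timeout = 60, retries = 3L,
                                  transport = NULL) {
  stopifnot(is.character(endpoint), length(endpoint) == 1L)
  structure(
    list(triples = NULL, mode = "remote", endpoint = endpoint,
         transport = transport %||% curl_transport,
         timeout = timeout, retries = as.integer(retries)),
    class = "knowledge_base"
  )
}

curl_transport <- function(endpoint, query, timeout) {
  h <- curl::new_handle(timeout = timeout)
  curl::handle_setheaders(h, Accept = "application/sparql-results+json")
  curl::handle_setform(h, query = query)
  resp <- curl::curl_fetch_memory(endpoint, handle = h)
  if (resp$status_code >= 400) {
    stop(sprintf("HTTP status %d", resp$status_code))
  }
  rawToChar(resp$content)
}

#' Number of statements in a local knowledge base
#' @param kb A `knowledge_base`.
#' @return Integer triple count (local mode only).
#' @export
kb_size <- function(kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  if (kb$mode != "local") usage_error("kb_size is only defined for local knowledge bases")
  nrow(kb$triples)
}

#' @export
print.knowledge_base <- function(x, ...) {
  if (x$mode == "local") {
    cat(sprintf("<knowledge_base: local, %d statements>\n", nrow(x$triples)))
  } else {
    cat(sprintf("<knowledge_base: remote, endpoint %s>\n", x$endpoint))
  }
  invisible(x)
}

#' Execute a SPARQL query against a knowledge base
#'
#' Local knowledge bases are evaluated in memory; remote ones are queried
#' over the SPARQL protocol with bounded retries.  Both modes return the
#' same bindings-table structure for identical data: a data.frame with one
#' column per selected variable and `NA` for unbound values.
#'
#' @param kb A `knowledge_base`.
#' @param query SPARQL `SELECT` query text (see package vignette for the
#'   supported local-evaluation subset).
#' @return A data.frame of bindings.
#' @export
execute_query <- function(kb, query) {
  stopifnot(inherits(kb, "knowledge_base"))
  if (kb$mode == "local") {
    return(sparql_eval(kb$triples, query))
  }
  # validate syntax locally before spending round-trips
  sparql_parse(query)
  last <- NULL
  for (attempt in seq_len(kb$retries)) {
    body <- tryCatch(kb$transport(kb$endpoint, query, kb$timeout),
                     error = function(e) { last <<- conditionMessage(e); NULL })
    if (!is.null(body)) return(parse_sparql_results_json(body))
  }
  transport_error(
    sprintf("SPARQL endpoint %s unreachable after %d attempt(s): %s",
            kb$endpoint, kb$retries, last %||% "unknown failure"),
    endpoint = kb$endpoint, attempts = kb$retries
  )
}

#' List the data sources attached to a knowledge base
#'
#' Returns every distinct data-source name attached to any statement via a
#' `bp:dataSource` provenance node.  Interactions without a provenance node
#' are not represented here (a warning is emitted in local mode); their
#' parsed interactions carry the source `"unspecified"`.
#'
#' @param kb A `knowledge_base`.
#' @return Sorted character vector of source names.
#' @export
list_data_sources <- function(kb) {
  q <- paste0(
    "PREFIX bp: <", BP, ">\n",
    "SELECT DISTINCT ?src WHERE {\n",
    "  ?x bp:dataSource ?ds .\n",
    "  { ?ds bp:displayName ?src . } UNION { ?ds bp:name ?src . }\n",
    "}"
  )
  res <- execute_query(kb, q)
  srcs <- sort_c(unique(res$src[!is.na(res$src) & nzchar(res$src)]))
  if (kb$mode == "local") {
    tr <- kb$triples
    inter_classes <- bp(c("TemplateReactionRegulation", "Control", "Catalysis"))
    inter <- tr$s[tr$p == RDF_TYPE & tr$o %in% inter_classes]
    tagged <- tr$s[tr$p == bp("dataSource")]
    untagged <- setdiff(inter, tagged)
    if (length(untagged)) {
      warning(sprintf("%d interaction(s) carry no data-source annotation", length(untagged)),
              call. = FALSE)
    }
  }
  srcs
}
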