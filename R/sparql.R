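# Restricted SPARQL engine for local knowledge bases.
#
# Supported grammar (the subset the query builders emit):
#   PREFIX decls; SELECT [DISTINCT] ?v ... WHERE { ... }
#   group elements: triple patterns (terminated by '.'), nested groups
#   combined with UNION, OPTIONAL { ... }, FILTER (?v [NOT] IN (...)).
# Semantics notes: joins treat unbound (NA) as matching NA only; generated
# queries never re-join a variable that can be unbound.  FILTER ... NOT IN
# keeps rows where the variable is unbound (used for provenance exclusion
# of untagged statements).
#
# Bound values are encoded internally as "U<iri>" / "L<literal>" so that
# the literal/IRI distinction survives joins and can be round-tripped
# through the SPARQL results JSON format.

sparql_parse <- function(query) {
  ts <- tryCatch(rdf_tokenize(query, "query"),
                 error = function(e) usage_error(conditionMessage(e)))
  toks <- ts$tokens
  n <- length(toks)
  i <- 1L
  prefixes <- c(rdf = RDF_NS)

  fail <- function(msg) usage_error(sprintf("query syntax error near token %d (%s): %s",
                                            i, sQuote(if (i <= n) toks[i] else "<eof>"), msg))
  peek <- function() if (i <= n) toks[i] else ""
  kw <- function(word) toupper(peek()) == word
  advance <- function() { i <<- i + 1L }
  expect_kw <- function(word) { if (!kw(word)) fail(sprintf("expected %s", word)); advance() }

  resolve_pname <- function(tok) {
    colon <- regexpr(":", tok, fixed = TRUE)
    pfx <- substr(tok, 1, colon - 1)
    if (!pfx %in% names(prefixes)) fail(sprintf("undeclared prefix %s", sQuote(pfx)))
    paste0(prefixes[[pfx]], substr(tok, colon + 1, nchar(tok)))
  }
  term <- function(role) {
    tok <- peek()
    if (tok == "") fail("unexpected end of query")
    advance()
    if (startsWith(tok, "?")) return(list(kind = "var", v = substr(tok, 2, nchar(tok))))
    if (startsWith(tok, "<")) return(list(kind = "iri", v = substr(tok, 2, nchar(tok) - 1)))
    if (startsWith(tok, "\"")) {
      if (role != "o") fail("literal only allowed in object position")
      return(list(kind = "lit", v = unescape_literal(tok)))
    }
    if (tok == "a" && role == "p") return(list(kind = "iri", v = RDF_TYPE))
    if (grepl(":", tok, fixed = TRUE)) return(list(kind = "iri", v = resolve_pname(tok)))
    fail("expected an IRI, literal or variable")
  }
  parse_literal_list <- function() {
    if (peek() != "(") fail("expected '('")
    advance()
    vals <- character()
    repeat {
      tok <- peek()
      if (!startsWith(tok, "\"")) fail("expected string literal in IN list")
      vals <- c(vals, unescape_literal(tok))
      advance()
      if (peek() == ",") { advance(); next }
      break
    }
    if (peek() != ")") fail("expected ')'")
    advance()
    vals
  }
  parse_group <- function() {
    if (peek() != "{") fail("expected '{'")
    advance()
    elements <- list()
    repeat {
      tok <- peek()
      if (tok == "}") { advance(); break }
      if (tok == "") fail("unterminated group")
      if (tok == "{") {
        branches <- list(parse_group())
        while (kw("UNION")) { advance(); branches[[length(branches) + 1L]] <- parse_group() }
        elements[[length(elements) + 1L]] <-
          if (length(branches) == 1L) branches[[1L]] else list(type = "union", branches = branches)
        next
      }
      if (kw("OPTIONAL")) {
        advance()
        elements[[length(elements) + 1L]] <- list(type = "optional", group = parse_group())
        next
      }
      if (kw("FILTER")) {
        advance()
        if (peek() != "(") fail("expected '(' after FILTER")
        advance()
        v <- term("o")
        if (v$kind != "var") fail("FILTER supports only ?var [NOT] IN (...)")
        negated <- FALSE
        if (kw("NOT")) { negated <- TRUE; advance() }
        expect_kw("IN")
        vals <- parse_literal_list()
        if (peek() != ")") fail("expected ')' closing FILTER")
        advance()
        elements[[length(elements) + 1L]] <-
          list(type = "filter", var = v$v, negated = negated, values = vals)
        next
      }
      s <- term("s"); p <- term("p"); o <- term("o")
      if (peek() != ".") fail("expected '.' after triple pattern")
      advance()
      elements[[length(elements) + 1L]] <- list(type = "triple", s = s, p = p, o = o)
    }
    list(type = "group", elements = elements)
  }

  while (kw("PREFIX")) {
    advance()
    pn <- peek()
    if (!grepl(":$", pn)) fail("expected prefix name ending in ':'")
    advance()
    iri <- peek()
    if (!startsWith(iri, "<")) fail("expected IRI in PREFIX")
    advance()
    prefixes[[substr(pn, 1, nchar(pn) - 1)]] <- substr(iri, 2, nchar(iri) - 1)
  }
  expect_kw("SELECT")
  distinct <- FALSE
  if (kw("DISTINCT")) { distinct <- TRUE; advance() }
  vars <- character()
  while (startsWith(peek(), "?")) { vars <- c(vars, substr(peek(), 2, nchar(peek()))); advance() }
  if (!length(vars)) fail("SELECT needs at least one variable")
  expect_kw("WHERE")
  grp <- parse_group()
  if (i <= n) fail("trailing tokens after query body")
  list(select = vars, distinct = distinct, group = grp)
}

## ---- evaluation -----------------------------------------------------------

sparql_unit <- function() data.frame(row.names = 1L)

sparql_join <- function(a, b, left = FALSE) {
  if (ncol(a) == 0L) return(if (nrow(a) > 0L) b else b[0L, , drop = FALSE])
  if (ncol(b) == 0L) return(if (nrow(b) > 0L || left) a else a[0L, , drop = FALSE])
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0L) {
    if (nrow(b) == 0L && left) return(a)
    ia <- rep(seq_len(nrow(a)), each = max(nrow(b), 0L))
    ib <- rep(seq_len(nrow(b)), times = nrow(a))
    return(cbind(a[ia, , drop = FALSE], b[ib, , drop = FALSE], row.names = NULL))
  }
  out <- merge(a, b, by = shared, all.x = left, sort = FALSE)
  rownames(out) <- NULL
  out
}

sparql_eval_group <- function(grp, tr) {
  sol <- sparql_unit()
  filters <- list()
  for (el in grp$elements) {
    sol <- switch(el$type,
      triple = sparql_join(sol, sparql_eval_triple(el, tr)),
      group = sparql_join(sol, sparql_eval_group(el, tr)),
      optional = sparql_join(sol, sparql_eval_group(el$group, tr), left = TRUE),
      union = {
        parts <- lapply(el$branches, sparql_eval_group, tr = tr)
        sparql_join(sol, rbind_fill(parts))
      },
      filter = { filters[[length(filters) + 1L]] <- el; sol }
    )
  }
  for (f in filters) {
    vals <- if (f$var %in% names(sol)) sol[[f$var]] else rep(NA_character_, nrow(sol))
    enc <- paste0("L", f$values)
    keep <- if (f$negated) is.na(vals) | !(vals %in% enc) else !is.na(vals) & vals %in% enc
    sol <- sol[keep, , drop = FALSE]
  }
  rownames(sol) <- NULL
  sol
}

rbind_fill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (m in setdiff(cols, names(d))) d[[m]] <- rep(NA_character_, nrow(d))
    d[, cols, drop = FALSE]
  })
  out <- do.call(rbind, dfs)
  rownames(out) <- NULL
  out
}

sparql_eval_triple <- function(el, tr) {
  enc <- attr(tr, "enc")
  sel <- rep(TRUE, nrow(tr))
  cols <- list(s = enc$s, p = enc$p, o = enc$o)
  for (pos in c("s", "p", "o")) {
    t <- el[[pos]]
    if (t$kind == "iri") sel <- sel & cols[[pos]] == paste0("U", t$v)
    else if (t$kind == "lit") sel <- sel & cols[[pos]] == paste0("L", t$v)
  }
  out <- list()
  for (pos in c("s", "p", "o")) {
    t <- el[[pos]]
    if (t$kind == "var") {
      vals <- cols[[pos]][sel]
      if (t$v %in% names(out)) {            # same var twice in a pattern
        keep <- out[[t$v]] == vals
        out <- lapply(out, `[`, keep)
        sel_idx <- which(sel)[keep]
        sel <- rep(FALSE, nrow(tr)); sel[sel_idx] <- TRUE
      } else out[[t$v]] <- vals
    }
  }
  if (length(out) == 0L) {
    return(if (any(sel)) sparql_unit() else sparql_unit()[0L, , drop = FALSE])
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# Evaluate a parsed (or textual) query against a triple data.frame.
# Returns a data.frame of decoded values (columns = selected vars, NA for
# unbound) with a "types" attribute ("uri"/"literal"/NA per cell).
sparql_eval <- function(triples, query) {
  ast <- if (is.character(query)) sparql_parse(query) else query
  enc <- list(
    s = paste0("U", triples$s),
    p = paste0("U", triples$p),
    o = paste0(ifelse(triples$o_lit, "L", "U"), triples$o)
  )
  attr(triples, "enc") <- enc
  sol <- sparql_eval_group(ast$group, triples)
  for (v in setdiff(ast$select, names(sol))) sol[[v]] <- rep(NA_character_, nrow(sol))
  sol <- sol[, ast$select, drop = FALSE]
  if (ast$distinct && nrow(sol)) {
    sol <- unique(sol)
    rownames(sol) <- NULL
  }
  types <- as.data.frame(lapply(sol, function(col)
    ifelse(is.na(col), NA_character_,
           ifelse(startsWith(col, "U"), "uri", "literal"))),
    stringsAsFactors = FALSE, optional = TRUE)
  decoded <- as.data.frame(lapply(sol, function(col)
    ifelse(is.na(col), NA_character_, substr(col, 2, nchar(col)))),
    stringsAsFactors = FALSE, optional = TRUE)
  names(decoded) <- names(sol)
  if (nrow(sol) == 0L) {
    decoded <- as.data.frame(setNames(rep(list(character()), length(ast$select)), ast$select),
                             stringsAsFactors = FALSE)
    types <- decoded
  }
  attr(decoded, "types") <- types
  decoded
}

## ---- SPARQL results JSON (remote protocol) --------------------------------

# Serialize a bindings table (as returned by sparql_eval) to the standard
# application/sparql-results+json document.  Used by the in-process test
# endpoint; the inverse is used for real remote endpoints.
sparql_results_json <- function(bindings) {
  vars <- names(bindings)
  types <- attr(bindings, "types")
  rows <- lapply(seq_len(nrow(bindings)), function(i) {
    row <- list()
    for (v in vars) {
      val <- bindings[[v]][i]
      if (is.na(val)) next
      ty <- if (!is.null(types)) types[[v]][i] else NULL
      if (is.null(ty) || is.na(ty)) ty <- if (grepl("^[a-z][a-z0-9+.-]*://", val)) "uri" else "literal"
      row[[v]] <- list(type = ty, value = val)
    }
    row
  })
  jsonlite::toJSON(
    list(head = list(vars = vars), results = list(bindings = rows)),
    auto_unbox = TRUE, null = "null"
  )
}

parse_sparql_results_json <- function(txt) {
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) results_error(
                    sprintf("malformed SPARQL results JSON: %s", conditionMessage(e))))
  vars <- unlist(doc$head$vars)
  if (is.null(vars)) results_error("SPARQL results JSON lacks head.vars")
  rows <- doc$results$bindings
  out <- lapply(vars, function(v)
    vapply(rows, function(r) if (is.null(r[[v]])) NA_character_ else r[[v]]$value, ""))
  names(out) <- vars
  df <- as.data.frame(out, stringsAsFactors = FALSE, optional = TRUE)
  if (length(rows) == 0L) {
    df <- as.data.frame(setNames(rep(list(character()), length(vars)), vars),
                        stringsAsFactors = FALSE)
  }
  types <- lapply(vars, function(v)
    vapply(rows, function(r) if (is.null(r[[v]])) NA_character_ else r[[v]]$type, ""))
  names(types) <- vars
  attr(df, "types") <- as.data.frame(types, stringsAsFactors = FALSE, optional = TRUE)
  df
}
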