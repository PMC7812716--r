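# Minimal RDF I/O over a plain triple table.
#
# Triples are held in a data.frame with columns
#   s, p, o : character (IRIs, or blank-node labels "_:x")
#   o_lit   : logical, TRUE when `o` is a literal
#
# Readers cover the serializations the package emits and the idioms found
# in BioPAX exports: Turtle (prefixes, `a`, `;`/`,` continuations, string
# and numeric literals with escapes), N-Triples, and flat RDF/XML
# (rdf:Description or typed elements with rdf:about/rdf:resource and
# literal property elements).  No OWL reasoning: only asserted triples.

new_triple_df <- function(s = character(), p = character(), o = character(),
                          o_lit = logical()) {
  data.frame(s = s, p = p, o = o, o_lit = o_lit, stringsAsFactors = FALSE)
}

## ---- shared tokenizer -----------------------------------------------------

# Token regex; alternative order matters (IRI/string before comment/punct).
rdf_token_regex <- paste0(
  "(<[^<>\"\\s]*>)",                                  # IRIREF
  "|(\"(?:[^\"\\\\\\n]|\\\\.)*\")",                   # STRING
  "|(\\?[A-Za-z_][A-Za-z0-9_]*)",                     # VAR (SPARQL)
  "|(_:[A-Za-z0-9_]+)",                               # BLANK
  "|((?:[A-Za-z_][A-Za-z0-9_.-]*)?:[A-Za-z0-9_.-]*)", # PNAME
  "|(@?[A-Za-z][A-Za-z0-9_-]*)",                      # KEYWORD / name
  "|([+-]?[0-9]+(?:\\.[0-9]+)?)",                     # NUMBER
  "|(\\^\\^)",                                        # datatype marker
  "|(#[^\\n]*)",                                      # COMMENT
  "|([{}()\\[\\].,;*])"                               # PUNCT
)

rdf_tokenize <- function(text, what = "input") {
  m <- gregexpr(rdf_token_regex, text, perl = TRUE)[[1]]
  toks <- if (m[1] == -1) character() else regmatches(text, list(m))[[1]]
  # every non-whitespace character must belong to some token
  covered <- text
  if (length(toks)) regmatches(covered, list(m)) <- list(rep("", length(toks)))
  bad <- regexpr("[^[:space:]]", covered)
  if (bad > 0) {
    line <- lengths(regmatches(substr(text, 1, bad), gregexpr("\n", substr(text, 1, bad)))) + 1
    input_error(sprintf("%s: unexpected character %s at position %d (line %d)",
                        what, sQuote(substr(covered, bad, bad)), bad, line))
  }
  toks <- toks[!startsWith(toks, "#")]
  starts <- if (length(toks)) m[!startsWith(regmatches(text, list(m))[[1]], "#")] else integer()
  list(tokens = toks, starts = starts, text = text)
}

tok_line <- function(ts, i) {
  if (i > length(ts$starts)) return(NA_integer_)
  pre <- substr(ts$text, 1, ts$starts[i])
  lengths(regmatches(pre, gregexpr("\n", pre, fixed = TRUE))) + 1L
}

unescape_literal <- function(tok) {
  x <- substr(tok, 2, nchar(tok) - 1)
  x <- gsub("\\\\t", "\t", x)
  x <- gsub("\\\\n", "\n", x)
  x <- gsub("\\\\r", "\r", x)
  x <- gsub("\\\\\"", "\"", x)
  gsub("\\\\\\\\", "\\\\", x)
}

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

## ---- Turtle reader --------------------------------------------------------

parse_turtle <- function(text, what = "turtle") {
  ts <- rdf_tokenize(text, what)
  toks <- ts$tokens
  n <- length(toks)
  i <- 1L
  prefixes <- c(rdf = RDF_NS)
  S <- character(); P <- character(); O <- character(); L <- logical()

  fail <- function(msg, at = i) {
    input_error(sprintf("%s parse error at line %s: %s", what,
                        tok_line(ts, min(at, n)) %||% NA, msg))
  }
  peek <- function() if (i <= n) toks[i] else ""
  advance <- function() { i <<- i + 1L }
  expect <- function(tok) {
    if (peek() != tok) fail(sprintf("expected %s, got %s", sQuote(tok), sQuote(peek())))
    advance()
  }
  resolve_pname <- function(tok) {
    colon <- regexpr(":", tok, fixed = TRUE)
    pfx <- substr(tok, 1, colon - 1)
    if (!pfx %in% names(prefixes)) fail(sprintf("undeclared prefix %s", sQuote(pfx)))
    paste0(prefixes[[pfx]], substr(tok, colon + 1, nchar(tok)))
  }
  # returns list(value, lit)
  term <- function(role) {
    tok <- peek()
    if (tok == "") fail("unexpected end of input")
    advance()
    if (startsWith(tok, "<")) {
      return(list(v = substr(tok, 2, nchar(tok) - 1), lit = FALSE))
    }
    if (startsWith(tok, "\"")) {
      if (role != "object") fail("literal not allowed as subject/predicate")
      # optional language tag or datatype
      if (peek() == "^^") { advance(); term("datatype") }
      else if (grepl("^@[A-Za-z-]+$", peek())) advance()
      return(list(v = unescape_literal(tok), lit = TRUE))
    }
    if (startsWith(tok, "_:")) return(list(v = tok, lit = FALSE))
    if (tok == "a") {
      if (role != "predicate") fail("'a' only valid as predicate")
      return(list(v = RDF_TYPE, lit = FALSE))
    }
    if (grepl("^[+-]?[0-9]", tok)) {
      if (role != "object") fail("numeric literal not allowed here")
      return(list(v = tok, lit = TRUE))
    }
    if (grepl(":", tok, fixed = TRUE)) {
      return(list(v = resolve_pname(tok), lit = FALSE))
    }
    fail(sprintf("unexpected token %s", sQuote(tok)), i - 1L)
  }

  while (i <= n) {
    tok <- peek()
    if (tok == "@prefix" || toupper(tok) == "PREFIX") {
      sparql_style <- toupper(tok) == "PREFIX" && tok != "@prefix"
      advance()
      pn <- peek()
      if (!grepl(":$", pn)) fail("expected prefix name ending in ':'")
      advance()
      iri <- peek()
      if (!startsWith(iri, "<")) fail("expected IRI in prefix declaration")
      advance()
      prefixes[[substr(pn, 1, nchar(pn) - 1)]] <- substr(iri, 2, nchar(iri) - 1)
      if (!sparql_style) expect(".")
      next
    }
    subj <- term("subject")
    repeat {
      pred <- term("predicate")
      repeat {
        obj <- term("object")
        S[length(S) + 1L] <- subj$v
        P[length(P) + 1L] <- pred$v
        O[length(O) + 1L] <- obj$v
        L[length(L) + 1L] <- obj$lit
        if (peek() == ",") { advance(); next }
        break
      }
      if (peek() == ";") {
        advance()
        if (peek() == ".") break   # dangling ';' before '.'
        next
      }
      break
    }
    expect(".")
  }
  new_triple_df(S, P, O, L)
}

## ---- N-Triples reader -----------------------------------------------------

parse_ntriples <- function(text, what = "ntriples") {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  keep <- !grepl("^[[:space:]]*(#|$)", lines)
  idx <- which(keep)
  rx <- paste0(
    "^[[:space:]]*(<[^<>\"[:space:]]*>|_:[A-Za-z0-9_]+)",
    "[[:space:]]+(<[^<>\"[:space:]]*>)",
    "[[:space:]]+(<[^<>\"[:space:]]*>|_:[A-Za-z0-9_]+|\"(?:[^\"\\\\]|\\\\.)*\"",
    "(?:\\^\\^<[^<>\"[:space:]]*>|@[A-Za-z-]+)?)",
    "[[:space:]]*\\.[[:space:]]*$"
  )
  m <- regmatches(lines[idx], regexec(rx, lines[idx], perl = TRUE))
  bad <- which(lengths(m) == 0)
  if (length(bad)) {
    input_error(sprintf("%s: malformed triple at line %d: %s", what,
                        idx[bad[1]], lines[idx[bad[1]]]))
  }
  strip <- function(x) ifelse(startsWith(x, "<"), substr(x, 2, nchar(x) - 1), x)
  s <- strip(vapply(m, `[[`, "", 2))
  p <- strip(vapply(m, `[[`, "", 3))
  oraw <- vapply(m, `[[`, "", 4)
  lit <- startsWith(oraw, "\"")
  o <- oraw
  o[!lit] <- strip(oraw[!lit])
  o[lit] <- vapply(oraw[lit], function(x) {
    x <- sub("(\\^\\^<[^>]*>|@[A-Za-z-]+)$", "", x)
    unescape_literal(x)
  }, "")
  new_triple_df(s, p, o, lit)
}

## ---- RDF/XML reader -------------------------------------------------------

parse_rdfxml <- function(path_or_text, what = "rdfxml") {
  doc <- tryCatch(xml2::read_xml(path_or_text),
                  error = function(e) input_error(
                    sprintf("%s: XML parse failure: %s", what, conditionMessage(e))))
  rdfns <- RDF_NS
  node_id <- function(node) {
    about <- xml2::xml_attr(node, "about", ns = character())
    if (!is.na(about)) return(about)
    nid <- xml2::xml_attr(node, "nodeID")
    if (!is.na(nid)) return(paste0("_:", nid))
    paste0("_:genid", xml2::xml_path(node))
  }
  S <- character(); P <- character(); O <- character(); L <- logical()
  add <- function(s, p, o, lit) {
    S[length(S) + 1L] <<- s; P[length(P) + 1L] <<- p
    O[length(O) + 1L] <<- o; L[length(L) + 1L] <<- lit
  }
  expand_name <- function(node) {
    ns <- xml2::xml_ns(doc)
    q <- xml2::xml_name(node, ns)      # "pfx:local" or "local"
    colon <- regexpr(":", q, fixed = TRUE)
    if (colon > 0) {
      pfx <- substr(q, 1, colon - 1)
      paste0(ns[[pfx]], substr(q, colon + 1, nchar(q)))
    } else q
  }
  walk_subject <- function(node) {
    sid <- node_id(node)
    tname <- expand_name(node)
    if (tname != paste0(rdfns, "Description")) add(sid, RDF_TYPE, tname, FALSE)
    for (prop in xml2::xml_children(node)) {
      piri <- expand_name(prop)
      res <- xml2::xml_attr(prop, "resource")
      kids <- xml2::xml_children(prop)
      if (!is.na(res)) {
        add(sid, piri, res, FALSE)
      } else if (length(kids)) {            # one nested resource level
        for (kid in kids) {
          add(sid, piri, node_id(kid), FALSE)
          walk_subject(kid)
        }
      } else {
        add(sid, piri, xml2::xml_text(prop), TRUE)
      }
    }
  }
  root <- xml2::xml_root(doc)
  if (expand_name(root) == paste0(rdfns, "RDF")) {
    for (child in xml2::xml_children(root)) walk_subject(child)
  } else {
    walk_subject(root)
  }
  new_triple_df(S, P, O, L)
}

## ---- writers --------------------------------------------------------------

format_term <- function(value, lit, prefixes) {
  if (lit) return(paste0("\"", escape_literal(value), "\""))
  for (pfx in names(prefixes)) {
    ns <- prefixes[[pfx]]
    if (startsWith(value, ns)) {
      local <- substr(value, nchar(ns) + 1, nchar(value))
      if (grepl("^[A-Za-z0-9_.-]*$", local)) return(paste0(pfx, ":", local))
    }
  }
  paste0("<", value, ">")
}

serialize_turtle <- function(triples,
                             prefixes = c(bp = BP, kb = KB_NS, rdf = RDF_NS)) {
  header <- sprintf("@prefix %s: <%s> .", names(prefixes), unname(prefixes))
  if (nrow(triples) == 0) return(paste0(paste(header, collapse = "\n"), "\n"))
  tr <- triples[order_c(triples$s, triples$p, triples$o), , drop = FALSE]
  fmt <- function(v, l) mapply(format_term, v, l, MoreArgs = list(prefixes = prefixes))
  body <- character()
  for (s in unique(tr$s)) {
    blk <- tr[tr$s == s, , drop = FALSE]
    po <- paste0("    ", fmt(blk$p, FALSE), " ", fmt(blk$o, blk$o_lit))
    body <- c(body, paste0(format_term(s, FALSE, prefixes), "\n",
                           paste(po, collapse = " ;\n"), " ."))
  }
  paste0(paste(header, collapse = "\n"), "\n\n", paste(body, collapse = "\n\n"), "\n")
}

serialize_ntriples <- function(triples) {
  if (nrow(triples) == 0) return("")
  obj <- ifelse(triples$o_lit,
                paste0("\"", escape_literal(triples$o), "\""),
                ifelse(startsWith(triples$o, "_:"), triples$o,
                       paste0("<", triples$o, ">")))
  sub <- ifelse(startsWith(triples$s, "_:"), triples$s, paste0("<", triples$s, ">"))
  lines <- paste0(sub, " <", triples$p, "> ", obj, " .")
  paste0(paste(sort_c(lines), collapse = "\n"), "\n")
}
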