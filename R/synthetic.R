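# Synthetic BioPAX Level 3 knowledge bases with planted ground truth.
#
# The generator emits an upstream-regulation DAG (TemplateReactionRegulation
# chains for regulation fixtures, Catalysis/BiochemicalReaction for
# signaling ones) with per-interaction controlType signs and data-source
# tags, complexes carrying BOTH explicit bp:component links and
# delimiter-joined labels (so both decomposition paths are exercised),
# alias display names covered by a companion gene_info synonym table, and
# decorated display names ("expression of X", "X mutant form").  All
# randomness flows from the spec seed through R's default RNG; the same
# spec serializes byte-identically.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic knowledge base
#'
#' @param n_genes Number of input (level 0) genes.
#' @param n_levels Number of upstream levels to plant.
#' @param branching Mean number of new regulators per node and level:
#'   every node gets `floor(branching)` regulators plus one more with
#'   probability `branching - floor(branching)` (at least one regulator
#'   per level overall, so the planted depth is always reachable).
#' @param p_shortcut Probability that a new regulator also targets a
#'   random node from an earlier level, creating cross edges (default 0,
#'   giving pure layered DAGs; e.g. `branching = 1, n_genes = 1` plants a
#'   chain).
#' @param p_inhibition,p_unknown Per-edge sign probabilities (the
#'   remainder is activation); must satisfy `p_inhibition + p_unknown <= 1`.
#' @param n_complexes Number of upstream nodes converted into protein
#'   complexes with `complex_size` members each.
#' @param complex_size Integer range `c(min, max)` of members per complex.
#' @param n_aliases Number of upstream nodes whose display name is an
#'   alias of their canonical symbol (covered by the synonym table).
#' @param n_decorated Number of upstream nodes whose display name carries
#'   a decoration prefix/suffix.
#' @param source_names Data-source names to tag interactions with.
#' @param kind `"regulation"` or `"signaling"`.
#' @param seed Integer seed driving all randomness.
#' @return A `kb_spec` object.
#' @export
kb_spec <- function(n_genes = 3L, n_levels = 3L, branching = 1,
                    p_shortcut = 0, p_inhibition = 0.2, p_unknown = 0,
                    n_complexes = 0L,
                    complex_size = c(2L, 3L), n_aliases = 0L,
                    n_decorated = 0L,
                    source_names = c("ctd", "pid", "panther"),
                    kind = c("regulation", "signaling"), seed = 1L) {
  kind <- match.arg(kind)
  if (p_inhibition < 0 || p_unknown < 0 || p_inhibition + p_unknown > 1) {
    usage_error("kb_spec: sign probabilities must be in [0,1] and sum to <= 1")
  }
  if (p_shortcut < 0 || p_shortcut > 1) {
    usage_error("kb_spec: p_shortcut must be in [0,1]")
  }
  if (n_genes < 1 || n_levels < 1 || branching < 0 || n_complexes < 0 ||
      n_aliases < 0 || n_decorated < 0) {
    usage_error("kb_spec: counts must be >= 0 (n_genes, n_levels >= 1)")
  }
  if (length(complex_size) != 2L || complex_size[1] < 2L ||
      complex_size[2] < complex_size[1]) {
    usage_error("kb_spec: complex_size must be c(min >= 2, max >= min)")
  }
  if (length(source_names) == 0L) usage_error("kb_spec: need >= 1 source name")
  structure(as.list(environment()), class = "kb_spec")
}

#' Generate a synthetic knowledge base with ground truth
#'
#' @param spec A [kb_spec()].
#' @param dir Optional directory; when given, `kb.ttl` (Turtle) and
#'   `gene_info.tsv` (synonym table covering planted aliases) are written
#'   there.
#' @return List with `kb` (a local `knowledge_base`), `truth` (the
#'   planted ground truth: `upstream_edges`, `complexes`, `aliases`,
#'   `decorated`, `input_genes`, `depth_of`), and `turtle` (the
#'   serialization text).
#' @export
generate_kb <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "kb_spec"))
  with_seed(spec$seed, {
    input <- sprintf("TG%02d", seq_len(spec$n_genes))
    levels <- list(input)
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), source_db = character(),
                        stringsAsFactors = FALSE)
    idx <- 0L
    for (l in seq_len(spec$n_levels)) {
      prev <- levels[[l]]
      new <- character()
      for (v in prev) {
        k <- floor(spec$branching) +
          (stats::runif(1L) < spec$branching - floor(spec$branching))
        for (j in seq_len(k)) {
          idx <- idx + 1L
          nm <- sprintf("RG%02d%03d", l, idx)
          new <- c(new, nm)
          edges <- rbind(edges, data.frame(
            source = nm, target = v, sign = draw_sign(spec),
            source_db = resample(spec$source_names, 1L),
            stringsAsFactors = FALSE))
        }
      }
      if (length(new) == 0L) {       # guarantee the planted depth is reachable
        idx <- idx + 1L
        nm <- sprintf("RG%02d%03d", l, idx)
        new <- nm
        edges <- rbind(edges, data.frame(
          source = nm, target = prev[[1L]], sign = draw_sign(spec),
          source_db = resample(spec$source_names, 1L),
          stringsAsFactors = FALSE))
      }
      # optional shortcut edges into earlier levels
      if (spec$p_shortcut > 0 && l > 1L) {
        for (nm in new) {
          if (stats::runif(1L) < spec$p_shortcut) {
            tgt <- resample(unlist(levels[seq_len(l - 1L)]), 1L)
            edges <- rbind(edges, data.frame(
              source = nm, target = tgt, sign = draw_sign(spec),
              source_db = resample(spec$source_names, 1L),
              stringsAsFactors = FALSE))
          }
        }
      }
      levels[[l + 1L]] <- new
    }
    upstream <- unlist(levels[-1L])

    # convert some upstream nodes into complexes (joined label + members)
    complexes <- list()
    n_cx <- min(spec$n_complexes, length(upstream))
    cx_nodes <- if (n_cx) resample(upstream, n_cx) else character()
    for (i in seq_along(cx_nodes)) {
      k <- resample(seq(spec$complex_size[1], spec$complex_size[2]), 1L)
      members <- sprintf("CX%02d%s", i, LETTERS[seq_len(k)])
      label <- paste(members, collapse = "/")
      old <- cx_nodes[[i]]
      edges$source[edges$source == old] <- label
      edges$target[edges$target == old] <- label
      complexes[[label]] <- members
    }
    plain <- setdiff(upstream, cx_nodes)

    aliases <- character()
    if (spec$n_aliases > 0L && length(plain)) {
      al_nodes <- resample(plain, min(spec$n_aliases, length(plain)))
      aliases <- stats::setNames(al_nodes, paste0(al_nodes, "ALT"))
      plain <- setdiff(plain, al_nodes)
    }
    decorated <- character()
    if (spec$n_decorated > 0L && length(plain)) {
      de_nodes <- resample(plain, min(spec$n_decorated, length(plain)))
      forms <- ifelse(seq_along(de_nodes) %% 2L == 1L,
                      paste("expression of", de_nodes),
                      paste(de_nodes, "mutant form"))
      decorated <- stats::setNames(de_nodes, forms)
    }

    truth <- list(
      upstream_edges = edges,
      complexes = complexes,
      aliases = aliases,          # named: alias -> canonical
      decorated = decorated,      # named: decorated label -> canonical
      input_genes = input,
      kind = spec$kind
    )
    truth$depth_of <- truth_depths(truth)
    triples <- emit_biopax(truth, spec)
    turtle <- serialize_turtle(triples)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      writeLines(turtle, file.path(dir, "kb.ttl"))
      write_gene_info(truth, file.path(dir, "gene_info.tsv"))
    }
    list(kb = kb_from_triples(triples), truth = truth, turtle = turtle)
  })
}

# sample() that never falls into the length-1 integer trap
resample <- function(x, size) x[sample.int(length(x), size)]

draw_sign <- function(spec) {
  u <- stats::runif(1L)
  if (u < spec$p_inhibition) "INHIBITION"
  else if (u < spec$p_inhibition + spec$p_unknown) "UNKNOWN"
  else "ACTIVATION"
}

# minimal BFS depths (input genes = 0) over planted edges + memberships
truth_depths <- function(truth) {
  depth <- stats::setNames(rep(0L, length(truth$input_genes)), truth$input_genes)
  frontier <- truth$input_genes
  lvl <- 0L
  while (length(frontier)) {
    lvl <- lvl + 1L
    hits <- truth$upstream_edges[truth$upstream_edges$target %in% frontier, , drop = FALSE]
    nxt <- unique(hits$source)
    nxt <- c(nxt, unlist(truth$complexes[intersect(nxt, names(truth$complexes))],
                         use.names = FALSE))
    nxt <- setdiff(unique(nxt), names(depth))
    if (length(nxt)) depth[nxt] <- lvl
    frontier <- nxt
  }
  depth
}

# Emit BioPAX triples for the planted truth.  One entity node per planted
# name; display names carry alias/decoration substitutions.
emit_biopax <- function(truth, spec) {
  all_names <- unique(c(
    truth$input_genes, truth$upstream_edges$source, truth$upstream_edges$target,
    names(truth$complexes), unlist(truth$complexes, use.names = FALSE)))
  display <- stats::setNames(all_names, all_names)
  display[unname(truth$aliases)] <- names(truth$aliases)
  display[unname(truth$decorated)] <- names(truth$decorated)
  ent_iri <- stats::setNames(
    paste0(KB_NS, sprintf("ent%04d", seq_along(all_names))), all_names)

  S <- character(); P <- character(); O <- character(); L <- logical()
  add <- function(s, p, o, lit = FALSE) {
    S[length(S) + 1L] <<- s; P[length(P) + 1L] <<- p
    O[length(O) + 1L] <<- o; L[length(L) + 1L] <<- lit
  }
  for (nm in all_names) {
    cls <- if (nm %in% names(truth$complexes)) "Complex" else "Protein"
    add(ent_iri[[nm]], RDF_TYPE, bp(cls))
    add(ent_iri[[nm]], bp("displayName"), display[[nm]], TRUE)
  }
  for (label in names(truth$complexes)) {
    for (m in truth$complexes[[label]]) {
      add(ent_iri[[label]], bp("component"), ent_iri[[m]])
    }
  }
  for (src in unique(truth$upstream_edges$source_db)) {
    iri <- paste0(KB_NS, "src_", src)
    add(iri, RDF_TYPE, bp("Provenance"))
    add(iri, bp("displayName"), src, TRUE)
  }
  e <- truth$upstream_edges
  for (i in seq_len(nrow(e))) {
    if (spec$kind == "regulation") {
      reg <- paste0(KB_NS, sprintf("reg%04d", i))
      tmpl <- paste0(KB_NS, sprintf("tmpl%04d", i))
      add(reg, RDF_TYPE, bp("TemplateReactionRegulation"))
      add(reg, bp("controlled"), tmpl)
      add(reg, bp("controller"), ent_iri[[e$source[i]]])
      if (e$sign[i] != "UNKNOWN") add(reg, bp("controlType"), e$sign[i], TRUE)
      add(reg, bp("dataSource"), paste0(KB_NS, "src_", e$source_db[i]))
      add(tmpl, RDF_TYPE, bp("TemplateReaction"))
      add(tmpl, bp("product"), ent_iri[[e$target[i]]])
    } else {
      ctl <- paste0(KB_NS, sprintf("ctl%04d", i))
      rxn <- paste0(KB_NS, sprintf("rxn%04d", i))
      add(ctl, RDF_TYPE, bp(if (i %% 2L) "Catalysis" else "Control"))
      add(ctl, bp("controlled"), rxn)
      add(ctl, bp("controller"), ent_iri[[e$source[i]]])
      if (e$sign[i] != "UNKNOWN") add(ctl, bp("controlType"), e$sign[i], TRUE)
      add(ctl, bp("dataSource"), paste0(KB_NS, "src_", e$source_db[i]))
      add(rxn, RDF_TYPE, bp("BiochemicalReaction"))
      add(rxn, bp("right"), ent_iri[[e$target[i]]])
    }
  }
  new_triple_df(S, P, O, L)
}

#' Write the companion gene_info synonym table for a ground truth
#'
#' Covers every planted non-complex name; aliased nodes carry their alias
#' in the Synonyms column.
#'
#' @param truth Ground truth from [generate_kb()].
#' @param path Output path (tab-separated, NCBI gene_info layout).
#' @return Invisibly, `path`.
#' @export
write_gene_info <- function(truth, path) {
  names_all <- sort_c(unique(c(
    truth$input_genes, truth$upstream_edges$source, truth$upstream_edges$target,
    unlist(truth$complexes, use.names = FALSE))))
  names_all <- setdiff(names_all, names(truth$complexes))
  syn <- vapply(names_all, function(nm) {
    al <- names(truth$aliases)[truth$aliases == nm]
    if (length(al)) paste(al, collapse = "|") else "-"
  }, "")
  lines <- c("GeneID\tSymbol\tSynonyms",
             sprintf("%d\t%s\t%s", seq_along(names_all), names_all, syn))
  writeLines(lines, path)
  invisible(path)
}

#' Brute-force upstream closure of a planted ground truth
#'
#' Breadth-first upstream exploration over the planted edge list up to
#' `depth` levels, expanding complex members, with all names resolved to
#' canonical symbols.  Independent of the assembler code path; used as
#' the oracle it is compared against.
#'
#' @param truth Ground truth from [generate_kb()].
#' @param genes Subset of planted names to start from.
#' @param depth Number of levels (0 gives an empty edge set).
#' @param drop_unknown Drop UNKNOWN-signed planted edges before walking.
#' @return List with `edges` (data.frame `source`, `target`, `sign`,
#'   `source_db`; PART_OF membership rows carry `source_db = ""`) and
#'   `nodes` (the endpoint name set).
#' @export
ground_truth_upstream <- function(truth, genes, depth, drop_unknown = FALSE) {
  e <- truth$upstream_edges
  if (drop_unknown) e <- e[e$sign != "UNKNOWN", , drop = FALSE]
  out <- data.frame(source = character(), target = character(),
                    sign = character(), source_db = character(),
                    stringsAsFactors = FALSE)
  frontier <- unique(genes)
  seen <- frontier
  explored <- character()
  lvl <- 0L
  while (length(frontier) && lvl < depth) {
    lvl <- lvl + 1L
    hits <- e[e$target %in% frontier, , drop = FALSE]
    out <- rbind(out, hits[, c("source", "target", "sign", "source_db")])
    new <- unique(hits$source)
    cx <- intersect(new, names(truth$complexes))
    for (label in cx) {
      for (m in truth$complexes[[label]]) {
        out <- rbind(out, data.frame(source = m, target = label,
                                     sign = "PART_OF", source_db = "",
                                     stringsAsFactors = FALSE))
      }
    }
    new <- unique(c(new, unlist(truth$complexes[cx], use.names = FALSE)))
    explored <- unique(c(explored, frontier))
    frontier <- sort_c(setdiff(new, seen))
    seen <- unique(c(seen, frontier))
  }
  out <- unique(out)
  out <- out[order_c(out$source, out$target, out$sign, out$source_db), , drop = FALSE]
  rownames(out) <- NULL
  list(edges = out, nodes = sort_c(unique(c(out$source, out$target))))
}

#' Generate a deterministic synthetic gene list
#'
#' Produces `n` distinct synthetic gene symbols, reproducible per seed,
#' optionally written as a single-column CSV usable as reconstruction
#' input.
#'
#' @param n Number of symbols (>= 1).
#' @param seed Integer seed.
#' @param path Optional output path (one symbol per line).
#' @return Character vector of length `n`.
#' @export
generate_gene_list <- function(n, seed = 1L, path = NULL) {
  if (n < 1L) usage_error("generate_gene_list: n must be >= 1")
  syms <- with_seed(seed, {
    pool <- replicate(n, paste0(
      paste(sample(LETTERS, 4L, replace = TRUE), collapse = ""),
      sample(0:9, 1L)))
    make.unique(pool, sep = "X")
  })
  if (!is.null(path)) writeLines(syms, path)
  syms
}
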