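# Shared fixtures (hand-written Turtle) and independent brute-force
# oracles used across the suite.

BP_NS <- "http://www.biopax.org/release/biopax-level3.owl#"

ttl_header <- paste(
  "@prefix bp: <http://www.biopax.org/release/biopax-level3.owl#> .",
  "@prefix kb: <http://example.org/kb/> .",
  sep = "\n")

write_ttl <- function(body) {
  f <- tempfile(fileext = ".ttl")
  writeLines(paste(ttl_header, body, sep = "\n"), f)
  f
}

kb_from_ttl <- function(body) load_rdf_graph(write_ttl(body))

# exactly 7 triples: one protein and one regulation interaction skeleton
fixture_seven_triples <- '
kb:x a bp:Protein .
kb:x bp:displayName "X" .
kb:reg1 a bp:TemplateReactionRegulation .
kb:reg1 bp:controlled kb:tmpl1 .
kb:reg1 bp:controller kb:x .
kb:tmpl1 a bp:TemplateReaction .
kb:tmpl1 bp:product kb:x .
'

# one planted regulation X -activates-> A, source "ctd"
fixture_regulation <- '
kb:x a bp:Protein ; bp:displayName "X" .
kb:a a bp:Protein ; bp:displayName "A" .
kb:src_ctd a bp:Provenance ; bp:displayName "ctd" .
kb:reg1 a bp:TemplateReactionRegulation ;
  bp:controlled kb:tmpl1 ;
  bp:controller kb:x ;
  bp:controlType "ACTIVATION" ;
  bp:dataSource kb:src_ctd .
kb:tmpl1 a bp:TemplateReaction ; bp:product kb:a .
'

# kinase K catalyzes a reaction producing P from P0 (source "pid")
fixture_signaling <- '
kb:k a bp:Protein ; bp:displayName "K" .
kb:p a bp:Protein ; bp:displayName "P" .
kb:p0 a bp:Protein ; bp:displayName "P0" .
kb:src_pid a bp:Provenance ; bp:displayName "pid" .
kb:ctl1 a bp:Catalysis ;
  bp:controlled kb:rxn1 ;
  bp:controller kb:k ;
  bp:controlType "ACTIVATION" ;
  bp:dataSource kb:src_pid .
kb:rxn1 a bp:BiochemicalReaction ; bp:right kb:p ; bp:left kb:p0 .
'

# activation chain X -> Y -> Z -> g, all ACTIVATION, source "ctd"
fixture_chain <- '
kb:g a bp:Protein ; bp:displayName "g" .
kb:z a bp:Protein ; bp:displayName "Z" .
kb:y a bp:Protein ; bp:displayName "Y" .
kb:x a bp:Protein ; bp:displayName "X" .
kb:src_ctd a bp:Provenance ; bp:displayName "ctd" .
kb:reg1 a bp:TemplateReactionRegulation ; bp:controlled kb:t1 ;
  bp:controller kb:z ; bp:controlType "ACTIVATION" ; bp:dataSource kb:src_ctd .
kb:t1 a bp:TemplateReaction ; bp:product kb:g .
kb:reg2 a bp:TemplateReactionRegulation ; bp:controlled kb:t2 ;
  bp:controller kb:y ; bp:controlType "ACTIVATION" ; bp:dataSource kb:src_ctd .
kb:t2 a bp:TemplateReaction ; bp:product kb:z .
kb:reg3 a bp:TemplateReactionRegulation ; bp:controlled kb:t3 ;
  bp:controller kb:x ; bp:controlType "ACTIVATION" ; bp:dataSource kb:src_ctd .
kb:t3 a bp:TemplateReaction ; bp:product kb:y .
'

gene_info_fixture <- function() {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("GeneID\tSymbol\tSynonyms",
               "7157\tTP53\tP53|LFS1",
               "4609\tMYC\tc-Myc|bHLHe39",
               "111\tAMBIG\tSHARED",
               "222\tAMBIG2\tSHARED",
               "333\tNOSYN\t-"), f)
  f
}

# explode an influence graph's edges into one row per provenance source
explode_edges <- function(graph) {
  e <- graph$edges
  if (!nrow(e)) {
    return(data.frame(source = character(), target = character(),
                      sign = character(), source_db = character(),
                      stringsAsFactors = FALSE))
  }
  prov <- strsplit(e$provenance, "|", fixed = TRUE)
  prov[lengths(prov) == 0L] <- list("")
  k <- lengths(prov)
  data.frame(source = rep(e$source, k), target = rep(e$target, k),
             sign = rep(e$sign, k), source_db = unlist(prov),
             stringsAsFactors = FALSE)
}

edge_key <- function(df) sort(do.call(paste, c(df, sep = "\r")))

expect_same_edge_set <- function(graph, oracle) {
  expect_identical(edge_key(explode_edges(graph)), edge_key(oracle$edges))
  expect_setequal(graph$nodes$name, oracle$nodes)
}

# reconstruct + unify against the planted synonym table
reconstruct_unified <- function(gk, depth, kind = gk$truth$kind,
                                excluded = character(), drop_unknown = FALSE) {
  f <- tempfile()
  write_gene_info(gk$truth, f)
  syn <- load_synonym_table(f)
  res <- reconstruct(gk$kb, gk$truth$input_genes, kind, max_depth = depth,
                     config = expansion_config(TRUE, TRUE, TRUE),
                     excluded_sources = excluded, drop_unknown = drop_unknown,
                     synonym_table = syn)
  list(result = res, unified = unify_graph(res$influence_graph, syn)$graph,
       synonyms = syn)
}

## ---- brute-force metric oracles -------------------------------------------

# random small influence graph for metric cross-checks
random_graph <- function(seed, n_max = 12L) {
  set.seed(seed)
  n <- sample(3:n_max, 1L)
  nodes <- sprintf("N%02d", seq_len(n))
  m <- sample(2:(2L * n), 1L)
  pairs <- expand.grid(s = nodes, t = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$s != pairs$t, ]
  pick <- pairs[sample(nrow(pairs), min(m, nrow(pairs))), ]
  edges <- data.frame(
    source = pick$s, target = pick$t,
    sign = sample(c("ACTIVATION", "INHIBITION", "UNKNOWN"), nrow(pick), TRUE),
    kind = "transcriptional",
    provenance = sample(c("ctd", "pid"), nrow(pick), TRUE),
    reaction = sprintf("r%03d", seq_len(nrow(pick))),
    stringsAsFactors = FALSE)
  influence_graph(
    nodes = data.frame(name = nodes, entity_class = "protein_or_gene",
                       aliases = "", stringsAsFactors = FALSE),
    edges = edges)
}

# directed simple adjacency matrix (multiedges collapsed, loops dropped)
adj_matrix <- function(graph) {
  nm <- sort(graph$nodes$name, method = "radix")
  A <- matrix(0L, length(nm), length(nm), dimnames = list(nm, nm))
  e <- unique(graph$edges[, c("source", "target")])
  e <- e[e$source != e$target, , drop = FALSE]
  A[cbind(e$source, e$target)] <- 1L
  A
}

bf_two_cycle <- function(graph) {
  e <- graph$edges[graph$edges$sign != "PART_OF", , drop = FALSE]
  if (!nrow(e)) return(0)
  hit <- vapply(seq_len(nrow(e)), function(i) {
    e$source[i] != e$target[i] &&
      any(e$source == e$target[i] & e$target == e$source[i])
  }, NA)
  mean(hit)
}

# exhaustive clique enumeration on the undirected simple projection
bf_cliques <- function(graph, max_size) {
  A <- adj_matrix(graph)
  U <- (A + t(A)) > 0
  nm <- rownames(U)
  n <- length(nm)
  counts <- integer(max_size - 2L)
  names(counts) <- as.character(3:max_size)
  max_cl <- min(n, 1L)
  if (any(U)) max_cl <- 2L
  for (k in 2:min(n, max(max_size, n))) {
    if (n < k) break
    found <- FALSE
    for (idx in utils::combn(n, k, simplify = FALSE)) {
      sub <- U[idx, idx, drop = FALSE]
      if (all(sub[upper.tri(sub)])) {
        found <- TRUE
        if (k >= 3 && k <= max_size) counts[as.character(k)] <- counts[as.character(k)] + 1L
        if (k > max_cl) max_cl <- k
      }
    }
    if (!found) break
  }
  list(counts = counts, max_clique_size = as.integer(max_cl))
}

# Floyd-Warshall directed distances
bf_distances <- function(graph) {
  A <- adj_matrix(graph)
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  D[A == 1L] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# betweenness via geodesic counting with matrix powers
bf_betweenness <- function(graph) {
  A <- adj_matrix(graph)
  n <- nrow(A)
  D <- bf_distances(graph)
  maxd <- max(D[is.finite(D)])
  P <- list(diag(n))                       # walks of length 0
  Ak <- diag(n)
  for (k in seq_len(max(maxd, 1))) { Ak <- Ak %*% A; P[[k + 1L]] <- Ak }
  sigma <- function(i, j) {
    d <- D[i, j]
    if (!is.finite(d)) return(0)
    P[[d + 1L]][i, j]
  }
  bet <- stats::setNames(numeric(n), rownames(A))
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || !is.finite(D[s, t])) next
    st <- sigma(s, t)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        bet[v] <- bet[v] + sigma(s, v) * sigma(v, t) / st
      }
    }
  }
  bet
}
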