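# Drug screening against DrugBank-like RDF: map target genes to drugs via
# the target / gene-name pattern, augment targets with one level of
# upstream regulators, and re-query drugs for the new targets.

#' Predicate mapping for a DrugBank-like RDF source
#'
#' The Bio2RDF DrugBank predicate IRIs drift between endpoint versions,
#' so they are configurable; the defaults follow the Bio2RDF DrugBank
#' vocabulary.
#'
#' @param target Drug-to-target predicate IRI.
#' @param gene_name Target-to-gene-symbol predicate IRI.
#' @param status Drug approval-group predicate IRI.
#' @param name Drug display-name predicate IRI.
#' @return A `drug_vocab` list.
#' @export
drug_vocab <- function(
    target = "http://bio2rdf.org/drugbank_vocabulary:target",
    gene_name = "http://bio2rdf.org/drugbank_vocabulary:gene-name",
    status = "http://bio2rdf.org/drugbank_vocabulary:group",
    name = "http://purl.org/dc/terms/title") {
  structure(list(target = target, gene_name = gene_name,
                 status = status, name = name), class = "drug_vocab")
}

#' Read a drug-vocabulary mapping from a JSON file
#'
#' @param path JSON file with any subset of the [drug_vocab()] fields.
#' @return A `drug_vocab` list.
#' @export
read_drug_vocab <- function(path) {
  if (!file.exists(path)) input_error(sprintf("vocab file not found: %s", path))
  vals <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(drug_vocab, vals[intersect(names(vals), names(formals(drug_vocab)))])
}

#' Build the drug-retrieval query for a set of gene symbols
#'
#' Matches drug -> target -> gene-name paths and, when `approved_only`,
#' restricts to drugs carrying the "approved" status.
#'
#' @param symbols Non-empty character vector of gene symbols.
#' @param approved_only Restrict to approved drugs.
#' @param vocab A [drug_vocab()].
#' @return SPARQL query text.
#' @export
build_drug_query <- function(symbols, approved_only = TRUE,
                             vocab = drug_vocab()) {
  if (length(symbols) == 0L) usage_error("build_drug_query: empty symbol set")
  paste0(
    "SELECT DISTINCT ?drug ?name ?status ?gene WHERE {\n",
    "  ?drug <", vocab$target, "> ?t .\n",
    "  ?t <", vocab$gene_name, "> ?gene .\n",
    sprintf("  FILTER (?gene IN (%s))\n",
            paste(quote_lit(sort_c(unique(symbols))), collapse = ", ")),
    "  ?drug <", vocab$status, "> ?status .\n",
    "  OPTIONAL { ?drug <", vocab$name, "> ?name . }\n",
    if (approved_only) "  FILTER (?status IN (\"approved\"))\n" else "",
    "}"
  )
}

query_drugs <- function(drug_kb, symbols, approved_only, vocab) {
  rows <- execute_query(drug_kb, build_drug_query(symbols, approved_only, vocab))
  if (nrow(rows) == 0L) {
    return(data.frame(drug_id = character(), drug_name = character(),
                      status = character(), gene = character(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    drug_id = rows$drug,
    drug_name = ifelse(is.na(rows$name), rows$drug, rows$name),
    status = rows$status, gene = rows$gene, stringsAsFactors = FALSE)
  out <- out[order_c(out$drug_id, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

distinct_drugs <- function(df) df[!duplicated(df$drug_id), , drop = FALSE]

#' Drug-screening workflow over a gene list
#'
#' Step 1 retrieves drugs targeting the input genes from the drug
#' knowledge base.  Step 2 reconstructs a depth-1 upstream regulation
#' graph of the genes from the pathway knowledge base (all query
#' expansions on) and takes the regulators — sources of signed or
#' unsigned non-membership edges — that are not input genes as new
#' candidate targets.  Step 3 re-queries drugs for the new targets.
#'
#' @param drug_kb `knowledge_base` with DrugBank-like content.
#' @param pathway_kb `knowledge_base` with BioPAX pathway content.
#' @param genes Non-empty character vector of target gene symbols.
#' @param config [expansion_config()]; defaults to all expansions on.
#' @param excluded_sources Pathway data sources to exclude.
#' @param synonym_table Optional synonym table.
#' @param approved_only Keep only approved drugs (default `TRUE`).
#' @param vocab A [drug_vocab()].
#' @return A `drug_screen_report` with `initial_targets`, `initial_drugs`,
#'   `new_targets`, `new_drugs` and the per-gene `links` provenance table.
#' @export
screen <- function(drug_kb, pathway_kb, genes,
                   config = expansion_config(use_synonyms = TRUE,
                                             use_complex_decomposition = TRUE,
                                             use_label_expansion = TRUE),
                   excluded_sources = character(), synonym_table = NULL,
                   approved_only = TRUE, vocab = drug_vocab()) {
  if (length(genes) == 0L) usage_error("screen: empty gene set")
  genes <- sort_c(unique(as.character(genes)))
  step <- function(what, expr) {
    tryCatch(expr, upnet_error = function(e) {
      up_abort(sprintf("drug screening failed at step %s: %s",
                       what, conditionMessage(e)), class(e)[[1L]])
    })
  }
  initial_drugs <- step("initial drug query",
                        query_drugs(drug_kb, genes, approved_only, vocab))
  res <- step("upstream regulator reconstruction",
              reconstruct(pathway_kb, genes, "regulation", max_depth = 1L,
                          config = config, excluded_sources = excluded_sources,
                          synonym_table = synonym_table))
  e <- res$influence_graph$edges
  regulators <- unique(e$source[e$kind != "membership"])
  regulators <- canonicalize_name(regulators, synonym_table)
  new_targets <- sort_c(setdiff(regulators, genes))
  new_drugs <- if (length(new_targets)) {
    step("augmented drug query",
         query_drugs(drug_kb, new_targets, approved_only, vocab))
  } else {
    initial_drugs[0L, , drop = FALSE]
  }
  structure(list(
    initial_targets = genes,
    initial_drugs = distinct_drugs(initial_drugs),
    new_targets = new_targets,
    new_drugs = distinct_drugs(new_drugs),
    links = rbind(cbind(initial_drugs, stage = if (nrow(initial_drugs)) "initial" else character()),
                  cbind(new_drugs, stage = if (nrow(new_drugs)) "augmented" else character()))
  ), class = "drug_screen_report")
}

#' @export
print.drug_screen_report <- function(x, ...) {
  cat("Drug screening report\n")
  cat(sprintf("  initial target genes: %d\n", length(x$initial_targets)))
  cat(sprintf("  candidate drugs:      %d\n", nrow(x$initial_drugs)))
  cat(sprintf("  new target genes:     %d\n", length(x$new_targets)))
  cat(sprintf("  new candidate drugs:  %d\n", nrow(x$new_drugs)))
  invisible(x)
}

#' Write a drug-screening report as TSV and JSON
#'
#' @param report A `drug_screen_report`.
#' @param tsv_path,json_path Output paths.
#' @return Invisibly, `report`.
#' @export
write_drug_screen_report <- function(report, tsv_path, json_path) {
  lk <- report$links
  writeLines(c("stage\tdrug_id\tdrug_name\tstatus\tgene",
               if (nrow(lk)) paste(lk$stage, lk$drug_id, lk$drug_name,
                                   lk$status, lk$gene, sep = "\t")
               else character()),
             tsv_path)
  jsonlite::write_json(list(
    initial_targets = report$initial_targets,
    initial_drugs = report$initial_drugs,
    new_targets = report$new_targets,
    new_drugs = report$new_drugs
  ), json_path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(report)
}
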