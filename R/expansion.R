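# The three optional input-augmentation steps applied around querying:
# complex-label decomposition, label (prefix/suffix) expansion, and NCBI
# gene_info synonym expansion; plus the inverse decoration stripping
# applied to names coming back from the knowledge base.

#' Expansion configuration
#'
#' Bundles the switches and word lists controlling query expansion.
#' Defaults: complex labels split on `/` and `:` (`-` is deliberately not
#' a delimiter because hyphens occur inside gene symbols such as HLA-A);
#' the prefix list holds `"expression of"` and the suffix list holds
#' common decorated forms seen in pathway databases.  Both lists are
#' configuration, not a fixed vocabulary, and can be loaded from YAML/JSON
#' via [read_expansion_config()].
#'
#' @param use_synonyms Expand frontier names with gene_info synonyms.
#' @param use_complex_decomposition Decompose complex controllers into
#'   members (PART_OF edges) and explore the members.
#' @param use_label_expansion Expand query names with decorated forms and
#'   strip decorations from returned names.
#' @param complex_delimiters Ordered, non-empty delimiter strings.
#' @param prefixes,suffixes Decoration word lists (no empty strings).
#' @return An `expansion_config` object.
#' @export
expansion_config <- function(use_synonyms = FALSE,
                             use_complex_decomposition = FALSE,
                             use_label_expansion = FALSE,
                             complex_delimiters = c("/", ":"),
                             prefixes = c("expression of"),
                             suffixes = c("mutant form", "phosphorylated",
                                          "protein", "gene")) {
  if (any(!nzchar(complex_delimiters))) {
    usage_error("expansion_config: empty complex delimiter")
  }
  if (any(!nzchar(prefixes)) || any(!nzchar(suffixes))) {
    usage_error("expansion_config: prefix/suffix lists must not contain empty strings")
  }
  structure(
    list(use_synonyms = isTRUE(use_synonyms),
         use_complex_decomposition = isTRUE(use_complex_decomposition),
         use_label_expansion = isTRUE(use_label_expansion),
         complex_delimiters = as.character(complex_delimiters),
         prefixes = as.character(prefixes),
         suffixes = as.character(suffixes)),
    class = "expansion_config"
  )
}

#' Read an expansion configuration from a YAML or JSON file
#'
#' The file may define any subset of the [expansion_config()] fields;
#' missing fields keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return An `expansion_config` object.
#' @export
read_expansion_config <- function(path) {
  if (!file.exists(path)) input_error(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      input_error("YAML config requires the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    usage_error("config file must be .yaml, .yml or .json")
  }
  do.call(expansion_config, vals[intersect(names(vals), names(formals(expansion_config)))])
}

#' Decompose a complex label into member names
#'
#' Splits a concatenated complex label (e.g. `"CDK4/CCND1"`) on the given
#' delimiters, applied in order, and trims the pieces.  A label with no
#' delimiter is returned unchanged as a single member.
#'
#' @param label Non-empty label string.
#' @param delimiters Ordered character vector of delimiter strings.
#' @return Character vector of at least one trimmed, non-empty member name.
#' @examples
#' decompose_complex_label("CDK4/CCND1")
#' decompose_complex_label("A/B:C")
#' @export
decompose_complex_label <- function(label, delimiters = c("/", ":")) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    usage_error("decompose_complex_label: label must be a non-empty string")
  }
  parts <- label
  for (d in delimiters) {
    parts <- unlist(strsplit(parts, d, fixed = TRUE), use.names = FALSE)
  }
  parts <- str_trim2(parts)
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) parts <- str_trim2(label)
  parts
}

#' Expand names with decorated (prefixed/suffixed) forms
#'
#' For each input name, emits the name itself plus every
#' `"<prefix> <name>"` and `"<name> <suffix>"` combination, deduplicated,
#' with the input names first in input order.
#'
#' @param names Character vector of names.
#' @param config An [expansion_config()] with `use_label_expansion = TRUE`.
#' @return Character vector of decorated names.
#' @export
expand_labels <- function(names, config) {
  stopifnot(inherits(config, "expansion_config"))
  if (!config$use_label_expansion) {
    usage_error("expand_labels: label expansion is not enabled in config")
  }
  if (length(names) == 0L) return(character())
  decorated <- unlist(lapply(names, function(nm) {
    c(nm,
      if (length(config$prefixes)) paste(config$prefixes, nm),
      if (length(config$suffixes)) paste(nm, config$suffixes))
  }), use.names = FALSE)
  unique(decorated)
}

#' Strip one known prefix and one known suffix from a label
#'
#' Inverse of [expand_labels()]: removes at most one configured prefix and
#' at most one configured suffix (with the separating whitespace).  The
#' operation is idempotent on its own output.
#'
#' @param label Label string (vectorized).
#' @param config An [expansion_config()].
#' @return Canonical label(s).
#' @export
strip_decorations <- function(label, config) {
  stopifnot(inherits(config, "expansion_config"))
  out <- label
  for (p in config$prefixes[order(-nchar(config$prefixes))]) {
    hit <- startsWith(out, paste0(p, " "))
    out[hit] <- str_trim2(substr(out[hit], nchar(p) + 2L, nchar(out[hit])))
  }
  for (s in config$suffixes[order(-nchar(config$suffixes))]) {
    hit <- endsWith(out, paste0(" ", s))
    out[hit] <- str_trim2(substr(out[hit], 1L, nchar(out[hit]) - nchar(s) - 1L))
  }
  out
}

#' Load an NCBI gene_info-style synonym table
#'
#' Reads a tab-delimited file with (at least) the columns `GeneID`,
#' `Symbol` and `Synonyms` (pipe-separated; `"-"` means none), as in
#' `Homo_sapiens.gene_info`.  A leading `#` on the header line is
#' accepted.
#'
#' @param path Path to the gene_info file.
#' @return A `synonym_table` with one record per row and an index mapping
#'   any name (canonical or synonym) to the matching gene ids.
#' @export
load_synonym_table <- function(path) {
  if (!file.exists(path)) input_error(sprintf("gene_info file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) input_error("gene_info file is empty (no header)")
  header <- strsplit(sub("^#[[:space:]]*", "", lines[[1L]]), "\t", fixed = TRUE)[[1L]]
  needed <- c("GeneID", "Symbol", "Synonyms")
  if (!all(needed %in% header)) {
    input_error(sprintf("gene_info file lacks mandatory column(s): %s",
                        paste(setdiff(needed, header), collapse = ", ")))
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  col <- function(nm) vapply(fields, function(f) {
    i <- match(nm, header)
    if (i <= length(f)) f[[i]] else NA_character_
  }, "")
  gene_id <- suppressWarnings(as.integer(col("GeneID")))
  symbol  <- col("Symbol")
  syn_raw <- col("Synonyms")
  synonyms <- lapply(syn_raw, function(x) {
    if (is.na(x) || x == "-" || !nzchar(x)) character()
    else unique(str_trim2(strsplit(x, "|", fixed = TRUE)[[1L]]))
  })
  records <- data.frame(gene_id = gene_id, symbol = symbol, stringsAsFactors = FALSE)
  records$synonyms <- synonyms
  # index: name -> gene ids (a name may map to several; ambiguity preserved)
  idx_names <- c(symbol, unlist(synonyms, use.names = FALSE))
  idx_ids <- c(gene_id, rep(gene_id, lengths(synonyms)))
  index <- split(idx_ids, idx_names)
  index <- lapply(index, function(v) sort(unique(v)))
  structure(list(records = records, index = index), class = "synonym_table")
}

#' @export
print.synonym_table <- function(x, ...) {
  cat(sprintf("<synonym_table: %d gene records, %d indexed names>\n",
              nrow(x$records), length(x$index)))
  invisible(x)
}

#' Expand a name list with registered synonyms
#'
#' Adds, for every gene id matched by any input name, the canonical symbol
#' and all registered synonyms.  Names absent from the table pass through
#' unchanged.  A name matching several gene ids expands over all of them
#' (a warning reports the ambiguity).  Output order is deterministic:
#' input names first, then additions sorted.
#'
#' @param names Character vector of names.
#' @param table A [load_synonym_table()] result.
#' @return Character vector of names (superset of the input).
#' @export
expand_synonyms <- function(names, table) {
  stopifnot(inherits(table, "synonym_table"))
  if (length(names) == 0L) return(character())
  ids <- unique(unlist(table$index[intersect(names, names(table$index))], use.names = FALSE))
  ambiguous <- names[vapply(names, function(nm)
    length(table$index[[nm]] %||% integer()) > 1L, NA)]
  if (length(ambiguous)) {
    warning(sprintf("ambiguous name(s) expanded over all matching genes: %s",
                    paste(sort_c(ambiguous), collapse = ", ")), call. = FALSE)
  }
  additions <- character()
  if (length(ids)) {
    hit <- table$records$gene_id %in% ids
    additions <- c(table$records$symbol[hit],
                   unlist(table$records$synonyms[hit], use.names = FALSE))
  }
  c(names, sort_c(setdiff(unique(additions), names)))
}

# Map a name to its canonical symbol when it identifies exactly one gene;
# ambiguous or unknown names map to themselves.
canonicalize_name <- function(names, table) {
  if (is.null(table)) return(names)
  vapply(names, function(nm) {
    ids <- table$index[[nm]] %||% integer()
    if (length(ids) == 1L) {
      table$records$symbol[match(ids, table$records$gene_id)]
    } else nm
  }, "", USE.NAMES = FALSE)
}
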