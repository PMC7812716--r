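# Internal helpers: classed conditions, C-locale sorting, logging.

up_abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "upnet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

usage_error     <- function(msg, ...) up_abort(msg, "upnet_usage_error", ...)
input_error     <- function(msg, ...) up_abort(msg, "upnet_input_error", ...)
transport_error <- function(msg, ...) up_abort(msg, "upnet_transport_error", ...)
export_error    <- function(msg, ...) up_abort(msg, "upnet_export_error", ...)
results_error   <- function(msg, ...) up_abort(msg, "upnet_results_error", ...)

# Locale-independent ordering so outputs are byte-stable across platforms.
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

up_log <- function(..., quiet = FALSE) {
  if (!quiet && isTRUE(getOption("upnet.verbose", FALSE))) {
    message(sprintf(...))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Trim ASCII + common unicode whitespace from both ends.
str_trim2 <- function(x) gsub("^[[:space:]]+|[[:space:]]+$", "", x)

empty_edges_df <- function() {
  data.frame(
    source = character(), target = character(), sign = character(),
    kind = character(), provenance = character(), reaction = character(),
    stringsAsFactors = FALSE
  )
}

empty_nodes_df <- function() {
  data.frame(
    name = character(), entity_class = character(), aliases = character(),
    stringsAsFactors = FALSE
  )
}
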