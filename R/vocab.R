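# BioPAX Level 3 vocabulary and the namespaces used by generated fixtures.

BP  <- "http://www.biopax.org/release/biopax-level3.owl#"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
KB_NS  <- "http://example.org/kb/"

bp <- function(local) paste0(BP, local)

RDF_TYPE <- paste0(RDF_NS, "type")

#' @noRd
BIOPAX_CLASSES <- c(
  "TemplateReactionRegulation", "TemplateReaction", "Control", "Catalysis",
  "BiochemicalReaction", "Complex", "Protein", "SmallMolecule", "Provenance"
)

# Map a BioPAX class IRI to the entity classes used in influence graphs.
entity_class_from_iri <- function(iri) {
  local <- sub("^.*[#/]", "", iri)
  out <- rep("unknown", length(iri))
  out[local == "Protein"]       <- "protein_or_gene"
  out[local == "Complex"]       <- "complex"
  out[local == "SmallMolecule"] <- "small_molecule"
  out[is.na(iri) | iri == ""]   <- "unknown"
  out
}

SIGN_TOKENS <- c("ACTIVATION", "INHIBITION", "UNKNOWN", "PART_OF")

# Collapse BioPAX controlType subtypes (e.g. ACTIVATION-ALLOSTERIC) to the
# two signs, anything else to UNKNOWN.
normalize_sign <- function(control_type) {
  out <- rep("UNKNOWN", length(control_type))
  has <- !is.na(control_type)
  out[has & grepl("ACTIVATION", control_type)] <- "ACTIVATION"
  out[has & grepl("INHIBITION", control_type)] <- "INHIBITION"
  out
}
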