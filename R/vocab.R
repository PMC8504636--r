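#' Relation and prefix vocabulary
#'
#' CURIE prefix map and the fixed relation vocabulary used throughout the
#' package.  Activity-to-activity edges are restricted to the four Relation
#' Ontology causal relations; structural edges (enabled-by, has-input,
#' has-output, occurs-in, part-of, located-in, transport start/end) complete
#' the closed vocabulary that serialized models may use.
#'
#' @name gocam_vocab
NULL

# CURIE prefix -> IRI expansion.  Fixed so output is bit-stable.
.gocamr_prefixes <- c(
  GO      = "http://purl.obolibrary.org/obo/GO_",
  CHEBI   = "http://purl.obolibrary.org/obo/CHEBI_",
  RO      = "http://purl.obolibrary.org/obo/RO_",
  BFO     = "http://purl.obolibrary.org/obo/BFO_",
  ECO     = "http://purl.obolibrary.org/obo/ECO_",
  UniProt = "http://identifiers.org/uniprot/",
  REACTO  = "http://purl.obolibrary.org/obo/go/extensions/reacto.owl#",
  Reactome = "http://identifiers.org/reactome/",
  rdf     = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs    = "http://www.w3.org/2000/01/rdf-schema#",
  owl     = "http://www.w3.org/2002/07/owl#",
  dc      = "http://purl.org/dc/elements/1.1/",
  lego    = "http://geneontology.org/lego/",
  oboInOwl = "http://www.geneontology.org/formats/oboInOwl#"
)

#' Causal and structural relation CURIEs
#'
#' @return Named list of relation CURIEs: the four causal relations
#'   (`causally_upstream_of`, `directly_provides_input_for`,
#'   `directly_positively_regulates`, `directly_negatively_regulates`)
#'   plus the structural relations used on activity units.
#' @export
#' @examples
#' gocam_relations()$directly_provides_input_for
gocam_relations <- function() {
  list(
    causally_upstream_of          = "RO:0002411",
    directly_provides_input_for   = "RO:0002413",
    directly_positively_regulates = "RO:0002629",
    directly_negatively_regulates = "RO:0002630",
    occurs_in                     = "BFO:0000066",
    part_of                       = "BFO:0000050",
    has_part                      = "BFO:0000051",
    enabled_by                    = "RO:0002333",
    has_input                     = "RO:0002233",
    has_output                    = "RO:0002234",
    located_in                    = "RO:0001025",
    has_start_location            = "RO:0002338",
    has_end_location              = "RO:0002339"
  )
}

.causal_relation_curies <- function() {
  unlist(gocam_relations()[c(
    "causally_upstream_of", "directly_provides_input_for",
    "directly_positively_regulates", "directly_negatively_regulates"
  )], use.names = TRUE)
}

# Root terms
.GO_ROOT_BP <- "GO:0008150"   # biological_process
.GO_BINDING <- "GO:0005488"   # binding (default MF for regulator binding nodes)
.GO_TRANSPORTER <- "GO:0005215" # transporter activity (optional step-4 inference)
.CHEBI_INFO_BIOMACROMOLECULE <- "CHEBI:33695"
.REACTO_MOLECULAR_EVENT <- "REACTO:MolecularEvent"

#' Pipeline configuration
#'
#' Declarative run configuration shared by the converter, serializer and the
#' command-line entry points.  The configuration is recorded verbatim in every
#' output model's provenance comment.
#'
#' @param disease_roots Character vector of disease-branch root pathway IDs;
#'   pathways reachable from these via subpathway links are filtered out.
#'   Defaults to Reactome's Disease top-level pathway.
#' @param drug_filter Remove reactions with a drug participant or controller?
#' @param infer_transport_mf If `TRUE`, transport-shaped reactions with no
#'   molecular-function cross-reference receive the generic transporter
#'   activity term instead of the molecular-event fallback.  Default `FALSE`
#'   (conservative: no inference beyond curated cross-references).
#' @param eco_class ECO class CURIE used on automatic evidence annotations.
#' @param binding_term GO molecular-function CURIE used when converting
#'   noncatalytic regulators to binding activity nodes.
#' @param model_base Base IRI for minted model identifiers.
#' @param seed Integer seed recorded in provenance (fixture generation only;
#'   the conversion itself is deterministic).
#' @return A list with class `gocam_config`.
#' @export
#' @examples
#' cfg <- gocam_config(drug_filter = FALSE)
#' cfg$eco_class
gocam_config <- function(disease_roots = "R-HSA-1643685",
                         drug_filter = TRUE,
                         infer_transport_mf = FALSE,
                         eco_class = "ECO:0000363",
                         binding_term = .GO_BINDING,
                         model_base = "http://model.geneontology.org/",
                         seed = NULL) {
  structure(list(
    disease_roots = disease_roots,
    drug_filter = drug_filter,
    infer_transport_mf = infer_transport_mf,
    eco_class = eco_class,
    binding_term = binding_term,
    model_base = model_base,
    seed = seed
  ), class = "gocam_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Unknown keys are rejected so typos in declarative configs fail loudly.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys are
#'   arguments of [gocam_config()].
#' @return A `gocam_config` object.
#' @export
read_gocam_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  allowed <- names(formals(gocam_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(gocam_config, raw)
}

# CURIE -> full IRI using the fixed prefix map; passes through full IRIs.
curie_to_iri <- function(curie) {
  vapply(curie, function(x) {
    if (is.na(x) || !nzchar(x)) return(NA_character_)
    if (grepl("^https?://", x)) return(x)
    parts <- strsplit(x, ":", fixed = TRUE)[[1]]
    if (length(parts) >= 2 && parts[1] %in% names(.gocamr_prefixes)) {
      paste0(.gocamr_prefixes[[parts[1]]], paste(parts[-1], collapse = ":"))
    } else x
  }, character(1), USE.NAMES = FALSE)
}

# Normalize (db, id) pairs from BioPAX xrefs into CURIEs with fixed prefixes.
normalize_xref <- function(db, id) {
  db0 <- tolower(trimws(db %||% ""))
  id <- trimws(id %||% "")
  if (!nzchar(id)) return(NA_character_)
  if (grepl("^uniprot", db0)) return(paste0("UniProt:", id))
  if (grepl("chebi", db0)) {
    return(paste0("CHEBI:", sub("^CHEBI:", "", id, ignore.case = TRUE)))
  }
  if (grepl("gene ontology|^go$", db0)) {
    return(paste0("GO:", sub("^GO:", "", id, ignore.case = TRUE)))
  }
  if (grepl("reactome", db0)) return(paste0("Reactome:", id))
  if (grepl("eco", db0)) return(paste0("ECO:", sub("^ECO:", "", id)))
  paste0(gsub("[^A-Za-z0-9]+", "", db %||% "xref"), ":", id)
}

# Drug cross-reference vocabularies (see package docs: drugs are detected by
# BioPAX Drug classes or by a cross-reference to one of these).
.drug_xref_dbs <- c("drugbank", "iuphar", "guide to pharmacology",
                    "guidetopharmacology")

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
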