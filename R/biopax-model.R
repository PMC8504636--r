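#' In-memory BioPAX pathway model
#'
#' Typed records for the parsed content of one BioPAX Level-3 document:
#' physical entities, reactions, controls and pathways, held in a
#' `pathway_collection`.  Entities reference each other (complex components,
#' set members) and reactions reference entities by local identifier, so the
#' collection's named lists are the single source of truth.
#'
#' @name biopax_model
NULL

.entity_kinds <- c("protein", "small_molecule", "complex", "entity_set",
                   "nucleic_acid", "other")

#' Construct a physical entity record
#'
#' @param local_id Opaque identifier (Reactome stable-ID style).
#' @param display_name Human-readable name.
#' @param kind One of `"protein"`, `"small_molecule"`, `"complex"`,
#'   `"entity_set"`, `"nucleic_acid"`, `"other"`.
#' @param reference_xrefs Character vector of CURIEs (UniProt, ChEBI, ...).
#' @param location_term GO cellular-component CURIE, or `NA`.  An entity
#'   carries at most one location (the source model mints one entity per
#'   entity-by-location combination).
#' @param location_label Free-text label of the location term.
#' @param modifications Character vector of modification descriptors
#'   (`"<feature term>@<position>"` or bare term).
#' @param components Local IDs of complex components (complexes only).
#' @param members Local IDs of set members (entity sets only).
#' @param is_drug Is the entity a drug?
#' @return A list of class `biopax_entity`.
#' @export
physical_entity <- function(local_id, display_name = local_id,
                            kind = "other", reference_xrefs = character(),
                            location_term = NA_character_,
                            location_label = NA_character_,
                            modifications = character(),
                            components = character(),
                            members = character(),
                            is_drug = FALSE) {
  kind <- match.arg(kind, .entity_kinds)
  if (kind == "complex" && length(components) == 0) {
    stop("complex entity '", local_id, "' must have components")
  }
  if (kind == "entity_set" && length(members) == 0) {
    stop("entity set '", local_id, "' must have members")
  }
  if (kind != "complex" && length(components) > 0) {
    stop("only complexes may have components ('", local_id, "')")
  }
  if (kind != "entity_set" && length(members) > 0) {
    stop("only entity sets may have members ('", local_id, "')")
  }
  if (length(location_term) > 1) {
    stop("entity '", local_id, "' has more than one location term")
  }
  # a cross-reference to a drug vocabulary marks the entity as a drug even
  # when the caller did not flag it
  xref_dbs <- tolower(sub(":.*$", "", reference_xrefs))
  is_drug <- isTRUE(is_drug) ||
    any(xref_dbs %in% gsub("[^a-z0-9]", "", .drug_xref_dbs))
  structure(list(
    local_id = local_id, display_name = display_name, kind = kind,
    reference_xrefs = reference_xrefs,
    location_term = location_term, location_label = location_label,
    modifications = modifications,
    components = components, members = members, is_drug = is_drug
  ), class = "biopax_entity")
}

#' Construct a control record
#'
#' @param controller Local ID of the controlling physical entity.
#' @param controlled Local ID of the controlled reaction.
#' @param control_type `"catalysis"`, `"activation"` or `"inhibition"`.
#'   Catalysis marks enzymatic control; the other two are noncatalytic
#'   regulation and are later converted to binding activity nodes.
#' @param control_id Optional identifier of the control element itself.
#' @return A list of class `biopax_control`.
#' @export
biopax_control <- function(controller, controlled, control_type,
                           control_id = NA_character_) {
  control_type <- match.arg(control_type,
                            c("catalysis", "activation", "inhibition"))
  structure(list(controller = controller, controlled = controlled,
                 control_type = control_type, control_id = control_id),
            class = "biopax_control")
}

#' Construct a reaction record
#'
#' @param local_id Reaction identifier.
#' @param display_name Human-readable name.
#' @param inputs,outputs Local IDs of participating entities.  Either may be
#'   empty (shorthand "black box" events omit inputs or outputs).
#' @param controls List of [biopax_control()] records targeting the reaction.
#' @param mf_xrefs GO molecular-function CURIEs from relationship xrefs.
#' @return A list of class `biopax_reaction` with `category` unset until
#'   [classify_reaction()] runs.
#' @export
biopax_reaction <- function(local_id, display_name = local_id,
                            inputs = character(), outputs = character(),
                            controls = list(), mf_xrefs = character()) {
  structure(list(
    local_id = local_id, display_name = display_name,
    inputs = inputs, outputs = outputs, controls = controls,
    mf_xrefs = mf_xrefs, category = NA_character_, is_transport = FALSE
  ), class = "biopax_reaction")
}

#' Construct a pathway record
#'
#' @param local_id Pathway identifier.
#' @param display_name Human-readable name.
#' @param step_reactions Ordered local IDs of the pathway's step reactions.
#' @param next_steps Two-column character matrix (or list of pairs) of
#'   (upstream reaction id, downstream reaction id) step links.
#' @param bp_xrefs GO biological-process CURIEs.
#' @param subpathways Local IDs of subpathways.
#' @param is_disease Is this pathway itself a disease-branch root?
#' @return A list of class `biopax_pathway`.
#' @export
biopax_pathway <- function(local_id, display_name = local_id,
                           step_reactions = character(),
                           next_steps = NULL,
                           bp_xrefs = character(),
                           subpathways = character(),
                           is_disease = FALSE) {
  next_steps <- normalize_next_steps(next_steps)
  structure(list(
    local_id = local_id, display_name = display_name,
    step_reactions = step_reactions, next_steps = next_steps,
    bp_xrefs = bp_xrefs, subpathways = subpathways, is_disease = is_disease
  ), class = "biopax_pathway")
}

normalize_next_steps <- function(next_steps) {
  if (is.null(next_steps) || length(next_steps) == 0) {
    return(matrix(character(), ncol = 2,
                  dimnames = list(NULL, c("from", "to"))))
  }
  if (is.list(next_steps)) {
    next_steps <- do.call(rbind, lapply(next_steps, function(p) {
      stopifnot(length(p) == 2)
      as.character(p)
    }))
  }
  colnames(next_steps) <- c("from", "to")
  next_steps
}

#' Assemble a pathway collection
#'
#' @param pathways List of [biopax_pathway()] records.
#' @param reactions List of [biopax_reaction()] records.
#' @param entities List of [physical_entity()] records.
#' @param source_version Free-text provenance of the source document.
#' @param unresolved Character vector of identifiers referenced but not
#'   resolvable in the document (the unresolved-reference registry).
#' @return A list of class `pathway_collection`; element lists are named by
#'   local ID.
#' @export
pathway_collection <- function(pathways = list(), reactions = list(),
                               entities = list(),
                               source_version = "unknown",
                               unresolved = character()) {
  name_by_id <- function(xs) stats::setNames(xs, vapply(xs, `[[`, "", "local_id"))
  structure(list(
    pathways = name_by_id(pathways),
    reactions = name_by_id(reactions),
    entities = name_by_id(entities),
    source_version = source_version,
    unresolved = unresolved
  ), class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat("<pathway_collection> ", x$source_version, "\n",
      "  pathways:  ", length(x$pathways), "\n",
      "  reactions: ", length(x$reactions), "\n",
      "  entities:  ", length(x$entities), "\n",
      "  unresolved references: ", length(x$unresolved), "\n", sep = "")
  invisible(x)
}

#' @export
print.biopax_entity <- function(x, ...) {
  cat("<biopax_entity> ", x$local_id, " [", x$kind, "] ", x$display_name,
      "\n", sep = "")
  invisible(x)
}

# Recursively flatten an entity-set id to its non-set leaf member ids.
flatten_set_members <- function(entity_id, collection, seen = character()) {
  if (entity_id %in% seen) return(character())  # guard against cycles
  e <- collection$entities[[entity_id]]
  if (is.null(e)) return(character())
  if (e$kind != "entity_set") return(entity_id)
  unique(unlist(lapply(e$members, flatten_set_members, collection = collection,
                       seen = c(seen, entity_id))))
}

# All entity ids participating in a reaction: inputs, outputs, controllers.
reaction_participants <- function(reaction, include_controllers = TRUE) {
  ids <- c(reaction$inputs, reaction$outputs)
  if (include_controllers) {
    ids <- c(ids, vapply(reaction$controls, `[[`, "", "controller"))
  }
  ids
}
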