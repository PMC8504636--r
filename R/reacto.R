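#' Generated entity ontology
#'
#' Pathway databases mint one physical entity per combination of molecule,
#' modification state and subcellular location; GO-CAM models instead type
#' individuals with ontology classes.  This module builds the bridging
#' ontology: one class per physical entity that does not map to an existing
#' standard-ontology class, with logical structure for entity sets (unions:
#' any member can act), complexes (named classes with has-part links) and
#' proteoforms (subclasses of the canonical protein's class carrying the
#' modification set in their definition).
#'
#' Identity rules, applied when a class is minted:
#' * small molecules with a ChEBI cross-reference map to the ChEBI class
#'   itself - no new class (cytosolic and nuclear ADP share one class);
#' * location never enters class identity - located duplicates of an entity
#'   share a class, and location is modeled on the activity/participant
#'   individual instead;
#' * unmodified proteins with the same UniProt accession share one class,
#'   cross-referenced to the accession;
#' * proteoforms with the same accession and the same modification set share
#'   one class, a subclass of the canonical protein's class;
#' * complexes with the same component-class multiset share one class;
#' * entity sets with the same flattened member-class set share one class.
#'
#' Gene-product-like classes are rooted under the information biomacromolecule
#' class (CHEBI:33695).  A `molecular event` root class is always present: it
#' is the superclass of both gene-product-enabled molecular functions and
#' activities whose enabler is unspecified, and serves as the fallback type
#' for activities with no curated molecular function.
#'
#' @name reacto
NULL

#' Create an empty entity ontology
#'
#' Contains only the structural roots: the molecular-event class and the
#' information-biomacromolecule root.
#'
#' @param provenance Free-text provenance (source document and version).
#' @return A list of class `entity_ontology` with `classes`,
#'   `entity_to_class` and `provenance` fields.
#' @export
empty_entity_ontology <- function(provenance = "unknown") {
  onto <- structure(list(
    classes = list(),
    entity_to_class = character(),
    # dedup keys -> IRI (proteoforms, complexes, sets, canonical proteins)
    identity_keys = character(),
    provenance = provenance
  ), class = "entity_ontology")
  onto <- add_class(onto, ontology_class(
    iri = .REACTO_MOLECULAR_EVENT, label = "molecular event",
    definition = paste("A molecular-scale event; superclass of gene-product",
                       "enabled molecular functions and of activities whose",
                       "enabler is unspecified.")
  ))
  onto <- add_class(onto, ontology_class(
    iri = .CHEBI_INFO_BIOMACROMOLECULE, label = "information biomacromolecule",
    definition = "Root for gene-product-like classes."
  ))
  onto
}

ontology_class <- function(iri, label, superclasses = character(),
                           union_members = NULL,
                           component_links = character(),
                           xrefs = character(), definition = "") {
  structure(list(iri = iri, label = label, superclasses = superclasses,
                 union_members = union_members,
                 component_links = component_links,
                 xrefs = xrefs, definition = definition),
            class = "ontology_class")
}

add_class <- function(ontology, cls) {
  ontology$classes[[cls$iri]] <- cls
  ontology
}

#' @export
print.entity_ontology <- function(x, ...) {
  cat("<entity_ontology> ", length(x$classes), " classes, ",
      length(x$entity_to_class), " entity mappings\n", sep = "")
  invisible(x)
}

reacto_iri <- function(local_id) paste0("REACTO:", sanitize_id(local_id))

first_xref <- function(entity, prefix) {
  hits <- entity$reference_xrefs[startsWith(entity$reference_xrefs,
                                            paste0(prefix, ":"))]
  if (length(hits)) hits[[1]] else NA_character_
}

#' Class for a physical entity
#'
#' Returns the ontology class IRI for an entity, minting a new class when
#' needed (see the identity rules in [reacto]).  Idempotent: repeated calls
#' with the same entity return the same IRI.  Called with an entity that has
#' neither name nor cross-references, a class is still minted (opaque label)
#' with a warning.
#'
#' @param entity A [physical_entity()].
#' @param ontology An `entity_ontology`.
#' @param collection The [pathway_collection()] used to resolve components
#'   and members.
#' @return List with `iri` (the class IRI) and `ontology` (possibly updated).
#' @export
class_for_entity <- function(entity, ontology, collection) {
  existing <- ontology$entity_to_class[entity$local_id]
  if (!is.na(existing)) return(list(iri = unname(existing), ontology = ontology))

  chebi <- first_xref(entity, "CHEBI")
  uniprot <- first_xref(entity, "UniProt")

  mint <- function(iri, cls, key = NULL) {
    if (is.null(ontology$classes[[iri]])) ontology <- add_class(ontology, cls)
    ontology$entity_to_class[[entity$local_id]] <- iri
    if (!is.null(key)) ontology$identity_keys[[key]] <- iri
    list(iri = iri, ontology = ontology)
  }
  keyed <- function(key) {
    hit <- ontology$identity_keys[key]
    if (is.na(hit)) return(NULL)
    ontology$entity_to_class[[entity$local_id]] <- unname(hit)
    list(iri = unname(hit), ontology = ontology)
  }

  # small molecules with a usable ChEBI xref: the ChEBI class directly
  if (entity$kind == "small_molecule" && !is.na(chebi)) {
    cls <- ontology_class(iri = chebi, label = entity$display_name,
                          xrefs = chebi)
    return(mint(chebi, cls))
  }

  if (entity$kind == "entity_set") {
    return(union_for_set(entity, ontology, collection))
  }

  if (entity$kind == "complex") {
    comp <- lapply(entity$components, function(cid) {
      ce <- collection$entities[[cid]]
      if (is.null(ce)) return(NA_character_)
      res <- class_for_entity(ce, ontology, collection)
      ontology <<- res$ontology
      res$iri
    })
    comp <- sort(unlist(comp))
    key <- paste0("complex|", paste(comp, collapse = "+"))
    hit <- keyed(key)
    if (!is.null(hit)) return(hit)
    iri <- reacto_iri(entity$local_id)
    cls <- ontology_class(
      iri = iri, label = entity$display_name,
      superclasses = .CHEBI_INFO_BIOMACROMOLECULE,
      component_links = comp[!is.na(comp)],
      definition = paste0("Complex of: ", paste(comp, collapse = ", "), ".")
    )
    return(mint(iri, cls, key))
  }

  if (entity$kind == "protein" && !is.na(uniprot)) {
    mods <- sort(entity$modifications)
    canon_key <- paste0("protein|", uniprot)
    if (length(mods) == 0) {
      hit <- keyed(canon_key)
      if (!is.null(hit)) return(hit)
      iri <- reacto_iri(entity$local_id)
      cls <- ontology_class(
        iri = iri, label = entity$display_name,
        superclasses = .CHEBI_INFO_BIOMACROMOLECULE, xrefs = uniprot,
        definition = paste0("Canonical gene product ", uniprot, ".")
      )
      return(mint(iri, cls, canon_key))
    }
    # proteoform: subclass of the canonical protein's class
    pf_key <- paste0("proteoform|", uniprot, "|", paste(mods, collapse = ";"))
    hit <- keyed(pf_key)
    if (!is.null(hit)) return(hit)
    canon_iri <- ontology$identity_keys[canon_key]
    if (is.na(canon_iri)) {
      canon_iri <- paste0("REACTO:", sub("^UniProt:", "", uniprot))
      ontology <- add_class(ontology, ontology_class(
        iri = canon_iri,
        label = sub("^UniProt:", "", uniprot),
        superclasses = .CHEBI_INFO_BIOMACROMOLECULE, xrefs = uniprot,
        definition = paste0("Canonical gene product ", uniprot, ".")
      ))
      ontology$identity_keys[[canon_key]] <- canon_iri
    }
    iri <- reacto_iri(entity$local_id)
    cls <- ontology_class(
      iri = iri, label = entity$display_name,
      superclasses = unname(canon_iri),
      definition = paste0("Proteoform of ", uniprot, " with modifications: ",
                          paste(mods, collapse = "; "), ".")
    )
    return(mint(iri, cls, pf_key))
  }

  # everything else: one class per entity, rooted by kind
  if (!nzchar(entity$display_name %||% "") &&
      length(entity$reference_xrefs) == 0) {
    warning("entity '", entity$local_id,
            "' has no name and no xrefs; minting opaque class", call. = FALSE)
  }
  iri <- reacto_iri(entity$local_id)
  super <- if (entity$kind %in% c("protein", "nucleic_acid"))
    .CHEBI_INFO_BIOMACROMOLECULE else character()
  cls <- ontology_class(
    iri = iri,
    label = if (nzchar(entity$display_name %||% "")) entity$display_name
            else entity$local_id,
    superclasses = super, xrefs = entity$reference_xrefs,
    definition = paste0("Physical entity ", entity$local_id, ".")
  )
  mint(iri, cls)
}

#' Union class for an entity set
#'
#' Entity sets are shorthand for interchangeable entities sharing an
#' activity; the set's class is a union (logical OR) of the classes of all
#' recursively flattened members, signifying that any member can act in the
#' reaction.  Nested sets are flattened to their leaves.  Sets with the same
#' flattened member-class set share one class.
#'
#' @param set_entity A [physical_entity()] with `kind = "entity_set"`.
#' @inheritParams class_for_entity
#' @return List with `iri` and (possibly updated) `ontology`.
#' @export
union_for_set <- function(set_entity, ontology, collection) {
  stopifnot(set_entity$kind == "entity_set")
  leaves <- flatten_set_members(set_entity$local_id, collection)
  if (length(leaves) == 0) {
    stop("entity set '", set_entity$local_id, "' has no resolvable members")
  }
  member_iris <- character()
  for (lid in leaves) {
    le <- collection$entities[[lid]]
    res <- class_for_entity(le, ontology, collection)
    ontology <- res$ontology
    member_iris <- c(member_iris, res$iri)
  }
  member_iris <- sort(unique(member_iris))
  key <- paste0("set|", paste(member_iris, collapse = "+"))
  hit <- ontology$identity_keys[key]
  if (!is.na(hit)) {
    ontology$entity_to_class[[set_entity$local_id]] <- unname(hit)
    return(list(iri = unname(hit), ontology = ontology))
  }
  iri <- reacto_iri(set_entity$local_id)
  cls <- ontology_class(
    iri = iri, label = set_entity$display_name,
    superclasses = .CHEBI_INFO_BIOMACROMOLECULE,
    union_members = member_iris,
    definition = paste0("Union of: ", paste(member_iris, collapse = ", "),
                        " (any member can act).")
  )
  ontology <- add_class(ontology, cls)
  ontology$entity_to_class[[set_entity$local_id]] <- iri
  ontology$identity_keys[[key]] <- iri
  list(iri = iri, ontology = ontology)
}

#' Build the entity ontology for a collection
#'
#' Covers every physical entity reachable from the collection's retained
#' reactions (participants, controllers, complex components, set members,
#' recursively), plus the structural roots.
#'
#' @param collection A (filtered) [pathway_collection()].
#' @return An `entity_ontology` whose `entity_to_class` is total over the
#'   reachable entities.
#' @export
#' @examples
#' col <- parse_biopax(make_crym_fixture())
#' onto <- build_entity_ontology(col)
#' onto$entity_to_class[["SmallMolecule_hydron"]]
build_entity_ontology <- function(collection) {
  ontology <- empty_entity_ontology(provenance = collection$source_version)
  reach <- character()
  frontier <- unique(unlist(lapply(collection$reactions,
                                   reaction_participants)))
  while (length(frontier)) {
    frontier <- intersect(frontier, names(collection$entities))
    frontier <- setdiff(frontier, reach)
    if (!length(frontier)) break
    reach <- c(reach, frontier)
    frontier <- unique(unlist(lapply(frontier, function(id) {
      e <- collection$entities[[id]]
      c(e$components, e$members)
    })))
  }
  for (id in sort(reach)) {
    res <- class_for_entity(collection$entities[[id]], ontology, collection)
    ontology <- res$ontology
  }
  ontology
}
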