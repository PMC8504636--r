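#' Parse a BioPAX Level-3 document
#'
#' Reads a BioPAX Level-3 RDF/XML document into a [pathway_collection()]:
#' pathways (with step order and next-step links), biochemical reactions
#' (including transport and degradation events), physical entities (with
#' complex components and set members resolved recursively), catalysis and
#' regulation controls, cellular locations and relationship cross-references.
#' GO, UniProt and ChEBI cross-references are normalized to CURIEs.
#'
#' Elements whose BioPAX class is not handled are skipped with a warning and
#' recorded in the collection's unresolved-reference registry, as are
#' references that do not resolve within the document.
#'
#' @param input Path to a `.owl` file, a literal XML string, or a raw vector.
#' @return A [pathway_collection()].
#' @export
#' @examples
#' doc <- make_crym_fixture()
#' col <- parse_biopax(doc)
#' col$reactions[["R-HSA-5693347"]]$mf_xrefs
parse_biopax <- function(input) {
  xml <- tryCatch(
    xml2::read_xml(input),
    error = function(e) stop("BioPAX parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  ns <- c(
    bp  = "http://www.biopax.org/release/biopax-level3.owl#",
    rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    owl = "http://www.w3.org/2002/07/owl#",
    rdfs = "http://www.w3.org/2000/01/rdf-schema#"
  )

  nodes <- xml2::xml_find_all(xml, "/rdf:RDF/*", ns)
  idx <- new.env(parent = emptyenv())
  unresolved <- character()
  for (nd in nodes) {
    id <- node_id(nd)
    if (!is.na(id) && nzchar(id)) assign(id, nd, envir = idx)
  }
  lookup <- function(ref) {
    if (is.na(ref)) return(NULL)
    get0(ref, envir = idx, inherits = FALSE)
  }

  entity_classes <- c("Protein", "SmallMolecule", "Complex", "PhysicalEntity",
                      "Dna", "Rna", "DnaRegion", "RnaRegion", "Gene",
                      "Drug")
  reaction_classes <- c("BiochemicalReaction", "Transport",
                        "TransportWithBiochemicalReaction", "Degradation",
                        "TemplateReaction")
  helper_classes <- c("Pathway", "PathwayStep", "BiochemicalPathwayStep",
                      "Catalysis", "Control", "Modulation",
                      "TemplateReactionRegulation",
                      "UnificationXref", "RelationshipXref",
                      "PublicationXref",
                      "ProteinReference", "SmallMoleculeReference",
                      "DnaReference", "RnaReference", "EntityReference",
                      "CellularLocationVocabulary",
                      "SequenceModificationVocabulary",
                      "RelationshipTypeVocabulary",
                      "ModificationFeature", "FragmentFeature",
                      "SequenceSite", "SequenceInterval",
                      "BioSource", "Provenance", "Evidence", "Stoichiometry")

  source_version <- "unknown"
  onto <- xml2::xml_find_first(xml, "/rdf:RDF/owl:Ontology/rdfs:comment", ns)
  if (!inherits(onto, "xml_missing")) {
    source_version <- xml2::xml_text(onto)
  }

  # ---- local accessors -------------------------------------------------
  prop_refs <- function(nd, prop) {
    kids <- xml2::xml_find_all(nd, paste0("./bp:", prop), ns)
    refs <- rdf_attr(kids, "resource")
    sub("^#", "", refs[!is.na(refs)])
  }
  prop_text <- function(nd, prop) {
    kids <- xml2::xml_find_all(nd, paste0("./bp:", prop), ns)
    xml2::xml_text(kids)
  }
  display_name <- function(nd, fallback) {
    nm <- prop_text(nd, "displayName")
    if (length(nm)) nm[[1]] else {
      nm <- prop_text(nd, "name")
      if (length(nm)) nm[[1]] else fallback
    }
  }
  xref_curie <- function(ref) {
    nd <- lookup(ref)
    if (is.null(nd)) { unresolved <<- c(unresolved, ref); return(NA_character_) }
    normalize_xref(prop_text(nd, "db")[1] %||% NA, prop_text(nd, "id")[1] %||% NA)
  }
  node_xrefs <- function(nd, node_class = NULL) {
    refs <- prop_refs(nd, "xref")
    if (!is.null(node_class)) {
      refs <- Filter(function(r) {
        x <- lookup(r); !is.null(x) && xml2::xml_name(x) %in% node_class
      }, refs)
    }
    out <- vapply(refs, xref_curie, character(1), USE.NAMES = FALSE)
    out[!is.na(out)]
  }

  # ---- physical entities ----------------------------------------------
  parse_location <- function(nd) {
    ref <- prop_refs(nd, "cellularLocation")
    if (!length(ref)) return(list(term = NA_character_, label = NA_character_))
    loc <- lookup(ref[[1]])
    if (is.null(loc)) {
      unresolved <<- c(unresolved, ref[[1]])
      return(list(term = NA_character_, label = NA_character_))
    }
    term <- node_xrefs(loc, "UnificationXref")
    term <- term[grepl("^GO:", term)]
    list(term = if (length(term)) term[[1]] else NA_character_,
         label = prop_text(loc, "term")[1] %||% NA_character_)
  }
  parse_modifications <- function(nd) {
    refs <- prop_refs(nd, "feature")
    mods <- character()
    for (r in refs) {
      f <- lookup(r)
      if (is.null(f) || xml2::xml_name(f) != "ModificationFeature") next
      term <- NA_character_
      mt <- prop_refs(f, "modificationType")
      if (length(mt)) {
        v <- lookup(mt[[1]])
        if (!is.null(v)) term <- prop_text(v, "term")[1] %||% NA_character_
      }
      pos <- NA_character_
      fl <- prop_refs(f, "featureLocation")
      if (length(fl)) {
        s <- lookup(fl[[1]])
        if (!is.null(s)) pos <- prop_text(s, "sequencePosition")[1] %||% NA_character_
      }
      if (is.na(term)) term <- "modified residue"
      mods <- c(mods, if (is.na(pos)) term else paste0(term, "@", pos))
    }
    mods
  }
  parse_entity <- function(nd) {
    id <- node_id(nd)
    cls <- xml2::xml_name(nd)
    members <- prop_refs(nd, "memberPhysicalEntity")
    components <- prop_refs(nd, "component")
    kind <-
      if (length(members)) "entity_set"
      else if (cls == "Complex") "complex"
      else if (cls %in% c("Protein")) "protein"
      else if (cls %in% c("SmallMolecule", "Drug")) "small_molecule"
      else if (cls %in% c("Dna", "Rna", "DnaRegion", "RnaRegion", "Gene"))
        "nucleic_acid"
      else "other"
    ref_xrefs <- character()
    er <- prop_refs(nd, "entityReference")
    if (length(er)) {
      ernd <- lookup(er[[1]])
      if (is.null(ernd)) unresolved <<- c(unresolved, er[[1]])
      else ref_xrefs <- node_xrefs(ernd, "UnificationXref")
    }
    own_xrefs <- node_xrefs(nd, "UnificationXref")
    ref_xrefs <- unique(c(ref_xrefs, own_xrefs))
    loc <- parse_location(nd)
    is_drug <- cls == "Drug" ||
      any(tolower(sub(":.*$", "", ref_xrefs)) %in%
            gsub("[^a-z0-9]", "", .drug_xref_dbs))
    physical_entity(
      local_id = id, display_name = display_name(nd, id), kind = kind,
      reference_xrefs = ref_xrefs,
      location_term = loc$term, location_label = loc$label,
      modifications = parse_modifications(nd),
      components = components, members = members, is_drug = is_drug
    )
  }

  entities <- list()
  for (nd in nodes) {
    if (xml2::xml_name(nd) %in% entity_classes) {
      e <- parse_entity(nd)
      entities[[e$local_id]] <- e
    }
  }

  # ---- reactions -------------------------------------------------------
  reactions <- list()
  for (nd in nodes) {
    if (!(xml2::xml_name(nd) %in% reaction_classes)) next
    id <- node_id(nd)
    mf <- node_xrefs(nd, "RelationshipXref")
    reactions[[id]] <- biopax_reaction(
      local_id = id, display_name = display_name(nd, id),
      inputs = prop_refs(nd, "left"),
      outputs = prop_refs(nd, "right"),
      mf_xrefs = mf[grepl("^GO:", mf)]
    )
  }

  # ---- controls --------------------------------------------------------
  control_classes <- c("Catalysis", "Control", "Modulation",
                       "TemplateReactionRegulation")
  for (nd in nodes) {
    cls <- xml2::xml_name(nd)
    if (!(cls %in% control_classes)) next
    id <- node_id(nd)
    controller <- prop_refs(nd, "controller")
    controlled <- prop_refs(nd, "controlled")
    if (!length(controller) || !length(controlled)) next
    ctype <- if (cls == "Catalysis") "catalysis" else {
      raw <- toupper(prop_text(nd, "controlType")[1] %||% "ACTIVATION")
      if (grepl("INHIBITION", raw)) "inhibition" else "activation"
    }
    for (tgt in controlled) {
      if (is.null(reactions[[tgt]])) {
        # control of a pathway or missing target: registry, not an error
        unresolved <- c(unresolved, paste0(id, "->", tgt))
        next
      }
      ctl <- biopax_control(controller = controller[[1]], controlled = tgt,
                            control_type = ctype, control_id = id)
      reactions[[tgt]]$controls <- c(reactions[[tgt]]$controls, list(ctl))
      if (is.null(entities[[controller[[1]]]])) {
        unresolved <- c(unresolved, controller[[1]])
      }
    }
  }

  # ---- pathways --------------------------------------------------------
  step_class <- c("PathwayStep", "BiochemicalPathwayStep")
  pathways <- list()
  for (nd in nodes) {
    if (xml2::xml_name(nd) != "Pathway") next
    id <- node_id(nd)
    comp <- prop_refs(nd, "pathwayComponent")
    step_rxns <- character(); subp <- character()
    for (c0 in comp) {
      cn <- lookup(c0)
      if (is.null(cn)) { unresolved <- c(unresolved, c0); next }
      if (xml2::xml_name(cn) == "Pathway") subp <- c(subp, c0)
      else if (xml2::xml_name(cn) %in% reaction_classes)
        step_rxns <- c(step_rxns, c0)
    }
    # pathwayOrder: steps hold processes; nextStep links steps
    pairs <- list()
    step_refs <- prop_refs(nd, "pathwayOrder")
    step_processes <- function(sref) {
      sn <- lookup(sref)
      if (is.null(sn) || !(xml2::xml_name(sn) %in% step_class)) return(character())
      pr <- c(prop_refs(sn, "stepProcess"), prop_refs(sn, "stepConversion"))
      pr[pr %in% names(reactions)]
    }
    for (sref in step_refs) {
      sn <- lookup(sref)
      if (is.null(sn)) { unresolved <- c(unresolved, sref); next }
      ups <- step_processes(sref)
      for (nref in prop_refs(sn, "nextStep")) {
        downs <- step_processes(nref)
        if (is.null(lookup(nref))) unresolved <- c(unresolved, nref)
        for (u in ups) for (d in downs) pairs[[length(pairs) + 1L]] <- c(u, d)
      }
    }
    bp <- node_xrefs(nd, "RelationshipXref")
    pathways[[id]] <- biopax_pathway(
      local_id = id, display_name = display_name(nd, id),
      step_reactions = step_rxns, next_steps = pairs,
      bp_xrefs = bp[grepl("^GO:", bp)], subpathways = subp
    )
  }

  # ---- unknown top-level classes --------------------------------------
  known <- c(entity_classes, reaction_classes, helper_classes, "Ontology")
  for (nd in nodes) {
    cls <- xml2::xml_name(nd)
    if (!(cls %in% known)) {
      warning("skipping unknown BioPAX class '", cls, "' (",
              node_id(nd), ")", call. = FALSE)
      unresolved <- c(unresolved, paste0("class:", cls, ":", node_id(nd)))
    }
  }

  # dangling references from reactions/entities into the registry
  all_ids <- c(names(entities), names(reactions), names(pathways))
  for (r in reactions) {
    miss <- setdiff(c(r$inputs, r$outputs), names(entities))
    unresolved <- c(unresolved, miss)
  }
  for (e in entities) {
    miss <- setdiff(c(e$components, e$members), names(entities))
    unresolved <- c(unresolved, miss)
  }
  for (p in pathways) {
    refs <- unique(as.vector(p$next_steps))
    unresolved <- c(unresolved, setdiff(refs, all_ids))
  }

  pathway_collection(
    pathways = unname(pathways), reactions = unname(reactions),
    entities = unname(entities), source_version = source_version,
    unresolved = unique(unresolved)
  )
}

# rdf:ID / rdf:about / rdf:resource attributes, tolerant of how the
# document declares the rdf prefix.
rdf_attr <- function(nds, name) {
  out <- xml2::xml_attr(nds, paste0("rdf:", name))
  alt <- xml2::xml_attr(nds, name)
  ifelse(is.na(out), alt, out)
}

node_id <- function(nd) {
  id <- rdf_attr(nd, "ID")
  if (length(id) == 0) return(NA_character_)
  if (is.na(id)) id <- sub("^#", "", rdf_attr(nd, "about"))
  id
}
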