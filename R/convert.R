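#' Reaction-to-activity conversion
#'
#' The central premise of the conversion: each conversion event in a
#' process-description pathway corresponds to one molecular activity in the
#' activity-flow model.  A complete activity unit specifies the molecular
#' function, the enabling gene product or complex, the inputs and outputs,
#' the cellular location, the biological process it is part of, and at least
#' one causal connection to another activity.  Every retained reaction yields
#' exactly one activity unit - conversion is total; missing attributes make
#' the unit incomplete, never unconvertible.
#'
#' @name conversion
NULL

#' Molecular function for a reaction
#'
#' The first GO molecular-function cross-reference on the reaction wins
#' (additional ones produce a warning).  Without one, the optional
#' transport-inference step can assign the generic transporter-activity term
#' to transport-shaped reactions (`config$infer_transport_mf`, default off);
#' otherwise the activity falls through to the `molecular event` class, the
#' generated superclass covering activities whose function is unspecified.
#'
#' @param reaction A classified [biopax_reaction()].
#' @param config A [gocam_config()].
#' @return A CURIE: a GO MF term, the transporter-activity term, or the
#'   molecular-event class.
#' @export
assign_molecular_function <- function(reaction, config = gocam_config()) {
  if (length(reaction$mf_xrefs) >= 1) {
    if (length(reaction$mf_xrefs) > 1) {
      warning("reaction '", reaction$local_id, "' has ",
              length(reaction$mf_xrefs),
              " molecular-function xrefs; using the first", call. = FALSE)
    }
    return(reaction$mf_xrefs[[1]])
  }
  if (isTRUE(config$infer_transport_mf) &&
      (isTRUE(reaction$is_transport) ||
       identical(reaction$category, "transport"))) {
    return(.GO_TRANSPORTER)
  }
  .REACTO_MOLECULAR_EVENT
}

#' Enabler for a reaction
#'
#' A catalysis controller enables the activity: a single protein maps to its
#' protein class, a complex to the complex class, an entity set to the union
#' class (any member can act).  Binding, dissociation and black-box reactions
#' without catalysis have no enabler.  Multiple catalysis controls use the
#' first in document order with a warning.
#'
#' @param reaction A [biopax_reaction()].
#' @param ontology An `entity_ontology` covering the reaction's entities.
#' @param collection The source [pathway_collection()].
#' @return A class CURIE/IRI, or `NA_character_` when there is no enabler.
#' @export
determine_enabler <- function(reaction, ontology, collection) {
  cats <- Filter(function(c) c$control_type == "catalysis", reaction$controls)
  if (length(cats) == 0) return(NA_character_)
  if (length(cats) > 1) {
    warning("reaction '", reaction$local_id,
            "' has multiple catalysis controls; using the first",
            call. = FALSE)
  }
  ctrl <- cats[[1]]$controller
  cls <- ontology$entity_to_class[ctrl]
  if (is.na(cls)) {
    e <- collection$entities[[ctrl]]
    if (is.null(e)) return(NA_character_)
    cls <- class_for_entity(e, ontology, collection)$iri
  }
  unname(cls)
}

#' Single location for a reaction
#'
#' An activity unit may carry only a single location.  When every participant
#' (inputs, outputs and catalysis controllers) carries the same location
#' term, the activity occurs there; otherwise the activity gets no location,
#' and the per-participant locations are preserved on the unit so no
#' information is lost.  Transport-shaped reactions additionally report the
#' start (input-side) and end (output-side) locations.
#'
#' @inheritParams determine_enabler
#' @return List with `location`, `transport_from`, `transport_to` (CURIEs or
#'   `NA_character_`).
#' @export
infer_location <- function(reaction, collection) {
  loc_of <- function(id) {
    e <- collection$entities[[id]]
    if (is.null(e)) NA_character_ else e$location_term
  }
  cat_ctrls <- vapply(
    Filter(function(c) c$control_type == "catalysis", reaction$controls),
    `[[`, "", "controller")
  participants <- c(reaction$inputs, reaction$outputs, cat_ctrls)
  locs <- vapply(participants, loc_of, character(1))
  uniq <- unique(locs)
  location <- if (length(participants) > 0 && length(uniq) == 1 &&
                  !is.na(uniq)) uniq else NA_character_

  transport_from <- transport_to <- NA_character_
  if (isTRUE(reaction$is_transport) ||
      identical(reaction$category, "transport")) {
    in_locs <- unique(stats::na.omit(vapply(reaction$inputs, loc_of,
                                            character(1))))
    out_locs <- unique(stats::na.omit(vapply(reaction$outputs, loc_of,
                                             character(1))))
    if (length(in_locs)) transport_from <- in_locs[[1]]
    if (length(out_locs)) transport_to <- out_locs[[1]]
  }
  list(location = location, transport_from = transport_from,
       transport_to = transport_to)
}

#' Biological process for a reaction
#'
#' The immediate parent pathway's first GO biological-process
#' cross-reference; without one, the root biological-process term.  No upward
#' search through grandparent pathways: a reaction inherits the curation gap
#' of its own pathway.
#'
#' @param reaction A [biopax_reaction()] (used for messages only).
#' @param parent The [biopax_pathway()] containing the reaction step, or
#'   `NULL`.
#' @return A GO biological-process CURIE.
#' @export
assign_process <- function(reaction, parent) {
  if (!is.null(parent) && length(parent$bp_xrefs) >= 1) {
    return(parent$bp_xrefs[[1]])
  }
  .GO_ROOT_BP
}

#' Convert one reaction to an activity unit
#'
#' Composes [assign_molecular_function()], [determine_enabler()],
#' [infer_location()] and [assign_process()], and attaches the inputs and
#' outputs as (entity class, participant location) pairs.  Total: every
#' retained reaction yields exactly one unit.
#'
#' @inheritParams determine_enabler
#' @param parent The containing [biopax_pathway()], or `NULL`.
#' @param config A [gocam_config()].
#' @param activity_id Minted individual IRI for the activity.
#' @return A list of class `activity_unit`.
#' @export
reaction_to_activity <- function(reaction, parent, ontology, collection,
                                 config = gocam_config(),
                                 activity_id = NA_character_) {
  part <- function(id) {
    e <- collection$entities[[id]]
    cls <- unname(ontology$entity_to_class[id])
    if (is.na(cls) && !is.null(e)) {
      cls <- class_for_entity(e, ontology, collection)$iri
    }
    list(entity_id = id, class_iri = cls,
         location = if (is.null(e)) NA_character_ else e$location_term)
  }
  loc <- infer_location(reaction, collection)
  enabler <- determine_enabler(reaction, ontology, collection)
  enabler_entity <- NA_character_
  enabler_location <- NA_character_
  cats <- Filter(function(c) c$control_type == "catalysis", reaction$controls)
  if (length(cats)) {
    enabler_entity <- cats[[1]]$controller
    ee <- collection$entities[[enabler_entity]]
    if (!is.null(ee)) enabler_location <- ee$location_term
  }
  structure(list(
    activity_id = activity_id,
    function_class = assign_molecular_function(reaction, config),
    enabler = enabler,
    enabler_entity = enabler_entity,
    enabler_location = enabler_location,
    inputs = lapply(reaction$inputs, part),
    outputs = lapply(reaction$outputs, part),
    location = loc$location,
    transport_from = loc$transport_from,
    transport_to = loc$transport_to,
    process_class = assign_process(reaction, parent),
    causal_edges = list(),
    source_reaction = reaction$local_id,
    source_category = reaction$category,
    is_transport = isTRUE(reaction$is_transport) ||
      identical(reaction$category, "transport"),
    complex_enabler = !is.na(enabler) && startsWith(enabler, "REACTO:") &&
      length(cats) > 0 && !is.null(collection$entities[[enabler_entity]]) &&
      collection$entities[[enabler_entity]]$kind == "complex"
  ), class = "activity_unit")
}

#' @export
print.activity_unit <- function(x, ...) {
  cat("<activity_unit> ", x$source_reaction, "\n",
      "  function: ", x$function_class,
      "  enabled by: ", ifelse(is.na(x$enabler), "-", x$enabler), "\n",
      "  inputs: ", length(x$inputs), "  outputs: ", length(x$outputs),
      "  location: ", ifelse(is.na(x$location), "-", x$location), "\n",
      "  process: ", x$process_class, "\n", sep = "")
  invisible(x)
}

#' Convert a pathway to a model skeleton
#'
#' One activity unit per retained step reaction; one process node per
#' subpathway.  A pathway containing only subpathways is represented by a
#' single process node.  The model identifier is derived from the pathway's
#' core identifier under the configured model base IRI.
#'
#' @param pathway A retained [biopax_pathway()].
#' @param collection The filtered, classified [pathway_collection()].
#' @param ontology An `entity_ontology` covering the collection.
#' @param config A [gocam_config()].
#' @return A list of class `gocam_model` with activities keyed by activity
#'   IRI.
#' @export
#' @examples
#' col <- classify_collection(parse_biopax(make_crym_fixture()))
#' onto <- build_entity_ontology(col)
#' m <- convert_pathway(col$pathways[["R-HSA-71064"]], col, onto)
#' length(m$activities)
convert_pathway <- function(pathway, collection, ontology,
                            config = gocam_config()) {
  model_id <- paste0(config$model_base, core_pathway_id(pathway$local_id))
  step_ids <- intersect(pathway$step_reactions, names(collection$reactions))
  if (length(step_ids) == 0 && length(pathway$subpathways) == 0) {
    warning("pathway '", pathway$local_id,
            "' has no retained steps; emitting an empty model", call. = FALSE)
  }
  activities <- list()
  ordinal <- 0L
  for (rid in step_ids) {
    ordinal <- ordinal + 1L
    aid <- mint_individual_iri(model_id, ordinal)
    unit <- reaction_to_activity(collection$reactions[[rid]], pathway,
                                 ontology, collection, config,
                                 activity_id = aid)
    activities[[aid]] <- unit
  }
  subpathway_nodes <- lapply(pathway$subpathways, function(sid) {
    sp <- collection$pathways[[sid]]
    list(pathway_id = sid,
         process_class = if (!is.null(sp) && length(sp$bp_xrefs))
           sp$bp_xrefs[[1]] else .GO_ROOT_BP,
         title = if (!is.null(sp)) sp$display_name else sid)
  })
  structure(list(
    model_id = model_id,
    pathway_id = pathway$local_id,
    title = pathway$display_name,
    process_class = if (length(pathway$bp_xrefs)) pathway$bp_xrefs[[1]]
                    else .GO_ROOT_BP,
    activities = activities,
    subpathway_nodes = subpathway_nodes,
    causal_edges = list(),
    n_dropped_links = 0L,
    next_ordinal = ordinal + 1L,
    provenance = collection$source_version,
    config = config
  ), class = "gocam_model")
}

#' @export
print.gocam_model <- function(x, ...) {
  cat("<gocam_model> ", x$model_id, "\n",
      "  title: ", x$title, "\n",
      "  activities: ", length(x$activities),
      "  causal edges: ", length(x$causal_edges),
      "  dropped links: ", x$n_dropped_links, "\n", sep = "")
  invisible(x)
}

#' Convert every retained pathway in a collection
#'
#' Runs [convert_pathway()], [link_pathway_steps()] and
#' [regulators_to_binding()] over the whole collection.
#'
#' @param collection A filtered [pathway_collection()] (classified if not
#'   already).
#' @param ontology Optional pre-built `entity_ontology`.
#' @param config A [gocam_config()].
#' @return Named list of `gocam_model` objects (by pathway ID).
#' @export
convert_collection <- function(collection, ontology = NULL,
                               config = gocam_config()) {
  collection <- classify_collection(collection)
  if (is.null(ontology)) ontology <- build_entity_ontology(collection)
  models <- list()
  for (pid in names(collection$pathways)) {
    m <- convert_pathway(collection$pathways[[pid]], collection, ontology,
                         config)
    m <- link_pathway_steps(m, collection$pathways[[pid]], collection,
                            ontology)
    m <- regulators_to_binding(m, collection, ontology, config)
    models[[pid]] <- m
  }
  models
}

# strip release suffixes: model URLs use core identifiers only
core_pathway_id <- function(id) sub("\\.[0-9]+$", "", id)
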