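#' Causal relation inference
#'
#' Pathway step links record that one reaction follows another; the converted
#' model must say what the connection *means*.  Each resolvable step link
#' becomes exactly one of four Relation Ontology causal relations, chosen by
#' ordered rules on entity overlap between the upstream activity's outputs
#' and the downstream activity's inputs and controllers:
#'
#' 1. an upstream output is a noncatalytic *activator* of the downstream
#'    reaction => `directly positively regulates` (RO:0002629);
#' 2. an upstream output is a noncatalytic *inhibitor* => `directly
#'    negatively regulates` (RO:0002630);
#' 3. an upstream output appears among the downstream inputs, or is the
#'    downstream catalysis controller => `directly provides input for`
#'    (RO:0002413);
#' 4. otherwise => `causally upstream of` (RO:0002411).
#'
#' Regulation outranks provides-input when both hold (the more specific
#' assertion wins).  Entity overlap is computed on location-stripped entity
#' classes - cytosolic and nuclear pools of the same molecule match - and a
#' union (entity-set) class matches if any member class matches.  Step links
#' with a filtered-out endpoint are dropped and counted, never silently
#' discarded.
#'
#' @name causal
NULL

# class-level overlap with union expansion; both args are class CURIEs/IRIs
classes_overlap <- function(a, b, ontology) {
  if (is.na(a) || is.na(b)) return(FALSE)
  expand <- function(x) {
    cls <- ontology$classes[[x]]
    if (!is.null(cls) && !is.null(cls$union_members)) {
      unique(c(x, unlist(lapply(cls$union_members, expand))))
    } else x
  }
  length(intersect(expand(a), expand(b))) > 0
}

participant_classes <- function(parts) {
  vapply(parts, `[[`, "", "class_iri")
}

#' Infer the causal relation for one step link
#'
#' @param upstream,downstream `activity_unit`s at the two ends of a recorded
#'   step link.
#' @param down_reaction The downstream [biopax_reaction()] (source of the
#'   noncatalytic-control context).
#' @param ontology An `entity_ontology` (for union expansion).
#' @return A list of class `causal_edge` with `source`, `target`, `relation`
#'   (CURIE), `basis` (one of `output_is_input`, `output_is_catalyst`,
#'   `regulation_pos`, `regulation_neg`, `step_only`) and `consumed_control`
#'   (the control id realized by a regulation edge, or `NA`).
#' @export
infer_causal_relation <- function(upstream, downstream, down_reaction,
                                  ontology) {
  rel <- gocam_relations()
  out_classes <- participant_classes(upstream$outputs)

  edge <- function(relation, basis, consumed = NA_character_) {
    structure(list(source = upstream$activity_id,
                   target = downstream$activity_id,
                   relation = relation, basis = basis,
                   consumed_control = consumed),
              class = "causal_edge")
  }

  # (1)/(2) regulation: an upstream output controls downstream noncatalytically
  noncat <- Filter(function(c) c$control_type %in% c("activation", "inhibition"),
                   down_reaction$controls)
  for (ctl in noncat) {
    ctl_cls <- unname(ontology$entity_to_class[ctl$controller])
    hit <- any(vapply(out_classes, classes_overlap, logical(1),
                      b = ctl_cls, ontology = ontology))
    if (hit) {
      if (ctl$control_type == "activation") {
        return(edge(rel$directly_positively_regulates, "regulation_pos",
                    ctl$control_id))
      }
      return(edge(rel$directly_negatively_regulates, "regulation_neg",
                  ctl$control_id))
    }
  }

  # (3) provides input: output among downstream inputs or its catalyst
  in_classes <- participant_classes(downstream$inputs)
  if (any(vapply(out_classes, function(o) {
    any(vapply(in_classes, classes_overlap, logical(1), a = o,
               ontology = ontology))
  }, logical(1)))) {
    return(edge(rel$directly_provides_input_for, "output_is_input"))
  }
  if (!is.na(downstream$enabler) &&
      any(vapply(out_classes, classes_overlap, logical(1),
                 b = downstream$enabler, ontology = ontology))) {
    return(edge(rel$directly_provides_input_for, "output_is_catalyst"))
  }

  # (4) default
  edge(rel$causally_upstream_of, "step_only")
}

#' Attach causal edges for a pathway's step links
#'
#' Every resolvable next-step pair yields exactly one causal edge; pairs with
#' a filtered-out endpoint increment the model's dropped-link count.
#'
#' @param model A `gocam_model` skeleton from [convert_pathway()].
#' @param pathway The source [biopax_pathway()].
#' @param collection The filtered [pathway_collection()].
#' @param ontology An `entity_ontology`.
#' @return The model with `causal_edges` and `n_dropped_links` populated.
#' @export
link_pathway_steps <- function(model, pathway, collection, ontology) {
  act_by_rxn <- stats::setNames(
    names(model$activities),
    vapply(model$activities, `[[`, "", "source_reaction"))
  pairs <- pathway$next_steps
  if (!nrow(pairs)) return(model)
  for (k in seq_len(nrow(pairs))) {
    u <- pairs[k, "from"]; d <- pairs[k, "to"]
    ua <- act_by_rxn[u]; da <- act_by_rxn[d]
    if (is.na(ua) || is.na(da)) {
      model$n_dropped_links <- model$n_dropped_links + 1L
      next
    }
    e <- infer_causal_relation(model$activities[[ua]],
                               model$activities[[da]],
                               collection$reactions[[d]], ontology)
    model$causal_edges[[length(model$causal_edges) + 1L]] <- e
  }
  model
}

#' Convert noncatalytic regulators to binding activity nodes
#'
#' A noncatalytic activator or inhibitor that is a free-standing entity (i.e.
#' not already realized as a regulation edge from an upstream activity whose
#' output it is) becomes a new activity node: a binding activity enabled by
#' the regulator's class, with a `directly positively regulates`
#' (activation) or `directly negatively regulates` (inhibition) edge to the
#' controlled reaction's activity.  Controls whose target reaction was
#' filtered out are a no-op.
#'
#' @param model A `gocam_model` with step edges attached.
#' @param collection The filtered [pathway_collection()].
#' @param ontology An `entity_ontology`.
#' @param config A [gocam_config()]; `binding_term` supplies the molecular
#'   function of the new nodes.
#' @return The model with binding nodes and their regulation edges appended.
#' @export
regulators_to_binding <- function(model, collection, ontology,
                                  config = gocam_config()) {
  rel <- gocam_relations()
  consumed <- stats::na.omit(vapply(model$causal_edges, `[[`, "",
                                    "consumed_control"))
  for (aid in names(model$activities)) {
    unit <- model$activities[[aid]]
    rxn <- collection$reactions[[unit$source_reaction]]
    if (is.null(rxn)) next
    noncat <- Filter(function(c)
      c$control_type %in% c("activation", "inhibition"), rxn$controls)
    for (ctl in noncat) {
      if (!is.na(ctl$control_id) && ctl$control_id %in% consumed) next
      ctl_cls <- unname(ontology$entity_to_class[ctl$controller])
      if (is.na(ctl_cls)) {
        e <- collection$entities[[ctl$controller]]
        if (!is.null(e)) ctl_cls <- class_for_entity(e, ontology, collection)$iri
      }
      bid <- mint_individual_iri(model$model_id, model$next_ordinal)
      model$next_ordinal <- model$next_ordinal + 1L
      ctl_ent <- collection$entities[[ctl$controller]]
      node <- structure(list(
        activity_id = bid,
        function_class = config$binding_term,
        enabler = ctl_cls,
        enabler_entity = ctl$controller,
        enabler_location = if (is.null(ctl_ent)) NA_character_
                           else ctl_ent$location_term,
        inputs = list(), outputs = list(),
        location = if (is.null(ctl_ent)) NA_character_
                   else ctl_ent$location_term,
        transport_from = NA_character_, transport_to = NA_character_,
        process_class = unit$process_class,
        causal_edges = list(),
        source_reaction = NA_character_,
        source_category = "regulator_binding",
        is_transport = FALSE, complex_enabler = FALSE
      ), class = "activity_unit")
      model$activities[[bid]] <- node
      relation <- if (ctl$control_type == "activation")
        rel$directly_positively_regulates else rel$directly_negatively_regulates
      model$causal_edges[[length(model$causal_edges) + 1L]] <-
        structure(list(source = bid, target = aid, relation = relation,
                       basis = "regulator_binding",
                       consumed_control = ctl$control_id),
                  class = "causal_edge")
    }
  }
  model
}
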