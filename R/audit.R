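#' Completeness audit
#'
#' A complete activity unit specifies five testable attributes: a real
#' molecular function (not the molecular-event fallback), an enabler, a
#' single location, at least one causal edge (in either direction - a
#' terminal reaction with only incoming edges is still causally connected),
#' and a specific biological process (not the root term).  Inputs and
#' outputs may legitimately be absent (shorthand black-box events), so they
#' do not enter the completeness definition.  The corpus summary reports the
#' census of missing-attribute categories (as the powerset of missing
#' attributes, so any region of a Venn-style breakdown is recoverable), the
#' causal-relation census for step links, dropped links, and the
#' binding/dissociation event counts.  Auditing never mutates models.
#'
#' @name audit
NULL

#' Audit one activity unit
#'
#' @param unit An `activity_unit`.
#' @param model The containing `gocam_model` (supplies the causal edges);
#'   optional - without it `has_causal` is computed from the unit's own
#'   `causal_edges`, which models populated by [link_pathway_steps()] leave
#'   at the model level.
#' @return A list of class `completeness_record`: the five booleans,
#'   `complete`, and `category_key` (comma-joined sorted missing attributes,
#'   `""` when complete).
#' @export
audit_activity <- function(unit, model = NULL) {
  causal_ids <- character()
  if (!is.null(model)) {
    causal_ids <- unlist(lapply(model$causal_edges,
                                function(e) c(e$source, e$target)))
  }
  has_mf <- !is.na(unit$function_class) &&
    unit$function_class != .REACTO_MOLECULAR_EVENT
  has_enabler <- !is.na(unit$enabler %||% NA)
  has_location <- !is.na(unit$location %||% NA)
  has_causal <- unit$activity_id %in% causal_ids ||
    length(unit$causal_edges) > 0
  has_specific_bp <- !is.na(unit$process_class) &&
    unit$process_class != .GO_ROOT_BP
  missing <- c(if (!has_mf) "MF", if (!has_enabler) "Enabler",
               if (!has_location) "Loc", if (!has_causal) "Causal",
               if (!has_specific_bp) "BP")
  structure(list(
    activity_id = unit$activity_id,
    source_reaction = unit$source_reaction,
    has_mf = has_mf, has_enabler = has_enabler,
    has_location = has_location, has_causal = has_causal,
    has_specific_bp = has_specific_bp,
    complete = length(missing) == 0,
    category_key = paste(sort(missing), collapse = ",")
  ), class = "completeness_record")
}

#' Audit a set of converted models
#'
#' @param models List of `gocam_model` objects (as from
#'   [convert_collection()]).
#' @return A list of class `audit_summary`: `n_reactions`, `n_complete`,
#'   `n_incomplete`, `missing_category_counts`, `n_root_bp`,
#'   `relation_counts` (step-link-derived edges by relation CURIE),
#'   `n_step_links`, `n_dropped_links`, `n_binding`, `n_dissociation`,
#'   `n_regulator_binding_nodes`, and `records` (per-activity
#'   `completeness_record`s).  `n_complete + n_incomplete = n_reactions` and
#'   `sum(relation_counts) + n_dropped_links = n_step_links` always hold.
#' @export
#' @examples
#' col <- filter_collection(parse_biopax(make_crym_fixture()), gocam_config())
#' models <- convert_collection(col)
#' audit_collection(models)$n_complete
audit_collection <- function(models) {
  records <- list()
  relation_counts <- stats::setNames(rep(0L, 4), .causal_relation_curies())
  n_dropped <- 0L
  n_binding <- 0L; n_dissociation <- 0L; n_regnodes <- 0L
  for (m in models) {
    n_dropped <- n_dropped + (m$n_dropped_links %||% 0L)
    for (e in m$causal_edges) {
      if (e$basis == "regulator_binding") next
      relation_counts[e$relation] <- relation_counts[e$relation] + 1L
    }
    for (unit in m$activities) {
      if (identical(unit$source_category, "regulator_binding")) {
        n_regnodes <- n_regnodes + 1L
        next
      }
      if (identical(unit$source_category, "binding")) {
        n_binding <- n_binding + 1L
      }
      if (identical(unit$source_category, "dissociation")) {
        n_dissociation <- n_dissociation + 1L
      }
      records[[length(records) + 1L]] <- audit_activity(unit, m)
    }
  }
  complete <- vapply(records, `[[`, logical(1), "complete")
  keys <- vapply(records, `[[`, "", "category_key")
  cat_counts <- table(keys[!complete])
  summary <- structure(list(
    n_reactions = length(records),
    n_complete = sum(complete),
    n_incomplete = sum(!complete),
    missing_category_counts = stats::setNames(as.integer(cat_counts),
                                              names(cat_counts)),
    n_root_bp = sum(!vapply(records, `[[`, logical(1), "has_specific_bp")),
    relation_counts = relation_counts,
    n_step_links = sum(relation_counts) + n_dropped,
    n_dropped_links = n_dropped,
    n_binding = n_binding,
    n_dissociation = n_dissociation,
    n_regulator_binding_nodes = n_regnodes,
    records = records
  ), class = "audit_summary")
  summary
}

#' @export
print.audit_summary <- function(x, ...) {
  rel_names <- names(gocam_relations())[1:4]
  cat("<audit_summary>\n",
      "  activity units (reactions): ", x$n_reactions, "\n",
      "  complete: ", x$n_complete, "   incomplete: ", x$n_incomplete, "\n",
      "  root-BP units: ", x$n_root_bp, "\n",
      "  binding events: ", x$n_binding,
      "   dissociation events: ", x$n_dissociation, "\n",
      "  step links: ", x$n_step_links,
      " (dropped: ", x$n_dropped_links, ")\n", sep = "")
  for (k in seq_along(x$relation_counts)) {
    cat("    ", rel_names[k], " (", names(x$relation_counts)[k], "): ",
        x$relation_counts[k], "\n", sep = "")
  }
  if (length(x$missing_category_counts)) {
    cat("  missing-attribute categories:\n")
    for (k in sort(names(x$missing_category_counts))) {
      cat("    {", k, "}: ", x$missing_category_counts[[k]], "\n", sep = "")
    }
  }
  invisible(x)
}

#' Tabulate an audit summary
#'
#' @param summary An `audit_summary`.
#' @return List of two data frames: `categories` (one row per
#'   missing-attribute category) and `activities` (one row per unit).
#' @export
audit_tables <- function(summary) {
  cats <- data.frame(
    category = names(summary$missing_category_counts) %||% character(),
    n = as.integer(summary$missing_category_counts) %||% integer(),
    stringsAsFactors = FALSE
  )
  acts <- do.call(rbind, lapply(summary$records, function(r) {
    data.frame(activity_id = r$activity_id,
               source_reaction = r$source_reaction %||% NA_character_,
               has_mf = r$has_mf, has_enabler = r$has_enabler,
               has_location = r$has_location, has_causal = r$has_causal,
               has_specific_bp = r$has_specific_bp,
               complete = r$complete, category_key = r$category_key,
               stringsAsFactors = FALSE)
  })) %||% data.frame()
  list(categories = cats, activities = acts)
}

#' Audit serialized models
#'
#' Re-audits models from their Turtle serialization.  Activity individuals
#' are recognized structurally as the subjects of part-of edges; the
#' molecular-event fallback type, enabled-by / occurs-in edges, causal edges
#' and the part-of target's type recover the five completeness booleans.
#' Dropped-link counts are read from the model header comment.
#'
#' @param paths Character vector of `.ttl` file paths (or Turtle strings).
#' @return An `audit_summary` (without per-reaction binding/dissociation
#'   counts, which are a property of the source reactions, reported as `NA`).
#' @export
audit_gocam_files <- function(paths) {
  rel <- gocam_relations()
  causal <- .causal_relation_curies()
  records <- list()
  relation_counts <- stats::setNames(rep(0L, 4), causal)
  n_dropped <- 0L; n_regnodes <- 0L
  for (p in paths) {
    doc <- read_gocam(p)
    tt <- doc$triples
    dl <- tt$o[tt$p == "rdfs:comment" &
                 grepl('^"dropped-step-links: ', tt$o)]
    if (length(dl)) {
      n_dropped <- n_dropped + as.integer(gsub('[^0-9]', '', dl[[1]]))
    }
    type_of <- stats::setNames(doc$individuals$type, doc$individuals$iri)
    act_ids <- unique(tt$s[tt$p == rel$part_of])
    edges <- tt[tt$p %in% causal, ]
    # regulator binding nodes are recognized by the marker reference on the
    # evidence annotating their edges
    ev_ref <- tt[tt$p == "dc:source", ]
    is_regnode <- function(aid) {
      # the axiom annotating this node's part_of edge carries the marker ref
      ax <- tt$s[tt$p == "owl:annotatedSource" & tt$o == aid]
      ev <- tt$o[tt$s %in% ax & tt$p == "lego:evidence"]
      refs <- ev_ref$o[ev_ref$s %in% ev]
      any(grepl("regulator-binding-node", refs))
    }
    for (aid in act_ids) {
      if (is_regnode(aid)) { n_regnodes <- n_regnodes + 1L; next }
      proc <- tt$o[tt$s == aid & tt$p == rel$part_of][1]
      rec <- structure(list(
        activity_id = aid, source_reaction = NA_character_,
        has_mf = !identical(unname(type_of[aid]), .REACTO_MOLECULAR_EVENT),
        has_enabler = any(tt$s == aid & tt$p == rel$enabled_by),
        has_location = any(tt$s == aid & tt$p == rel$occurs_in),
        has_causal = any((edges$s == aid | edges$o == aid)),
        has_specific_bp = !identical(unname(type_of[proc]), .GO_ROOT_BP),
        complete = NA, category_key = NA_character_
      ), class = "completeness_record")
      missing <- c(if (!rec$has_mf) "MF", if (!rec$has_enabler) "Enabler",
                   if (!rec$has_location) "Loc", if (!rec$has_causal) "Causal",
                   if (!rec$has_specific_bp) "BP")
      rec$complete <- length(missing) == 0
      rec$category_key <- paste(sort(missing), collapse = ",")
      records[[length(records) + 1L]] <- rec
    }
    for (k in seq_len(nrow(edges))) {
      # count step-derived edges only: skip edges out of regulator nodes
      if (is_regnode(edges$s[k]) ) next
      relation_counts[edges$p[k]] <- relation_counts[edges$p[k]] + 1L
    }
  }
  complete <- vapply(records, `[[`, logical(1), "complete")
  keys <- vapply(records, `[[`, "", "category_key")
  cat_counts <- table(keys[!complete])
  structure(list(
    n_reactions = length(records),
    n_complete = sum(complete),
    n_incomplete = sum(!complete),
    missing_category_counts = stats::setNames(as.integer(cat_counts),
                                              names(cat_counts)),
    n_root_bp = sum(!vapply(records, `[[`, logical(1), "has_specific_bp")),
    relation_counts = relation_counts,
    n_step_links = sum(relation_counts) + n_dropped,
    n_dropped_links = n_dropped,
    n_binding = NA_integer_,
    n_dissociation = NA_integer_,
    n_regulator_binding_nodes = n_regnodes,
    records = records
  ), class = "audit_summary")
}
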