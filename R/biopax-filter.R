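#' Filter a pathway collection
#'
#' Applies the corpus filters used when building the converted model set:
#' removes (a) every pathway reachable from a configured disease-branch root
#' via subpathway links, and (b) every reaction in which any participant or
#' controller is a drug.  Filtered counts are reported as a message; a
#' disease root that is not present in the document degrades to a no-op with
#' a warning.  A pathway is only removed when it is disease-flagged — losing
#' its drug reactions alone never removes a pathway.
#'
#' Step links whose endpoints disappear (e.g. the partner reaction was a drug
#' reaction, or sat in a filtered disease pathway) are *kept* on the pathway
#' record; the causal linker later counts them as dropped links rather than
#' silently discarding them.
#'
#' @param collection A [pathway_collection()].
#' @param config A [gocam_config()] naming `disease_roots` and `drug_filter`.
#' @return A new, filtered [pathway_collection()].
#' @export
#' @examples
#' col <- parse_biopax(make_crym_fixture())
#' nrow_before <- length(col$reactions)
#' col2 <- filter_collection(col, gocam_config())
#' length(col2$reactions) == nrow_before  # nothing to filter here
filter_collection <- function(collection, config = gocam_config()) {
  stopifnot(inherits(collection, "pathway_collection"))

  # disease closure over subpathway links
  roots <- intersect(config$disease_roots, names(collection$pathways))
  missing_roots <- setdiff(config$disease_roots, names(collection$pathways))
  flagged <- names(which(vapply(collection$pathways, `[[`, logical(1),
                                "is_disease")))
  roots <- union(roots, flagged)
  if (length(missing_roots) && length(collection$pathways)) {
    warning("disease root(s) not found, filter is a no-op for: ",
            paste(missing_roots, collapse = ", "), call. = FALSE)
  }
  diseased <- character()
  frontier <- roots
  while (length(frontier)) {
    diseased <- union(diseased, frontier)
    nxt <- unlist(lapply(frontier, function(p) {
      collection$pathways[[p]]$subpathways
    }))
    frontier <- setdiff(intersect(nxt, names(collection$pathways)), diseased)
  }

  # drug reactions
  drug_rxns <- character()
  if (isTRUE(config$drug_filter)) {
    for (id in names(collection$reactions)) {
      r <- collection$reactions[[id]]
      parts <- reaction_participants(r)
      expanded <- unique(c(parts, unlist(lapply(parts, function(p) {
        e <- collection$entities[[p]]
        if (is.null(e)) character() else c(e$components, e$members)
      }))))
      has_drug <- any(vapply(expanded, function(p) {
        e <- collection$entities[[p]]
        !is.null(e) && isTRUE(e$is_drug)
      }, logical(1)))
      if (has_drug) drug_rxns <- c(drug_rxns, id)
    }
  }

  keep_pathways <- setdiff(names(collection$pathways), diseased)
  # reactions reachable only from diseased pathways also leave the corpus
  retained_refs <- unique(unlist(lapply(keep_pathways, function(p) {
    collection$pathways[[p]]$step_reactions
  })))
  orphan_ok <- setdiff(names(collection$reactions),
                       unique(unlist(lapply(names(collection$pathways),
                                            function(p) collection$pathways[[p]]$step_reactions))))
  keep_rxns <- setdiff(union(retained_refs, orphan_ok), drug_rxns)
  keep_rxns <- intersect(names(collection$reactions), keep_rxns)

  new_pathways <- lapply(keep_pathways, function(pid) {
    p <- collection$pathways[[pid]]
    p$step_reactions <- intersect(p$step_reactions, keep_rxns)
    p$subpathways <- setdiff(p$subpathways, diseased)
    p
  })

  new_reactions <- collection$reactions[keep_rxns]

  message(sprintf(
    "filter_collection: removed %d disease pathway(s), %d drug reaction(s); retained %d pathway(s), %d reaction(s)",
    length(intersect(diseased, names(collection$pathways))),
    length(drug_rxns), length(new_pathways), length(new_reactions)))

  pathway_collection(
    pathways = new_pathways,
    reactions = unname(new_reactions),
    entities = unname(collection$entities),
    source_version = collection$source_version,
    unresolved = collection$unresolved
  )
}
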