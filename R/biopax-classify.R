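#' Classify a reaction by shape
#'
#' Assigns exactly one category to a reaction by ordered rules:
#'
#' 1. any catalysis control present => `catalyzed`; additionally flagged as
#'    transport when an input and an output share a reference cross-reference
#'    but differ in location (catalyzed transporters keep the `catalyzed`
#'    category so the molecular function and enabler are still extracted,
#'    while start/end locations remain recoverable);
#' 2. no catalysis and no inputs or no outputs => `black_box` (shorthand
#'    events such as "gene transcription");
#' 3. no catalysis, more inputs than outputs and a complex among the
#'    outputs => `binding`;
#' 4. no catalysis, more outputs than inputs and a complex among the
#'    inputs => `dissociation`;
#' 5. no catalysis, equal counts but differing participant locations =>
#'    `transport`;
#' 6. otherwise `other`.
#'
#' The function is total and deterministic.
#'
#' @param reaction A [biopax_reaction()].
#' @param collection The [pathway_collection()] the reaction's participants
#'   resolve in.
#' @return A single string, one of `"catalyzed"`, `"transport"`, `"binding"`,
#'   `"dissociation"`, `"black_box"`, `"other"`; the transport flag for
#'   catalyzed transporters is available via [classify_collection()].
#' @export
#' @examples
#' col <- parse_biopax(make_crym_fixture())
#' classify_reaction(col$reactions[["R-HSA-5693347"]], col)
classify_reaction <- function(reaction, collection) {
  classify_reaction_full(reaction, collection)$category
}

classify_reaction_full <- function(reaction, collection) {
  ctypes <- vapply(reaction$controls, `[[`, "", "control_type")
  has_cat <- any(ctypes == "catalysis")
  n_in <- length(reaction$inputs)
  n_out <- length(reaction$outputs)
  get_e <- function(id) collection$entities[[id]]
  is_complex <- function(ids) {
    any(vapply(ids, function(i) {
      e <- get_e(i); !is.null(e) && e$kind == "complex"
    }, logical(1)))
  }
  locs <- function(ids) {
    vapply(ids, function(i) {
      e <- get_e(i); if (is.null(e)) NA_character_ else e$location_term
    }, character(1))
  }
  transport_shaped <- function() {
    # an input and output share a reference xref but differ in location
    for (i in reaction$inputs) {
      ei <- get_e(i); if (is.null(ei)) next
      for (o in reaction$outputs) {
        eo <- get_e(o); if (is.null(eo)) next
        shared <- length(intersect(ei$reference_xrefs, eo$reference_xrefs)) > 0
        differ <- !identical(ei$location_term, eo$location_term)
        if (shared && differ) return(TRUE)
      }
    }
    FALSE
  }

  if (has_cat) {
    return(list(category = "catalyzed", is_transport = transport_shaped()))
  }
  if (n_in == 0 || n_out == 0) {
    return(list(category = "black_box", is_transport = FALSE))
  }
  if (n_in > n_out && is_complex(reaction$outputs)) {
    return(list(category = "binding", is_transport = FALSE))
  }
  if (n_out > n_in && is_complex(reaction$inputs)) {
    return(list(category = "dissociation", is_transport = FALSE))
  }
  if (n_in == n_out) {
    all_locs <- c(locs(reaction$inputs), locs(reaction$outputs))
    if (length(unique(all_locs[!is.na(all_locs)])) > 1) {
      return(list(category = "transport", is_transport = TRUE))
    }
  }
  list(category = "other", is_transport = FALSE)
}

#' Classify every reaction in a collection
#'
#' @param collection A [pathway_collection()].
#' @return The collection with `category` and `is_transport` set on every
#'   reaction.
#' @export
classify_collection <- function(collection) {
  for (id in names(collection$reactions)) {
    cf <- classify_reaction_full(collection$reactions[[id]], collection)
    collection$reactions[[id]]$category <- cf$category
    collection$reactions[[id]]$is_transport <- cf$is_transport
  }
  collection
}
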