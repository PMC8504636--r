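#' GO-CAM OWL instance graphs in Turtle
#'
#' A serialized model is an OWL instance graph: nodes are OWL individuals
#' typed with exactly one ontology class, edges are object properties from
#' the closed relation vocabulary, and every asserted edge carries an
#' evidence annotation (OWL axiom-annotation reification) with the
#' configured ECO class and the source reaction's stable identifier as
#' reference.  Serialization is deterministic: individual IRIs are minted
#' from the model IRI plus a strictly increasing ordinal, and triples are
#' emitted in lexicographic order, so identical inputs give byte-identical
#' Turtle.  No blank nodes are used, which makes the write-read round trip an
#' exact graph (triple-set) equality.
#'
#' @name gocam_io
NULL

#' Mint a deterministic individual IRI
#'
#' @param model_id Model IRI.
#' @param ordinal Strictly increasing integer within the model.
#' @return `model_id "/" zero-padded-ordinal`.
#' @export
#' @examples
#' mint_individual_iri("http://model.geneontology.org/R-HSA-71064", 1)
mint_individual_iri <- function(model_id, ordinal) {
  stopifnot(is.numeric(ordinal), ordinal >= 1)
  paste0(model_id, "/", sprintf("%06d", as.integer(ordinal)))
}

# ---- triple store helpers ----------------------------------------------

new_triples <- function() {
  env <- new.env(parent = emptyenv())
  env$s <- character(); env$p <- character(); env$o <- character()
  env
}
add_triple <- function(tr, s, p, o) {
  n <- length(tr$s) + 1L
  tr$s[n] <- s; tr$p[n] <- p; tr$o[n] <- o
  invisible(tr)
}
triples_df <- function(tr) {
  data.frame(s = tr$s, p = tr$p, o = tr$o, stringsAsFactors = FALSE)
}

# term rendering: IRIs in <>, CURIEs bare, literals quoted
term_render <- function(x) {
  if (grepl("^https?://", x)) paste0("<", x, ">") else x
}
lit <- function(x) {
  paste0('"', gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x)), '"')
}
is_literal <- function(x) startsWith(x, '"')

render_turtle <- function(df) {
  header <- paste0("@prefix ", names(.gocamr_prefixes), ": <",
                   unname(.gocamr_prefixes), "> .")
  header <- sort(header)
  lines <- paste(term_render_v(df$s), term_render_v(df$p),
                 vapply(df$o, function(o) {
                   if (is_literal(o)) o else term_render(o)
                 }, character(1)), ".")
  lines <- sort(unique(lines))
  paste0(paste(c(header, "", lines), collapse = "\n"), "\n")
}
term_render_v <- function(x) vapply(x, term_render, character(1))

#' Serialize a model as Turtle
#'
#' Emits model metadata (typed `owl:Ontology`, title, state, provenance
#' comment naming the source version and the verbatim run configuration),
#' one typed individual per activity, enabler, participant, location and
#' process, the structural and causal edges, and one evidence-annotated
#' `owl:Axiom` per asserted edge.
#'
#' @param model A `gocam_model` with causal edges attached.
#' @param ontology The `entity_ontology` (unused for emission but validates
#'   that typed classes exist).
#' @param config A [gocam_config()]; supplies the ECO evidence class.
#' @param path Optional output file.
#' @return Turtle document as a single string (invisibly when `path` given).
#' @export
write_gocam <- function(model, ontology = NULL, config = NULL, path = NULL) {
  config <- config %||% model$config %||% gocam_config()
  rel <- gocam_relations()
  tr <- new_triples()
  ordinal <- model$next_ordinal %||% (length(model$activities) + 1L)
  mint <- function() {
    iri <- mint_individual_iri(model$model_id, ordinal)
    ordinal <<- ordinal + 1L
    iri
  }

  # --- model metadata ---------------------------------------------------
  add_triple(tr, model$model_id, "rdf:type", "owl:Ontology")
  add_triple(tr, model$model_id, "dc:title", lit(model$title))
  add_triple(tr, model$model_id, "lego:modelstate", lit("automated"))
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               null = "null")
  add_triple(tr, model$model_id, "rdfs:comment",
             lit(paste0("source: ", model$provenance)))
  add_triple(tr, model$model_id, "rdfs:comment",
             lit(paste0("config: ", cfg_json)))
  add_triple(tr, model$model_id, "rdfs:comment",
             lit(paste0("dropped-step-links: ", model$n_dropped_links %||% 0L)))

  typed <- character()  # iri -> class, to enforce one type per individual
  type_individual <- function(iri, class_iri) {
    if (!is.null(ontology) && startsWith(class_iri, "REACTO:") &&
        is.null(ontology$classes[[class_iri]])) {
      stop("class ", class_iri, " not present in the entity ontology")
    }
    if (!is.na(typed[iri] %||% NA) && !is.na(typed[iri])) return(invisible())
    typed[iri] <<- class_iri
    add_triple(tr, iri, "rdf:type", class_iri)
    add_triple(tr, iri, "rdf:type", "owl:NamedIndividual")
  }

  evid <- function(s, p, o, ref) {
    ax <- mint(); ev <- mint()
    add_triple(tr, ax, "rdf:type", "owl:Axiom")
    add_triple(tr, ax, "owl:annotatedSource", s)
    add_triple(tr, ax, "owl:annotatedProperty", p)
    add_triple(tr, ax, "owl:annotatedTarget", o)
    add_triple(tr, ax, "lego:evidence", ev)
    add_triple(tr, ev, "rdf:type", config$eco_class)
    add_triple(tr, ev, "rdf:type", "owl:NamedIndividual")
    add_triple(tr, ev, "dc:source", lit(ref %||% "automated-conversion"))
  }
  edge <- function(s, p, o, ref) {
    add_triple(tr, s, p, o)
    evid(s, p, o, ref)
  }

  # one process individual per distinct process class in the model
  proc_ind <- character()
  process_individual <- function(class_iri) {
    hit <- proc_ind[class_iri]
    if (!is.na(hit)) return(unname(hit))
    iri <- mint()
    proc_ind[class_iri] <<- iri
    type_individual(iri, class_iri)
    iri
  }
  loc_individual <- function(class_iri) {
    iri <- mint()
    type_individual(iri, class_iri)
    iri
  }

  for (aid in names(model$activities)) {
    a <- model$activities[[aid]]
    ref <- a$source_reaction
    if (is.na(ref %||% NA)) ref <- "regulator-binding-node"
    type_individual(aid, a$function_class)
    # process
    pind <- process_individual(a$process_class)
    edge(aid, rel$part_of, pind, ref)
    # enabler
    if (!is.na(a$enabler %||% NA)) {
      eind <- mint()
      type_individual(eind, a$enabler)
      edge(aid, rel$enabled_by, eind, ref)
      if (is.na(a$location %||% NA) && !is.na(a$enabler_location %||% NA)) {
        lind <- loc_individual(a$enabler_location)
        edge(eind, rel$located_in, lind, ref)
      }
    }
    # participants
    for (side in c("inputs", "outputs")) {
      p_rel <- if (side == "inputs") rel$has_input else rel$has_output
      for (prt in a[[side]]) {
        pind2 <- mint()
        type_individual(pind2, prt$class_iri)
        edge(aid, p_rel, pind2, ref)
        if (!is.na(prt$location %||% NA)) {
          lind <- loc_individual(prt$location)
          edge(pind2, rel$located_in, lind, ref)
        }
      }
    }
    # single location
    if (!is.na(a$location %||% NA)) {
      lind <- loc_individual(a$location)
      edge(aid, rel$occurs_in, lind, ref)
    }
    # transport start/end
    if (!is.na(a$transport_from %||% NA)) {
      lind <- loc_individual(a$transport_from)
      edge(aid, rel$has_start_location, lind, ref)
    }
    if (!is.na(a$transport_to %||% NA)) {
      lind <- loc_individual(a$transport_to)
      edge(aid, rel$has_end_location, lind, ref)
    }
  }

  # subpathway process nodes (a pathway of only subpathways keeps a single
  # node per subpathway; no outgoing part-of, so they are not activities)
  for (sp in model$subpathway_nodes) {
    iri <- mint()
    type_individual(iri, sp$process_class)
    add_triple(tr, iri, "rdfs:comment", lit(paste0("subpathway: ",
                                                   sp$pathway_id)))
  }
  # a pathway with no activities at all is represented by its own single node
  if (length(model$activities) == 0 && length(model$subpathway_nodes) == 0) {
    iri <- mint()
    type_individual(iri, model$process_class)
  }

  # causal edges
  for (e in model$causal_edges) {
    src_rxn <- model$activities[[e$source]]$source_reaction
    edge(e$source, e$relation, e$target,
         if (is.na(src_rxn %||% NA)) "regulator-binding-node" else src_rxn)
  }

  doc <- render_turtle(triples_df(tr))
  if (!is.null(path)) {
    writeLines(doc, path, sep = "")
    return(invisible(doc))
  }
  doc
}

#' Read a Turtle GO-CAM document
#'
#' Reads the line-oriented Turtle this package emits (one triple per line,
#' no blank nodes) back into a triple table with typed-individual and edge
#' accessors.  The result is graph-isomorphic to what [write_gocam()]
#' serialized; re-rendering it reproduces the input bytes.
#'
#' @param input Path to a `.ttl` file or a Turtle string.
#' @return A list of class `gocam_document` with `triples` (s/p/o data
#'   frame), `individuals` (iri/type data frame), `edges` (object-property
#'   triples between individuals) and `model_id`.
#' @export
read_gocam <- function(input) {
  lines <- if (length(input) == 1 && grepl("\n", input)) {
    strsplit(input, "\n", fixed = TRUE)[[1]]
  } else if (length(input) == 1 && file.exists(input)) {
    readLines(input)
  } else as.character(input)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "@prefix")]

  parse_line <- function(ln) {
    ln <- trimws(ln)
    if (!endsWith(ln, " .")) stop("malformed Turtle line: ", ln)
    ln <- substr(ln, 1, nchar(ln) - 2)
    m <- regexec("^(\\S+)\\s+(\\S+)\\s+(.*)$", ln)
    parts <- regmatches(ln, m)[[1]]
    if (length(parts) != 4) stop("malformed Turtle line: ", ln)
    c(s = strip_angle(parts[2]), p = strip_angle(parts[3]),
      o = if (startsWith(parts[4], '"')) parts[4] else strip_angle(parts[4]))
  }
  parsed <- t(vapply(lines, parse_line, character(3)))
  df <- data.frame(s = unname(parsed[, "s"]), p = unname(parsed[, "p"]),
                   o = unname(parsed[, "o"]), stringsAsFactors = FALSE)

  model_id <- df$s[df$p == "rdf:type" & df$o == "owl:Ontology"]
  types <- df[df$p == "rdf:type" & df$o != "owl:NamedIndividual" &
                df$o != "owl:Axiom" & df$o != "owl:Ontology", ]
  vocab <- unlist(gocam_relations(), use.names = FALSE)
  edges <- df[df$p %in% vocab, ]
  structure(list(triples = df,
                 individuals = data.frame(iri = types$s, type = types$o,
                                          stringsAsFactors = FALSE),
                 edges = edges,
                 model_id = if (length(model_id)) model_id[[1]] else NA),
            class = "gocam_document")
}

strip_angle <- function(x) sub("^<(.*)>$", "\\1", x)

#' Re-serialize a parsed GO-CAM document
#'
#' Renders a [read_gocam()] result with the same deterministic prefix block
#' and triple ordering as [write_gocam()]; write -> read -> write is a fixed
#' point.
#'
#' @param doc A `gocam_document`.
#' @param path Optional output file.
#' @return Turtle string.
#' @export
write_gocam_document <- function(doc, path = NULL) {
  out <- render_turtle(doc$triples)
  if (!is.null(path)) {
    writeLines(out, path, sep = "")
    return(invisible(out))
  }
  out
}

#' Serialize the entity ontology as Turtle
#'
#' Classes are emitted with labels, superclass links, cross-references and
#' definitions; entity-set classes get a proper `owl:unionOf` RDF list
#' (with deterministically minted list-node IRIs rather than blank nodes, so
#' output is byte-stable and round-trippable), and complexes carry has-part
#' links to their component classes.
#'
#' @param ontology An `entity_ontology`.
#' @param path Optional output file.
#' @return Turtle string.
#' @export
write_entity_ontology <- function(ontology, path = NULL) {
  tr <- new_triples()
  onto_iri <- paste0(.gocamr_prefixes[["REACTO"]], "ontology")
  add_triple(tr, onto_iri, "rdf:type", "owl:Ontology")
  add_triple(tr, onto_iri, "rdfs:comment",
             lit(paste0("generated entity ontology; source: ",
                        ontology$provenance)))
  for (iri in names(ontology$classes)) {
    cls <- ontology$classes[[iri]]
    add_triple(tr, iri, "rdf:type", "owl:Class")
    add_triple(tr, iri, "rdfs:label", lit(cls$label))
    for (sup in cls$superclasses) add_triple(tr, iri, "rdfs:subClassOf", sup)
    for (x in cls$xrefs) {
      add_triple(tr, iri, "oboInOwl:hasDbXref", lit(x))
    }
    if (nzchar(cls$definition %||% "")) {
      add_triple(tr, iri, "rdfs:comment", lit(cls$definition))
    }
    for (cm in cls$component_links) {
      add_triple(tr, iri, gocam_relations()$has_part, cm)
    }
    if (!is.null(cls$union_members)) {
      un <- paste0(iri, "_union")
      add_triple(tr, iri, "owl:equivalentClass", un)
      add_triple(tr, un, "rdf:type", "owl:Class")
      node <- paste0(un, "_l1")
      add_triple(tr, un, "owl:unionOf", node)
      for (k in seq_along(cls$union_members)) {
        add_triple(tr, node, "rdf:first", cls$union_members[[k]])
        nxt <- if (k == length(cls$union_members)) "rdf:nil"
               else paste0(un, "_l", k + 1)
        add_triple(tr, node, "rdf:rest", nxt)
        node <- nxt
      }
    }
  }
  doc <- render_turtle(triples_df(tr))
  if (!is.null(path)) {
    writeLines(doc, path, sep = "")
    return(invisible(doc))
  }
  doc
}
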