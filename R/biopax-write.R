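#' Serialize a pathway collection as BioPAX Level-3 RDF/XML
#'
#' Inverse of [parse_biopax()] for the subset of BioPAX this package models.
#' Output is deterministic: elements are emitted in sorted identifier order
#' and helper elements (xrefs, references, location vocabularies, features,
#' controls, pathway steps) get identifiers derived from their owners, so the
#' same collection always yields the same bytes.  Used by the fixture
#' generator and by round-trip tests; re-parsing the output yields a
#' collection isomorphic to the input.
#'
#' @param collection A [pathway_collection()].
#' @param path Optional file path; when given the document is written there.
#' @return The document as a single character string (invisibly when `path`
#'   is given).
#' @export
write_biopax <- function(collection, path = NULL) {
  esc <- xml_escape
  out <- character()
  emit <- function(...) out[[length(out) + 1L]] <<- paste0(...)

  emit('<?xml version="1.0" encoding="UTF-8"?>')
  emit('<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
       ' xmlns:owl="http://www.w3.org/2002/07/owl#"',
       ' xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"',
       ' xmlns:bp="http://www.biopax.org/release/biopax-level3.owl#"',
       ' xml:base="http://gocamr.test/biopax#">')
  emit('<owl:Ontology rdf:about="">')
  emit('  <owl:imports rdf:resource="http://www.biopax.org/release/biopax-level3.owl#"/>')
  emit('  <rdfs:comment>', esc(collection$source_version), '</rdfs:comment>')
  emit('</owl:Ontology>')

  # helper registries, deduplicated by content, ids derived from content
  xref_nodes <- new.env(parent = emptyenv())
  loc_nodes <- new.env(parent = emptyenv())

  xref_id <- function(curie, class = "UnificationXref") {
    key <- paste0(class, "|", curie)
    if (is.null(get0(key, envir = xref_nodes))) {
      assign(key, TRUE, envir = xref_nodes)
    }
    paste0(tolower(substr(class, 1, 1)), "x_", sanitize_id(curie))
  }
  register_loc <- function(term, label) {
    label <- label %||% NA_character_
    key <- paste0(term, "|", ifelse(is.na(label), "", label))
    assign(key, c(term = term, label = label), envir = loc_nodes)
    paste0("loc_", sanitize_id(key))
  }

  split_curie <- function(curie) {
    p <- strsplit(curie, ":", fixed = TRUE)[[1]]
    db <- switch(p[1],
                 UniProt = "UniProt", CHEBI = "ChEBI", GO = "GENE ONTOLOGY",
                 Reactome = "Reactome", ECO = "ECO", p[1])
    id <- paste(p[-1], collapse = ":")
    if (db == "ChEBI") id <- paste0("CHEBI:", id)
    if (db == "GENE ONTOLOGY") id <- paste0("GO:", id)
    c(db = db, id = id)
  }

  # ---- entities (sorted by id) ----------------------------------------
  ent_class <- c(protein = "Protein", small_molecule = "SmallMolecule",
                 complex = "Complex", entity_set = "PhysicalEntity",
                 nucleic_acid = "Dna", other = "PhysicalEntity")
  ref_class <- c(protein = "ProteinReference",
                 small_molecule = "SmallMoleculeReference",
                 nucleic_acid = "DnaReference")
  mod_blocks <- character()

  for (id in sort(names(collection$entities))) {
    e <- collection$entities[[id]]
    cls <- if (e$kind == "entity_set") {
      # sets keep their member class family when homogeneous; generic otherwise
      "PhysicalEntity"
    } else ent_class[[e$kind]]
    emit('<bp:', cls, ' rdf:ID="', esc(id), '">')
    emit('  <bp:displayName>', esc(e$display_name), '</bp:displayName>')
    # entity reference (UniProt/ChEBI) vs direct xrefs (Reactome, drug vocab)
    er_xrefs <- e$reference_xrefs[grepl("^(UniProt|CHEBI):", e$reference_xrefs)]
    other_xrefs <- setdiff(e$reference_xrefs, er_xrefs)
    if (length(er_xrefs) && e$kind %in% names(ref_class)) {
      emit('  <bp:entityReference rdf:resource="#', esc(id), '_er"/>')
    } else {
      other_xrefs <- e$reference_xrefs
      er_xrefs <- character()
    }
    for (x in other_xrefs) {
      emit('  <bp:xref rdf:resource="#', xref_id(x), '"/>')
    }
    if (!is.na(e$location_term) || !is.na(e$location_label %||% NA)) {
      lid <- register_loc(e$location_term, e$location_label)
      emit('  <bp:cellularLocation rdf:resource="#', lid, '"/>')
    }
    for (m in e$members) {
      emit('  <bp:memberPhysicalEntity rdf:resource="#', esc(m), '"/>')
    }
    for (cmp in e$components) {
      emit('  <bp:component rdf:resource="#', esc(cmp), '"/>')
    }
    if (length(e$modifications)) {
      for (k in seq_along(e$modifications)) {
        emit('  <bp:feature rdf:resource="#', esc(id), '_mod', k, '"/>')
      }
    }
    emit('</bp:', cls, '>')

    if (length(er_xrefs)) {
      emit('<bp:', ref_class[[e$kind]], ' rdf:ID="', esc(id), '_er">')
      for (x in er_xrefs) emit('  <bp:xref rdf:resource="#', xref_id(x), '"/>')
      emit('</bp:', ref_class[[e$kind]], '>')
    }
    for (k in seq_along(e$modifications)) {
      m <- e$modifications[[k]]
      term <- sub("@.*$", "", m)
      pos <- if (grepl("@", m)) sub("^.*@", "", m) else NA
      b <- c(paste0('<bp:ModificationFeature rdf:ID="', esc(id), '_mod', k, '">'),
             paste0('  <bp:modificationType rdf:resource="#', esc(id),
                    '_mod', k, 'v"/>'))
      if (!is.na(pos)) {
        b <- c(b, paste0('  <bp:featureLocation rdf:resource="#', esc(id),
                         '_mod', k, 's"/>'))
      }
      b <- c(b, '</bp:ModificationFeature>',
             paste0('<bp:SequenceModificationVocabulary rdf:ID="', esc(id),
                    '_mod', k, 'v">'),
             paste0('  <bp:term>', esc(term), '</bp:term>'),
             '</bp:SequenceModificationVocabulary>')
      if (!is.na(pos)) {
        b <- c(b, paste0('<bp:SequenceSite rdf:ID="', esc(id), '_mod', k, 's">'),
               paste0('  <bp:sequencePosition>', esc(pos),
                      '</bp:sequencePosition>'),
               '</bp:SequenceSite>')
      }
      mod_blocks <- c(mod_blocks, b)
    }
  }
  out <- c(out, mod_blocks)
  emit <- function(...) out[[length(out) + 1L]] <<- paste0(...)

  # ---- reactions + controls -------------------------------------------
  for (id in sort(names(collection$reactions))) {
    r <- collection$reactions[[id]]
    emit('<bp:BiochemicalReaction rdf:ID="', esc(id), '">')
    emit('  <bp:displayName>', esc(r$display_name), '</bp:displayName>')
    for (i in r$inputs) emit('  <bp:left rdf:resource="#', esc(i), '"/>')
    for (o in r$outputs) emit('  <bp:right rdf:resource="#', esc(o), '"/>')
    for (x in r$mf_xrefs) {
      emit('  <bp:xref rdf:resource="#', xref_id(x, "RelationshipXref"), '"/>')
    }
    emit('</bp:BiochemicalReaction>')
    for (k in seq_along(r$controls)) {
      ctl <- r$controls[[k]]
      cls <- if (ctl$control_type == "catalysis") "Catalysis" else "Control"
      ctype <- switch(ctl$control_type, catalysis = "ACTIVATION",
                      activation = "ACTIVATION", inhibition = "INHIBITION")
      emit('<bp:', cls, ' rdf:ID="', esc(id), '_ctl', k, '">')
      emit('  <bp:controller rdf:resource="#', esc(ctl$controller), '"/>')
      emit('  <bp:controlled rdf:resource="#', esc(id), '"/>')
      emit('  <bp:controlType>', ctype, '</bp:controlType>')
      emit('</bp:', cls, '>')
    }
  }

  # ---- pathways + steps ------------------------------------------------
  for (id in sort(names(collection$pathways))) {
    p <- collection$pathways[[id]]
    emit('<bp:Pathway rdf:ID="', esc(id), '">')
    emit('  <bp:displayName>', esc(p$display_name), '</bp:displayName>')
    for (s in p$step_reactions) {
      emit('  <bp:pathwayComponent rdf:resource="#', esc(s), '"/>')
    }
    for (s in p$subpathways) {
      emit('  <bp:pathwayComponent rdf:resource="#', esc(s), '"/>')
    }
    for (x in p$bp_xrefs) {
      emit('  <bp:xref rdf:resource="#', xref_id(x, "RelationshipXref"), '"/>')
    }
    # one step per reaction participating in any link + isolated steps
    step_rxns <- unique(c(p$step_reactions, as.vector(p$next_steps)))
    for (s in step_rxns) {
      emit('  <bp:pathwayOrder rdf:resource="#', esc(id), '_step_',
           sanitize_id(s), '"/>')
    }
    emit('</bp:Pathway>')
    for (s in step_rxns) {
      emit('<bp:PathwayStep rdf:ID="', esc(id), '_step_', sanitize_id(s), '">')
      emit('  <bp:stepProcess rdf:resource="#', esc(s), '"/>')
      if (nrow(p$next_steps)) {
        downs <- p$next_steps[p$next_steps[, "from"] == s, "to"]
        for (d in downs) {
          emit('  <bp:nextStep rdf:resource="#', esc(id), '_step_',
               sanitize_id(d), '"/>')
        }
      }
      emit('</bp:PathwayStep>')
    }
  }

  # ---- shared helper nodes --------------------------------------------
  for (key in sort(ls(xref_nodes))) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    cls <- parts[1]; curie <- parts[2]
    dbid <- split_curie(curie)
    emit('<bp:', cls, ' rdf:ID="', tolower(substr(cls, 1, 1)), 'x_',
         sanitize_id(curie), '">')
    emit('  <bp:db>', esc(dbid[["db"]]), '</bp:db>')
    emit('  <bp:id>', esc(dbid[["id"]]), '</bp:id>')
    emit('</bp:', cls, '>')
  }
  for (key in sort(ls(loc_nodes))) {
    v <- get(key, envir = loc_nodes)
    lid <- paste0("loc_", sanitize_id(key))
    emit('<bp:CellularLocationVocabulary rdf:ID="', lid, '">')
    if (!is.na(v[["label"]])) {
      emit('  <bp:term>', esc(v[["label"]]), '</bp:term>')
    }
    if (!is.na(v[["term"]])) {
      emit('  <bp:xref rdf:resource="#ux_', sanitize_id(v[["term"]]), '"/>')
      # ensure the GO xref node exists even if no entity used it directly
      dbid <- split_curie(v[["term"]])
      emit('</bp:CellularLocationVocabulary>')
      emit('<bp:UnificationXref rdf:ID="ux_', sanitize_id(v[["term"]]), '">')
      emit('  <bp:db>', esc(dbid[["db"]]), '</bp:db>')
      emit('  <bp:id>', esc(dbid[["id"]]), '</bp:id>')
      emit('</bp:UnificationXref>')
    } else {
      emit('</bp:CellularLocationVocabulary>')
    }
  }

  emit('</rdf:RDF>')
  doc <- paste0(paste(out, collapse = "\n"), "\n")
  # location GO xref nodes can repeat when several labels share a term
  doc <- dedupe_xml_nodes(doc)
  if (!is.null(path)) {
    writeLines(doc, path, sep = "")
    return(invisible(doc))
  }
  doc
}

sanitize_id <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

# Drop exact duplicate top-level element blocks (same rdf:ID emitted twice).
dedupe_xml_nodes <- function(doc) {
  lines <- strsplit(doc, "\n", fixed = TRUE)[[1]]
  seen <- character(); keep <- logical(length(lines)); keep[] <- TRUE
  i <- 1L
  while (i <= length(lines)) {
    m <- regmatches(lines[i], regexpr('rdf:ID="[^"]+"', lines[i]))
    if (length(m) == 1 && grepl("^<bp:", lines[i])) {
      # find end of the block
      tag <- sub("^<(bp:[A-Za-z]+).*$", "\\1", lines[i])
      j <- i
      while (j <= length(lines) && !grepl(paste0("^</", tag, ">$"), lines[j])) {
        j <- j + 1L
      }
      if (m %in% seen) keep[i:j] <- FALSE else seen <- c(seen, m)
      i <- j + 1L
    } else i <- i + 1L
  }
  paste0(paste(lines[keep], collapse = "\n"), "\n")
}
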