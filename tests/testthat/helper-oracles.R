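# Shared fixtures and independent oracles for the suite.

# standard synthetic study corpus used by several test files
std_corpus <- function(seed = 101, ...) {
  make_random_pathway_corpus(fixture_spec(seed = seed, ...))
}

std_config <- function(...) {
  gocam_config(disease_roots = "P-TST-DISEASE-ROOT", ...)
}

# run the full pipeline on a fixture, quietly
run_pipeline <- function(fx_or_doc, config = std_config()) {
  doc <- if (is.list(fx_or_doc)) fx_or_doc$document else fx_or_doc
  col <- parse_biopax(doc)
  col <- suppressMessages(suppressWarnings(filter_collection(col, config)))
  col <- classify_collection(col)
  onto <- build_entity_ontology(col)
  models <- suppressWarnings(convert_collection(col, onto, config))
  list(collection = col, ontology = onto, models = models,
       summary = audit_collection(models))
}

# Independently coded classification truth table: a direct restatement of
# the category definitions, kept free of the package's rule ordering code.
oracle_classify <- function(has_catalysis, n_in, n_out,
                            complex_in, complex_out, locations_differ) {
  if (has_catalysis) return("catalyzed")
  if (n_in == 0 || n_out == 0) return("black_box")
  if (n_in > n_out && complex_out) return("binding")
  if (n_out > n_in && complex_in) return("dissociation")
  if (n_in == n_out && locations_differ) return("transport")
  "other"
}

# Build a one-reaction collection realizing a truth-table grid point.
# Participants carry distinct reference xrefs so the catalyzed-transport
# flag never fires; complexes (if requested) sit in slot 1 of their side.
grid_collection <- function(has_catalysis, n_in, n_out,
                            complex_in, complex_out, locations_differ) {
  locs <- c("GO:0005829", "GO:0005634")
  ents <- list()
  ctr <- 0
  mk <- function(kind = "small_molecule", loc = locs[1],
                 components = character()) {
    ctr <<- ctr + 1
    id <- sprintf("E%02d", ctr)
    ents[[length(ents) + 1]] <<- physical_entity(
      id, id, kind = kind, reference_xrefs = sprintf("CHEBI:99%04d", ctr),
      location_term = loc, location_label = "x", components = components)
    id
  }
  mk_part <- function(k, is_complex, loc) {
    if (k == 1 && is_complex) {
      mk(kind = "complex", loc = loc, components = c(mk(), mk()))
    } else mk(loc = loc)
  }
  ins <- if (n_in > 0) vapply(seq_len(n_in), function(k) {
    mk_part(k, complex_in, if (locations_differ && k == 1) locs[2]
                           else locs[1])
  }, "") else character()
  outs <- if (n_out > 0) vapply(seq_len(n_out), function(k) {
    mk_part(k, complex_out, locs[1])
  }, "") else character()
  r <- biopax_reaction("RX", "RX", inputs = ins, outputs = outs)
  if (has_catalysis) {
    r$controls <- list(biopax_control(mk(kind = "protein"), "RX",
                                      "catalysis", "c1"))
  }
  pathway_collection(pathways = list(), reactions = list(r),
                     entities = ents, source_version = "grid")
}

# Brute-force expected audit facts recomputed from a fixture ledger
# (independent of the conversion code paths).
ledger_expectations <- function(ledger, drug_filter = TRUE) {
  rx <- ledger$reactions
  pw <- ledger$pathways
  disease_pw <- pw$id[pw$is_disease]
  rx$retained <- !(rx$pathway %in% disease_pw) &
    !(drug_filter & rx$is_drug)
  lk <- ledger$links
  lk <- lk[!(lk$pathway %in% disease_pw), , drop = FALSE]
  retained_ids <- rx$id[rx$retained]
  lk$kept <- lk$from %in% retained_ids & lk$to %in% retained_ids

  has_bp <- stats::setNames(pw$has_bp, pw$id)
  standalone <- ledger$controls[ledger$controls$standalone, , drop = FALSE]

  causal_ids <- unique(c(lk$from[lk$kept], lk$to[lk$kept],
                         intersect(standalone$reaction, retained_ids)))
  rx$exp_complete <- rx$retained & rx$has_mf & rx$has_catalysis &
    rx$uniform_loc & unname(has_bp[rx$pathway]) & (rx$id %in% causal_ids)

  rel_counts <- table(factor(lk$relation[lk$kept],
                             levels = c("RO:0002411", "RO:0002413",
                                        "RO:0002629", "RO:0002630")))
  list(
    reactions = rx,
    n_retained = sum(rx$retained),
    n_complete = sum(rx$exp_complete),
    relation_counts = as.integer(rel_counts),
    relation_names = names(rel_counts),
    n_dropped = sum(!lk$kept),
    n_step_links = nrow(lk),
    n_binding = sum(rx$retained & rx$category == "binding"),
    n_dissociation = sum(rx$retained & rx$category == "dissociation"),
    n_regulator_nodes = sum(standalone$reaction %in% retained_ids)
  )
}
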