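crym_pipeline <- function() run_pipeline(make_crym_fixture(),
                                         config = gocam_config(
                                           disease_roots = character()))

test_that("the worked-example reaction converts to a complete unit", {
  pl <- crym_pipeline()
  m <- pl$models[["R-HSA-71064"]]
  unit <- Filter(function(a) identical(a$source_reaction, "R-HSA-5693347"),
                 m$activities)[[1]]
  expect_equal(unit$function_class, "GO:0047127")
  expect_equal(unit$location, "GO:0005782")
  expect_equal(unit$process_class, "GO:0006554")
  crym_cls <- unname(pl$ontology$entity_to_class["Protein_CRYM"])
  expect_equal(unit$enabler, crym_cls)
  expect_length(unit$inputs, 3)
  expect_length(unit$outputs, 2)
  rec <- audit_activity(unit, m)
  expect_true(rec$complete)
})

test_that("molecular-function assignment falls through as specified", {
  r <- biopax_reaction("R1", mf_xrefs = c("GO:0003824", "GO:0016301"))
  expect_warning(mf <- assign_molecular_function(r), "using the first")
  expect_equal(mf, "GO:0003824")
  r2 <- biopax_reaction("R2")
  expect_equal(assign_molecular_function(r2), "REACTO:MolecularEvent")
  # optional transport inference, off by default
  r3 <- biopax_reaction("R3"); r3$category <- "transport"
  expect_equal(assign_molecular_function(r3), "REACTO:MolecularEvent")
  expect_equal(
    assign_molecular_function(r3, gocam_config(infer_transport_mf = TRUE)),
    "GO:0005215")
})

test_that("enabler resolution covers protein, set, complex and none", {
  suite <- make_edge_case_suite()
  for (case in c("set_catalyst", "complex_enabler")) {
    col <- classify_collection(parse_biopax(suite[[case]]$document))
    onto <- build_entity_ontology(col)
    rid <- names(col$reactions)[1]
    enab <- determine_enabler(col$reactions[[rid]], onto, col)
    cls <- onto$classes[[enab]]
    if (case == "set_catalyst") {
      expect_length(cls$union_members, suite[[case]]$expect$union_size)
    } else {
      expect_length(cls$component_links,
                    suite[[case]]$expect$component_count)
    }
  }
  # binding reaction without catalysis: no enabler
  col <- grid_collection(FALSE, 2, 1, FALSE, TRUE, FALSE)
  onto <- build_entity_ontology(col)
  expect_true(is.na(determine_enabler(col$reactions[["RX"]], onto, col)))
})

test_that("single-location inference preserves participant locations", {
  suite <- make_edge_case_suite()
  col <- classify_collection(parse_biopax(
    suite$multi_location_transport$document))
  onto <- build_entity_ontology(col)
  r <- col$reactions[["R-TST-TRANS"]]
  loc <- infer_location(r, col)
  expect_true(is.na(loc$location))
  expect_equal(loc$transport_from, suite$multi_location_transport$expect$from)
  expect_equal(loc$transport_to, suite$multi_location_transport$expect$to)
  unit <- reaction_to_activity(r, col$pathways[[1]], onto, col)
  # the spanning locations survive on the participants and enabler
  part_locs <- c(vapply(unit$inputs, `[[`, "", "location"),
                 vapply(unit$outputs, `[[`, "", "location"),
                 unit$enabler_location)
  expect_setequal(part_locs, c("GO:0005576", "GO:0005829", "GO:0005886"))
})

test_that("process assignment uses only the immediate parent", {
  r <- biopax_reaction("R1")
  with_bp <- biopax_pathway("P1", bp_xrefs = "GO:0006554")
  without_bp <- biopax_pathway("P2")
  expect_equal(assign_process(r, with_bp), "GO:0006554")
  expect_equal(assign_process(r, without_bp), "GO:0008150")
  expect_equal(assign_process(r, NULL), "GO:0008150")
})

test_that("a black-box event converts to an enabler-less molecular event", {
  suite <- make_edge_case_suite()
  pl <- run_pipeline(suite$black_box$document,
                     config = gocam_config(disease_roots = character()))
  unit <- pl$models[[1]]$activities[[1]]
  expect_equal(unit$function_class, "REACTO:MolecularEvent")
  expect_true(is.na(unit$enabler))
  expect_length(unit$inputs, 0)
  expect_length(unit$outputs, 1)
})

test_that("conversion is total: one unit per retained reaction", {
  fx <- std_corpus(seed = 53, n_drug_reactions = 1, n_disease_pathways = 1)
  pl <- run_pipeline(fx)
  exp <- ledger_expectations(fx$ledger)
  n_units <- sum(vapply(pl$models, function(m) {
    sum(vapply(m$activities, function(a)
      !identical(a$source_category, "regulator_binding"), logical(1)))
  }, integer(1)))
  expect_equal(n_units, exp$n_retained)
})

test_that("location information is conserved through conversion", {
  fx <- std_corpus(seed = 59)
  pl <- run_pipeline(fx)
  col <- pl$collection
  for (m in pl$models) {
    for (unit in m$activities) {
      if (identical(unit$source_category, "regulator_binding")) next
      r <- col$reactions[[unit$source_reaction]]
      cat_ctl <- vapply(Filter(function(c) c$control_type == "catalysis",
                               r$controls), `[[`, "", "controller")
      before <- vapply(c(r$inputs, r$outputs, cat_ctl), function(id) {
        e <- col$entities[[id]]
        if (is.null(e)) NA_character_ else e$location_term
      }, character(1))
      after <- c(vapply(unit$inputs, `[[`, "", "location"),
                 vapply(unit$outputs, `[[`, "", "location"),
                 if (!is.na(unit$enabler)) unit$enabler_location)
      expect_equal(sort(after, na.last = TRUE),
                   sort(unname(before), na.last = TRUE),
                   info = unit$source_reaction)
      if (!is.na(unit$location)) {
        expect_true(all(before == unit$location))
      }
    }
  }
})

test_that("a subpathway-only pathway becomes a single-node model", {
  sub <- biopax_pathway("SUB1", bp_xrefs = "GO:0006554")
  top <- biopax_pathway("TOP", subpathways = "SUB1")
  col <- pathway_collection(pathways = list(top, sub),
                            source_version = "t")
  onto <- empty_entity_ontology()
  m <- convert_pathway(col$pathways[["TOP"]], col, onto)
  expect_length(m$activities, 0)
  expect_length(m$subpathway_nodes, 1)
  expect_equal(m$subpathway_nodes[[1]]$process_class, "GO:0006554")
  expect_match(m$model_id, "^http://model.geneontology.org/TOP$")
})

test_that("model identifiers use the pathway core identifier", {
  p <- biopax_pathway("R-HSA-71064.3")
  col <- pathway_collection(pathways = list(p), source_version = "t")
  m <- suppressWarnings(
    convert_pathway(p, col, empty_entity_ontology()))
  expect_equal(m$model_id, "http://model.geneontology.org/R-HSA-71064")
})
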