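test_that("worked-example document parses with full reaction detail", {
  col <- parse_biopax(make_crym_fixture())
  r <- col$reactions[["R-HSA-5693347"]]
  expect_setequal(
    vapply(r$inputs, function(i) col$entities[[i]]$display_name, ""),
    c("hydron", "P2C", "NADPH"))
  expect_setequal(
    vapply(r$outputs, function(i) col$entities[[i]]$display_name, ""),
    c("NADP+", "PPCA"))
  expect_equal(r$mf_xrefs, "GO:0047127")
  ctl <- r$controls[[1]]
  expect_equal(ctl$control_type, "catalysis")
  expect_equal(col$entities[[ctl$controller]]$display_name, "CRYM")
  expect_equal(col$entities[[ctl$controller]]$reference_xrefs,
               "UniProt:Q14894")
  # every participant located in the peroxisomal matrix
  locs <- vapply(c(r$inputs, r$outputs, ctl$controller),
                 function(i) col$entities[[i]]$location_term, "")
  expect_true(all(locs == "GO:0005782"))
  p <- col$pathways[["R-HSA-71064"]]
  expect_equal(p$bp_xrefs, "GO:0006554")
  expect_equal(unname(p$next_steps[1, ]),
               c("R-HSA-5693347", "R-TST-0000001"))
})

test_that("document with zero pathway elements gives an empty collection", {
  doc <- paste0(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    ' xmlns:owl="http://www.w3.org/2002/07/owl#"',
    ' xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"',
    ' xmlns:bp="http://www.biopax.org/release/biopax-level3.owl#">',
    '<owl:Ontology rdf:about=""><rdfs:comment>v-test</rdfs:comment>',
    '</owl:Ontology></rdf:RDF>')
  col <- parse_biopax(doc)
  expect_length(col$pathways, 0)
  expect_length(col$reactions, 0)
  expect_length(col$entities, 0)
  expect_equal(col$source_version, "v-test")
})

test_that("parsed element counts equal the generator's ledger", {
  for (seed in c(3, 17)) {
    fx <- make_random_pathway_corpus(fixture_spec(seed = seed))
    col <- parse_biopax(fx$document)
    expect_length(col$reactions, fx$ledger$counts$n_reactions)
    expect_length(col$entities, fx$ledger$counts$n_entities)
    expect_length(col$pathways, fx$ledger$counts$n_pathways)
  }
})

test_that("malformed XML raises a parse error naming the location", {
  expect_error(suppressWarnings(parse_biopax("<a><b></a>")),
               "BioPAX parse error")
})

test_that("unknown BioPAX classes are skipped with a registry entry", {
  doc <- paste0(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    ' xmlns:bp="http://www.biopax.org/release/biopax-level3.owl#">',
    '<bp:FrobnicationEvent rdf:ID="weird1"/>',
    '</rdf:RDF>')
  expect_warning(col <- parse_biopax(doc), "unknown BioPAX class")
  expect_true(any(grepl("FrobnicationEvent", col$unresolved)))
})

test_that("parse -> serialize -> parse is isomorphic", {
  fx <- make_random_pathway_corpus(
    fixture_spec(seed = 23, n_drug_reactions = 1))
  col1 <- parse_biopax(fx$document)
  col2 <- parse_biopax(write_biopax(col1))
  expect_setequal(names(col2$entities), names(col1$entities))
  expect_setequal(names(col2$reactions), names(col1$reactions))
  expect_setequal(names(col2$pathways), names(col1$pathways))
  for (id in names(col1$entities)) {
    a <- col1$entities[[id]]; b <- col2$entities[[id]]
    expect_equal(b$kind, a$kind, info = id)
    expect_setequal(b$reference_xrefs, a$reference_xrefs)
    expect_equal(b$location_term, a$location_term, info = id)
    expect_setequal(b$members, a$members)
    expect_setequal(b$components, a$components)
    expect_equal(b$is_drug, a$is_drug, info = id)
    expect_setequal(b$modifications, a$modifications)
  }
  for (id in names(col1$reactions)) {
    a <- col1$reactions[[id]]; b <- col2$reactions[[id]]
    expect_equal(sort(b$inputs), sort(a$inputs), info = id)
    expect_equal(sort(b$outputs), sort(a$outputs), info = id)
    expect_equal(b$mf_xrefs, a$mf_xrefs, info = id)
    expect_setequal(vapply(b$controls, `[[`, "", "control_type"),
                    vapply(a$controls, `[[`, "", "control_type"))
  }
  for (id in names(col1$pathways)) {
    a <- col1$pathways[[id]]; b <- col2$pathways[[id]]
    expect_setequal(b$step_reactions, a$step_reactions)
    expect_setequal(b$subpathways, a$subpathways)
    expect_equal(b$bp_xrefs, a$bp_xrefs, info = id)
    pairs <- function(m) if (nrow(m)) paste(m[, 1], m[, 2]) else character()
    expect_setequal(pairs(b$next_steps), pairs(a$next_steps))
  }
})
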