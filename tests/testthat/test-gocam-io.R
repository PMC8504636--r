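test_that("individual IRIs are minted deterministically", {
  m <- "http://model.geneontology.org/R-HSA-71064"
  expect_equal(mint_individual_iri(m, 1), paste0(m, "/000001"))
  expect_identical(mint_individual_iri(m, 42), mint_individual_iri(m, 42))
})

test_that("serialization is byte-deterministic", {
  pl <- run_pipeline(make_crym_fixture(),
                     config = gocam_config(disease_roots = character()))
  m <- pl$models[[1]]
  expect_identical(write_gocam(m, pl$ontology), write_gocam(m, pl$ontology))
  # rebuilding the whole pipeline gives the same bytes too
  pl2 <- run_pipeline(make_crym_fixture(),
                      config = gocam_config(disease_roots = character()))
  expect_identical(write_gocam(pl2$models[[1]], pl2$ontology),
                   write_gocam(m, pl$ontology))
})

test_that("the worked-example serialization carries the expected structure", {
  pl <- run_pipeline(make_crym_fixture(),
                     config = gocam_config(disease_roots = character()))
  doc <- read_gocam(write_gocam(pl$models[[1]], pl$ontology))
  type_of <- stats::setNames(doc$individuals$type, doc$individuals$iri)
  act <- doc$individuals$iri[doc$individuals$type == "GO:0047127"]
  expect_length(act, 1)
  rel <- gocam_relations()
  ed <- doc$edges
  # occurs in the peroxisomal matrix
  occ <- ed$o[ed$s == act & ed$p == rel$occurs_in]
  expect_equal(unname(type_of[occ]), "GO:0005782")
  # part of lysine catabolic process
  proc <- ed$o[ed$s == act & ed$p == rel$part_of]
  expect_equal(unname(type_of[proc]), "GO:0006554")
  # enabled by the CRYM class
  enab <- ed$o[ed$s == act & ed$p == rel$enabled_by]
  expect_equal(unname(type_of[enab]),
               unname(pl$ontology$entity_to_class["Protein_CRYM"]))
  expect_length(ed$o[ed$s == act & ed$p == rel$has_input], 3)
  expect_length(ed$o[ed$s == act & ed$p == rel$has_output], 2)
})

test_that("write -> read -> write is a byte fixed point on fixture models", {
  fx <- std_corpus(seed = 73, n_pathways = 3)
  pl <- run_pipeline(fx)
  for (m in pl$models) {
    t1 <- write_gocam(m, pl$ontology)
    doc <- read_gocam(t1)
    t2 <- write_gocam_document(doc)
    expect_identical(t2, t1, info = m$model_id)
    # graph isomorphism: identical triple sets (no blank nodes used)
    doc2 <- read_gocam(t2)
    expect_setequal(do.call(paste, doc2$triples), do.call(paste, doc$triples))
  }
})

test_that("emitted relations stay inside the declared vocabulary", {
  fx <- std_corpus(seed = 79)
  pl <- run_pipeline(fx)
  vocab <- unlist(gocam_relations(), use.names = FALSE)
  for (m in pl$models) {
    doc <- read_gocam(write_gocam(m, pl$ontology))
    expect_true(all(doc$edges$p %in% vocab))
    # every individual has exactly one asserted type class
    expect_false(any(duplicated(doc$individuals$iri)))
    # causal relations on activity-activity edges only come from the four
    causal <- doc$edges[doc$edges$p %in% vocab[1:4], ]
    if (nrow(causal)) {
      expect_true(all(causal$p %in% c("RO:0002411", "RO:0002413",
                                      "RO:0002629", "RO:0002630")))
    }
  }
})

test_that("every asserted edge carries an ECO evidence annotation", {
  pl <- run_pipeline(make_crym_fixture(),
                     config = gocam_config(disease_roots = character()))
  doc <- read_gocam(write_gocam(pl$models[[1]], pl$ontology))
  tt <- doc$triples
  n_edges <- nrow(doc$edges)
  ax <- tt$s[tt$p == "rdf:type" & tt$o == "owl:Axiom"]
  expect_length(ax, n_edges)
  ev <- tt$o[tt$s %in% ax & tt$p == "lego:evidence"]
  ev_types <- tt$o[tt$s %in% ev & tt$p == "rdf:type" &
                     tt$o != "owl:NamedIndividual"]
  expect_true(all(ev_types == "ECO:0000363"))
  # the reference names the source reaction
  refs <- tt$o[tt$s %in% ev & tt$p == "dc:source"]
  expect_true(any(grepl("R-HSA-5693347", refs)))
})

test_that("an empty model yields valid metadata-only Turtle", {
  p <- biopax_pathway("P-EMPTY", display_name = "empty")
  col <- pathway_collection(pathways = list(p), source_version = "t")
  m <- suppressWarnings(convert_pathway(p, col, empty_entity_ontology()))
  ttl <- write_gocam(m)
  doc <- read_gocam(ttl)
  expect_equal(doc$model_id, m$model_id)
  expect_equal(nrow(doc$edges), 0)
})

test_that("the entity ontology serializes unions and parts round-trippably", {
  suite <- make_edge_case_suite()
  col <- parse_biopax(suite$nested_set$document)
  onto <- build_entity_ontology(col)
  ttl <- write_entity_ontology(onto)
  doc <- read_gocam(ttl)
  tt <- doc$triples
  expect_true(any(tt$p == "owl:unionOf"))
  # union list recoverable: rdf:first chain has the flattened leaf classes
  firsts <- tt$o[tt$p == "rdf:first"]
  set_iri <- unname(onto$entity_to_class["SETA"])
  expect_setequal(intersect(firsts, onto$classes[[set_iri]]$union_members),
                  onto$classes[[set_iri]]$union_members)
  expect_identical(write_entity_ontology(onto), ttl)
})
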