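test_that("the worked-example pair links by directly-provides-input-for", {
  pl <- run_pipeline(make_crym_fixture(),
                     config = gocam_config(disease_roots = character()))
  m <- pl$models[["R-HSA-71064"]]
  expect_length(m$causal_edges, 1)
  e <- m$causal_edges[[1]]
  expect_equal(e$relation, "RO:0002413")
  expect_equal(e$basis, "output_is_input")
  src <- m$activities[[e$source]]
  expect_equal(src$source_reaction, "R-HSA-5693347")
})

test_that("planted causal bases are recovered over a random corpus", {
  fx <- std_corpus(seed = 61, n_pathways = 8)
  pl <- run_pipeline(fx)
  # gather edges with their source/target reactions
  got <- do.call(rbind, unlist(lapply(pl$models, function(m) {
    lapply(m$causal_edges, function(e) {
      if (e$basis == "regulator_binding") return(NULL)
      data.frame(from = m$activities[[e$source]]$source_reaction,
                 to = m$activities[[e$target]]$source_reaction,
                 relation = e$relation, basis = e$basis,
                 stringsAsFactors = FALSE)
    })
  }), recursive = FALSE))
  lk <- fx$ledger$links
  expect_equal(nrow(got), nrow(lk))
  key <- function(d) paste(d$from, d$to)
  got <- got[order(key(got)), ]; lk <- lk[order(key(lk)), ]
  expect_equal(key(got), key(lk))
  expect_equal(got$relation, lk$relation)
  expect_equal(got$basis, lk$basis)
})

test_that("relation counts partition the step links", {
  fx <- std_corpus(seed = 67, n_drug_reactions = 2, n_disease_pathways = 1)
  pl <- run_pipeline(fx)
  s <- pl$summary
  exp <- ledger_expectations(fx$ledger)
  expect_equal(unname(s$relation_counts[exp$relation_names]),
               exp$relation_counts)
  expect_equal(s$n_dropped_links, exp$n_dropped)
  expect_equal(sum(s$relation_counts) + s$n_dropped_links, exp$n_step_links)
})

test_that("a step link with no entity overlap defaults to causally-upstream", {
  col <- grid_collection(TRUE, 1, 1, FALSE, FALSE, FALSE)
  onto <- build_entity_ontology(classify_collection(col))
  r <- classify_collection(col)$reactions[["RX"]]
  mk_unit <- function(aid, outputs = list(), inputs = list()) {
    structure(list(activity_id = aid, function_class = "GO:0003824",
                   enabler = NA_character_, enabler_entity = NA_character_,
                   enabler_location = NA_character_,
                   inputs = inputs, outputs = outputs,
                   location = NA_character_, transport_from = NA_character_,
                   transport_to = NA_character_,
                   process_class = "GO:0008150", causal_edges = list(),
                   source_reaction = "r", source_category = "catalyzed",
                   is_transport = FALSE, complex_enabler = FALSE),
              class = "activity_unit")
  }
  up <- mk_unit("a1", outputs = list(list(entity_id = "x",
                                          class_iri = "CHEBI:990001",
                                          location = NA)))
  down <- mk_unit("a2", inputs = list(list(entity_id = "y",
                                           class_iri = "CHEBI:990099",
                                           location = NA)))
  e <- infer_causal_relation(up, down, biopax_reaction("r2"), onto)
  expect_equal(e$relation, "RO:0002411")
  expect_equal(e$basis, "step_only")
  # overlap through a union class: any member of a set matches
  onto2 <- empty_entity_ontology()
  onto2$classes[["REACTO:U1"]] <- list(iri = "REACTO:U1", label = "u",
                                       superclasses = character(),
                                       union_members = c("CHEBI:990001",
                                                         "CHEBI:990088"),
                                       component_links = character(),
                                       xrefs = character(), definition = "")
  down2 <- mk_unit("a3", inputs = list(list(entity_id = "s",
                                            class_iri = "REACTO:U1",
                                            location = NA)))
  e2 <- infer_causal_relation(up, down2, biopax_reaction("r3"), onto2)
  expect_equal(e2$relation, "RO:0002413")
})

test_that("a noncatalytic inhibitor becomes a binding node with a negative edge", {
  suite <- make_edge_case_suite()
  pl <- run_pipeline(suite$inhibitor$document,
                     config = gocam_config(disease_roots = character()))
  m <- pl$models[[1]]
  binders <- Filter(function(a)
    identical(a$source_category, "regulator_binding"), m$activities)
  expect_length(binders, suite$inhibitor$expect$binding_nodes)
  b <- binders[[1]]
  expect_equal(b$function_class, "GO:0005488")
  expect_false(is.na(b$enabler))
  reg_edges <- Filter(function(e) e$basis == "regulator_binding",
                      m$causal_edges)
  expect_length(reg_edges, 1)
  expect_equal(reg_edges[[1]]$relation, suite$inhibitor$expect$relation)
  expect_equal(reg_edges[[1]]$source, b$activity_id)
})

test_that("binding-node count equals the planted standalone regulators", {
  fx <- std_corpus(seed = 71, n_noncatalytic_controls = 4)
  pl <- run_pipeline(fx)
  exp <- ledger_expectations(fx$ledger)
  expect_equal(pl$summary$n_regulator_binding_nodes, exp$n_regulator_nodes)
  # a model with no noncatalytic controls is unchanged
  pl0 <- run_pipeline(std_corpus(seed = 71, n_noncatalytic_controls = 0))
  expect_equal(pl0$summary$n_regulator_binding_nodes, 0)
})

test_that("the dangling-link fixture drops exactly one link", {
  suite <- make_edge_case_suite()
  pl <- run_pipeline(suite$dangling_link$document,
                     config = gocam_config(disease_roots = character()))
  expect_equal(pl$summary$n_dropped_links,
               suite$dangling_link$expect$dropped_links)
  expect_equal(sum(pl$summary$relation_counts), 0)
})
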