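make_three_pathway_doc <- function() {
  ents <- list(
    physical_entity("E1", "E1", kind = "small_molecule",
                    reference_xrefs = "CHEBI:900201"),
    physical_entity("E2", "E2", kind = "small_molecule",
                    reference_xrefs = "CHEBI:900202"))
  rxns <- lapply(1:3, function(k) {
    biopax_reaction(paste0("RX", k), inputs = "E1", outputs = "E2")
  })
  pws <- list(
    biopax_pathway("PW1", step_reactions = "RX1"),
    biopax_pathway("PW2", step_reactions = "RX2"),
    biopax_pathway("PW3", step_reactions = "RX3"),
    biopax_pathway("DROOT", subpathways = "PW3")
  )
  pathway_collection(pathways = pws, reactions = rxns, entities = ents,
                     source_version = "filter-test")
}

test_that("pathways under a disease root are removed by subpathway closure", {
  col <- make_three_pathway_doc()
  cfg <- gocam_config(disease_roots = "DROOT")
  out <- suppressMessages(filter_collection(col, cfg))
  expect_setequal(names(out$pathways), c("PW1", "PW2"))
  expect_false("RX3" %in% names(out$reactions))
})

test_that("a missing disease root degrades to a warned no-op", {
  col <- make_three_pathway_doc()
  cfg <- gocam_config(disease_roots = "NOT-THERE")
  expect_warning(out <- suppressMessages(filter_collection(col, cfg)),
                 "no-op")
  expect_length(out$pathways, 4)
})

test_that("drug reactions are removed but their pathway is retained", {
  drug <- physical_entity("DRUG1", "drug", kind = "small_molecule",
                          reference_xrefs = c("CHEBI:900203",
                                              "DrugBank:DB00001"))
  ents <- list(drug,
               physical_entity("E1", "E1", kind = "small_molecule",
                               reference_xrefs = "CHEBI:900204"))
  rxns <- list(
    biopax_reaction("RXD", inputs = "DRUG1", outputs = "E1"),
    biopax_reaction("RXN", inputs = "E1", outputs = "E1"))
  pw <- biopax_pathway("PW1", step_reactions = c("RXD", "RXN"))
  col <- pathway_collection(pathways = list(pw), reactions = rxns,
                            entities = ents, source_version = "t")
  out <- suppressMessages(suppressWarnings(
    filter_collection(col, gocam_config())))
  expect_setequal(names(out$reactions), "RXN")
  expect_true("PW1" %in% names(out$pathways))
  # drug filter off keeps the reaction
  out2 <- suppressMessages(suppressWarnings(
    filter_collection(col, gocam_config(drug_filter = FALSE))))
  expect_true("RXD" %in% names(out2$reactions))
})

test_that("retained set equals brute-force recomputation from planted flags", {
  fx <- make_random_pathway_corpus(
    fixture_spec(seed = 31, n_disease_pathways = 2, n_drug_reactions = 2))
  col <- parse_biopax(fx$document)
  out <- suppressMessages(filter_collection(col, std_config()))
  exp <- ledger_expectations(fx$ledger)
  expect_setequal(names(out$reactions),
                  exp$reactions$id[exp$reactions$retained])
  expect_setequal(names(out$pathways),
                  fx$ledger$pathways$id[!fx$ledger$pathways$is_disease])
})
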