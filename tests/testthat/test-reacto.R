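located_sm <- function(id, chebi, loc) {
  physical_entity(id, id, kind = "small_molecule", reference_xrefs = chebi,
                  location_term = loc, location_label = loc)
}

test_that("located duplicates of a small molecule share the ChEBI class", {
  ents <- list(located_sm("ADP_cyt", "CHEBI:16761", "GO:0005829"),
               located_sm("ADP_nuc", "CHEBI:16761", "GO:0005634"))
  col <- pathway_collection(entities = ents, source_version = "t")
  onto <- empty_entity_ontology()
  r1 <- class_for_entity(col$entities[["ADP_cyt"]], onto, col)
  r2 <- class_for_entity(col$entities[["ADP_nuc"]], r1$ontology, col)
  expect_equal(r1$iri, "CHEBI:16761")
  expect_equal(r2$iri, r1$iri)
  # no new class was minted for either
  expect_false(any(startsWith(names(r2$ontology$classes), "REACTO:CHEBI")))
})

test_that("a proteoform becomes a subclass of the canonical protein class", {
  ents <- list(
    physical_entity("KRAS", "KRAS4A", kind = "protein",
                    reference_xrefs = "UniProt:P01116"),
    physical_entity("KRAS_mod", "S-Farn-Me-PalmS KRAS4A", kind = "protein",
                    reference_xrefs = "UniProt:P01116",
                    modifications = c("S-palmitoyl-L-cysteine@179",
                                      "S-farnesyl-L-cysteine@186")))
  col <- pathway_collection(entities = ents, source_version = "t")
  onto <- empty_entity_ontology()
  canon <- class_for_entity(col$entities[["KRAS"]], onto, col)
  pf <- class_for_entity(col$entities[["KRAS_mod"]], canon$ontology, col)
  expect_false(pf$iri == canon$iri)
  cls <- pf$ontology$classes[[pf$iri]]
  expect_equal(cls$superclasses, canon$iri)
  # the UniProt accession stays on the canonical parent
  expect_equal(pf$ontology$classes[[canon$iri]]$xrefs, "UniProt:P01116")
  # same accession + same modification set elsewhere reuses the class
  ents2 <- c(ents, list(
    physical_entity("KRAS_mod2", "same proteoform", kind = "protein",
                    reference_xrefs = "UniProt:P01116",
                    modifications = c("S-farnesyl-L-cysteine@186",
                                      "S-palmitoyl-L-cysteine@179"))))
  col2 <- pathway_collection(entities = ents2, source_version = "t")
  pf2 <- class_for_entity(col2$entities[["KRAS_mod2"]], pf$ontology, col2)
  expect_equal(pf2$iri, pf$iri)
  # gene-product classes root under the information-biomacromolecule class
  expect_equal(pf$ontology$classes[[canon$iri]]$superclasses, "CHEBI:33695")
})

test_that("class minting is idempotent", {
  col <- parse_biopax(make_crym_fixture())
  onto <- build_entity_ontology(col)
  e <- col$entities[["Protein_CRYM"]]
  a <- class_for_entity(e, onto, col)
  b <- class_for_entity(e, a$ontology, col)
  expect_identical(a$iri, b$iri)
  expect_identical(length(a$ontology$classes), length(b$ontology$classes))
})

test_that("entity sets become unions of their flattened member classes", {
  prot <- function(id, acc) physical_entity(id, id, kind = "protein",
                                            reference_xrefs = paste0("UniProt:", acc))
  ents <- list(prot("GCK", "P35557"), prot("HK1", "P19367"),
               prot("HK2", "P52789"), prot("HK3", "P52790"),
               physical_entity("HEXOKINASES", "glucokinase and hexokinases",
                               kind = "entity_set",
                               members = c("GCK", "HK1", "HK2", "HK3")))
  col <- pathway_collection(entities = ents, source_version = "t")
  onto <- empty_entity_ontology()
  res <- union_for_set(col$entities[["HEXOKINASES"]], onto, col)
  cls <- res$ontology$classes[[res$iri]]
  expect_length(cls$union_members, 4)
  # every union member is itself a class in the ontology
  expect_true(all(cls$union_members %in% names(res$ontology$classes)))
  # singleton set: a union of one
  ents2 <- c(ents, list(physical_entity("SOLO", "SOLO", kind = "entity_set",
                                        members = "GCK")))
  col2 <- pathway_collection(entities = ents2, source_version = "t")
  res2 <- union_for_set(col2$entities[["SOLO"]], res$ontology, col2)
  expect_length(res2$ontology$classes[[res2$iri]]$union_members, 1)
})

test_that("nested sets flatten to the planted leaf count", {
  suite <- make_edge_case_suite()
  col <- parse_biopax(suite$nested_set$document)
  onto <- build_entity_ontology(col)
  iri <- unname(onto$entity_to_class["SETA"])
  cls <- onto$classes[[iri]]
  # brute-force leaf traversal of the fixture
  leaves <- new.env(); count_leaves <- function(id) {
    e <- col$entities[[id]]
    if (e$kind == "entity_set") for (m in e$members) count_leaves(m)
    else assign(id, TRUE, envir = leaves)
  }
  count_leaves("SETA")
  expect_length(cls$union_members, length(ls(leaves)))
  expect_length(cls$union_members, suite$nested_set$expect$leaf_count)
})

test_that("the ontology covers every reachable entity exactly once", {
  fx <- std_corpus(seed = 41)
  col <- classify_collection(parse_biopax(fx$document))
  onto <- build_entity_ontology(col)
  reach <- unique(unlist(lapply(col$reactions, function(r) {
    ids <- c(r$inputs, r$outputs,
             vapply(r$controls, `[[`, "", "controller"))
    expand <- function(x) {
      e <- col$entities[[x]]
      c(x, unlist(lapply(c(e$components, e$members), expand)))
    }
    unlist(lapply(ids, expand))
  })))
  expect_setequal(names(onto$entity_to_class), reach)
  # deterministic: rebuilding yields identical IRIs
  onto2 <- build_entity_ontology(col)
  expect_identical(onto$entity_to_class, onto2$entity_to_class)
  # no minted class shadows a usable ChEBI mapping
  for (id in reach) {
    e <- col$entities[[id]]
    if (e$kind == "small_molecule" &&
        any(startsWith(e$reference_xrefs, "CHEBI:"))) {
      expect_true(startsWith(unname(onto$entity_to_class[id]), "CHEBI:"))
    }
  }
  # structural roots always present
  expect_true("REACTO:MolecularEvent" %in% names(onto$classes))
  expect_true("CHEBI:33695" %in% names(onto$classes))
})
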