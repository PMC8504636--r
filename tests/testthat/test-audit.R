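test_that("completeness records reflect the five attribute checks", {
  pl <- run_pipeline(make_crym_fixture(),
                     config = gocam_config(disease_roots = character()))
  m <- pl$models[[1]]
  recs <- lapply(m$activities, audit_activity, model = m)
  expect_true(all(vapply(recs, `[[`, logical(1), "complete")))
  # strip everything: a unit missing all five lands in the full category
  bare <- structure(list(
    activity_id = "a", function_class = "REACTO:MolecularEvent",
    enabler = NA_character_, enabler_entity = NA_character_,
    enabler_location = NA_character_, inputs = list(), outputs = list(),
    location = NA_character_, transport_from = NA_character_,
    transport_to = NA_character_, process_class = "GO:0008150",
    causal_edges = list(), source_reaction = "r",
    source_category = "black_box", is_transport = FALSE,
    complex_enabler = FALSE), class = "activity_unit")
  rec <- audit_activity(bare)
  expect_false(rec$complete)
  expect_equal(rec$category_key, "BP,Causal,Enabler,Loc,MF")
})

test_that("audit counts equal brute-force recomputation from the ledger", {
  fx <- std_corpus(seed = 83, n_drug_reactions = 1, n_disease_pathways = 1,
                   n_noncatalytic_controls = 3)
  pl <- run_pipeline(fx)
  s <- pl$summary
  exp <- ledger_expectations(fx$ledger)
  expect_equal(s$n_reactions, exp$n_retained)
  expect_equal(s$n_complete, exp$n_complete)
  expect_equal(s$n_binding, exp$n_binding)
  expect_equal(s$n_dissociation, exp$n_dissociation)
  # per-unit agreement, not just totals
  got <- do.call(rbind, lapply(s$records, function(r) {
    data.frame(id = r$source_reaction, complete = r$complete,
               stringsAsFactors = FALSE)
  }))
  want <- exp$reactions[exp$reactions$retained, c("id", "exp_complete")]
  got <- got[order(got$id), ]; want <- want[order(want$id), ]
  expect_equal(got$id, want$id)
  expect_equal(got$complete, want$exp_complete)
})

test_that("partition identities hold on every corpus", {
  for (seed in c(89, 97)) {
    fx <- std_corpus(seed = seed, n_drug_reactions = 2)
    pl <- run_pipeline(fx)
    s <- pl$summary
    expect_equal(s$n_complete + s$n_incomplete, s$n_reactions)
    expect_equal(sum(s$relation_counts) + s$n_dropped_links, s$n_step_links)
    expect_equal(sum(s$missing_category_counts), s$n_incomplete)
  }
})

test_that("auditing does not mutate models", {
  pl <- run_pipeline(std_corpus(seed = 101, n_pathways = 2))
  before <- pl$models
  invisible(audit_collection(pl$models))
  expect_identical(pl$models, before)
})

test_that("the empty model list audits to zero", {
  s <- audit_collection(list())
  expect_equal(s$n_reactions, 0)
  expect_equal(s$n_complete, 0)
  expect_equal(sum(s$relation_counts), 0)
})

test_that("re-auditing serialized models matches the in-memory audit", {
  fx <- std_corpus(seed = 103, n_pathways = 3, n_noncatalytic_controls = 2)
  pl <- run_pipeline(fx)
  dir <- tempfile("gocamr-audit-")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  paths <- character()
  for (m in pl$models) {
    f <- file.path(dir, paste0(basename(m$model_id), ".ttl"))
    write_gocam(m, pl$ontology, path = f)
    paths <- c(paths, f)
  }
  s_mem <- pl$summary
  s_ttl <- audit_gocam_files(paths)
  expect_equal(s_ttl$n_reactions, s_mem$n_reactions)
  expect_equal(s_ttl$n_complete, s_mem$n_complete)
  expect_equal(s_ttl$n_root_bp, s_mem$n_root_bp)
  expect_equal(s_ttl$relation_counts, s_mem$relation_counts)
  expect_equal(s_ttl$n_dropped_links, s_mem$n_dropped_links)
  expect_equal(s_ttl$n_regulator_binding_nodes,
               s_mem$n_regulator_binding_nodes)
})
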