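#' Synthetic BioPAX fixtures
#'
#' Generators for BioPAX Level-3 documents emulating the structures of a
#' Reactome-style export - catalyzed reactions, catalyzed transport,
#' binding/dissociation events, black-box shorthand events, entity sets,
#' complexes, proteoforms, cellular locations, GO/UniProt/ChEBI
#' cross-references, noncatalytic regulators, disease pathways and drug
#' reactions - so every pipeline stage is testable without any download.
#' Alongside each random document a machine-readable ledger of planted
#' truths (categories, gaps, causal bases, filter flags) is produced and
#' used as the oracle by the test suite.
#'
#' Fixture identifiers live in a reserved `-TST-` namespace so they cannot
#' collide with real stable IDs; the worked-example fixture intentionally
#' reuses the published CRYM reaction/pathway identifiers for traceability.
#' Small molecules named in the worked example carry their real ChEBI
#' CURIEs; all other fixture CURIEs are synthetic and marked as such in
#' entity display names.
#'
#' @name fixtures
NULL

#' Worked-example fixture: CRYM reduces P2C to PPCA
#'
#' A two-reaction fragment of the lysine catabolism pathway (R-HSA-71064,
#' GO:0006554): the published reaction "CRYM reduces P2C to PPCA"
#' (R-HSA-5693347; catalysis by CRYM, inputs hydron/P2C/NADPH, outputs
#' NADP+/PPCA, molecular function GO:0047127, all participants in the
#' peroxisomal matrix GO:0005782) followed by a downstream pipecolate
#' oxidation step consuming PPCA, linked by a pathway step relation.  The
#' downstream reaction is a synthetic reconstruction (identifier in the
#' `-TST-` namespace) standing in for the real follow-on reaction, which the
#' worked example only depicts.
#'
#' The document is byte-identical across calls.
#'
#' @param as_collection Return the in-memory [pathway_collection()] instead
#'   of the serialized document.
#' @return BioPAX RDF/XML as a single string (or a collection).
#' @export
#' @examples
#' col <- parse_biopax(make_crym_fixture())
#' length(col$reactions[["R-HSA-5693347"]]$inputs)  # 3
make_crym_fixture <- function(as_collection = FALSE) {
  loc <- "GO:0005782"; loclab <- "peroxisomal matrix"
  sm <- function(id, name, chebi) {
    physical_entity(id, name, kind = "small_molecule",
                    reference_xrefs = chebi,
                    location_term = loc, location_label = loclab)
  }
  entities <- list(
    physical_entity("Protein_CRYM", "CRYM", kind = "protein",
                    reference_xrefs = "UniProt:Q14894",
                    location_term = loc, location_label = loclab),
    physical_entity("Protein_PIPOX", "PIPOX", kind = "protein",
                    reference_xrefs = "UniProt:Q9P0Z9",
                    location_term = loc, location_label = loclab),
    sm("SmallMolecule_hydron", "hydron", "CHEBI:15378"),
    sm("SmallMolecule_P2C", "P2C", "CHEBI:16654"),
    sm("SmallMolecule_NADPH", "NADPH", "CHEBI:16474"),
    sm("SmallMolecule_NADPplus", "NADP+", "CHEBI:18009"),
    sm("SmallMolecule_PPCA", "PPCA", "CHEBI:30913"),
    sm("SmallMolecule_O2", "O2", "CHEBI:15379"),
    sm("SmallMolecule_P6C", "P6C (synthetic)", "CHEBI:900001"),
    sm("SmallMolecule_H2O2", "H2O2", "CHEBI:16240")
  )
  crym <- biopax_reaction(
    "R-HSA-5693347", "CRYM reduces P2C to PPCA",
    inputs = c("SmallMolecule_hydron", "SmallMolecule_P2C",
               "SmallMolecule_NADPH"),
    outputs = c("SmallMolecule_NADPplus", "SmallMolecule_PPCA"),
    mf_xrefs = "GO:0047127"
  )
  crym$controls <- list(biopax_control("Protein_CRYM", "R-HSA-5693347",
                                       "catalysis", "R-HSA-5693347_cat"))
  down <- biopax_reaction(
    "R-TST-0000001", "PIPOX oxidises PPCA (synthetic reconstruction)",
    inputs = c("SmallMolecule_PPCA", "SmallMolecule_O2"),
    outputs = c("SmallMolecule_P6C", "SmallMolecule_H2O2"),
    mf_xrefs = "GO:0050031"
  )
  down$controls <- list(biopax_control("Protein_PIPOX", "R-TST-0000001",
                                       "catalysis", "R-TST-0000001_cat"))
  pw <- biopax_pathway(
    "R-HSA-71064", "lysine catabolism",
    step_reactions = c("R-HSA-5693347", "R-TST-0000001"),
    next_steps = list(c("R-HSA-5693347", "R-TST-0000001")),
    bp_xrefs = "GO:0006554"
  )
  col <- pathway_collection(
    pathways = list(pw), reactions = list(crym, down), entities = entities,
    source_version = "gocamr synthetic fixture (Reactome-style BioPAX L3)"
  )
  if (as_collection) return(col)
  write_biopax(col)
}

#' Specification for a random fixture corpus
#'
#' The defaults define the standard synthetic study conditions used across
#' the test suite: mostly catalyzed reactions with a minority of catalyzed
#' transport, binding, dissociation and black-box events; curation gaps
#' (missing molecular functions on non-catalyzed events, missing pathway
#' process terms, mixed participant locations) planted at fixed rates.
#' Catalyzed reactions - including catalyzed transport - always carry a
#' molecular-function cross-reference and a catalyst, mirroring source
#' curation practice where enzymatic events are systematically classified;
#' the `frac_mf` gap rate applies to non-catalyzed events only.
#'
#' @param n_pathways Number of normal-biology pathways.
#' @param reaction_mix Named counts per pathway of planted categories among
#'   `catalyzed`, `transport` (catalyzed transport), `binding`,
#'   `dissociation`, `black_box`, `other`.
#' @param n_sets Catalyzed reactions (corpus-wide) whose catalyst is an
#'   entity set of three proteins.
#' @param n_complexes Catalyzed reactions whose catalyst is a two-component
#'   complex.
#' @param n_proteoforms Catalyst proteins planted as modified forms
#'   (phosphoserine) of a canonical protein also present in the document.
#' @param n_noncatalytic_controls Free-standing regulator entities planted
#'   on retained reactions (they become binding activity nodes).
#' @param activation_fraction Fraction of planted regulators that activate
#'   (the rest inhibit).
#' @param frac_mf Probability a *non-catalyzed* reaction carries a GO MF
#'   cross-reference.
#' @param frac_bp Probability a pathway carries a GO BP cross-reference.
#' @param frac_uniform_loc Probability all participants of a non-transport
#'   reaction share one location.
#' @param n_disease_pathways Pathways planted under a disease root
#'   (`P-TST-DISEASE-ROOT`).
#' @param n_drug_reactions Reactions (appended to pathway chains) with a
#'   drug participant; filtering them leaves dangling step links.
#' @param seed Integer; fully determines the output bytes.
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_pathways = 5,
                         reaction_mix = c(catalyzed = 3, transport = 1,
                                          binding = 1, dissociation = 1,
                                          black_box = 1),
                         n_sets = 1, n_complexes = 1, n_proteoforms = 1,
                         n_noncatalytic_controls = 2,
                         activation_fraction = 0.75,
                         frac_mf = 0.7, frac_bp = 0.6,
                         frac_uniform_loc = 0.5,
                         n_disease_pathways = 0, n_drug_reactions = 0,
                         seed = 1) {
  counts <- c(n_pathways, reaction_mix, n_sets, n_complexes, n_proteoforms,
              n_noncatalytic_controls, n_disease_pathways, n_drug_reactions)
  if (any(counts < 0)) stop("fixture_spec counts must be >= 0")
  bad <- setdiff(names(reaction_mix),
                 c("catalyzed", "transport", "binding", "dissociation",
                   "black_box", "other"))
  if (length(bad)) stop("unknown reaction_mix categories: ",
                        paste(bad, collapse = ", "))
  if (n_pathways == 0 && sum(reaction_mix) > 0) {
    stop("reactions requested but n_pathways is 0")
  }
  n_cat <- (reaction_mix["catalyzed"] %||% 0) * n_pathways
  if (n_sets + n_complexes > n_cat) {
    stop("n_sets + n_complexes exceeds the number of catalyzed reactions")
  }
  for (f in c(activation_fraction, frac_mf, frac_bp, frac_uniform_loc)) {
    if (f < 0 || f > 1) stop("fractions must be in [0, 1]")
  }
  structure(list(
    n_pathways = n_pathways, reaction_mix = reaction_mix,
    n_sets = n_sets, n_complexes = n_complexes,
    n_proteoforms = n_proteoforms,
    n_noncatalytic_controls = n_noncatalytic_controls,
    activation_fraction = activation_fraction,
    frac_mf = frac_mf, frac_bp = frac_bp,
    frac_uniform_loc = frac_uniform_loc,
    n_disease_pathways = n_disease_pathways,
    n_drug_reactions = n_drug_reactions, seed = as.integer(seed)
  ), class = "fixture_spec")
}

.fixture_locations <- c("GO:0005829", "GO:0005634", "GO:0005886",
                        "GO:0005576")
.fixture_location_labels <- c("cytosol", "nucleoplasm", "plasma membrane",
                              "extracellular region")

#' Generate a random pathway corpus with a planted-truth ledger
#'
#' Realizes a [fixture_spec()] as a BioPAX document plus a ledger of every
#' planted truth, used as the independent oracle by downstream tests.
#' Reactions within a pathway are chained linearly by step links; each
#' link's causal basis is planted (entity reuse for provides-input, a
#' regulator sourced from the upstream outputs for regulation, no overlap
#' for plain ordering) respecting the downstream reaction's shape, so the
#' expected relation is known by construction.  An internal self-check
#' verifies the ledger against the emitted document before returning.
#'
#' @param spec A [fixture_spec()].
#' @return List with `document` (BioPAX XML string), `collection` (the
#'   source [pathway_collection()]) and `ledger` (list of data frames:
#'   `pathways`, `reactions`, `links`, `controls`, plus scalar `counts`).
#' @export
#' @examples
#' fx <- make_random_pathway_corpus(fixture_spec(n_pathways = 2, seed = 7))
#' nrow(fx$ledger$reactions)
make_random_pathway_corpus <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)

  env <- new.env(parent = emptyenv())
  env$entities <- list(); env$reactions <- list(); env$pathways <- list()
  env$e_ctr <- 0L; env$r_ctr <- 0L; env$mf_ctr <- 0L

  led_rxn <- list(); led_pw <- list(); led_link <- list(); led_ctl <- list()

  add_entity <- function(e) { env$entities[[e$local_id]] <- e; e$local_id }
  new_id <- function() { env$e_ctr <- env$e_ctr + 1L
                         sprintf("E-TST-%05d", env$e_ctr) }
  new_rxn_id <- function() { env$r_ctr <- env$r_ctr + 1L
                             sprintf("R-TST-%04d", env$r_ctr) }
  new_mf <- function() { env$mf_ctr <- env$mf_ctr + 1L
                         sprintf("GO:%07d", 3000000L + env$mf_ctr) }
  new_sm <- function(loc) {
    id <- new_id()
    add_entity(physical_entity(
      id, paste0("test molecule ", env$e_ctr, " (synthetic)"),
      kind = "small_molecule",
      reference_xrefs = sprintf("CHEBI:%06d", 900000L + env$e_ctr),
      location_term = loc,
      location_label = loc_label(loc)))
  }
  new_protein <- function(loc, mods = character()) {
    id <- new_id()
    add_entity(physical_entity(
      id, paste0("test protein ", env$e_ctr, " (synthetic)"),
      kind = "protein",
      reference_xrefs = sprintf("UniProt:TST%05d", env$e_ctr),
      location_term = loc, location_label = loc_label(loc),
      modifications = mods))
  }
  loc_label <- function(loc) {
    if (is.na(loc)) return(NA_character_)
    .fixture_location_labels[match(loc, .fixture_locations)]
  }
  pick_loc <- function() sample(.fixture_locations, 1)

  # which catalyzed reactions get set/complex catalysts or proteoform catalysts
  mix <- spec$reaction_mix[spec$reaction_mix > 0]
  cat_total <- (mix["catalyzed"] %||% 0) * spec$n_pathways
  special <- rep("protein", max(cat_total, 0))
  if (spec$n_sets > 0) special[seq_len(spec$n_sets)] <- "set"
  if (spec$n_complexes > 0) {
    special[spec$n_sets + seq_len(spec$n_complexes)] <- "complex"
  }
  pf_left <- spec$n_proteoforms
  cat_seen <- 0L

  make_reaction <- function(category, pathway_id) {
    rid <- new_rxn_id()
    uniform <- stats::runif(1) < spec$frac_uniform_loc
    # uniform reactions share the pathway's location so entity reuse along
    # the chain (causal-basis planting) cannot break planted uniformity
    base_loc <- env$pw_loc
    ploc <- function(k) {
      if (uniform) base_loc
      else .fixture_locations[((k - 1) %% 2) + 1]
    }
    has_mf <- FALSE; has_cat <- FALSE
    inputs <- character(); outputs <- character(); controls <- list()
    is_transport <- FALSE
    if (category %in% c("catalyzed", "transport")) {
      has_mf <- TRUE; has_cat <- TRUE
      if (category == "transport") {
        # catalyzed transporter: same molecule, two locations
        locA <- .fixture_locations[1]; locB <- .fixture_locations[2]
        chebi <- sprintf("CHEBI:%06d", 900000L + env$e_ctr + 1L)
        idA <- new_id()
        add_entity(physical_entity(
          idA, paste0("cargo ", env$e_ctr, " (synthetic)"),
          kind = "small_molecule", reference_xrefs = chebi,
          location_term = locA, location_label = loc_label(locA)))
        idB <- new_id()
        add_entity(physical_entity(
          idB, paste0("cargo ", env$e_ctr - 1L, " (synthetic)"),
          kind = "small_molecule", reference_xrefs = chebi,
          location_term = locB, location_label = loc_label(locB)))
        inputs <- idA; outputs <- idB
        uniform <- FALSE
        is_transport <- TRUE
        ctl_id <- new_protein(locB)
      } else {
        inputs <- c(new_sm(ploc(1)), new_sm(ploc(2)))
        outputs <- c(new_sm(ploc(1)), new_sm(ploc(1)))
        cat_seen <<- cat_seen + 1L
        kind <- if (cat_seen <= length(special)) special[cat_seen]
                else "protein"
        ctl_id <- switch(kind,
          protein = {
            mods <- if (pf_left > 0) {
              pf_left <<- pf_left - 1L
              # canonical form present elsewhere in the document
              canon <- new_protein(ploc(1))
              pf <- new_id()
              acc <- env$entities[[canon]]$reference_xrefs
              add_entity(physical_entity(
                pf, paste0("phospho form of ",
                           env$entities[[canon]]$display_name),
                kind = "protein", reference_xrefs = acc,
                location_term = ploc(1), location_label = loc_label(ploc(1)),
                modifications = "O-phospho-L-serine@42"))
              pf
            } else new_protein(ploc(1))
            mods
          },
          set = {
            ms <- c(new_protein(ploc(1)), new_protein(ploc(1)),
                    new_protein(ploc(1)))
            sid <- new_id()
            add_entity(physical_entity(
              sid, paste0("test set ", env$e_ctr, " (synthetic)"),
              kind = "entity_set", members = ms,
              location_term = ploc(1), location_label = loc_label(ploc(1))))
            sid
          },
          complex = {
            cs <- c(new_protein(ploc(1)), new_protein(ploc(1)))
            cid <- new_id()
            add_entity(physical_entity(
              cid, paste0("test complex ", env$e_ctr, " (synthetic)"),
              kind = "complex", components = cs,
              location_term = ploc(1), location_label = loc_label(ploc(1))))
            cid
          })
      }
      controls <- list(biopax_control(ctl_id, rid, "catalysis",
                                      paste0(rid, "_cat")))
      category <- "catalyzed"  # the classifier category; transport is a flag
    } else if (category == "binding") {
      has_mf <- stats::runif(1) < spec$frac_mf
      a <- new_protein(ploc(1)); b <- new_protein(ploc(2))
      cx <- new_id()
      add_entity(physical_entity(
        cx, paste0("test complex ", env$e_ctr, " (synthetic)"),
        kind = "complex", components = c(a, b),
        location_term = ploc(1), location_label = loc_label(ploc(1))))
      inputs <- c(a, b); outputs <- cx
    } else if (category == "dissociation") {
      has_mf <- stats::runif(1) < spec$frac_mf
      a <- new_protein(ploc(1)); b <- new_protein(ploc(2))
      cx <- new_id()
      add_entity(physical_entity(
        cx, paste0("test complex ", env$e_ctr, " (synthetic)"),
        kind = "complex", components = c(a, b),
        location_term = ploc(1), location_label = loc_label(ploc(1))))
      inputs <- cx; outputs <- c(a, b)
    } else if (category == "black_box") {
      has_mf <- stats::runif(1) < spec$frac_mf
      outputs <- new_protein(ploc(1))
    } else { # other: 1 -> 1, same location, no catalysis
      has_mf <- stats::runif(1) < spec$frac_mf
      inputs <- new_sm(base_loc); outputs <- new_sm(base_loc)
      uniform <- TRUE
    }
    r <- biopax_reaction(rid, paste0("test reaction ", rid),
                         inputs = inputs, outputs = outputs,
                         mf_xrefs = if (has_mf) new_mf() else character())
    r$controls <- controls
    env$reactions[[rid]] <- r
    led_rxn[[length(led_rxn) + 1L]] <<- data.frame(
      id = rid, pathway = pathway_id, category = category,
      is_transport = is_transport, has_mf = has_mf, has_catalysis = has_cat,
      uniform_loc = uniform && !is_transport, is_drug = FALSE,
      stringsAsFactors = FALSE)
    rid
  }

  plant_link <- function(pathway_id, u, d) {
    ur <- env$reactions[[u]]; dr <- env$reactions[[d]]
    dcat <- led_rxn[[which(vapply(led_rxn, function(x) x$id, "") == d)]]
    allowed <- c("step_only", "regulation_pos", "regulation_neg")
    if (dcat$category %in% c("catalyzed", "binding")) {
      allowed <- c(allowed, "output_is_input")
    }
    if (dcat$category == "catalyzed") {
      allowed <- c(allowed, "output_is_catalyst")
    }
    basis <- sample(allowed, 1)
    if (basis == "output_is_input") {
      # reuse an upstream output as an extra downstream input
      env$reactions[[d]]$inputs <- c(env$reactions[[d]]$inputs,
                                     ur$outputs[[1]])
    } else if (basis == "output_is_catalyst") {
      # replace the downstream catalyst with an upstream output: make the
      # upstream reaction produce the downstream catalyst
      ctl <- Filter(function(c) c$control_type == "catalysis",
                    env$reactions[[d]]$controls)[[1]]
      env$reactions[[u]]$outputs <- c(env$reactions[[u]]$outputs,
                                      ctl$controller)
    } else if (basis %in% c("regulation_pos", "regulation_neg")) {
      ctype <- if (basis == "regulation_pos") "activation" else "inhibition"
      reg <- ur$outputs[[1]]
      cid <- paste0(d, "_reg_", u)
      env$reactions[[d]]$controls <- c(
        env$reactions[[d]]$controls,
        list(biopax_control(reg, d, ctype, cid)))
      led_ctl[[length(led_ctl) + 1L]] <<- data.frame(
        control_id = cid, reaction = d, type = ctype, standalone = FALSE,
        stringsAsFactors = FALSE)
    }
    relation <- switch(basis,
      step_only = "RO:0002411",
      output_is_input = "RO:0002413",
      output_is_catalyst = "RO:0002413",
      regulation_pos = "RO:0002629",
      regulation_neg = "RO:0002630")
    led_link[[length(led_link) + 1L]] <<- data.frame(
      pathway = pathway_id, from = u, to = d, basis = basis,
      relation = relation, stringsAsFactors = FALSE)
  }

  make_pathway <- function(pid, disease = FALSE) {
    env$pw_loc <- pick_loc()
    has_bp <- stats::runif(1) < spec$frac_bp
    cats <- rep(names(mix), times = mix)
    rids <- vapply(cats, make_reaction, "", pathway_id = pid)
    rids <- unname(rids)
    for (k in seq_len(max(length(rids) - 1L, 0))) {
      plant_link(pid, rids[k], rids[k + 1L])
    }
    # drug reaction appended to the chain on request
    is_drug_pw <- FALSE
    if (env$drugs_left > 0L && !disease) {
      env$drugs_left <- env$drugs_left - 1L
      drug_ent <- new_id()
      add_entity(physical_entity(
        drug_ent, paste0("test drug ", env$e_ctr, " (synthetic)"),
        kind = "small_molecule",
        reference_xrefs = c(sprintf("CHEBI:%06d", 900000L + env$e_ctr),
                            sprintf("DrugBank:DBTST%04d", env$e_ctr)),
        location_term = .fixture_locations[1],
        location_label = .fixture_location_labels[1]))
      did <- new_rxn_id()
      dr <- biopax_reaction(did, paste0("drug reaction ", did),
                            inputs = c(drug_ent, new_sm(.fixture_locations[1])),
                            outputs = new_sm(.fixture_locations[1]))
      dr$mf_xrefs <- new_mf()
      dr$controls <- list(biopax_control(new_protein(.fixture_locations[1]),
                                         did, "catalysis",
                                         paste0(did, "_cat")))
      env$reactions[[did]] <- dr
      led_rxn[[length(led_rxn) + 1L]] <<- data.frame(
        id = did, pathway = pid, category = "catalyzed",
        is_transport = FALSE, has_mf = TRUE, has_catalysis = TRUE,
        uniform_loc = TRUE, is_drug = TRUE, stringsAsFactors = FALSE)
      if (length(rids)) {
        led_link[[length(led_link) + 1L]] <<- data.frame(
          pathway = pid, from = rids[length(rids)], to = did,
          basis = "step_only", relation = "RO:0002411",
          stringsAsFactors = FALSE)
      }
      rids <- c(rids, did)
    }
    links <- Filter(function(x) x$pathway == pid, led_link)
    env$pathways[[pid]] <- biopax_pathway(
      pid, paste0("test pathway ", pid), step_reactions = rids,
      next_steps = lapply(links, function(l) c(l$from, l$to)),
      bp_xrefs = if (has_bp) sprintf("GO:%07d", 1900000L +
                                       length(env$pathways) + 1L)
                 else character(),
      is_disease = FALSE
    )
    led_pw[[length(led_pw) + 1L]] <<- data.frame(
      id = pid, has_bp = has_bp, is_disease = disease,
      stringsAsFactors = FALSE)
    pid
  }

  env$drugs_left <- spec$n_drug_reactions
  env$regs_left <- spec$n_noncatalytic_controls

  for (k in seq_len(spec$n_pathways)) {
    make_pathway(sprintf("P-TST-%03d", k))
  }
  if (spec$n_disease_pathways > 0) {
    dids <- vapply(seq_len(spec$n_disease_pathways), function(k) {
      make_pathway(sprintf("P-TST-DIS-%03d", k), disease = TRUE)
    }, "")
    env$pathways[["P-TST-DISEASE-ROOT"]] <- biopax_pathway(
      "P-TST-DISEASE-ROOT", "Disease (synthetic root)",
      subpathways = dids, is_disease = FALSE
    )
    led_pw[[length(led_pw) + 1L]] <- data.frame(
      id = "P-TST-DISEASE-ROOT", has_bp = FALSE, is_disease = TRUE,
      stringsAsFactors = FALSE)
  }

  # free-standing regulators on normal-biology, non-drug reactions
  led_rxn_df <- do.call(rbind, led_rxn)
  eligible <- led_rxn_df$id[!led_rxn_df$is_drug &
                              !grepl("^P-TST-DIS", led_rxn_df$pathway)]
  n_regs <- min(spec$n_noncatalytic_controls, length(eligible))
  if (n_regs > 0) {
    tgts <- sample(eligible, n_regs, replace = FALSE)
    for (tgt in tgts) {
      reg <- new_protein(pick_loc())
      ctype <- if (stats::runif(1) < spec$activation_fraction)
        "activation" else "inhibition"
      cid <- paste0(tgt, "_reg_standalone")
      env$reactions[[tgt]]$controls <- c(
        env$reactions[[tgt]]$controls,
        list(biopax_control(reg, tgt, ctype, cid)))
      led_ctl[[length(led_ctl) + 1L]] <- data.frame(
        control_id = cid, reaction = tgt, type = ctype, standalone = TRUE,
        stringsAsFactors = FALSE)
    }
  }

  collection <- pathway_collection(
    pathways = unname(env$pathways),
    reactions = unname(env$reactions),
    entities = unname(env$entities),
    source_version = paste0("gocamr synthetic corpus (seed ", spec$seed, ")")
  )

  # recompute the uniform-location truth from the final entity table
  # (basis planting can add participants and change it)
  led_rxn_df$uniform_loc <- vapply(led_rxn_df$id, function(rid) {
    r <- env$reactions[[rid]]
    cat_ctl <- vapply(Filter(function(c) c$control_type == "catalysis",
                             r$controls), `[[`, "", "controller")
    parts <- c(r$inputs, r$outputs, cat_ctl)
    locs <- vapply(parts, function(p) {
      e <- env$entities[[p]]
      if (is.null(e)) NA_character_ else e$location_term
    }, character(1))
    length(parts) > 0 && length(unique(locs)) == 1 && !anyNA(locs)
  }, logical(1))

  ledger <- list(
    pathways = do.call(rbind, led_pw),
    reactions = led_rxn_df,
    links = if (length(led_link)) do.call(rbind, led_link) else
      data.frame(pathway = character(), from = character(),
                 to = character(), basis = character(),
                 relation = character(), stringsAsFactors = FALSE),
    controls = if (length(led_ctl)) do.call(rbind, led_ctl) else
      data.frame(control_id = character(), reaction = character(),
                 type = character(), standalone = logical(),
                 stringsAsFactors = FALSE),
    counts = list(n_entities = length(env$entities),
                  n_reactions = length(env$reactions),
                  n_pathways = length(env$pathways))
  )
  document <- write_biopax(collection)
  validate_fixture_ledger(collection, ledger)
  list(document = document, collection = collection, ledger = ledger,
       spec = spec)
}

# internal self-check: the ledger must agree with the emitted document
validate_fixture_ledger <- function(collection, ledger) {
  stopifnot(
    nrow(ledger$reactions) == length(collection$reactions),
    length(collection$pathways) == nrow(ledger$pathways),
    all(ledger$reactions$id %in% names(collection$reactions)),
    all(ledger$links$from %in% names(collection$reactions)),
    all(ledger$links$to %in% names(collection$reactions))
  )
  cl <- classify_collection(collection)
  for (k in seq_len(nrow(ledger$reactions))) {
    row <- ledger$reactions[k, ]
    got <- cl$reactions[[row$id]]$category
    if (got != row$category) {
      stop("fixture self-check failed: reaction ", row$id, " planted as ",
           row$category, " but classified as ", got)
    }
  }
  invisible(TRUE)
}

#' Write fixture files to a directory
#'
#' @param fx Result of [make_random_pathway_corpus()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written: the document, a JSON ledger and
#'   per-table TSVs.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  doc_path <- file.path(dir, "corpus.owl")
  writeLines(fx$document, doc_path, sep = "")
  ledger_json <- file.path(dir, "ledger.json")
  jsonlite::write_json(fx$ledger, ledger_json, auto_unbox = TRUE,
                       dataframe = "rows")
  paths <- c(doc_path, ledger_json)
  for (nm in c("pathways", "reactions", "links", "controls")) {
    p <- file.path(dir, paste0("ledger_", nm, ".tsv"))
    utils::write.table(fx$ledger[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Minimal edge-case documents
#'
#' One minimal BioPAX document per tricky structure: an entity-set catalyst,
#' a nested set, a complex enabler, a proteoform, a multi-location
#' (catalyzed) transport step, a black-box event, a noncatalytic inhibitor,
#' and a dangling step link (a chain whose second reaction involves a drug,
#' so filtering drops the link).  Each element carries an `expect` list with
#' the planted truth the corresponding test asserts.
#'
#' @return Named list; each element has `document` and `expect`.
#' @export
make_edge_case_suite <- function() {
  loc1 <- "GO:0005829"; lab1 <- "cytosol"
  loc2 <- "GO:0005634"; lab2 <- "nucleoplasm"
  prot <- function(id, acc, loc = loc1, lab = lab1, mods = character()) {
    physical_entity(id, id, kind = "protein",
                    reference_xrefs = paste0("UniProt:", acc),
                    location_term = loc, location_label = lab,
                    modifications = mods)
  }
  smol <- function(id, chebi, loc = loc1, lab = lab1) {
    physical_entity(id, id, kind = "small_molecule",
                    reference_xrefs = chebi,
                    location_term = loc, location_label = lab)
  }
  doc_of <- function(pathway, reactions, entities) {
    write_biopax(pathway_collection(
      pathways = list(pathway), reactions = reactions, entities = entities,
      source_version = "gocamr edge-case fixture"))
  }
  simple_rxn <- function(id, ins, outs, ctl = NULL, mf = character()) {
    r <- biopax_reaction(id, id, inputs = ins, outputs = outs, mf_xrefs = mf)
    if (!is.null(ctl)) r$controls <- list(ctl)
    r
  }
  chain_pathway <- function(rids, id = "P-TST-EDGE") {
    ns <- if (length(rids) > 1) {
      lapply(seq_len(length(rids) - 1), function(k) c(rids[k], rids[k + 1]))
    } else NULL
    biopax_pathway(id, id, step_reactions = rids, next_steps = ns,
                   bp_xrefs = "GO:1900001")
  }

  suite <- list()

  # entity set catalyst
  ents <- list(prot("P1", "TST00001"), prot("P2", "TST00002"),
               prot("P3", "TST00003"),
               physical_entity("SET1", "SET1", kind = "entity_set",
                               members = c("P1", "P2", "P3"),
                               location_term = loc1, location_label = lab1),
               smol("A", "CHEBI:900101"), smol("B", "CHEBI:900102"))
  r <- simple_rxn("R-TST-SET", "A", "B",
                  biopax_control("SET1", "R-TST-SET", "catalysis", "c1"),
                  mf = "GO:3000001")
  suite$set_catalyst <- list(
    document = doc_of(chain_pathway("R-TST-SET"), list(r), ents),
    expect = list(union_size = 3))

  # nested set: SETA = {P1, SETB}, SETB = {P2, P3} -> 3 leaves
  ents2 <- list(prot("P1", "TST00001"), prot("P2", "TST00002"),
                prot("P3", "TST00003"),
                physical_entity("SETB", "SETB", kind = "entity_set",
                                members = c("P2", "P3"),
                                location_term = loc1, location_label = lab1),
                physical_entity("SETA", "SETA", kind = "entity_set",
                                members = c("P1", "SETB"),
                                location_term = loc1, location_label = lab1),
                smol("A", "CHEBI:900101"), smol("B", "CHEBI:900102"))
  r2 <- simple_rxn("R-TST-NEST", "A", "B",
                   biopax_control("SETA", "R-TST-NEST", "catalysis", "c1"),
                   mf = "GO:3000001")
  suite$nested_set <- list(
    document = doc_of(chain_pathway("R-TST-NEST"), list(r2), ents2),
    expect = list(leaf_count = 3))

  # complex enabler
  ents3 <- list(prot("P1", "TST00001"), prot("P2", "TST00002"),
                physical_entity("CPLX", "CPLX", kind = "complex",
                                components = c("P1", "P2"),
                                location_term = loc1, location_label = lab1),
                smol("A", "CHEBI:900101"), smol("B", "CHEBI:900102"))
  r3 <- simple_rxn("R-TST-CPLX", "A", "B",
                   biopax_control("CPLX", "R-TST-CPLX", "catalysis", "c1"),
                   mf = "GO:3000001")
  suite$complex_enabler <- list(
    document = doc_of(chain_pathway("R-TST-CPLX"), list(r3), ents3),
    expect = list(component_count = 2))

  # proteoform: canonical + modified form sharing an accession
  ents4 <- list(prot("KIN", "TST00009"),
                prot("KIN_p", "TST00009", mods = "O-phospho-L-serine@42"),
                smol("A", "CHEBI:900101"), smol("B", "CHEBI:900102"))
  r4 <- simple_rxn("R-TST-PF", "A", "B",
                   biopax_control("KIN_p", "R-TST-PF", "catalysis", "c1"),
                   mf = "GO:3000001")
  suite$proteoform <- list(
    document = doc_of(chain_pathway("R-TST-PF"), list(r4), ents4),
    expect = list(accession = "UniProt:TST00009"))

  # catalyzed transport across three compartments (uptake-style)
  ents5 <- list(smol("X_out", "CHEBI:900110", "GO:0005576",
                     "extracellular region"),
                smol("X_in", "CHEBI:900110", loc1, lab1),
                prot("TRANSP", "TST00010", "GO:0005886", "plasma membrane"))
  r5 <- simple_rxn("R-TST-TRANS", "X_out", "X_in",
                   biopax_control("TRANSP", "R-TST-TRANS", "catalysis", "c1"),
                   mf = "GO:3000002")
  suite$multi_location_transport <- list(
    document = doc_of(chain_pathway("R-TST-TRANS"), list(r5), ents5),
    expect = list(from = "GO:0005576", to = loc1))

  # black box (gene-transcription shorthand): no inputs, no catalysis
  ents6 <- list(prot("NOTCH3", "TST00011", loc2, lab2))
  r6 <- simple_rxn("R-TST-BB", character(), "NOTCH3")
  suite$black_box <- list(
    document = doc_of(chain_pathway("R-TST-BB"), list(r6), ents6),
    expect = list(category = "black_box"))

  # noncatalytic inhibitor on a catalyzed reaction
  ents7 <- list(prot("ENZ", "TST00012"), prot("INHIB", "TST00013"),
                smol("A", "CHEBI:900101"), smol("B", "CHEBI:900102"))
  r7 <- simple_rxn("R-TST-INH", "A", "B",
                   biopax_control("ENZ", "R-TST-INH", "catalysis", "c1"),
                   mf = "GO:3000001")
  r7$controls <- c(r7$controls,
                   list(biopax_control("INHIB", "R-TST-INH", "inhibition",
                                       "c2")))
  suite$inhibitor <- list(
    document = doc_of(chain_pathway("R-TST-INH"), list(r7), ents7),
    expect = list(binding_nodes = 1, relation = "RO:0002630"))

  # dangling step link: r2 involves a drug, filtering drops the r1->r2 link
  ents8 <- list(smol("A", "CHEBI:900101"), smol("B", "CHEBI:900102"),
                smol("C", "CHEBI:900103"),
                physical_entity("DRUG", "DRUG (synthetic)",
                                kind = "small_molecule",
                                reference_xrefs = c("CHEBI:900104",
                                                    "DrugBank:DBTST0001"),
                                location_term = loc1, location_label = lab1),
                prot("ENZ1", "TST00014"), prot("ENZ2", "TST00015"))
  r8a <- simple_rxn("R-TST-D1", "A", "B",
                    biopax_control("ENZ1", "R-TST-D1", "catalysis", "c1"),
                    mf = "GO:3000001")
  r8b <- simple_rxn("R-TST-D2", c("B", "DRUG"), "C",
                    biopax_control("ENZ2", "R-TST-D2", "catalysis", "c2"),
                    mf = "GO:3000002")
  suite$dangling_link <- list(
    document = doc_of(chain_pathway(c("R-TST-D1", "R-TST-D2")),
                      list(r8a, r8b), ents8),
    expect = list(dropped_links = 1))

  suite
}
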