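---
title: "Converting process-description pathways to causal activity models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting process-description pathways to causal activity models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gocamr)
```

## The two representations

Reaction-centric pathway databases are *process descriptions*: a reaction
transforms input entity pools into output pools, with catalysts and
regulators attached, and a pathway is a directed network of such reactions.
GO-CAMs are *activity flows*: the node is a molecular activity (an instance
of a GO molecular function) enabled by a gene product or complex, and edges
are causal relations between activities.  `gocamr` maps one representation
onto the other reaction by reaction, on the premise that every conversion
event corresponds to a potential molecular activity.  Conversion is total
by design: a reaction that lacks attributes still yields an activity unit,
and the gaps are what the audit quantifies — incompleteness is a property
to be measured, not an error to be thrown.

## The activity unit and its attributes

A complete unit specifies: molecular function; enabler; inputs and outputs;
a single cellular location; membership in a biological process; and at
least one causal connection.  The extraction rules, and the choices behind
them where the mapping was genuinely open, are:

* **Molecular function.**  The first GO MF relationship cross-reference on
  the reaction wins; extra cross-references produce a warning rather than a
  depth heuristic, keeping the choice auditable.  Reactions with no MF fall
  through to the generated *molecular event* class — a superclass covering
  both gene-product-enabled functions and events whose enabler is
  unspecified (black-box events such as gene-transcription shorthand).  An
  optional inference step (`infer_transport_mf`, default off) assigns the
  generic transporter-activity term to transport-shaped reactions without a
  curated MF; it is off because conservative defaults make the audit a
  faithful census of source curation rather than of our guesses.
* **Enabler.**  The catalysis controller's class.  A set controller enables
  as the set's union class (any member can act); a complex controller
  enables as the complex class, always, with a `complex_enabler` flag on
  the unit — whether an activity is genuinely emergent on the complex
  rather than ascribable to one subunit is curatorial knowledge automation
  does not have, so the information-preserving choice is made and flagged.
* **Location.**  An activity may occur in only one location.  When every
  participant (inputs, outputs, catalysis controller) carries the same
  term, the activity gets it; any disagreement — e.g. uptake of an
  extracellular molecule spanning extracellular space, membrane and
  cytosol — yields no activity location, but every participant keeps its
  own location annotation, so no information is lost.  Transport-shaped
  reactions also record start and end locations from the input- and
  output-side terms.
* **Process.**  The immediate parent pathway's first GO BP
  cross-reference, else the root biological-process term.  Deliberately no
  upward search through grandparents: a reaction should inherit its own
  pathway's curation gap, which is exactly what the root-BP census in the
  audit measures.
* **Causal edges.**  See below.

## Reaction classification

Categories are assigned by ordered shape rules: catalysis present ⇒
`catalyzed` (with a transport flag when an input and output share a
reference cross-reference but differ in location — catalyzed transporters
stay `catalyzed` so MF and enabler are still extracted); otherwise missing
inputs or outputs ⇒ `black_box`; more inputs than outputs with a complex
product ⇒ `binding`; the mirror image ⇒ `dissociation`; equal counts with
differing locations ⇒ `transport`; else `other`.  Stoichiometry is ignored
throughout — the exports we target do not mark it in a way that would
change these shapes.

## The generated entity ontology

Classes are minted only where no standard class serves: small molecules
with ChEBI cross-references map to ChEBI itself, and location never enters
class identity (the source convention of minting one entity per
entity-location combination is deliberately collapsed; location lives on
instances).  Proteoform identity is the pair (accession, modification
set) — two entities with the same accession and the same modifications
share one class, a subclass of the canonical protein's class, preventing
class explosion while keeping modified forms distinct.  Complexes are named
classes with has-part links to component classes rather than full
intersection expressions: GO-CAM consumes named classes, and the logical
detail is kept in the definition text.  Sets are unions over recursively
flattened members; nesting flattens to leaves because union-of-union and
flat union have the same "any member can act" semantics.  Minted IRIs
derive from source stable identifiers, not UUIDs, so output is
byte-reproducible.  Gene-product-like classes root under the information
biomacromolecule class (CHEBI:33695).

## Causal relations

Each step link becomes exactly one of four relations by ordered tests on
entity overlap (upstream outputs vs downstream inputs/controllers):
regulation (positive, then negative), then provides-input (downstream input
*or* downstream catalyst), then plain causal ordering.  Three decisions
matter here:

* **Precedence**: regulation outranks provides-input when both hold,
  because it is the more specific biological assertion.
* **Overlap is class-level and location-stripped**: cytosolic and nuclear
  pools of one metabolite match.  Matching located entities instead would
  block biologically real links exactly where compartments change.
* **Union expansion**: a set class matches if any member matches.

Step links whose endpoint was filtered away (disease pathway, drug
reaction) are dropped *and counted*; the partition `relation counts +
dropped = step links` is asserted over every corpus.  Noncatalytic
regulators not already realized as regulation edges become binding activity
nodes (default function: the root GO binding term, configurable) with a
regulation edge to their target.

## Serialization and determinism

Models are OWL instance graphs in Turtle: every individual has exactly one
asserted type, every edge relation comes from a closed vocabulary, and
every asserted edge carries an axiom-annotation with a configurable ECO
class (default ECO:0000363, computational inference in automatic assertion)
and the source reaction's identifier as reference.  Individual IRIs are
`model-IRI/NNNNNN` with a strictly increasing ordinal; triples are emitted
in lexicographic order; no blank nodes are used (union lists in the entity
ontology get minted list-node IRIs).  Consequences: identical inputs give
byte-identical files, write→read→write is a byte fixed point, and graph
isomorphism reduces to triple-set equality.  Model IRIs use pathway *core*
identifiers (release suffixes stripped), one `.ttl` per pathway; a pathway
containing only subpathways is a single process node.

## The synthetic corpus generator

No pathway export is bundled; every test input is generated.  The generator
emulates the structures that drive the conversion: catalyzed reactions (a
configurable minority with set, complex or proteoform catalysts), catalyzed
transport (same cargo, two compartments), binding (two inputs, one complex
product), dissociation, black-box events, linearly chained step links with
*planted causal bases*, free-standing regulators, disease-branch pathways
and drug reactions.  Defaults (per pathway: 3 catalyzed, 1 transport, 1
binding, 1 dissociation, 1 black-box; 70% MF coverage on non-catalyzed
events; 60% pathway BP coverage; 50% single-location reactions) are fixed
study conditions chosen to exercise every audit category at realistic
rates, not tuning knobs.  Two conditions deserve justification:

* Catalyzed reactions always carry an MF cross-reference and a catalyst,
  mirroring source curation practice where enzymatic events are
  systematically classified; the MF gap rate applies to non-catalyzed
  events only.  This is what makes "all catalyzed/transport units have a
  real MF and enabler" a property of the corpus, as it is of the real one.
* Reactions reused across a chain share the pathway's location when planted
  as single-location, so basis planting cannot silently break planted
  location uniformity.

The generator emits a ledger of every planted truth and self-checks it
against the document (e.g. planted categories vs the classifier) before
returning.  Tests then compare pipeline output against brute-force
recomputation from the ledger — an oracle independent of the conversion
code paths.

What the generator does *not* emulate: the size distribution and topology
of real exports (branching step graphs, deeply nested subpathway trees),
cross-pathway entity reuse, curation idiosyncrasies (duplicate controls,
stoichiometric coefficients, generic-entity placeholders), and real
ontology term depth.  Passing tests therefore demonstrate that the rules
are implemented as specified and are internally consistent at corpus scale,
not that real-corpus censuses would be reproduced; those depend on the
pinned source release.

## Problem sizes and degenerate inputs

The suite runs corpora of 5–29 pathways (35–214 reactions), chosen so the
whole suite and the acceptance script finish in well under a minute while
every category, basis and filter path occurs many times; the acceptance
corpus is 200 reactions.  Degenerate inputs are defined, not errors: empty
documents give empty collections; a reaction with no participants is a
black box; a singleton set is a union of one; a pathway with no retained
steps emits an empty model with a warning; a missing disease root degrades
the filter to a warned no-op.

## Known limitations

* Identifying the enabling partner inside binding/dissociation events
  (e.g. ligand vs receptor) requires curation the input does not carry;
  such units legitimately lack enablers and dominate the incomplete census.
* Causal links *between* models (pathway-to-pathway) are out of scope, as
  the target formalism cannot yet represent them.
* No OWL reasoning is performed over the generated ontology or models;
  reasoning-based deepening of classifications is deliberately left to
  downstream consumers.
* Proteoform classes are keyed by accession and modification set, not
  reconciled against an external protein-form ontology.
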