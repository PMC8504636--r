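# gocamr

Convert BioPAX Level-3 pathway descriptions into GO-CAM causal activity
models.

## The problem

Pathway knowledgebases such as Reactome describe biology in a
*process-description* style: each reaction is a transformation of pools of
physical entities (small molecules, proteins, complexes), optionally
catalyzed or regulated by other entities, and reactions are chained into
pathways.  The Gene Ontology's causal activity models (GO-CAMs) use an
*activity-flow* style instead: the unit is a gene product's molecular
activity, and activities are linked by causal relations from the Relation
Ontology.  `gocamr` implements a rule-based conversion between the two, for
bioinformaticians who want standard GO-CAM models (and hence standard GO
annotations) out of BioPAX pathway content.

## The method

Each retained reaction becomes one **activity unit** with the attributes of
a complete GO-CAM node:

* a molecular function `F` (a curated GO MF cross-reference; otherwise the
  generated *molecular event* class),
* an enabler via `enabled_by` (RO:0002333): the catalysis controller's
  class — a protein, a complex, or a union class for an entity set,
* inputs/outputs via `has_input`/`has_output` (RO:0002233/0002234),
* a single location via `occurs_in` (BFO:0000066) when *all* participants
  share one cellular component — otherwise no activity location, with
  per-participant locations preserved (plus start/end locations for
  transport),
* a biological process via `part_of` (BFO:0000050): the parent pathway's GO
  BP term, or the root term when the pathway lacks one.

Entities with no standard-ontology class (complexes, entity sets,
proteoforms, modified/located forms) get classes in a generated entity
ontology: sets become unions (any member can act), proteoforms become
subclasses of the canonical protein's class, and small molecules with ChEBI
cross-references map to ChEBI directly, so cytosolic and nuclear pools of
one metabolite share a class.

Every pathway step link becomes exactly one of four causal relations,
decided by entity overlap between the upstream activity's outputs and the
downstream activity's inputs and controllers:

| condition (ordered)                                   | relation |
|-------------------------------------------------------|----------|
| upstream output noncatalytically activates downstream  | `directly positively regulates` (RO:0002629) |
| upstream output noncatalytically inhibits downstream   | `directly negatively regulates` (RO:0002630) |
| upstream output is a downstream input or its catalyst  | `directly provides input for` (RO:0002413) |
| otherwise                                              | `causally upstream of` (RO:0002411) |

Remaining noncatalytic regulators become *binding* activity nodes with a
regulation edge to their target.  Models are serialized as OWL instance
graphs in Turtle (deterministic IRIs, sorted triples, ECO-annotated edges),
and an audit reports per-activity completeness (function, enabler,
location, causal connection, specific process) and the corpus-level
relation census.

## Worked example

The bundled worked-example fixture contains the reaction "CRYM reduces P2C
to PPCA" from the lysine catabolism pathway, plus a downstream step
consuming its product:

```r
library(gocamr)
cfg <- gocam_config(disease_roots = character())
col <- filter_collection(parse_biopax(make_crym_fixture()), cfg)
models <- convert_collection(col, config = cfg)
print(models[["R-HSA-71064"]]$activities[[1]])
#> <activity_unit> R-HSA-5693347
#>   function: GO:0047127  enabled by: REACTO:Protein_CRYM
#>   inputs: 3  outputs: 2  location: GO:0005782
#>   process: GO:0006554
print(audit_collection(models))
#> <audit_summary>
#>   activity units (reactions): 2
#>   complete: 2   incomplete: 0
#>   root-BP units: 0
#>   binding events: 0   dissociation events: 0
#>   step links: 1 (dropped: 0)
#>     causally_upstream_of (RO:0002411): 0
#>     directly_provides_input_for (RO:0002413): 1
#>     directly_positively_regulates (RO:0002629): 0
#>     directly_negatively_regulates (RO:0002630): 0
```

The CRYM reaction converts to a *complete* activity unit — typed by its
curated dehydrogenase activity (GO:0047127), enabled by the CRYM protein
class, occurring in the peroxisomal matrix (GO:0005782), part of lysine
catabolism (GO:0006554), with its three substrates and two products
attached — and the two activities are linked by a single `directly
provides input for` edge because PPCA, the upstream product, is the
downstream substrate.  `write_gocam()` serializes the model to Turtle;
`write_entity_ontology()` emits the generated entity ontology.

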