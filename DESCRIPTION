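Package: gocamr
Title: Convert BioPAX Level-3 Pathway Descriptions into GO-CAM Causal
    Activity Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts process-description pathway documents in the BioPAX
    Level-3 exchange format (as exported by the Reactome Knowledgebase)
    into Gene Ontology Causal Activity Models (GO-CAMs), the activity-flow
    representation used by the GO Consortium.  Each biochemical reaction
    becomes a GO-CAM activity unit (molecular function, enabler, inputs,
    outputs, cellular location, biological process); pathway step links
    become Relation Ontology causal edges; physical entities without a
    standard ontology class (complexes, entity sets, proteoforms) are
    given classes in a generated entity ontology.  Models are serialized
    as OWL instance graphs in Turtle.  Includes corpus filtering (disease
    branch, drug reactions), a completeness audit of converted activity
    units, and a synthetic BioPAX fixture generator for fully offline
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
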