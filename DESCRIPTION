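Package: salonr
Title: Semantic Representation, Validation and Enrichment of Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Represents pairwise and multiple sequence alignments under the
    SALON vocabulary (<https://w3id.org/salon>). Parses MACSIM XML (BAliBASE
    dialect) and FASTA files with UniProtKB/NCBI description-line dialects into
    a typed S4 alignment model, maps the model to RDF triples with Turtle,
    RDF/XML, N-Triples and JSON-LD serializations, computes column and
    alignment score functions (column entropy, percent totally-conserved
    columns, percent non-gaps), validates alignments against score-bound and
    cardinality rules with reliability-based column flagging, builds federated
    SPARQL enrichment queries against UniProtKB, and generates standardized
    FASTA description lines. Includes a seeded synthetic alignment generator
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    xml2,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'schema-registry.R'
    'alignment-model.R'
    'fasta-io.R'
    'macsim-io.R'
    'rdf-graph.R'
    'rdf-mapping.R'
    'scoring.R'
    'validation.R'
    'enrichment.R'
    'fixtures.R'
    'cli.R'
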