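Package: dnmso
Title: De Novo Mass Spectrometry Ontology Documents for Peptide Sequencing Results
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ontology-backed container format for de novo peptide sequencing
    results from tandem mass spectrometry. Provides the full peptide-spectrum-match
    data model (spectra, predictions, sequences with amino acids, modified amino
    acids and mass gaps, multiple scores, PSI-MOD referenced modifications),
    rule-based validation of its structural invariants, spectra ingestion from
    MGF, mzML and mzXML, converters from legacy de novo tool outputs (PepNovo,
    Lutefisk, DNML, pepXML, PEAKS-style CSV), deterministic round-trip RDF
    serialization (Turtle, RDF/XML, JSON-LD) with a SPARQL SELECT engine,
    score-threshold filtering, cross-tool consensus prediction, and lossy export
    to mzIdentML.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
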