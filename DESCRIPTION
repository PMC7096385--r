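Package: chebimap
Title: Ontology-Based Matching of Lipidomics Data onto Genome-Scale Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Matches experimentally measured lipids and metabolites onto the
    metabolites of a genome-scale metabolic network. Exact matching by
    normalized name and by ChEBI identifier is complemented by an
    ontology-based matcher that traverses the ChEBI "is a" hierarchy and
    computes a signed semantic distance (negative toward more specific
    species, positive toward more generic classes), with small penalties for
    crossing conjugate acid/base (0.1) and tautomer (0.01) relationships.
    Includes an SBML reader harvesting ChEBI annotations, compartment
    de-duplication and census utilities, extraction of a reduced subnetwork
    as the union of lightest paths under squared-degree node weights, a
    brute-force path enumerator used as an independent oracle, and fixture
    generators for reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
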