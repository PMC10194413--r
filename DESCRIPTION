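Package: sysmapr
Title: Building, Merging and Simplifying Participatory Causal System Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for participatory systems mapping with signed directed
    graphs ('causal maps') as elicited from subject-matter experts in
    one-on-one interviews. Reads individual maps from signed edge lists or
    MentalModeler-style adjacency matrices, validates their structure (node
    typology, diameter, feedback loops, density), canonicalizes concept
    labels through a curated thesaurus, aggregates a panel of maps into one
    combined map with per-expert provenance, simplifies the result by
    endpoint pruning and sign-preserving contraction of pass-through chains,
    and reports a structural census. Includes a seeded generator of
    synthetic expert maps and panels with realistic lexical variation for
    testing every stage without interview data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    xml2,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
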