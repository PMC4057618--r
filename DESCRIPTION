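Package: orthoflux
Title: Ortholog-Guided Flux Balance Analysis of Active-Site Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the phenotypic impact of human active-site
    nonsynonymous variants through their yeast orthologs. Detects reciprocal
    best-hit ortholog pairs between two proteomes from pairwise alignment
    hits, maps annotated active-site residues through gapped alignments and
    scores their conservation, applies a candidate-selection cascade
    (single-pathway/single-reaction enzymes, ortholog intersection,
    active-site conservation, paralog exclusion, pathway chemistry
    comparison), and simulates loss-of-function knockouts in genome-scale
    metabolic models by flux balance analysis with taxicab-norm flux
    minimization and an augmentable biomass objective. Includes deterministic
    generators for planted-ortholog proteomes and hand-solvable toy metabolic
    models, plus curated annotation tables for 34 human enzymes with
    active-site variants and their yeast orthologs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
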