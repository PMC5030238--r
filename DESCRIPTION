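Package: neuroconn
Title: Rule-Based Extraction of Directed Brain-Region Connectivity from Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A knowledge-based pipeline for mining directed neuroanatomical
    connectivity relations between brain regions from neuroscience text.
    Sentences are nominated by trigger patterns over connectivity keywords
    ("projects to", "receives input from", ...), the related brain-region
    arguments are located with rules over constituency and dependency parse
    trees, mentions are normalized against a brain-region dictionary, and
    the directionality of each projection (agent region to target region)
    is read off the matched pattern. Extracted relations are scored against
    gold-standard annotations (strict, lenient, and NLP-based modes) and
    assembled into a directed connectivity multigraph with edge-betweenness
    scores and degree rankings. Includes readers for interaction-annotated
    corpora in the unified interaction XML dialect, bracketed constituency
    trees and typed dependency triples, a Schwartz-Hearst abbreviation
    expander, and a deterministic synthetic fixture-corpus generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
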