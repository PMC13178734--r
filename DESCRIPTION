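Package: medstars
Title: Entity-Centric Exploration of Medical Text Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multilevel, entity-centric exploration of medical text
    corpora. Extracts typed medical entities (nine classes: disease, symptom,
    drug, equipment, procedure, body, examination item, microorganism,
    department) per paragraph with a gazetteer matcher, embeds text with a
    deterministic hashed term-frequency model, clusters documents into topics
    with class-based TF-IDF keywords and a topic-diversity score, builds
    document- and paragraph-level similarity graphs, partitions paragraphs
    into size-capped constellations with a Kernighan-Lin refined bisection
    partitioner, lays constellations out under a multi-force model anchored to
    nine entity-class poles, groups entity sets sharing entities into an
    association tree, and computes focused co-occurrence profiles. All views
    export as validated JSON. Includes a seeded synthetic clinical-note
    generator with planted ground truth for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
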