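Package: kbmatch
Title: Clinical Variant Knowledgebase Matching, Caching and Export Toolkit
Version: 0.1.0
Authors@R: person("KB", "Match Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A self-contained toolkit for working with snapshots of a
    clinical variant knowledgebase: a linked record model (genes, variants,
    evidence items, assertions) parsed from JSON snapshot files, a local
    cache with time-based expiration, a sorted variant coordinate index
    answering bulk interval queries under four match modes via a two-pointer
    merge, a VCF 4.2 exporter that encodes clinical statements as CSQ
    annotations, and a cohort summarizer that classifies tumor samples by
    match class and highest matched evidence level. A synthetic snapshot and
    cohort generator with known ground truth makes every component testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
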