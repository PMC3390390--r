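Package: slapr
Title: Semantic Link Association Prediction on Heterogeneous Drug-Target Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the association between a drug and a protein target in a
    typed heterogeneous network (compounds, targets, GO terms, pathways,
    substructures, tissues, side effects, diseases) by enumerating bounded-length
    simple paths, scoring each path by its degree-normalized traversal
    log-probability, z-normalizing path scores within semantic path patterns
    (meta-paths) against a random-pair sample, and summing valid-path z scores
    into an association score with a log-normal p-value. Includes meta-path
    informativeness filtering by standalone AUROC, benchmarking against simple
    topological baselines, polypharmacology profile (drug x target score matrix)
    similarity networks, and a seeded generator of synthetic heterogeneous
    networks with planted associations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
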