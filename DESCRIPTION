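Package: ssnet
Title: Single-Source Probabilistic Functional Integrated Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds probabilistic functional integrated networks (PFINs) from a
    single curated interaction database without an external Gold Standard.
    High-throughput studies are scored by log-likelihood against the pooled
    low-throughput data; low-throughput experimental types are scored
    iteratively against each other (leave-one-type-out); all evidence is then
    combined with a rank-decay weighted sum into one confidence-weighted
    network. Includes BioGRID tab-format parsing, Gene Ontology (OBO/GAF)
    annotation propagation, pathway- and GO-derived comparison Gold Standards,
    leave-one-out function prediction with Maximum Weight ROC evaluation and
    Wilcoxon standard errors, network topology statistics, native Markov
    clustering, and a synthetic interactome generator with planted ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
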