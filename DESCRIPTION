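Package: toxalert
Title: Explainable Mining of Structural Alerts for Endocrine Disruption
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An explainable machine-learning workflow for discovering
    structural alerts (toxicophores) associated with endocrine disruption.
    Curates binary-labelled SMILES datasets, computes 1024-bit
    extended-connectivity fingerprints with full bit-to-atom-environment
    bookkeeping, trains random-forest probability classifiers per
    nuclear-receptor task, explains individual predictions with a locally
    fitted perturbation surrogate over fingerprint bits, maps influential
    bits back to molecular substructures, and aggregates them into ranked
    toxic-alert tables. Includes a synthetic-molecule generator with
    planted alert substructures so the entire pipeline can be exercised
    and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    igraph,
    jsonlite,
    ranger,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
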