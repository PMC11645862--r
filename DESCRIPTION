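Package: foldscreen
Title: Interface Confidence Scoring and Composite Assembly for Predicted
    Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for triaging predicted multi-chain protein complex
    structures. Extracts confident inter-chain residue contacts from
    predicted models using per-residue pLDDT and pairwise predicted
    aligned error (PAE) filters, summarises interface confidence
    (average interface pLDDT and PAE, ensemble model-agreement score,
    pDockQ), applies published confidence thresholds, and ranks
    many-pair in-silico interaction screens. Also provides
    anchored rigid-body superposition (Kabsch), sequential composite
    model assembly, steric clash censuses, and named-atom distance
    measurements, plus a deterministic synthetic-data generator so the
    whole pipeline is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
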