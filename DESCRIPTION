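Package: synthzoo
Title: A Metadata-Driven Zoo of Generative Models for Medical Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A registry, search and ranking, execution, contribution, and
    latent-exploration toolkit for pretrained generative models of medical
    images, together with an evaluation suite implementing the Frechet
    distance between Gaussian feature summaries, the Frechet inception
    distance (FID) under configurable normalization and pluggable feature
    extractors, the real-real lower bound FIDrr, and the FID ratio rFID.
    Models are described by a single JSON metadata file with execution,
    selection, and description sections; model packages are resolved lazily,
    imported, and run through a standardized generate interface with chunked
    batching and deterministic seeding. Ships procedural fixture models and a
    deterministic toy feature extractor so the full stack is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
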