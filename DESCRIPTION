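Package: pentrack
Title: Fixed-Cardinality Tracking and Identification of Group-Housed Animals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Long-term tracking of a fixed number of animals housed in a pen,
    from imperfect per-frame keypoint detections. Builds exactly N continuous
    shoulder-tail tracks per frame by cost-based pruning, bidirectional
    duplication and time-weighted interpolation; fuses intermittent ear-tag
    classification evidence into per-slot identity likelihoods; and resolves
    per-frame identities with an underflow-safe forward-backward smoother
    followed by Hungarian assignment. Includes a synthetic detection
    generator with configurable dropout, false positives and tag confusion,
    evaluation by mutual-nearest matching gated on body length, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
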