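Package: emgctl
Title: Simulation of an Embedded Myoelectric Prosthetic-Hand Controller
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulation of a wearable surface-EMG prosthetic hand
    controller: a synthetic 4-channel EMG-envelope generator following a
    contraction/rest session protocol, an embedded-style one-vs-one RBF
    support vector machine with a packed flash-image model format and
    memory-footprint accounting, a finite-state-machine control strategy
    with spike removal, temporal majority voting and open-hand reset logic,
    a gateway-to-node model transfer protocol with per-packet checksums and
    stop-and-wait acknowledgements, and a gesture-level end-to-end
    evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
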