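Package: projectome
Title: Single-Neuron Axonal Projectome Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the brain-wide axonal output of single
    reconstructed neurons. Reads and validates SWC neuron reconstructions,
    computes per-neuron morphometrics (cable length, branch and terminal-tip
    counts, per structure class), annotates axonal cable against a voxel
    label volume with a region ontology, quantifies projection strength as
    the fraction of axonal length per brain region with an ipsilateral /
    contralateral decomposition, classifies intratelencephalic neurons into
    callosal (CPN) and associative (APN) projection classes, and produces
    group-level summary tables and two-sample comparisons. Includes a
    seeded synthetic-data generator that builds a two-hemisphere box atlas
    and grows IT-like morphologies with known ground-truth region
    allocations, so the whole pipeline can be exercised end to end against
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
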