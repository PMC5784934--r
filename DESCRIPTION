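Package: memcoh
Title: Episodic Memory Coherence Analysis and Attractor-Network Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the coherence of multi-element episodic
    memories. Implements the contingency-table dependency statistic (observed
    dependency D against Independent and Dependent model predictions with an
    episodic factor and a guessing floor), generators for person-location-object
    experiment schedules (simultaneous triples or overlapping pairs under
    person-last and person-first encoding orders with six-alternative
    forced-choice tests), a rate-coded recurrent attractor network with
    threshold-linear units, probabilistic Hebbian learning under a BCM-like
    postsynaptic threshold and emotion-modulated plasticity, and synthetic
    behavioural response generators with known ground-truth dependency
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
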