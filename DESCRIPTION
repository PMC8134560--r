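Package: flnet
Title: Task-Conditioned Functional Language Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds task-conditioned functional brain networks from
    block-design BOLD fMRI: activation mapping (hemodynamic-response
    cross-correlation, voxel-wise significance, signal-stability exclusion,
    cluster-extent family-wise-error correction), voxel- and fROI-scale
    network construction, group-level common networks with link frequencies
    and a named link-weight hierarchy, and k-shell decomposition with
    normalized shell-occupancy histograms per module and sum-of-squared-error
    comparisons between groups. Includes a seeded synthetic multi-subject
    BOLD generator with planted active regions and a controllable
    inter-region coupling structure so the whole pipeline is testable end to
    end without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
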