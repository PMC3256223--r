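Package: miRpetri
Title: Hybrid Petri-Net Modeling of miRNA Regulation in the EGFR Signaling Pathway
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds biochemical Petri-net models of growth-factor signaling
    networks with embedded microRNA regulation, simulates them with a
    discrete-time hybrid firing rule with multi-timescale decay, and runs
    in-silico perturbation studies: miRNA over-expression with log2-ratio
    heatmaps, dose-response scans, receptor activation-threshold scans, and
    anti-miRNA inhibitor screens ranked by paired t-test significance.
    Includes motif-based model construction from miRNA-target tables and
    pathway configurations, SBML import/export, a curated desk-scale fixture
    of the EGFR/PI3K-AKT/MEK-ERK cascade, and seeded random-network
    generators for property-based validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    grid,
    yaml,
    xml2,
    jsonlite,
    ggplot2,
    pheatmap
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
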