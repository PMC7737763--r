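Package: chainview
Title: Per-Residue Protein Model Validation with Radial Chain-View Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-residue validation metrics for protein models
    (B-factor statistics, backbone torsions with Ramachandran probability and
    classification, continuous and discrete rotamer scoring against a
    compressed bit-packed contour-grid library, and real-space electron
    density fit scores from structure-factor synthesis), normalizes them with
    a resolution-binned integer-percentile library, collates two model
    iterations by pairwise sequence alignment, and renders a compact
    interactive radial chain-view and residue-view report as SVG embedded in
    a single HTML file. Includes seeded generators for synthetic models,
    maps, and reference libraries so the full pipeline runs without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    Biostrings,
    optparse,
    yaml
Config/testthat/edition: 3
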