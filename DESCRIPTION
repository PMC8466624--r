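Package: vhhpb
Title: Protein Block Assessment of Nanobody Comparative Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assessment toolkit for comparative (homology) models of camelid
    single-domain antibody variable domains (VHH, nanobodies). Implements the
    16-letter Protein Blocks (PB) structural alphabet assigned from backbone
    phi/psi dihedrals, per-position ensemble statistics (PB frequency
    profiles, the Neq effective number of PBs, delta-Neq and delta-PB profile
    distances, PB maps), least-squares Calpha superposition with global and
    region-wise RMSD, CDR loop-termini geometry, framework/CDR region
    annotation, pairwise global alignment with the four classical
    template-selection scenarios, and an internal-coordinate synthetic
    backbone-ensemble generator with position-dependent von Mises angular
    noise so the full analysis is testable without external structures or a
    modeling engine.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
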