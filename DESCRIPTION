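Package: g4integrity
Title: Structural Integrity Analysis of Guanine Quadruplexes with Strand-Break Damage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to assess the structural integrity of guanine-quadruplex
    (G4) DNA in the presence of backbone strand-break lesions. Models
    canonical (5'-PO4/3'-OH) and non-canonical (5'-OH/3'-PO4) breaks on the
    human telomeric sequence and enumerates damage configurations in a
    star-notation scheme; reads and writes multi-model PDB conformational
    ensembles; detects guanine tetrads from Hoogsteen hydrogen-bond geometry
    and orders them along the channel axis; computes a descriptor suite
    (tetrad centre-of-mass distances, intra-tetrad guanine angles,
    inter-tetrad twist, Kabsch-superposed RMSD series and 2D-RMSD maps);
    tracks channel cation occupancy and leakage; and aggregates everything
    into a per-structure stability verdict. A synthetic-data module builds
    ideal three-tetrad parallel G4 models and stochastic ensembles with a
    rigid core, flexible loops, axial cations and optional injected
    destabilization events, so the whole pipeline is testable without
    molecular-dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
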