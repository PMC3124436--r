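Package: hemescan
Title: Prediction of Heme-Binding Residues from Protein Structure and
    Sequence Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Per-residue prediction of heme-binding sites in protein
    structures.  Computes structure-derived descriptors (relative solvent
    accessibility by a Shrake-Rupley rolling probe, residue depth index,
    protrusion index) and evolutionary conservation from PSI-BLAST
    position-specific scoring matrices, encodes residues through spatial
    and sliding windows, trains radial-basis-function support vector
    machines with balanced sampling and chain-level cross-validation,
    and refines calls with a spatial false-positive filter and a
    structure/sequence voting ensemble.  Includes a generator of
    self-contained synthetic heme-protein complexes and profiles for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
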