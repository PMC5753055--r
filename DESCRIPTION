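Package: strandscope
Title: Beta-Strand Propensity Analysis of Short Peptide Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Conformational analysis toolkit for short peptides, built around
    CF3-threonine-containing pentapeptides and their natural Ser/Thr
    analogues. Generates backbone dihedral ensembles from a two-basin
    (alpha/beta) wrapped-Gaussian mixture model, builds idealized backbone
    coordinates, and computes the descriptors used to call extended
    (beta-strand-like) structure: psi-basin probabilities and the global
    extension probability product, end-to-end distance distributions,
    ensemble-averaged 3J(HN-HA) couplings via a Karplus relation,
    neighbor-count ("gromos"/Daura) RMSD clustering, chemical shift
    deviations from random coil, amide temperature coefficients with
    hydrogen-bond classification, and chi1 rotamer calls from 3J(HA-HB).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
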