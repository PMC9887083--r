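Package: helixforge
Title: Generative Design of Full-Atom Alpha-Helices and D-Peptide Analogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for de novo design of full-atom alpha-helical peptides with a
    Wasserstein generative adversarial network trained on an internal-coordinate
    feature map (one-hot sequence plus backbone and side-chain torsions). Includes
    exact internal-coordinate to Cartesian reconstruction, mirror (L/D)
    transformation for D-peptide design, Kabsch superposition and partial-alignment
    RMSD, a constrained latent-space gradient search that matches user-specified
    hotspot residues in identity and conformation, an overlapping-fragment pipeline
    for designing long helical analogs, and corpus construction / quality
    assessment utilities with an external Rosetta scoring hook.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
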