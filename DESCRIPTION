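Package: pseudoatomES
Title: Electrostatic Interaction Energies from Transferable Aspherical Pseudoatoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs molecular charge densities from transferable
    Hansen-Coppens pseudoatom parameters and computes pairwise electrostatic
    interaction energies with a hybrid scheme: exact Coulomb integrals for
    close atom pairs and a Buckingham-type multipole expansion for distant
    pairs. The difference between the two defines the charge-penetration
    contribution. Includes multi-model PDB input/output, covalent
    connectivity perception and connectivity-based atom typing, a text
    format for pseudoatom parameter banks, residue/chain-level aggregation
    of energies, ensemble averaging over structural snapshots with mean(SD)
    reporting, hydrogen-bond occupancy profiling, a point-charge reference
    model, and generators for fully synthetic test systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
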