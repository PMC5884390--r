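Package: bdamage
Title: Detect Specific Radiation Damage in Protein Crystal Structures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies specific radiation damage in individual protein
    crystal structures from standard PDB or mmCIF coordinate files. Each
    atom's isotropic B factor is normalised by the mean B factor of atoms
    occupying a similar crystal-packing environment, yielding the per-atom
    B_Damage metric. Packing density is measured as the atomic contact
    number within a 7 Angstrom radius after expanding the asymmetric unit
    to a trimmed 3x3x3 assembly of unit cells via crystallographic
    symmetry. Includes kernel density summaries of the B_Damage
    distribution, a B_net summary statistic for damage-prone carboxyl
    sites, batch processing driven by a plain-text run-configuration file,
    and a generator of small synthetic crystal structures with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
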