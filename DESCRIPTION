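Package: toxsel
Title: Engineering Potassium-Channel Toxin Selectivity from Interface
    Contacts and Interaction Energies
Version: 0.1.0
Authors@R:
    person("toxsel", "maintainers", email = "toxsel@example.org",
           role = c("aut", "cre"))
Description: Tools for redesigning the channel selectivity of pore-blocking
    scorpion toxins (KTx) from structural models of their complexes with
    voltage-gated potassium (Kv1.x) channels. Reads structures and
    multi-model trajectories from PDB, grafts a toxin onto a channel-bound
    scaffold by rigid-body (Kabsch) superposition, fingerprints the
    toxin-channel interface frame by frame (hydrogen bonds, salt bridges,
    cation-pi, stacking and hydrophobic contacts with explicit geometric
    criteria), decomposes the short-range non-bonded interaction energy
    (Coulomb + Lennard-Jones, truncated at 1.5 nm) per residue pair,
    compares contact maps and energy profiles across channel isoforms to
    propose selectivity-switching point mutations (polar-contact residues
    to Ala, conserved repulsive acidic residues to Arg), and fits Hill
    concentration-response curves to obtain IC50s, Hill coefficients and
    pairwise selectivity factors. Ships deterministic synthetic-complex and
    dose-response generators with recorded ground truth so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
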