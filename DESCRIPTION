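Package: phorescreen
Title: Structure-Based Pharmacophore Screening and Drug-Likeness Triage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: In-silico triage of small-molecule libraries against an
    L-type voltage-gated calcium channel (L-VGCC) pharmacophore.
    Implements a molecular graph model with SMILES and SDF input,
    physicochemical descriptors (Ertl fragment-contribution TPSA,
    atom-contribution logP, hydrogen-bond donor/acceptor and
    rotatable-bond counts, estimated oral absorption), Lipinski
    rule-of-five filtering, rigid three-dimensional pharmacophore
    matching with exclusion volumes, and geometric annotation of
    docked protein-ligand poses (surrounding residues, hydrogen
    bonds, active-site contacts). Ships synthetic-data generators
    (feature-knockout decoys, perturbed conformers, toy binding
    pockets with planted hydrogen-bond geometry) so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
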