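# phorescreen

In-silico triage of small-molecule libraries for candidate blockers of the
L-type voltage-gated calcium channel (L-VGCC). The package takes compounds
as SMILES or SDF, computes the standard drug-likeness descriptor panel,
applies Lipinski's rule of five, matches each compound rigidly against a
six-feature 3D pharmacophore with exclusion volumes, and annotates
externally docked poses with surrounding residues, geometric hydrogen
bonds and active-site contacts. It is aimed at computational chemists who
want a scriptable, fully deterministic triage pipeline with every stage
testable offline.

## What it computes

**Descriptors.** For a molecule with polar atoms indexed by their Ertl
environment class \(e(i)\):

- TPSA \(= \sum_{i \in \mathrm{N,O}} c_{e(i)}\) (published fragment
  contributions; ±0.05 Å² reproduction of reference tables),
- logP \(= \sum_i a_{t(i)}\) over Wildman–Crippen atom types \(t(i)\),
- nON (all N+O), nOHNH (H on N/O), rotatable bonds (acyclic single bonds,
  both ends ≥2 heavy neighbors, amides excluded),
- estimated oral absorption %Ab \(= 109 - 0.345 \cdot \mathrm{TPSA}\).

**Rule of five.** MW ≤ 500, logP ≤ 5, nOHNH ≤ 5, nON ≤ 10 (inclusive
boundaries); compounds violating more than one rule are flagged.

**Pharmacophore matching.** Ligand features (donors, acceptors,
hydrophobic centroids) are perceived per conformer; an injective,
type-compatible assignment onto all six model features is searched by
backtracking with pairwise-distance pruning, scored by least-squares
rigid superposition (Kabsch), and accepted only if every aligned feature
falls within its tolerance sphere and no heavy atom enters an exclusion
volume. Matched compounds are ranked by fit RMSD.

**Pose annotation.** Heavy-atom contacts within 4.5 Å, hydrogen bonds at
≤ 3.5 Å and ≥ 120° D–H···A, and the overlap of the surrounding-residue
set with the packaged 32-residue channel-pore active site. Docked
energies are pass-through annotations, never computed.

## Worked example

```r
library(phorescreen)

lib <- fixture_library()              # the six reference compounds
descriptor_table(lib)[, c("id", "mw", "logp", "tpsa", "n_on",
                          "n_ohnh", "n_rotb", "pct_ab")]
#>             id     mw    logp   tpsa n_on n_ohnh n_rotb pct_ab
#> 1 Zinc67664832 437.90  2.1269 128.09    9      4     12 64.809
#> 2 Zinc20267861 485.36  2.8534 102.96    8      2     12 73.479
#> 3 Zinc18204217 501.74  3.7927 123.42    8      2      5 66.420
#> 4 Zinc38735350 469.97 -0.2119 138.37    9      7     14 61.262
#> 5 Zinc33254827 395.46  2.5424  82.45    7      1      6 80.555
#> 6   Amlodipine 409.89  1.5495 101.50    7      4     10 73.983
```

Each row is one compound: mass in g/mol on the protomer as drawn,
TPSA in Å², and the counts feeding the rule of five. The one compound
above 500 g/mol carries exactly one Lipinski violation:

```r
lipinski_report(descriptor_set(lib$Zinc18204217))
#> <RuleReport Zinc18204217: 1 violation(s) [MW<=500]>
```

Screening the amlodipine query against the shipped six-feature model
recovers it as a perfect hit (the model was realized from a deterministic
conformation of this very compound):

```r
run_screen(lib["Amlodipine"], reference_model(),
           screen_config(n_conformers = 5))
#> <HitTable: 1 compound(s), 1 ranked hit(s)>
#>           id    mw  tpsa n_violations matched phore_rmsd rank
#> 1 Amlodipine 409.9 101.5            0    TRUE  4.153e-15    1
```

Pose annotation on a synthetic pocket with known ground truth (5
residues in range, 3 ideal hydrogen bonds, 2 active-site members):

```r
pk <- generate_toy_pocket(5, 3, 2, seed = 7)
d <- tempfile(); write_toy_pocket(pk, d)
summarize_interactions(read_sdf(file.path(d, "pose.sdf"))[[1]],
                       read_protein(file.path(d, "pocket.pdb")),
                       load_active_site(file.path(d, "site.json")),
                       external_score = -8.1)
#> <InteractionTable: 5 surrounding residue(s), 3 H-bond(s),
#>  2 active-site interaction(s), external score -8.1 kcal/mol>
```

A command-line front end with `descriptors`, `lipinski`, `screen`,
`annotate` and `synth` subcommands lives at `inst/cli/phorescreen.R`.

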