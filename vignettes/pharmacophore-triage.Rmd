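---
title: "Methods: pharmacophore screening and drug-likeness triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacophore screening and drug-likeness triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phorescreen)
```

## Scope and model of the problem

`phorescreen` triages small-molecule libraries for candidate blockers of
the L-type voltage-gated calcium channel (L-VGCC). The triage has four
stages, each usable on its own:

1. **Molecular model** — an attributed graph (elements, formal charges,
   implicit hydrogens, aromaticity, ring membership) built from SMILES or
   SDF input.
2. **Physicochemical descriptors** — topological polar surface area
   (TPSA), an atom-contribution logP, hydrogen-bond donor/acceptor counts,
   rotatable bonds, molecular weight, and an estimated oral absorption.
3. **Drug-likeness** — Lipinski's rule of five with a configurable
   violation budget.
4. **3D pharmacophore matching** — a rigid, all-features match of
   perceived ligand features against a six-feature model with exclusion
   volumes; optionally followed by geometric annotation of externally
   docked poses (surrounding residues, hydrogen bonds, active-site
   contacts).

Docking itself, pocket detection, and machine-learned ADMET endpoints are
out of scope; docked poses and their binding energies are consumed as
annotations, never computed.

## Molecular model

Charged protomers are kept exactly as drawn: the amlodipine query is its
terminal ammonium cation, and two of the reference ZINC protomers are
anions. Molecular weight is the plain sum of conventional standard atomic
weights (C 12.011, H 1.008, N 14.007, O 15.999, Cl 35.453, S 32.06) over
all atoms including implicit hydrogens; this reproduces vendor catalogue
masses to three decimals. `neutralize()` performs pure hydrogen
arithmetic (protonating anionic N/O, deprotonating cationic N/O) and is
only applied on request — one reference compound is catalogued at its
neutral mass while its SMILES is anionic, and the package targets the
catalogue mass for that compound.

Stereo marks are parsed and retained but never used: every downstream
computation is atom-position or connectivity based.

## Descriptors

* **nON** counts every nitrogen and oxygen atom regardless of charge;
  **nOHNH** counts hydrogens attached to N or O (an `[NH3+]` contributes
  three). These conventions jointly reproduce the full reference
  descriptor table for all six packaged compounds.
* **Rotatable bonds**: acyclic single bonds between two heavy atoms that
  each have at least two heavy neighbors, excluding amide C–N bonds.
  Ester C–O bonds rotate; bonds to terminal groups do not (the terminal
  atom has one heavy neighbor). This single rule reproduces all six
  reference counts simultaneously, which is the validation we rely on;
  behavior on exotic ester edge cases beyond those six is untested by
  construction.
* **TPSA** is the Ertl fragment-contribution sum over N/O (and optionally
  S/P) environments keyed by element, charge, aromaticity, hydrogen
  count, bond pattern and three-membered-ring membership. Two anionic
  nitrogen environments (`[N-](-*)-*` and `[NH-]-*`) are absent from the
  published table; they are tabulated here as 12.03 and 25.59 — the
  secondary-amine analogy value and the `[NH2+]=*` value — calibrated so
  that descriptor tables computed with the original Molinspiration
  service are reproduced within the package's ±0.05 Å² agreement band.
  An N/O environment outside the table is an error, not a silent zero.
* **logP** follows the Wildman–Crippen atom-contribution scheme with the
  published values, typed by local graph predicates rather than SMARTS.
  The proprietary miLogP values printed in the reference tables are *not*
  reproduction targets; only rule-of-five consequences (all six
  compounds sit far below 5) depend on logP, and those are insensitive
  to the scheme choice. Untypable environments fall back to the
  published element defaults with a warning.
* **%Ab** is the linear model `%Ab = 109 − 0.345 × TPSA`, applied without
  clamping, so extremely polar molecules can report negative estimated
  absorption.

## Drug-likeness

All four Lipinski thresholds are inclusive (`MW ≤ 500`, `logP ≤ 5`,
`nOHNH ≤ 5`, `nON ≤ 10`); a molecular weight of exactly 500 passes. The
filter default allows one violation, matching the usual reading that
compounds violating *more than one* rule are flagged.

## Conformer embedding

Conformers are generated by distance-geometry stress minimization:
idealized bond lengths (covalent radii scaled by bond order), 1–3
distances from idealized angles, and a 2.4 Å lower-bound hinge on all
remaining pairs, minimized by BFGS from a seeded Gaussian start in two
stages (topology first, sterics second). Conformer `k` depends only on
(molecule, seed, `k`), so ensembles are prefix-stable and bit-identical
across runs; different seeds land in different torsional minima. The
embedder is *not* a force field: geometries satisfy bonded constraints
well (all bond lengths within 0.6–2.0 Å is enforced, with bounded
retries) but are not Boltzmann-weighted and ignore stereochemistry. That
is sufficient here because the pharmacophore model itself is realized
from the same embedder, so model and ligand geometries live on the same
footing, and nothing downstream claims energetic realism.

## The six-feature pharmacophore model

The model comprises two hydrogen-bond donors and four hydrophobic
groups, with exclusion spheres marking protein-occupied space. Because
no 3D coordinates for the model were ever published, the package
realizes the model *once* from a deterministic embedding (seed 42) of
the amlodipine query: the two donors are the dihydropyridine ring N–H
and the terminal ammonium; the four hydrophobics are the phenyl ring
centroid, the ring chlorine, the carboxyethyl methyl and the ring
methyl. The serialized JSON (`inst/extdata/lvgcc_model.json`) is
normative — inter-feature distances are the contract. Two interpretive
choices are worth recording:

* The fourth hydrophobic region is described in the source material as
  sitting on an "amide benzene ring", which amlodipine does not have; it
  is mapped here to the dihydropyridine ring methyl cluster.
* Donor directions are stored in the model but not enforced during
  matching (the original description gives directions only as residue
  names, not geometry). One exclusion sphere (radius 1.2 Å) is placed
  3 Å along each donor direction, nudged outward if it would clash with
  the generating conformation.

Default tolerance radius is 1.5 Å per feature; both radii are exposed as
arguments.

## Matching algorithm

`match_features()` searches injective, type-compatible assignments of
ligand features to every non-exclusion model feature by backtracking,
pruning candidate pairs with the lossless pairwise bound
`|d_model − d_ligand| ≤ max(r_i, τ) + max(r_j, τ)` (equal to `2τ` at the
default radii). Every surviving complete assignment is scored by
least-squares rigid superposition (SVD-based Kabsch) of ligand feature
centers onto model centers; it is accepted when every aligned feature
lies within `max(radius, τ)` of its model feature (with a 1e-9 epsilon
against boundary jitter) and no ligand heavy atom falls inside an
exclusion sphere. The lowest-RMSD accepted assignment wins; exact ties
break lexicographically on the mapping for determinism. The test suite
holds this search to exact agreement with an exhaustive enumerator that
uses an independently implemented superposition (Horn's quaternion
method).

`screen_molecule()` embeds the ensemble lazily and applies a
feature-count prefilter: if the molecular graph cannot supply enough
features of a required kind, no conformer can match and embedding is
skipped entirely. This makes donor-knockout decoys essentially free to
reject. Degenerate inputs are defined, not errors: an empty ligand
feature list or a zero-conformer request reports `matched = FALSE` with
a diagnostic.

The ensemble seed defaults to 42 — the same constant the shipped model
was built with — so screening the query compound regenerates the
model's source conformation as conformer 1 and self-matches at RMSD ≈ 0.
This constant is part of the screening protocol, not a tunable.

## Pose annotation

Hydrogen bonds use standard geometric criteria: heavy-atom
donor–acceptor distance ≤ 3.5 Å and D–H···A angle ≥ 120°. Donors with
explicit hydrogens (e.g. the synthetic pockets) use the recorded
positions; donors without them — the common case for crystallographic
PDB files and always for the implicit-hydrogen ligand model — have the
hydrogen inferred along the donor–acceptor axis, which satisfies any
angle criterion. Published per-complex H-bond counts from docking
viewers use unstated criteria, so such counts are treated as report
semantics, never as numeric targets. The surrounding-residue cutoff
defaults to 4.5 Å (a typical hydrophobic-contact threshold);
active-site interaction counts are the intersection of the surrounding
set with the packaged residue list (32 residues across the four pore
chains). Externally computed binding energies are passed through
verbatim.

## Synthetic data: what it emulates and what it does not

The original screening library (a ~7,875-compound ZINC slice) is not
reconstructible — no identifiers were published — so enrichment behavior
is demonstrated on constructed libraries instead: unedited copies of the
query as actives and donor-knockout edits as decoys. The knockout is a
*structural guarantee* of failure under the all-features rule, so the
expected enrichment is exactly 1.0 and any deviation is a defect, not
noise. These decoys are deliberately easy; they are not property-matched
(DUD-E-style) decoys, and a perfect enrichment here says nothing about
performance against property-matched traps.

Toy pockets plant pseudo-residues radially around a rigid poly-ether
probe: donors at exactly 2.9 Å / 180°, inert carbon residues inside the
contact cutoff, far decoy residues outside it. Each bundle carries a
manifest of its planted ground truth, and the annotation stage must
recover those counts exactly (PDB's three-decimal coordinate precision
is the only slack, 5e-3 Å). Real binding sites — with bifurcated
hydrogen bonds, borderline geometries and crowded shells — are not
emulated; passing these tests shows correctness of the geometric
criteria, not robustness to structural noise.

## Problem sizes and numerical choices

The shipped test suite uses sizes chosen to exercise every code path
while staying comfortably interactive: 1,000 random matcher instances
against the exhaustive oracle (models of 3–5 features, ligands up to 8),
100 random rigid transforms (drift bound 1e-6 Å), 100 planted exclusion
clashes, 50 random toy pockets, and five 60-compound active/decoy
libraries at 3 conformers each. The acceptance script recomputes the
same families at 200 instances / 50 transforms / 25 pockets / three
libraries. Embedding uses BFGS with `reltol` 1e-10/1e-12 and at most
250 + 300 iterations; conformer retries (fresh derived seed) are bounded
at five before erroring.

## Known limitations

* Aromaticity follows the input's lowercase notation (SMILES) or bond
  order 4 (SDF); kekulized SDF input without aromatic bond orders will
  type aromatic N/O atoms by their Kekulé pattern, shifting TPSA by
  fractions of an Å².
* The SMILES writer is deterministic but not graph-canonical across
  arbitrary input orderings; round-trip preservation of formula, charge
  and descriptors is the guaranteed contract.
* logP typing is a reduced predicate set, faithful for the chemistry in
  scope; molecules dominated by exotic environments fall back to element
  defaults (with warnings) and should not be ranked by logP alone.
* Pharmacophore matching is rigid per conformer; flexible alignment and
  directional (vector) scoring are not implemented.
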