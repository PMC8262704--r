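---
title: "Residue interaction energetics and conservation: models, parameters, design"
author: "ResidueIEM authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue interaction energetics and conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ResidueIEM)
```

# The model

`ResidueIEM` scores the noncovalent interaction of every residue pair
in a protein 3D structure as a sum over cross-residue atom pairs of a
Lennard-Jones term and a point-charge electrostatic term, and
assembles the results into a symmetric residue-by-residue interaction
energy matrix (IEM) with a zero diagonal. The total (net) interaction
energy of a residue is its row sum. Everything is nonbonded: bonds,
angles and dihedrals are out of scope, as are nonpolar/surface-area
solvation terms.

Three electrostatic treatments are provided.

* **Vacuum** Coulomb, `E = k q_i q_j / (ε_in r)`, with
  k = 332.0636 kcal·Å·mol⁻¹·e⁻². No environment at all.
* **DDDC**, a distance-dependent dielectric `ε(r) = slope · r`. This
  is a legacy heuristic: it damps long-range electrostatics at zero
  computational cost but has no physical derivation. It is kept for
  comparability with older analyses; the slope (default 1, so
  ε(r) = r) is configurable because no canonical value exists.
* **Generalized Born (GB)**, the default for aqueous media. The pair
  energy is

  `E = k q_i q_j / (ε_in r) − k (1/ε_in − 1/ε_out) q_i q_j / f_GB`,
  `f_GB = sqrt(r² + R_i R_j exp(−r²/(4 R_i R_j)))`.

  GB is an analytic approximation to Poisson–Boltzmann continuum
  electrostatics. We do not solve Poisson–Boltzmann numerically: that
  requires spatial discretization, is slow and implementation
  sensitive, and — decisively for this package — is not pairwise
  additive, so it cannot populate a pairwise IEM. GB is, which is why
  it is the model of choice here.

## Born radii (OBC model II)

The effective Born radius `R_i` expresses an atom's distance from the
dielectric boundary: near its intrinsic radius when solvent exposed,
large when buried. Radii are computed with the
Hawkins–Cramer–Truhlar (HCT) pairwise descreening approximation
rescaled through the Onufriev–Bashford–Case (OBC) tanh form,
parameter set II:

* `ρ̃_i = ρ_i − offset`, offset = 0.09 Å;
* `I_i = Σ_{j≠i} H(ρ̃_i, S_j ρ_j, r_ij)`, where `H` is the analytic
  approximation to `(1/4π)∫ r'⁻⁴ dV` over neighbor j's descreening
  sphere (radius `S_j ρ_j`), excluding the region within `ρ̃_i` of
  atom i — implemented piecewise for the separated, partially
  overlapping, engulfed and atom-inside-neighbor arrangements;
* `Ψ_i = I_i ρ̃_i`;
* `1/R_i = 1/ρ̃_i − tanh(α Ψ_i − β Ψ_i² + γ Ψ_i³)/ρ_i` with
  (α, β, γ) = (1.0, 0.8, 4.85).

The constants are exposed via `obcParameters()` rather than
hard-wired, since different GB parameterizations exist in the
literature and users may want to match a particular simulation
package.

Two properties are worth internalizing. First, an isolated atom has
`Ψ = 0` and hence `R = ρ − 0.09` exactly; the test suite checks this
to machine precision. Second, `I_i` sums over **all** atoms of the
structure, so Born radii — and therefore every GB pair energy — depend
on the global geometry, not just on the pair. `buildIEM()` computes
radii once from the full structure; computing them per pair would be
both slower and wrong. The test suite demonstrates the consequence:
adding a third residue changes the GB energy of a fixed pair while
leaving its vacuum energy untouched.

The descreening integral is validated against a brute-force
Monte-Carlo volume integration (2×10⁶ points per configuration, fixed
seeds) in both non-overlapping and overlapping sphere arrangements at
1% tolerance; in practice the analytic piecewise form agrees to about
0.1% (Monte-Carlo noise dominates the comparison).

# Tunable parameters

| Parameter | Default | Units | Why this default |
|---|---|---|---|
| `epsIn` | 1.0 | — | solute interior treated as vacuum-like, the common GB convention |
| `epsOut` | 78.5 | — | water at room temperature |
| `dddcSlope` | 1.0 | Å⁻¹ | the canonical ε(r) = r form |
| OBC α, β, γ | 1.0, 0.8, 4.85 | — | OBC model-II constants |
| GB `offset` | 0.09 | Å | OBC dielectric offset |
| `threshold` (combined matrix) | 5.0 | Å | a common heavy-atom contact cutoff; distant pairs have IEs near zero and would otherwise hide the informative contacts |
| `cutoff` (energy summation) | none | Å | desk-scale structures need no truncation; a flag exists for very large inputs |
| `exclusions` | `"none"` | — | see below |

Units are fixed package-wide — Å, elementary charges, kcal/mol — and
conversions happen nowhere except the single Coulomb constant. This
single-unit discipline is deliberate: mixed kJ/kcal conventions are a
classic source of silent errors.

# Design decisions that were genuinely open

**Exclusion policy across the peptide bond.** The plain reading of a
pairwise residue IE is "sum over all cross-residue atom pairs", and
that is the default. But covalently adjacent residues then contribute
large bonded-contact terms (atoms 1–2 and 1–3 across the peptide bond
sit far inside van-der-Waals contact). Force fields handle this by
excluding 1–2/1–3 pairs and scaling 1–4 pairs; `exclusions = "ff"`
applies exactly that (electrostatics × 1/1.2, Lennard-Jones × 1/2),
with the bonded topology recognized name-based across consecutive
residue numbers (including the proline CD in place of the amide
hydrogen). Both behaviors are exposed because either can be the right
one depending on whether the user wants raw nonbonded sums or
FF-consistent energies.

**Hydrogens are required, never added.** Hydrogen-placement tools are
themselves a known error source (unrealistic overlaps propagate into
unphysical IEM elements), and automatic model repair tends to become
the dominant source of instability. The package therefore validates —
`assignParameters()` reports template atoms missing from the
structure, and the pipeline refuses to score such inputs, naming the
atoms — instead of guessing coordinates.

**Backbone subgroup membership.** The backbone selection is the name
set {N, CA, C, O} plus their hydrogens {H, HA, HA2, HA3} plus the
terminal atoms {OXT, H1, H2, H3}; the side chain is the complement
within each residue. Including the terminal atoms in the backbone is a
package choice (they are chemically backbone); the two masks partition
every residue's atoms by construction, and the same mask is applied to
energies and distances so the two matrices stay comparable.

**Altloc and model handling.** Only the first model of a multi-model
file is used (an IEM over superimposed models is not well defined);
alternate locations resolve to the highest-occupancy record, ties to
the first encountered. Both are documented defaults, not inferences
about any particular upstream tool.

**Shipped parameter table.** The built-in table
(`defaultParameterSet()`) is minimal and illustrative: Amber-99-like
backbone charges, group-rule side-chain charges balanced exactly to
each residue's formal charge, Amber-type Lennard-Jones classes,
mbondi2-like GB radii and element-based HCT scales. Redistributing a
published force field verbatim is deliberately avoided; any force
field exported to the documented TSV format can be supplied via
`loadParameterSet()`, which is also why every fixture embeds its own
table — no test depends on the shipped values.

**Terminal patches are name-based.** OXT and H1–H3 are mapped to the
mid-chain O and H parameters by name, not by connectivity perception.
This is crude but transparent, and wrong assignments surface as named
unassigned atoms rather than silent drops.

# Conservation

Chain sequences are read from the structure in file order
(non-standard residues become `X`; chains without a single standard
amino acid are dropped). Given an alignment containing the chain
sequence as a row, the package computes:

* **GSC weights** — pairwise distances are 1 − fractional identity
  over columns where neither row is gapped; a UPGMA guide tree is
  built (via average-linkage `hclust`, whose deterministic tie-break
  we adopt); then, processing merges from the leaves toward the root,
  each branch length is divided among the leaves below in proportion
  to their accumulated weights (equal split while all are zero) and
  added to them. Weights are rescaled to mean one, so the classic
  3-row case (two identical rows plus one distant) gives
  (0.75, 0.75, 1.5).
* **Weighted column IC** — weighted frequencies over the 20 standard
  amino acids; gaps and ambiguity codes (B, Z, X) are excluded and the
  remaining weight mass renormalized; `IC = log2(20) − H` in bits,
  with no background-frequency correction, so the scale runs exactly
  from 0 (uniform) to log2(20) ≈ 4.32 (single residue type). An
  all-gap column is NA, not 0: "no information" and "no data" are
  different things.
* **Per-column gap frequency** — reported alongside IC because high
  IC at chain termini is often an artifact of most sequences simply
  being unmatched there; the gap fraction lets users flag such
  columns cheaply.

The mapping onto the chain walks the non-gap positions of the query
row; a mismatch between the ungapped query and the chain sequence is
an error naming the first offending position (X is a wildcard on
either side), and chain residues beyond the alignment get NA.

An optional adapter (`runHomologySearch()`) shells out to an external
`phmmer` binary to build a query-anchored alignment from a local
sequence database. It is a convenience, not a dependency: everything
else works from user-supplied alignments, and the adapter's only
tested contract is that a missing tool raises an environment error.
No phylogenetic tree reconstruction or evolutionary-rate modeling is
attempted — GSC weighting is the entire defense against uneven
phylogenetic sampling, which is what keeps the conservation pipeline
fast.

# Numerical choices and degenerate inputs

* Coincident atoms across residues (r = 0) are a hard error — a
  degenerate geometry, not a scorable input.
* Over-descreened atoms (non-positive inverse Born radius, possible
  for malformed or deeply buried inputs) are clamped to R = 100 Å
  with a warning, so a damaged structure still yields a diagnosable
  result instead of dying midway.
* The IEM is symmetrized by averaging with its transpose after
  aggregation, removing floating-point asymmetry of order 1e-16;
  class validity then enforces symmetry and a zero diagonal.
* Residues with an empty atom selection under a subgroup (glycine
  side chain) produce NA distances with a warning and zero energy
  rows; they are never silently dropped.
* Tabular exports fix numbers at 6 significant digits and contain no
  timestamps, making pipeline outputs byte-reproducible; this is
  tested.

# What the fixtures emulate — and what they do not

The generators (`makeToyStructure()`, `makeToyMSA()`) produce
deterministic, byte-identical files per (kind, seed): single-atom
charge pairs for Coulomb worked examples, two-sphere configurations
for Born-radius checks, protonated alanine dipeptides, and
helical alanine arrangements (100° twist, 3 Å rise, 2 Å radial
offset) whose residues pack near van-der-Waals contact without
clashes (minimum interatomic distance ≥ 1 Å is enforced by
construction and tested). Alignment fixtures place fully conserved,
uniform-composition and random columns at known indices.

These fixtures exercise every code path, but they are not proteins:
no real secondary-structure geometry, no side-chain diversity, no
missing atoms, no alternate conformations beyond the synthetic altloc
tests, and alignments with idealized column structure. Passing tests
therefore establish the correctness of the implemented formulas and
invariants (symmetry, equivariance, rigid-motion invariance, model
limits, oracle agreement), not the biochemical accuracy of any
particular force field on real structures — that depends on the
parameter table the user supplies.

Problem sizes used by the suite are deliberately desk-scale: helices
of 5–16 residues (IEMs up to 16×16, a few hundred atoms), alignments
of up to 20 rows, and 2×10⁶-point Monte-Carlo integrals — enough to
separate signal from tolerance everywhere the formulas could go
wrong, while keeping the full suite around a minute.

# Known limitations

* Nonbonded-only scoring: no bonded terms, no SASA/nonpolar
  solvation, no periodic boundary conditions or Ewald summation.
* PDB input only (no mmCIF), standard amino acids; HETATM ligands are
  parsed and flagged but scored only if the user's table covers them.
* GB self-energies (atom i with itself, intra-residue solvation) are
  intentionally absent: the IEM is strictly pairwise between
  residues, so its entries are interaction terms, not a decomposition
  of the total solvation free energy.
* Name-based terminal patches and peptide-bond topology: correct for
  standard naming, blind to exotic chemistry (covalent ligands,
  cyclic peptides).
* The conservation pipeline trusts the user's alignment; it does not
  model sequence evolution.
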