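---
title: "Methods: interface fingerprinting, energy decomposition and rule-based toxin redesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface fingerprinting, energy decomposition and rule-based toxin redesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxsel)
```

## Scope and model

`toxsel` analyzes pre-computed structural ensembles of a two-entity complex —
a small disulfide-stabilized toxin docked on the extracellular vestibule of a
tetrameric Kv1 channel — and turns them into a mutation proposal that shifts
the toxin's isoform selectivity. It deliberately stops at both ends of the
physics: it neither builds the complex models (homology modeling) nor
generates the dynamics (MD). Its inputs are structures and multi-model-PDB
trajectories; its outputs are contact occupancies, per-residue interaction
energies, a substitution list, and Hill-fit pharmacology.

All internal lengths are nm (the unit in which the geometric criteria are
conventionally stated); PDB I/O converts to and from Å at the format's
`%8.3f` precision. Energies are kJ/mol; the Coulomb constant is fixed at
138.935458 kJ·mol⁻¹·nm·e⁻².

## Contact criteria and their defaults

Only the hydrogen-bond criterion has a canonical published form, the GROMACS
`hbond` convention: donor–acceptor distance D–A ≤ 0.35 nm **and** angle at
the hydrogen ∠D–H–A ≥ 150°. We adopt it verbatim, which has two
consequences baked into the code: hydrogens must be explicit (the generator
always emits them; annotation without donor hydrogens simply yields no
donors), and the angle is measured at H, not the ~30° donor-centered
complement convention.

The remaining contact classes have no single standard; their thresholds are
explicit, config-overridable conventions recorded in every output's
metadata:

| parameter | default | meaning |
|---|---|---|
| `saltbridge_max` | 0.40 nm | min N/O–N/O distance, opposite-sign groups |
| `cationpi_max` / `cationpi_angle_max` | 0.60 nm / 45° | cation–ring-centroid distance; angle to the ring normal (folded to [0°, 90°]) |
| `stacking_centroid_max` | 0.55 nm | ring-centroid distance |
| `stacking_parallel_max` | 30° | interplanar angle, parallel window |
| `stacking_tshape_min/max` | 60–90° | interplanar angle, T-shaped window |
| `hydrophobic_cc_max` | 0.45 nm | any apolar C–C pair; one contact per residue pair |

All comparisons are inclusive exactly as written (≤ / ≥). Ring planes are
least-squares planes (SVD of the centered ring coordinates); a collinear
ring is an error, not a guess. Cation positions are charged-group centroids.
Only cross-entity (toxin–channel) pairs are ever considered, and occupancy
is the fraction of post-burn-in frames in which a (toxin residue, channel
residue, kind) triple is detected; never-seen triples are absent keys rather
than zero rows.

A contact "exists" for the differential analysis when its occupancy reaches
`occupancy_threshold` (default 0.10). The source analysis states no
threshold; 0.10 discards single-frame noise while keeping genuinely
transient polar contacts, and `differential_contacts()` is provably
monotone in this parameter (raising it never adds contacts), so the choice
is auditable.

Histidine protonation is exposed as configuration
(`default_annotation_rules(his = "HIE"/"HID"/"HIP")`), defaulting to the
neutral N<sub>ε</sub> tautomer. The analysis that motivated this package did
not state its choice, so the package refuses to hard-code one: a cation-π
partner histidine is neutral-aromatic under HIE/HID and becomes a cationic
group under HIP.

## Energy decomposition

The short-range non-bonded interaction energy of an atom pair is the sum of
a Coulomb term `f·q_i·q_j/r` and a Lennard-Jones term
`4ε[(σ/r)¹² − (σ/r)⁶]` with Lorentz–Berthelot combination
(σ arithmetic, ε geometric mean). Both terms are **plainly truncated** at
the 1.5 nm cutoff, applied per atom pair: no switch, shift, reaction field
or lattice summation. Those corrections belong to an MD engine computing
total system energetics; here the quantity of interest is the *relative,
per-residue decomposition* of the interface energy, for which consistent
truncation is sufficient and exactly reproducible. Intramolecular pairs are
never computed — this is an interface decomposition, so 1–4 scaling never
arises.

Per-frame pair energies are averaged over all frames after a configurable
burn-in (default 0, since the source window is unstated); the per-toxin-residue
profile is the sum over that residue's channel partners, making marginals
and the pair matrix consistent by construction (enforced by test). A
positive mean total flags a residue that *repels* the channel — the
charge-reversal candidate.

The bundled force-field table is a reduced stand-in, not a port of a
biomolecular force field: round values (|q| ∈ {0, 0.5, 1} e, σ ∈
{0.30, 0.35} nm, ε ∈ {0, 0.4} kJ/mol) over the package's reduced residue
rosters, chosen so that neutral residues sum to exactly 0 e and every
energy assertion has a closed form. Real force-field tables can be supplied
as TSV (`read_forcefield()`); assignment is total-or-error, listing every
unmatched atom.

## Superposition and grafting

`kabsch_superpose()` is the standard SVD solution for the least-squares
proper rotation (determinant-corrected against reflections), requiring ≥ 3
non-collinear mapped pairs (second singular value > 1e-12). Because a toxin
and a scaffold toxin of different length have no canonical atom
correspondence, the residue mapping is a *required user input*; the default
atom set is Cα, with full backbone (N, CA, C, O) by flag. Grafting removes
the scaffold chain, inserts the transformed toxin, and reports — never
repairs — the count of inter-entity heavy-atom pairs closer than 0.2 nm.
Relaxing a grafted pose is downstream refinement's job; silently minimizing
it here would hide exactly the clashes a modeler needs to see.

## Design rules

Two rules, both deliberately minimal and deterministic:

1. **Ala substitution**: a toxin residue whose polar contacts (hydrogen
   bond, salt bridge, cation-π) occur — at or above the occupancy
   threshold — with at least one off-target isoform and *no* polar contact
   with the target isoform is replaced by Ala. Hydrophobic and stacking
   contacts never trigger this rule: the engineering idea is to abolish
   polar contacts, and Ala does not remove a generic hydrophobic surface.
2. **Charge reversal**: an acidic residue (Asp/Glu) whose mean total energy
   is positive in *every* isoform is replaced by Arg (configurable to Lys).
   "Significant" is not quantified by the source; the package therefore
   reports the mean-over-sd ratio but thresholds only the sign (default
   threshold 0 kJ/mol).

If one residue triggers both rules it receives a **single Ala substitution
with a combined rationale**: Ala simultaneously abolishes the polar contact
and deletes the repelling charge, whereas Arg could itself nucleate new
polar contacts, making the outcome harder to reason about. This was a
genuinely open design point; the choice is recorded here and in the
proposal's rationale strings. Cysteines are never proposed or accepted as
substitution sites (disulfide scaffold guard), and proposals are pure
functions of their inputs, ordered by position.

## The synthetic world

The generator plants features — H-bonds, salt bridges (with or without a
co-occurring H-bond, the Lys–Glu situation), cation-π, parallel/T-shaped
stacking, hydrophobic contacts, and like-charge "repulsion" pairs — each on
its own angular slot of a circle wide enough (slot spacing ≥ 0.8 nm) that
slots cannot interact. Key atoms satisfy their criterion with margin
(≥ 0.02 nm / ≥ 5°, e.g. planted D–A 0.30 vs 0.35 nm, planted cation-π angle
0° vs 45°), and per-frame jitter is *uniform and bounded* (default
half-width 0.005 nm, worst-case pair displacement ≈ 0.017 nm), so sub-margin
jitter can never flip a detection — occupancy assertions are exact, not
statistical. Occupancies are planted by frame counting (`round(o·n)` leading
frames on, the rest broken by a 0.6 nm retraction of the toxin residue),
never by Bernoulli draws. T-shaped stacking at realizable centroid
distances geometrically implies an apolar-carbon contact; the ground truth
records that co-occurrence rather than pretending it away.

What a green test on this world establishes: the detectors, energy sums,
occupancy bookkeeping and design rules compute exactly what their
definitions say. What it does not establish: anything about real
conformational ensembles — no solvent, no ions, no backbone flexibility, no
competing contacts, no periodic images (trajectories are assumed whole).
The curated contact ledger used by the acceptance path is a transcription
of published qualitative facts, with a documented ±5 kJ/mol stand-in
magnitude for the repulsion rows (only the sign is consumed). The bundled
37-mer sequence is likewise a synthetic scaffold stand-in honouring the
published positional constraints (Gln12 before the second Cys, Lys15
between Cys2/Cys3, Lys18 after the third Cys, pore Lys26, Asp33 between
Cys5/Cys6); every shipped numeric result is independent of it.

## Hill fitting

The two-parameter model `y = 100/[1 + (IC50/[toxin])^h]` is fitted exactly
as printed: asymptotes fixed at 0 and 100, replicates pooled unweighted.
Initialization is IC50 at the geometric mean of tested concentrations and
h = 1; bounds IC50 > 0, h ∈ [0.1, 5] (a Hill slope outside that range on
6–8 concentration points is a data problem, not a parameter). The optimizer
is `nls(algorithm = "port")` followed by a log-scale Nelder-Mead + BFGS
polish (the log parameterization removes the positivity constraints and is
where the objective is closest to quadratic); the polish also rescues
zero-residual datasets on which `nls` historically struggles. Standard
errors are Gauss-Newton curvature estimates σ²(JᵀJ)⁻¹ from a central-
difference Jacobian at the optimum. Failure is flagged, never silent:
constant responses short-circuit to `converged = FALSE` (the model is
unidentifiable), and fewer than 3 distinct concentrations is an error.

Selectivity factors are plain IC50 ratios (antisymmetric by construction);
report tables render unfitted channels as `"N/A"` and round-trip through a
numeric long-format CSV.

## Numerical conventions

* Threshold comparisons are inclusive; ties detect.
* Ring/plane degeneracy (collinear atoms) and coincident atoms (r = 0) are
  errors, not NaNs.
* Angles between normals are folded to [0°, 90°] (a normal's sign is
  arbitrary).
* Occupancy × frame count is an integer by construction, and contact maps
  are bit-reproducible on identical input.
* The pipeline manifest echoes the full configuration (no hidden defaults)
  and md5 checksums of every output; logs go to stderr only.

## Known limitations

Detectors are O(pairs) per frame without spatial indexing — appropriate for
interface-sized systems (hundreds of atoms, thousands of frames), not whole
proteomes. The energy model has no polarization, solvent screening or
entropy; its output ranks residues within one interface and should not be
read as binding free energies. The design rules encode one published
engineering idea (abolish off-target polar contacts; reverse conserved
repulsion) and will not invent contacts the contact maps do not contain.
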