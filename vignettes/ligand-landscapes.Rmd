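---
title: "Affinity landscapes, binding modes and interaction geometry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Affinity landscapes, binding modes and interaction geometry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligandscape)
```

This vignette documents the models and numerical choices behind
ligandscape, in the spirit of a methods section: what each quantity
means, which knobs matter, and what the synthetic fixtures do and do
not establish about real data.

## The landscape indices

For a pair of ligands with structural similarity $s \in [0, 1]$ and
scalar values $v_1, v_2$ (a measured activity such as $K_i$, or a
docking binding affinity in kcal/mol), the landscape index is

$$\mathrm{index}(v_1, v_2, s) = \frac{|v_1 - v_2|}{1 - s}.$$

`sali()` and `sbai()` are the same functional; the two names reflect
the two input kinds (measured activity vs docking affinity), and the
package never mixes them within one pair table. The index is symmetric
in its value arguments, strictly increasing in $|v_1 - v_2|$ at fixed
$s$, and strictly increasing in $s$ at fixed nonzero difference — the
properties that make it a cliff detector. These are property-tested on
random inputs rather than assumed.

**The $s = 1$ singularity.** Two distinct values at unit similarity
give an infinite index. We keep the `Inf` sentinel in the `index`
column (it ranks first, as it should: an identical structure with a
different outcome is the sharpest possible cliff) and carry a finite
`capped_index = min(index, cap)` alongside for display and node
sizing. The default `cap = 2000` matches the truncation used when the
surface is plotted; capping is presentational only, and a test asserts
that it never reorders uncapped pairs. Equal values give index 0 even
at $s = 1$.

**Activity scale.** The index is scale-covariant, not scale-invariant:
running it on $K_i$ versus $pK_i$ changes which pairs dominate. The
package uses values exactly as supplied and leaves any log transform
to the caller, because the choice is a scientific one about what "a
large activity change" means for the assay at hand.

**Similarity measures.** Three are supported. `circular` is a
Morgan-style fingerprint: per-atom invariants (element, heavy degree,
hydrogen count, aromaticity, ring membership) are iteratively hashed
over bond neighborhoods to `radius` (default 2) and folded into
`n_bits` (default 2048) — community-standard resolution. The hashing
is a deterministic polynomial hash implemented in-package, so
fingerprints are bit-stable across platforms. `feature_pair` encodes
pharmacophore feature pairs (donor, acceptor, aromatic-ring centroid,
hydrophobic carbon, halogen) with their separation binned at 2 Å from
0 to 12 Å; with no 3D conformer the separation falls back to
topological bond counts scaled by 1.5 Å per bond (a typical bond
length — crude, but monotone in through-bond separation, which is what
binning needs). Feature typing is deliberately exclusive for N/O
atoms: with a hydrogen the atom is a donor, without one an acceptor,
so a donor–acceptor pair is counted once. `external` accepts any
precomputed similarity matrix (CSV with id headers), so descriptor
tools outside the R ecosystem can drive the same landscape machinery.
Tanimoto similarity over bit sets feeds the index; two empty
fingerprints compare as 1 with a warning (identical absence of
features), avoiding a 0/0 while flagging the degenerate input.

**Graphs.** `build_graph()` thresholds edges at `s_threshold`
(default 0.65, a conventional similarity-network cutoff; the parameter
is fully exposed because no single value is canonical). Node scores
aggregate the capped index over incident edges; the default `max_index`
highlights each node's sharpest cliff partner, `mean_index` is the
smoother alternative. Which aggregation best matches published node
sizings is genuinely underdetermined, which is why both ship.

## Binding-mode fingerprints and distances

A binding-mode fingerprint maps keys (residues like `Val66`, or ligand
atoms) to interaction strengths. Strengths are either energies
(kcal/mol, from a docking decomposition) or dimensionless
counts/weights (from detected contacts); the `source` field records
which, and the two are never mixed in one comparison.

Fingerprints are aligned on the sorted union of keys with missing
entries set to 0 — a residue that is not contacted contributes no
interaction energy. On aligned vectors:

* Manhattan $\sum_i |p_i - q_i|$ and Euclidean
  $\sqrt{\sum_i (p_i - q_i)^2}$ are metrics (symmetry, identity,
  triangle inequality — property-tested);
* the additive distance $\sum_i (p_i - q_i)$ is *signed*: energies are
  negative, so a negative sum means the first mode binds more strongly
  overall. It is antisymmetric and bounded by the Manhattan distance.
  The "balance of contributions" reading is why it is a plain signed
  sum rather than another absolute aggregate;
* $\mathrm{RMSD_{BM}} = \sqrt{\tfrac1n \sum_i (p_i - q_i)^2}$ is
  exactly the Euclidean distance divided by $\sqrt n$ — an algebraic
  identity the suite asserts to 1e-12 on random fingerprints.

Residue ranking uses the mean *absolute* strength across ligands
(strongest first), because with negative energies "strongest" is a
magnitude statement; ties break lexicographically so the order is
deterministic.

Heatmap matrices are exported with 17 significant digits so a CSV
round trip is bit-exact. The red–yellow–green scheme is used for
binding strengths, the red–blue diverging scheme for signed
differences.

## Interaction geometry

The detectors operate on heavy-atom coordinates from PDB files
(bio3d reader; waters excluded unless `keep_waters = TRUE`; alternate
locations resolved to highest occupancy, ties by altloc letter).
Covalent bonds are inferred from distances against covalent radii
(+0.45 Å tolerance), which is what makes the detectors work on hetero
groups without CONECT records.

Geometric criteria (all config-exposed, defaults chosen to capture the
hydrogen- and halogen-bond geometries typical of kinase co-crystals,
including long weak bonds near 4 Å and highly non-linear ones near
100°):

| interaction | distance | angle | class |
|---|---|---|---|
| hydrogen bond | D⋯A ≤ 3.6 Å | D–H⋯A ≥ 120° | strong |
| hydrogen bond | D⋯A ≤ 4.1 Å | D–H⋯A ≥ 90° | weak |
| halogen bond | X⋯A ≤ 3.8 Å | C–X⋯A ≥ 140° | — |
| hydrophobic | C⋯C ≤ 4.0 Å | — | — |

Donor/acceptor typing is residue-aware on the protein side: backbone
and amide nitrogens donate; carbonyl and carboxylate oxygens never do;
Ser/Thr/Tyr hydroxyls and Cys sulfur do; water oxygens do when waters
are retained (this is how water bridges surface). Halogens are
acceptors only in the weak class; fluorine is excluded from σ-hole
donation by default because its hole is negligible. When a structure
carries no hydrogens the donor angle uses the heavy-atom surrogate
(antecedent–donor⋯acceptor, threshold 90°) rather than placing
hydrogens — deterministic, at the cost of a cruder angle; ligand
oxygens without explicit hydrogens are treated as acceptors only,
since ligand chemistry is unknown to the reader. When both directed
passes report the same atom pair, the record with the measured
D–H⋯A angle wins over a surrogate, and strong over weak.

Hydrophobic contacts pair apolar carbons (no bonded N/O/S) and are
aggregated to one record per (ligand atom, residue) at the minimum
distance, which keeps fingerprints from over-counting a single buried
atom.

Candidate pairs come from a cell-grid neighbor search; the suite
asserts exact agreement with an all-pairs brute-force oracle on random
clouds, and rigid-motion invariance of the full detection to 1e-6.

## Flexibility profiles

"Normalized B-factor" means the per-chain z-score with the population
standard deviation — standard crystallographic practice, and the only
normalization consistent with difference maps whose color scales sit
at a few units either side of zero. Normalization errors out on
constant profiles rather than dividing by zero. Difference maps
subtract profiles on the intersection of (chain, residue-number) keys;
matching across structures is by residue number with an optional
constant offset, not by structural alignment, which keeps the
operation transparent (and limits it to structures with compatible
numbering — see limitations). RMSF profiles are ingested from CSV; the
simulations that produce them are out of scope.

## Synthetic fixtures: what they do and do not show

`synth_complex()` builds one scaffold residue per requested contact
(Ala/Val/Leu/Asn templates with idealized geometry, 25 Å apart so
plants cannot interfere) and places ligand atoms so the planted
distance and angle are realized exactly: the hydrogen position for a
planted D–H⋯A angle is solved in closed form from the law of cosines.
The in-memory complex is exact to numerical precision (1e-6 Å /
1e-4°); the PDB written alongside is exact to the format's fixed
0.001 Å. The generator refuses clashing or out-of-range specs.

`synth_landscape()` draws background similarities and affinities
uniformly from stated ranges and realizes each planted cliff on a
dedicated ligand pair at exactly its $(s, d_{BA})$; defaults
(similarity 0.2–0.5, affinities −10 to −5 kcal/mol) mirror the spread
of a typical docking campaign over one scaffold family. Cliff
similarities must exceed the background range, so detection thresholds
can bracket the plants; generation is a pure function of spec and
seed, and restores the session RNG state.

These fixtures establish *correctness of the machinery*: that planted
geometry is detected exactly inside the acceptance envelope and not
outside it (boundary-tested at cutoff ± 1e-3), and that planted cliffs
are recovered with full precision and recall. They do not emulate
conformational strain, crystallographic noise, correlated similarity
structure, or the heavy-tailed affinity distributions of real
campaigns — so passing tests demonstrate the arithmetic and the
detection logic, not that the default cutoffs are optimal for any
particular crystal form.

## Problem sizes and numerics

The shipped checks run the full 40-ligand library (780 pairs), random
property loops of 25–50 repetitions under fixed seeds, and
neighbor-search oracles on clouds of a few thousand points — sizes
chosen so the whole suite exercises every code path at interactive
speed. Tolerances: algebraic identities at 1e-12, planted geometry at
1e-6 Å / 1e-4°, PDB round trips at the format's 0.001 Å. Ties are
always broken deterministically (lexicographic keys, altloc letter
order) so repeated runs are identical.

## Known limitations

* π-stacking and ionic interactions are not detected; protonation
  states are never assigned.
* The circular and feature-pair descriptors are open substitutes for
  proprietary descriptor families; similarity *values* from other
  tools will differ even where the landscape topology agrees, which is
  why external matrices are a first-class input.
* Residue matching in flexibility maps assumes comparable numbering
  between structures; an offset handles constant shifts, nothing
  handles insertions.
* Configuration files for the CLI are YAML.
* The energy decompositions shipped with the package are docking
  *outputs*; nothing here re-derives them, and conclusions drawn from
  them inherit the docking engine's assumptions.
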