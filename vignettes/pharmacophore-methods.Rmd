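---
title: "Receptor-based pharmacophores: model, matching and planted validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptor-based pharmacophores: model, matching and planted validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phoreseed)
library(dplyr)
```

## The model

A pharmacophore here is a receptor-shaped filter for agonist conformers.
It has two parts.

**Interaction features.** Typed points — cation, aromatic, H-bond donor,
H-bond acceptor — each with a centre (Å), a tolerance sphere, and an
*essential* flag. For a D1-style full-agonist model the canonical triad is
a cation feature (the TM3-aspartate salt bridge partner), an aromatic
feature (the TM6-phenylalanine stacking partner) and a donor feature (the
TM5-serine hydrogen-bond partner); `default_feature_spec()` encodes
exactly this. Features are *seeded* at the annotation points of the bound
reference agonist (`place_features()`), and may be rigidly translated as a
block relative to the volumes (`shift_features()`), which is the
one-dimensional analogue of the manual feature/volume alignment step used
when such models are refined against a training set.

**Excluded volumes.** Spheres the ligand must stay out of, encoding pocket
shape. They are centred on the *hydrogen atoms* of every residue with any
atom within 3.0 Å of a ligand heavy atom — deliberately including
hydrogens engaged in intermolecular hydrogen bonds — plus one 2.5 Å sphere
at the centroid of each aromatic side-chain ring (His/Phe/Tyr/Trp) of a
contact residue, guarding against face-to-edge ring clashes. Radii are a
per-class map: Bondi van der Waals values (aliphatic 1.2 Å;
aromatic/hydroxy/amine, i.e. "polar", 1.0 Å) as the physical starting
point, and an empirically inflated final map (1.5/1.3 Å) as the default; a
looser D2-style map (2.1/1.9 Å) is provided as `radius_map_d2()`. Because
each hydrogen-derived volume stores its class, `set_radius_map()` can
re-derive all radii from any map without rebuilding geometry — which is
what makes grid tuning cheap. Volumes built from several pre-superposed
complexes are unioned, merging centres within 0.25 Å (below coordinate
noise) and keeping the larger radius. Element-specific volumes ("ExclO":
rejects only the elements in its set, e.g. oxygen) are supported
end-to-end but are not produced by the builder; they exist for D2-style
selectivity modelling where an oxygen-intolerant subpocket must be
encoded.

## Matching

`match_conformer()` decides a hit in three barriers, in order:

1. **Correspondence.** All injective, kind-compatible assignments of
   annotation points to features that cover every essential feature and
   any subset of optional ones, pruned by pairwise distance
   compatibility `|d(c_i, c_j) − d(p_σi, p_σj)| ≤ t_i + t_j`. The pruned
   enumeration is provably identical to the unpruned one filtered by the
   same predicate (tested against brute force).
2. **Tolerance.** The matched points are superposed onto the matched
   feature centres with a Kabsch least-squares proper rotation
   (reflections disallowed; one point degenerates to a translation, two
   points to an optimal axis alignment). Every matched point must land
   inside its feature's tolerance sphere.
3. **Clash.** The same transform is applied to the ligand heavy atoms;
   any atom centre *strictly* inside an applicable volume rejects the
   correspondence. Ligand hydrogens are not clash-tested: volumes derive
   from receptor hydrogens, and ligand hydrogen positions are
   conformer-generator artefacts. Atom centres (not van der Waals
   surfaces) are tested, consistent with radii that were inflated from
   Bondi values precisely to absorb the ligand's own extent.

Among surviving correspondences the one matching the most optional
features wins, ties broken by lower RMSD; unmatched optional features are
never penalised. The reported RMSD is the root mean square distance
between feature centres and their matched points, over matched features
only. `reject_reason` records the last barrier passed
(`no-correspondence` → `tolerance` → `clash`), which is what makes decoy
bookkeeping testable.

Screening an ensemble applies the relative-energy cutoff first
(ΔE ≤ 4 kcal/mol, *inclusive*, so boundary conformers count; kJ/mol
inputs are divided by 4.184 at the file boundary and re-based to
min = 0). `#c` counts conformers under the cutoff, `#h` those that hit;
the best hit is lowest-ΔE-then-lowest-RMSD. The discrimination score of a
labelled screen is the active hit fraction minus the inactive hit
fraction, and `tune_radii()` simply maximises it over a user grid of
radius maps, breaking ties toward larger radii (the stricter shape), then
lexicographically — a reproducible stand-in for what is otherwise a
manual tuning loop.

## Perception conventions

Annotation-point typing follows standard medicinal-chemistry conventions,
stated here because upstream tools vary:

* nitrogen with formal charge +1, and neutral sp3 amine nitrogens (not
  amide, not N-oxide, not ring-aromatic) give a **cation** point;
  tertiary amines included — steric discrimination against them is the
  excluded volumes' job, not the typing's;
* O–H and neutral N–H heavy atoms give a **donor** with direction along
  the hydrogen; a +1 nitrogen gives a cation point *only*, its
  salt-bridge role being captured there (so a protonated dopamine-like
  ligand perceives 2 donors, 2 acceptors, 1 cation, 1 aromatic);
* oxygens and non-quaternary neutral nitrogens with an available lone
  pair give an **acceptor**;
* each 5-/6-membered aromatic ring gives an **aromatic** point at the
  unweighted heavy-atom centroid ("centre of mass" is immaterial for the
  all-carbon rings this models) with the least-variance eigenvector as
  unit normal (sign fixed to +z, then +x). Aromaticity is read from bond
  flags or alternating Kekulé patterns in 6-rings; no Hückel perception,
  because ensembles arrive pre-typed from conformer generators.

Receptor hydrogens are classified without a bond table: the nearest heavy
atom in the residue is the covalent partner (N/O/S → polar; ring carbon
of an aromatic residue → aromatic; else aliphatic).

## The synthetic study conditions

The generator emulates the data such a study consumes but cannot ship:

* `make_toy_complex(seed)` — a dopamine-like rigid ligand (catechol ring,
  ethylamine chain, protonated N) surrounded by a serine accepting the
  catechol O–H, an aspartate carboxylate paired with the ammonium, a
  phenylalanine ring stacked 2.9 Å face-on, and a glycine shell 4.5–6 Å
  out. Receptor hydrogens point away from the ligand so the reference
  pose clears its own volume set. At least three residues are within
  3.0 Å contact. Coordinates are rounded to PDB precision (1e-3 Å) at
  generation so file round-trips are exact.
* `make_planted_ensemble(model, planted_spec(...))` — conformers of a
  minimal probe ligand (aromatic ring, N+, hydroxyl, linker and probe
  carbons; chemically plausible connectivity, geometry dictated by the
  feature layout rather than a force field). Actives present their points
  at the feature centres plus uniform jitter (default 0.3 Å, necessarily
  below the 1.0 Å feature tolerance); each decoy violates exactly one
  constraint, so reject-reason tallies are themselves testable. Probe
  carbons sit at a clearance above the volume radii that scales with the
  jitter, because the rigid fit can displace heavy atoms by roughly twice
  the point jitter.
* `make_labeled_library(model, 15, 10, seed)` — the 25-ligand study
  library (15 full actives, 10 inactives, mirroring the published set's
  structure). Inactive clash decoys cycle their planted probe through the
  three hydrogen classes at radius − 0.15 Å while actives carry probes at
  radius + 0.15 Å, making the library separable *exactly* at the map the
  model was built with: smaller maps let some decoy through, larger maps
  clash some active. That is what gives grid tuning a unique score-1.0
  optimum, up to ties resolved by the documented larger-radii rule.

Two generator behaviours deserve an explicit note. First, the tolerance
decoy: displacing one point of a three-point constellation by
tolerance + 0.5 Å does **not** guarantee a miss, because the best-fit
rigid transform redistributes the error (a single-point displacement δ
leaves a worst-case best-fit residual near 2δ/3, and a favourable
rotation can do better still). The generator therefore starts at the
nominal displacement and escalates geometrically until the matcher
verifiably rejects the conformer with reason `tolerance`; the planted
label is thus a checked property of the emitted geometry, not an
assumption. Second, energies: file readers re-base energies to min = 0,
so the generator anchors one in-cutoff conformer at ΔE = 0 whenever one
exists; an ensemble consisting solely of energy decoys keeps its
above-cutoff energies as planted (re-basing would drag them under the
cutoff and change their meaning).

What passing these tests shows — and does not. The planted fixtures prove
the machinery: correspondence search, superposition, tolerance and clash
logic, energy filtering, file round-trips, tuning recovery. They do not
emulate force-field conformer distributions, tautomers/protomers,
receptor flexibility, or the chemotype diversity of a real training set,
so perfect planted recovery is a statement about the implementation, not
about expected screening performance on real data.

## Pocket analysis

`pocket_volume()` is a declared grid estimator (the volume algorithms
inside modelling suites are generally unpublished): points on a grid
(default 0.5 Å; 0.25 Å converges the single-atom analytic sphere to
within 0.5%) within 4.0 Å of a ligand heavy atom, outside every receptor
atom's Bondi sphere (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Å), and
6-connected-reachable from the grid point nearest the ligand centroid,
times the cell volume. It is rigid-motion invariant up to discretisation
error (tested at 5%). Published pocket volumes from other estimators are
context for magnitude, not comparison targets.

Conservation mapping is strict one-letter identity through a pairwise
alignment column map; gap-aligned residues are non-conserved, and
physicochemical similarity classes are deliberately out of scope.
Ballesteros–Weinstein indices are pure arithmetic off user-declared helix
spans and x.50 anchors (`nn = 50 + seq − seq(x.50)`) — never inferred
from structure. Hydrogen-bond thresholds (donor–acceptor ≤ 3.5 Å,
D–H···A ≥ 120°) are conventions chosen inside the bracket that typical
reported geometries (2.7–2.9 Å accepted, 4.6 Å rejected) imply; close
contacts use a strict < 2.6 Å on non-bonded interface pairs.

## Numerical choices and degenerate inputs

* Kabsch uses SVD with the determinant sign correction on the smallest
  singular value; proper rotations only. `det(R) = 1` to 1e-9.
* Clash and cutoff comparisons: strict `<` for volumes (a point *on* the
  sphere is outside), inclusive `≤` for contact and energy cutoffs.
* Ring normal sign: +z, tie → +x, then +y; collinear rings error.
* Serialisation: JSON with unlimited digits; round-trips hold to 1e-9
  (PDB and SDF are exact because the generator rounds to format
  precision first).
* Empty inputs: an empty ensemble screens to a 0/0 row with absent best
  fields; a moleculeless perception returns an empty point table; an
  empty radius grid errors.

## Problem sizes

Test and acceptance runs use the generator at study scale but small
geometry: 25-ligand libraries of 3–4 conformer ensembles, 200-instance
oracle comparisons (≤ 4 features, ≤ 8 points), 50 model/ensemble
monotonicity pairs, a staged 10^6-rotation stochastic check of the
superposition optimum, and 0.25 Å pocket grids (~30k cells). These sizes
keep each property's evidence independent and the whole suite
interactive-fast.

## Known limitations

No directional (vector) feature constraints; no flexible-ligand
refinement inside the model; no protonation/tautomer engine (inputs must
arrive protonated, and the reader enforces it); no automatic receptor
superposition (multi-complex volume union assumes a shared frame); no
mmCIF/MOL2; no NMR multi-model PDB handling. Feature-position
optimisation is limited to rigid translation of the feature block.
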