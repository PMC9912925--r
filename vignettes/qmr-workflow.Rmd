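---
title: "In-situ ligand restraints: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-situ ligand restraints: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmrestraints)
```

## The model

Crystallographic refinement restrains every ligand bond, valence angle and
torsion to an ideal target with a stiffness set by its estimated standard
deviation (e.s.d.), approximating the local potential-energy surface as a
parabola. Bond and angle targets transfer well between environments;
torsions between rigid fragments and ring puckers do not — their minima
move with the binding pocket, which is why torsion restraints carry large
e.s.d.s (30° is typical, against 2° for angles) and may be *periodic*
(a methyl torsion with period 3 has equivalent minima at 60°, 180° and
300°) or carry an explicit list of aperiodic *alternative targets* for
puckered rings.

This package regenerates the targets **in situ**. The procedure:

1. **Cluster selection.** The ligand plus every residue or water with at
   least one atom within the cutoff radius of any ligand atom, each copied
   *whole*. Crystallographic symmetry images participate: every operator
   of the space group is combined with lattice translations over a shift
   box wide enough to cover the radius, and any image residue inside the
   radius joins the cluster with full provenance (operator index, lattice
   shift). The default radius of 3.5 Å spans hydrogen-bond and van der
   Waals contact distance while keeping the cluster small.
2. **Chemical completion.** Extracting the cluster cuts covalent bonds
   (typically peptide bonds of pocket residues). By default each cut bond
   is terminated by a hydrogen link atom placed along the former bond
   vector at the standard element–H distance (C–H 1.09 Å, N–H 1.01 Å,
   O–H 0.96 Å); the optional zwitterionic mode instead completes backbone
   cuts as charged termini (carboxylate OXT at 1.25 Å in the sp² plane of
   the carbonyl; ammonium hydrogens tetrahedral about the N–CA axis).
   Waters, usually deposited as bare O atoms, receive two hydrogens at
   0.96 Å with an H–O–H angle of 104.5°.
3. **Optimization.** The cluster geometry is relaxed with the ligand, the
   caps and the water hydrogens mobile and the environment heavy atoms
   fixed; an option lets model-native side chains co-optimize. Symmetry
   image atoms are always immobile — moving them would desynchronize them
   from their source atoms.
4. **Target generation.** Every bond/angle/torsion target of the base
   dictionary is replaced by the value measured from the relaxed
   coordinates; e.s.d.s are copied from the base restraints. Torsions
   become unimodal (period 1, alternatives cleared): the defining semantic
   of in-situ restraints is that the environment-compatible minimum is now
   known. Planes and chirality are copied, not re-derived — re-measuring a
   plane from a slightly puckered optimized geometry would wrongly
   deplanarize aromatics. Restraints whose atoms are absent from the
   coordinates (usually hydrogens) keep their base targets.

Ligand protonation is accepted as given: the tool compares the ligand's
hydrogen count against the dictionary roster and warns on a mismatch, but
never invents protonation states. Ligands carrying alternate conformations
are parsed without loss and rejected at environment validation rather than
silently split.

## Deviation analysis

The sign convention is `Δ = target − actual`, which makes published
worked-example outlier tables directly reproducible. Torsions are stored
in (−180°, 180°]; out-of-range inputs are wrapped on ingest, and the
deviation of a torsion is computed against the *nearest* candidate target:
the base target, its periodic images `target + k·360/period`, and any
aperiodic alternatives, with ties broken towards the base target. The
deviation magnitude therefore never exceeds `180/period` for a purely
periodic restraint. Periodicity-aware deviation is applied uniformly, also
to baseline dictionaries.

Per-category r.m.s.d. is the root of the mean squared deviation from the
restraint targets (not a positional r.m.s.d.), taken over non-hydrogen
restraints by default (`include_h = TRUE` includes them); an empty
category reports `NA`, never 0. Outlier cutoffs default to 0.02 Å, 5° and
30°. Resolution-binned summaries use a wide 0.8–1.4 Å high-resolution bin
followed by 0.2 Å bins to 3.0 Å (right-closed, so 1.39 Å falls in the
first bin and 1.41 Å in the second), report mean and s.e.m. (`sd/√n`,
undefined below n = 2) per condition, and compare two conditions per bin
with a Welch two-sample t-test.

## Screening rules

A ligand instance qualifies as a test case when (all bounds inclusive):
resolution ≤ 3.0 Å; no other ligands, metals or alternate conformations
within 5.5 Å (measured on the input model, before hydrogen addition) and
no missing heavy atoms within 3.5 Å (against the component's dictionary
roster or the standard amino-acid rosters); map–model correlation ≥ 0.7
(supplied as metadata, never computed here); 8–40 non-hydrogen atoms;
total charge in {−1, 0, +1}; a strain trigger of mean bond r.m.s.d.
≥ 0.2 Å **or** angle r.m.s.d. ≥ 5° **or** torsion r.m.s.d. ≥ 30°; and a
component code outside the common-solvent list (MES, PEG fragments,
glycerol, sulfate, …; user-extensible — the published list is explicitly
open-ended). Missing metadata yields an *indeterminate* verdict, never a
silent pass, and each criterion is logged with its observed value. Before
per-ligand screening, entry-level predicates check molecular weight
(< 2000 kDa), absence of nucleic-acid residues and presence of a ligand.

## The built-in optimizer (and what it is not)

The built-in backend is **not** a quantum-mechanical method. It exists so
the complete pipeline — including caching, mobile-atom bookkeeping and
restraint regeneration — is exercisable and testable at desk scale, and
as a transparent reference implementation of the mechanics. Its objective
is assembled from the base dictionary:

* harmonic bond terms, weight `1/esd²` (Å⁻²);
* harmonic angle terms in radians, weight `1/esd_rad²`;
* periodic cosine torsion terms `k·(1 − cos(p·(φ − φ₀)))` with
  `k = 2/(esd_rad²·p²)`, so the small-deviation curvature matches the
  harmonic e.s.d.;
* a soft nonbonded repulsion `100·(r₀ − r)²` for `r < r₀` with
  `r₀ = 0.75·(vdW_i + vdW_j)`, skipping pairs within three bonds and
  polar-hydrogen/acceptor pairs (hydrogen bonds are wanted contacts);
* caps and water hydrogens restrained to their ideal attachment geometry;
  co-optimized side chains restrained to their input bond lengths.

Minimization is diagonally preconditioned conjugate-gradient descent
(Polak–Ribière⁺ with automatic reset) under an Armijo backtracking line
search; an accepted step is additionally shrunk while halving it strictly
improves the objective, which suppresses the zigzag of barely-decreasing
overshoots on stiff bond terms. The per-atom preconditioner is the summed
curvature of the incident terms. Everything is deterministic — no
randomness anywhere — so the trajectory, the monotone objective trace and
the result are bit-reproducible. Convergence is declared when the largest
gradient component falls below 10⁻² objective units/Å (objective units are
squared deviations in e.s.d.s, so this corresponds to residuals of a few
tenths of a degree on a 30° torsion) or when 25 consecutive accepted steps
change the objective by less than one part in 10⁹; the step budget
defaults to 10⁴. A gradient above 10⁶ aborts with diagnostics;
non-convergence is reported in the result, not thrown.

Results are cached to a JSON sidecar keyed by an MD5 content hash of the
job (method, charge, mobile set, all coordinates at 10⁻⁷ Å resolution,
dictionary targets), so a rerun of an identical job reads the file —
changing any coordinate by 10⁻⁶ Å invalidates the entry.

External engines are reached through a file-level adapter: a MOPAC-style
Cartesian deck (method keyword and charge directive; one row per atom with
per-coordinate optimization flags, 1 mobile / 0 fixed) and a parser that
extracts the last Cartesian-coordinates block and the final
heat-of-formation scalar. The engine binary itself is out of scope; the
adapter takes a runner callback and the tests exercise it with an echo
mock.

## The fixture generator

`generate_fixture()` builds the study system every test runs on: a toy
ligand constructed from internal coordinates (6–n heavy atoms: a butane-
like backbone, a hydroxyl, a tertiary amine carrying a methyl whose
H-torsion has period 3, and an alkyl tail), with a dictionary *measured
from the ground-truth geometry* — so every target is exact by
construction. Three torsion restraints are designated: a rotatable
backbone torsion (period 1), a pucker-like torsion carrying an aperiodic
alternative 120° away, and the period-3 methyl torsion. The pocket is a
set of glycine tripeptides whose middle residues touch the ligand at
3.0–3.3 Å (each contributing two genuine peptide cut bonds), and waters
are bare O atoms near the ligand's polar atoms. The pocket is placed
around the **ground-truth** conformation: the crystal environment holds
the in-situ geometry, and the perturbed ligand plays the mis-restrained
deposited model. Perturbations apply seed-signed offsets to the ligand's
internal coordinates; the torsion magnitude twists each restrained
rotatable bond by exactly that amount, so a 40° setting yields a torsion
r.m.s.d. of 40° by construction. A fixed seed gives byte-identical PDB and
CIF output.

What the generator does *not* emulate: experimental data (no structure
factors, maps or map–model correlations — CC values are metadata inputs
throughout), conformational disorder and altlocs, metals and their
coordination chemistry, aromatic systems and genuine fused-ring pucker,
solvent beyond explicitly placed waters, and coordinate noise of the kind
refinement against real data produces. Green tests therefore demonstrate
the correctness of the mechanics — selection, symmetry, capping,
measurement, regeneration arithmetic and the optimizer's contract — not
that a semi-empirical Hamiltonian would reproduce a particular deposited
ligand geometry.

Test problem sizes are deliberately small: fixtures of ~38 atoms, clusters
of ~30, brute-force symmetry enumerations over one-atom models in 50
random cells, and a 10⁴-sample periodicity property check; the full suite
runs in well under a minute on one core.

## Degenerate inputs and edge rules

Cells with non-positive axes, angles outside (0°, 180°) or zero volume are
refused. Unknown space groups without explicit operators are a
configuration error; matching is case- and spacing-insensitive and accepts
short monoclinic symbols. Symmetry images that coincide with their source
atom within 0.1 Å (special positions) are dropped. Selection and
validation radii are compared inclusively (an atom at 3.49 Å is in, at
3.51 Å out). Collinear atoms make a torsion undefined (an error, not a
NaN). Restraints with missing e.s.d.s fall back to 0.02 Å / 2° / 30° with
a warning. Waters with more than two hydrogens are a validation error; one
existing hydrogen is completed to the 104.5° geometry. Water hydrogens
point at the two nearest O/N acceptors within 3.5 Å; with one acceptor the
second hydrogen completes the angle in a deterministic frame, with none a
canonical frame is used — a documented heuristic, since no orientation
rule is standard.

## Known limitations

* The built-in objective has no electrostatics, no attractive dispersion
  and no hydrogen-bond term; it cannot rank competing poses, only relax
  into the nearest pocket-compatible minimum.
* Zwitterionic termination implements the standard charged termini only;
  unusual backbone chemistry falls back to hydrogen caps with a warning.
* pKa prediction, histidine flips and protonation-state enumeration are
  out of scope, as is strain-energy calculation.
* Anisotropic displacement records, multi-model ensembles and
  SEQRES/entity bookkeeping are not parsed.
* The monomer-library CIF writer emits the categories this workflow needs;
  exotic dictionary extensions beyond the documented
  `_qmrestraints_tor_alt` loop are not round-tripped.
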