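---
title: "Shift-dependent interaction maps: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shift-dependent interaction maps: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftmaps)
```

## The problem

In NMR crystallography of molecular solids one routinely has a molecule's
covalent structure and a set of assigned experimental isotropic chemical
shifts (¹H, ¹³C), and wants to decide which of many computed candidate
crystal packings (a crystal structure prediction, CSP, set) is compatible
with those shifts. Chemical shifts are exquisitely sensitive to the local
packing — hydrogen bonding, ring currents, close contacts — but turning a
shift into a statement about three-dimensional structure normally requires
expensive quantum chemical shift calculations for every candidate.

`shiftmaps` implements a statistical alternative. Given a database of
crystal structures in which every ¹H and ¹³C site carries a *predicted*
chemical shift (with an uncertainty), the local packing statistics of
chemically matching sites can be conditioned on the shift itself:

* a **shift-independent interaction map (IIM)** summarizes the average 3D
  atomic density around a class of chemically equivalent sites, built from
  environments selected at random;
* a **shift-dependent interaction map (SIM)** is the same density built
  from environments whose predicted shifts cluster around the measured
  value;
* the **difference SIM − IIM** shows which intermolecular features are
  promoted (positive) or suppressed (negative) by the measured shift; and
* a candidate packing is **scored** by overlapping its own local atomic
  density with that difference map.

## The procedure step by step

**Site classes are covalent descriptors.** The environment of a site is
characterized purely topologically: the labelled bond graph of all atoms
within $w$ bonds of the site (element labels and connectivity only — no
bond orders, charges or geometry, so the descriptor can be built directly
from a 2D structure drawing). Two sites match when an element-preserving
graph isomorphism maps center to center. Matching is confirmed by VF2
search; a Weisfeiler–Lehman refinement key is used as a sound prefilter
and as the database index (equal keys are re-checked by isomorphism, so a
hash collision can never produce a false match). The depth starts at
$w = 6$ and is reduced until more than `min_matches` database sites match
(3000 by default), trading specificity for sample size exactly when a deep
descriptor becomes too rare.

**Environments.** For every matching database site, the local atomic
environment is every atom within 7 Å, with the unit cell repeated so that
no periodic image inside the sphere is missed (the replication bound
`ceiling(radius / perpendicular_width) + 1` per axis provably covers
skewed cells).

**Selection.** From the matches, `n_select` (default 1000) environments
are drawn *without replacement* — sampling with replacement would count
the same atoms several times in the density average. The IIM selection is
uniform. The SIM selection repeats: draw a value from a Gaussian centered
at the experimental shift with width σ (0.5 ppm for ¹H, 5 ppm for ¹³C,
the scale of the database's prediction uncertainty) and take the
not-yet-selected entry with the nearest predicted shift, ties broken by
ascending entry id for determinism. For bonded C–H pairs with a correlated
(HETCOR-type) assignment, the draw is from an axis-aligned 2D Gaussian and
the nearest entry under the σ-normalized distance
$d = \sqrt{((c-\delta_C)/\sigma_C)^2 + ((h-\delta_H)/\sigma_H)^2}$
is taken; the per-axis widths are independent (no correlation term), and
one pair yields one map and one score, not two.

**Alignment.** Each selected environment is rigidly superposed onto a
chosen reference conformation of the query molecule by minimizing the RMSD
of 3–4 anchor atoms (Kabsch algorithm, proper rotations only — a
reflection would silently invert chirality). Anchor atoms should sit
within about two bonds of each other, except in rigid motifs (phenyl,
carboxyl) where more distant atoms are fine; the choice is chemistry
dependent and therefore user configuration, not automation. When local
symmetry (a methyl rotor, for example) admits several witness
isomorphisms, all are enumerated and the lowest-RMSD pairing is used.

**Density maps.** Per element, the aligned environments are accumulated as
unnormalized unit-amplitude Gaussians of standard deviation σ = 0.5 Å
placed at each atomic position, evaluated on a 31 × 31 × 31 grid with
12 Å sides centered at the queried site (spacing exactly 12/30 = 0.4 Å),
and divided by the number of environments. The normalization fixes the
scale: an atom present at the same position in *every* environment gives a
value of exactly 1, making maps comparable across different `n_select`.
All atoms of an environment contribute, including any outside the box, so
there is no edge discontinuity. In the difference map, voxels with
magnitude below 0.01 are set to zero to suppress selection noise.

**Scoring.** A candidate's site score is the plain voxelwise product sum
of its own single-environment density (per element, summed over all
element channels) with the thresholded difference map: positive means the
candidate realizes packing promoted by the measured shift, zero means
shift-neutral, negative means the packing is typical of *other* shifts.
Sites whose descriptor maps onto several atoms with different assigned
shifts (CH₂ protons, symmetric aromatic positions) are flagged ambiguous
and excluded from the global mean. Across a candidate set the global
scores are mean-centered, which removes systematic offsets (including any
overall scale: no voxel-volume factor or candidate-mass normalization is
applied, because any common factor cancels here) and makes scores
comparable only *within* a set — the intended use is pre-selection and
ranking, not an absolute compatibility measure.

## The synthetic database

The package is validated without any proprietary structure database or
learned shift model, using `generate_toy_crystals()`: orthorhombic cells
containing rigid formic acid (and methanol) molecules packed as

* **dimers** — two molecules related by inversion with a pair of
  O–H···O=C bonds (H···O drawn from 1.60–1.80 Å),
* **chains** — a translation catemer; a straight-on H-bond would force a
  sterically impossible ~3.2 Å period, so the bond is bent 55° in-plane,
  giving a 3.97 Å period with a minimum non-designed intermolecular
  contact of 2.14 Å,
* **isolated molecules** — no intermolecular contact under 2.5 Å.

Pseudo-shifts replace the learned predictor with the minimal coupling that
makes SIM ≠ IIM: `shift = class base + Δ · 1(intermolecular acceptor O
within 2.0 Å) + Normal(0, noise)`, with Δ = 4 ppm and noise 0.2 ppm as the
validation conditions, class bases of 6 ppm (hydroxyl H), 8 ppm (formyl
H), 3.5 ppm (alkyl H), 165/50 ppm (carboxylic/alkyl C), and uncertainties
fixed at 0.5 ppm (H) and 5 ppm (C). A hydroxyl proton therefore reads
10 ppm when hydrogen bonded and 6 ppm when not — an idealized, step-like
caricature of the real downfield H-bond shift.

What the generator deliberately does **not** emulate: conformational
flexibility, thermal disorder, realistic shift distributions (real ones
are continuous and multimodal, not two-valued), aromatic ring currents,
or descriptor diversity (two molecule species only). Passing tests
demonstrate that the machinery — matching, selection, alignment,
accumulation, scoring — recovers a known structure–shift relationship;
they do not demonstrate discrimination power on real CSP sets.

## A worked run

```{r example, eval = FALSE}
toy <- generate_toy_crystals(40, seed = 11)
shifts <- make_shift_table(toy$structures, seed = 12)
db <- build_database(toy$structures, shifts)

cand <- make_candidate_set(n_decoys = 3, seed = 13)
asn <- assignment_table(label = c("H2", "H1"), nucleus = c("H", "H"),
                        shift_ppm = c(10, 8))
anchors <- list(H2 = c("H2", "O2", "C1", "O1"),
                H1 = c("H1", "C1", "O1", "O2"))

fit <- shift_maps(db, cand$molecule, asn, anchors,
                  n_select = 30, min_matches = 10, seed = 42)
summary(fit)
plot(fit, site = "H2", element = "O")
predict(fit, cand$candidates)
```

On this database the O-channel difference map for the hydroxyl proton
peaks at ~0.24 in the acceptor shell 1.6–1.8 Å from the proton, and the
dimer candidate ranks first with a strongly positive normalized score
while the isolated decoys tie slightly below zero.

## Numerical choices and degenerate inputs

* **Problem sizes.** The validation suite runs at deliberately small
  scale: databases of 8–40 structures, 8–30 selected environments per
  map, and `min_matches` lowered accordingly (the two thresholds are
  plain configuration). The statistical structure of the method is
  unchanged; only sampling noise is larger, which the tests' tolerances
  account for.
* **Coordinates.** Fractional coordinates are stored in [0, 1); Cartesian
  conversion uses the standard lower-triangular cell matrix (a along x,
  b in the xy plane). One convention everywhere removes any ambiguity in
  image generation.
* **σ as standard deviation.** The density "width" is implemented as the
  standard deviation in $\exp(-d^2/2\sigma^2)$; likewise the shift
  sampling widths. This is an interpretation choice, applied
  consistently.
* **Ties.** Nearest-shift ties break by ascending entry id; equal
  candidate scores keep stable id order. Both make seeded runs
  byte-for-byte reproducible.
* **Degenerate inputs.** Near-zero cell volume, collinear anchor atoms,
  partial-occupancy (disordered) CIF sites, selection requests exceeding
  the match pool, and all-ambiguous assignments are refused with specific
  errors rather than silently handled — each would corrupt maps or scores
  quietly.
* **Bond perception** uses the 1.15 × covalent-radius-sum heuristic
  (radii shipped as a data file, both configurable); hydrogens must end
  up with exactly one bond or a warning is raised.
* **Volumetric export** writes Gaussian cube (text, Bohr) and MRC/CCP4
  (binary, float32) for contour display in standard viewers; both
  round-trip within 10⁻⁵.

## Known limitations

* Symmetry-equivalent sites of a database structure are all indexed; the
  redundancy slightly over-weights high-symmetry packings in the
  statistics (de-duplication would require symmetry perception, which is
  out of scope).
* Descriptors ignore bond orders and charges; sites differing only in
  those are treated as one class.
* The 2D selection assumes independent per-axis widths; correlated
  uncertainties are not modelled.
* Scores are relative within a candidate set. A single candidate cannot
  be accepted or rejected on its own score.
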