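---
title: "Alignment-free comparison of enzyme active sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free comparison of enzyme active sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biogps)
```

## The problem

Enzymes of the serine-hydrolase superfamily — lipases, esterases,
proteases, amidases — share essentially the same catalytic machinery (a
nucleophilic serine, a general base, an oxyanion hole) yet hydrolyze very
different substrates. Sequence identity across the superfamily is low and
plain structural superposition of the catalytic residues shows them nearly
indistinguishable, so neither sequence alignment nor geometric overlap
explains the functional split. The working hypothesis behind this package
is that the difference lives in the *pre-organized environment* of the
active site: the spatial arrangement of hydrogen-bond donors, acceptors and
hydrophobic surface that stabilizes one transition state better than
another.

`biogps` quantifies that environment. Each active site is mapped with four
chemical probes, the resulting interaction fields are condensed into an
alignment-free four-point fingerprint, sites are compared all-against-all
by the volume overlap of their fields (a Tanimoto score per probe plus a
global score), and the similarity profiles are clustered by principal
component analysis. New structures — for instance point mutants designed to
shift activity — are *projected* into the fitted map without refitting,
which turns the map into a fixed roadmap for enzyme engineering.

## Pipeline and model

### 1. Pocket detection

The active site is found on a cubic lattice (default spacing 1 Å, 4 Å
margin) by a buriedness scan: a node belongs to the pocket when it is
solvent-accessible (≥ 1.4 Å outside every van der Waals surface) and at
least `b_min = 14` of the 26 lattice rays hit protein within 8 Å. The
pocket is the largest 26-connected component of such seed nodes, grown by
hysteresis through neighbors with buriedness ≥ 12. The hysteresis step
matters: any single threshold flickers at the mask boundary when the
structure is re-gridded in a rotated frame, while seed-plus-growth keeps
node agreement above 99% in our rotation tests. A deterministic manual
override, `pocket_from_serine()`, takes every accessible node within a
radius (default 10 Å) of the catalytic serine Oγ, so mutant studies need
not depend on cavity-detection details.

### 2. Probe fields

Four probes sense complementary properties on the pocket nodes:

| probe | senses                | energy terms                          |
|-------|-----------------------|---------------------------------------|
| H     | shape                 | 12-6 Lennard-Jones only               |
| O     | site H-bond donors    | LJ + directional H-bond well at donors |
| N1    | site H-bond acceptors | LJ + directional H-bond well at acceptors |
| DRY   | hydrophobicity        | LJ + Gaussian kernel at nonpolar carbons |

The H-bond well is `e_hb · cos²θ · exp(−(r − 2.9)²/(2·0.45²))` inside 4 Å,
with θ measured from the donor-H (or acceptor lone-pair) axis approximated
by the bonded-neighbor direction, `e_hb = −4` kcal/mol for the O probe and
`−3` for N1 — the probes' implicit partial charges enter through these
magnitudes. The hydrophobic kernel is `−0.6 · exp(−(r − 4)²/2)` per carbon
bonded only to C/H (a named table per residue). Energies are clamped to
[−15, +5] kcal/mol. Donor/acceptor typing is a transparent residue/atom
table covering the backbone and the usual side chains. All constants sit in
`probe_params()` and can be overridden from a config file; they are an
openly documented energy model, not a reproduction of any proprietary
force-field table.

### 3. Pseudo-fields and representative points

Each field is condensed twice. For scoring, the favorable part is
re-expressed as Gaussian kernels centred on the chemically eligible atoms
(donors for O, acceptors for N1, nonpolar carbons for DRY, pocket-lining
heavy atoms for H); every favorable node is attributed to its nearest
eligible atom. By default an atom's weight is binary — it attracted
favorable energy or it did not — because the raw energy split between
neighboring atoms depends on lattice placement much more than on chemistry;
`weight_mode = "energy"` keeps the attributed energy sums, normalized by a
per-probe characteristic energy `e_ref` so that electrostatic and
hydrophobic fields live on one scale. Kernel widths are σ = 1.0 Å (H),
1.2 Å (O/N1/DRY); widths well below ~1 Å make the overlap blind to the
ordinary positional variation of equivalent donors between structures.

For matching, `select_points()` greedily keeps the most favorable nodes at
least `min_sep = 1.5` Å apart (at most `k_per_probe = 8` per probe in the
pipeline, so the pooled set stays near 30 points and the quadruplet count
in the tens of thousands).

### 4. Quadruplet fingerprint (Common Reference Framework)

All C(n, 4) four-point subsets of the pooled representative points are
encoded as discrete codes: the sorted probe-label multiset, the six
pairwise distances binned at 2 Å (capped at 16 Å), and a chirality sign
(zeroed below 0.5 Å³ of signed volume). Members are canonically ordered by
probe label, then the sorted triple of incident distances, then energy, so
any permutation of the same four points yields one code. Codes are
invariant under rigid motion and flip only their chirality field under
reflection. The 2 Å bin width is deliberate: with 1 Å bins, two
independently built pockets of the same chemistry almost never place a
corresponding quadruplet in identical bins (six distances each jittered by
~0.5 Å), and matching degenerates to coincidental collisions.

### 5. Comparison and Tanimoto scores

Two sites are compared through their shared codes. Every matched quadruplet
proposes a superposition (Horn fit of the four points); correct alignments
are proposed independently by many genuine matches while collisions
scatter, so candidate poses are clustered by rotation/translation
(geometric-hashing voting) and the consensus poses are scored. Four
principal-axis alignments of the pooled pseudo-fields are always added as
global shape guesses, and each candidate is polished by coarse-to-fine
kernel-correlation refinement (an EM loop that alternates soft same-probe
correspondences with a weighted rigid fit, first at doubled kernel widths,
then at the true widths). The pose maximizing the global score wins and all
per-probe scores are reported at that single pose.

Volumes are analytic Gaussian overlap integrals: `V_a` is a field's
self-overlap, `V_overlap` the cross integral under the pose (capped at
`min(V_a, V_b)`), and each probe scores `T = V_ov/(V_a + V_b − V_ov)` ∈
[0, 1]. The global score pools volumes over probes before the Tanimoto
(`global_mode = "pooled"`); the mean of defined probe scores is available
as an alternative. Pairs are always evaluated in a canonical id order, so
`compare_pair(a, b)` and `compare_pair(b, a)` agree exactly, and
self-comparison scores 1 by construction.

### 6. Clustering and projection

`all_against_all()` assembles five square Tanimoto matrices (H, O, N1, DRY,
global). `fit_upca()` treats each site's matrix row — its similarity
profile against all references — as its feature vector, mean-centers the
columns and decomposes them (no variance scaling; the profiles are already
on one scale). Explained-variance ratios cover all components and sum
to 1; eigenvector signs follow a fixed convention so maps are reproducible.
`project_site()` computes a new structure's similarity row against the
original references only, centers it with the stored means and multiplies
by the loadings — the model is never refitted, so mutants cannot deform the
map they are judged against. `baseline_rmsd_mds()` provides the whole-fold
foil: classical MDS of a crude backbone RMSD matrix (backbone atoms paired
by residue rank, truncated to the shorter chain).

### 7. Catalytic-machinery superposition

Independently of the alignment-free pipeline, `superpose_on_anchors()`
implements the classical visual-inspection superposition: the general-base
nitrogen (e.g. His Nε2) and the two oxyanion-hole backbone amide nitrogens
are fitted with the closed-form Horn quaternion solution, iteratively (15
rounds by default; round 1 fits everything to the first structure, later
rounds to the running mean anchor positions — the anchor-RMSD trace is
provably non-increasing). Serine hydrolases occur in both hands; with a
serine Oγ as fourth anchor the signed volume of the anchor tetrahedron
decides handedness and `auto_reflect = TRUE` mirrors (x → −x) structures of
opposite chirality before fitting. The oxyanion-hole selectors default to
backbone amide N, the natural reading of the conserved donors, and accept
explicit atom overrides (e.g. `"TYR 473 OH"`) for the rare Tyr-hydroxyl
oxyanion holes.

## The synthetic test bed

Validating this kind of method on real enzymes requires downloading crystal
structures and committing to a full force-field parameterization; neither
belongs in an offline, seconds-scale test suite. The package therefore
ships a deterministic generator of synthetic "active sites" with a
controllable ground truth. `make_toy_pocket()` builds a spherical-cap cup
(default radius 8 Å) lined with `n_lining = 24` rigid two-atom groups
pointing inward — amide-like N–H donors, carbonyl-like C=O acceptors,
methyl-like carbons, jittered by σ = 0.35 Å — behind a dense shape-only
carbon wall that makes the cavity watertight for the buriedness scan. Atom
and residue names are legal PDB names (GLY/ALA fragments), so the readers
and typing tables run unchanged. Three study classes differ only in lining
chemistry: donor-rich, acceptor-rich and hydrophobic (0.70/0.15/0.15
splits), eight seeds each. `morph_pocket()` re-types a seeded subset of
groups step by step toward a target chemistry — a mutant series with known
direction. `make_mirror()` supplies enantiomeric copies.

What the fixtures do *not* emulate: real pocket shapes (every cup is the
same cap), backbone context, conformational flexibility, water, or the
energetic subtlety of a real force field. Passing the studies below
therefore shows that the machinery — detection, mapping, encoding,
matching, scoring, clustering, projection — behaves correctly and
discriminates chemistry under controlled noise; it does not certify
accuracy on crystal structures.

## Validation studies and problem sizes

The test suite and `scripts/acceptance.R` recompute, from scratch:

- **Similarity axioms** on ~16 random-recipe pockets, 100 pairs in both
  directions: every score in [0, 1], exact symmetry, self-similarity 1.
- **Rigid-motion recovery**: a site against rigidly moved copies of itself
  (global ≥ 0.99; pose recovered within 2° / 0.25 Å).
- **Horn oracle**: the quaternion fit against a brute-force Euler-grid
  search on ≤ 6-point sets; mirror pairs keep a strictly positive residual.
- **Combinatorics**: C(n, 4) counts, rigid-motion invariance of the code
  histogram, chirality flips under reflection.
- **PCA/MDS oracles**: scores and variance ratios against direct
  eigendecomposition; planar-distance recovery to 1e-6.
- **Class recovery**: the 3 × 8 study; within-class mean global similarity
  exceeds between-class by ≥ 0.05 and the class silhouette on (PC1, PC2)
  is ≥ 0.4.
- **Mutant-morph projection**: a 3-step donor→hydrophobic morph moves
  monotonically toward the hydrophobic centroid; step 0 stays nearest its
  own class.

These sizes (24 reference pockets, 10–25 random repetitions per oracle)
were chosen so a full run completes in minutes on one CPU while leaving
large margins on every threshold.

## Worked example

```{r example, eval = FALSE}
library(biogps)

# three donor-rich and three hydrophobic pockets
classes <- fixture_classes()[c("donor", "hydrophobic")]
structs <- make_fixture_set(classes, per_class = 3, seed = 7)

sites  <- lapply(structs, characterize_site)
simmat <- all_against_all(unname(sites))
round(simmat$global, 2)

model <- fit_upca(simmat, "global", n_components = 2)
model          # variance shares of PC1/PC2
plot_embedding(model$embedding, labels = attr(structs, "manifest")$class)

# project a morphed "mutant" into the fitted map
mutant <- morph_pocket(structs[["donor_01"]],
                       fixture_classes()$hydrophobic,
                       steps = 3, seed = 42)[[4]]
project_site(model, characterize_site(mutant), unname(sites))
```

## Numerical choices and degenerate inputs

- Pose candidates are deduplicated at 8° / 1.5 Å; refinement runs 6 EM
  iterations at doubled widths, then 6 at the true widths; ties in the best
  global score keep the earlier candidate in vote order. Budgets
  (`m_max = 500` matches, `max_poses = 15` clusters) are config options.
- Collinear quadruplets cannot anchor a pose and are skipped; `horn_fit()`
  rejects n < 3 and collinear sets outright.
- Probes absent on both sides are undefined (`NA`) and excluded from the
  global score; absent on one side they count as zero overlap.
- Empty point sets give empty fingerprints (with a warning) and zero
  scores; pairwise failures inside `all_against_all()` are flagged and
  recorded, never fatal.
- A near-planar quadruplet (|signed volume| < 0.5 Å³) gets chirality 0 and
  matches either hand.
- Similarity matrices with NA probes lose that probe from the PCA input
  only if selected explicitly; `fit_upca()` warns and zero-fills.

## Known limitations

- The energy model is deliberately simple (no electrostatics beyond the
  H-bond term, no protonation assignment, no solvent model); per-probe
  scores should be read comparatively, not as binding energies.
- Exact-code matching trades recall for speed; two sites sharing chemistry
  but differing everywhere by > 1 bin would produce no quadruplet poses and
  rely on the principal-axis candidates alone.
- The backbone-RMSD baseline pairs residues by rank, not by alignment; it
  is intentionally crude and only serves as a contrast to the
  alignment-free descriptors.
- Runtime grows with the fourth power of the representative-point count;
  the defaults keep a pairwise comparison below a second, but
  `k_per_probe` beyond ~12 becomes noticeably slower.
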