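---
title: "Mapping potential small-molecule binding sites with pocketmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping potential small-molecule binding sites with pocketmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketmap)
```

## The problem

Most structure-based drug discovery starts from a binding site that is
already known, usually because a ligand is bound in a crystal
structure. pocketmap implements the complementary, ligand-independent
route: detect candidate cavities purely from the geometry of a protein
structure, turn each cavity into a comparable *binding-site patch*,
score all patch pairs for similarity, and organise the resulting
similarity matrix into a map of binding-site space — clusters of
conserved sites within each protein target and links between targets
that share structurally similar sites (a signature of potential
polypharmacology).

The pipeline has five stages, each usable on its own:

1. **structures** — PDB/mmCIF input, atom classification, per-atom
   solvent accessibility, Kabsch superposition, crystallographic
   quality filtering.
2. **cavities** — alpha-sphere detection on the Delaunay complex,
   single-linkage pocket clustering, descriptors and a linear score,
   95%-recall threshold calibration, fpocket output parsing.
3. **patches** — pharmacophore-typed surface patches from a bound
   ligand (4 Å rule) or from a detected cavity via a pseudo-ligand
   (0.3 Å site size).
4. **compare** — Gaussian-overlap alignment and the 0–4 PatchScore;
   all-against-all similarity matrices.
5. **retrieval / mapping** — AUROC, enrichment factor, BEDROC;
   conservation filtering, hierarchical and DBSCAN clustering, link
   tables and Circos-compatible exports.

## Cavity detection

An *alpha sphere* is an empty sphere tangent to four atoms — the
circumsphere of a tetrahedron of the Delaunay complex of protein
heavy-atom centers. Spheres that are too small (buried interstices) or
too large (bulk solvent) are discarded; the defaults keep radii in
[3.0, 6.0] Å. The lower bound of 3.0 Å, together with a minimum
cluster size of 3 spheres, mirrors a detection setup biased towards
concise, ligandable depressions rather than large shallow basins.
Candidate spheres are clustered into cavities by single-linkage
connected components at 3.0 Å.

Two numerical choices matter here:

* The Delaunay complex is built by incremental Bowyer–Watson insertion
  with a deterministic 10⁻⁶ Å perturbation for general position.
  Candidate spheres are then *re-derived from the unperturbed
  coordinates* and re-checked against the empty-sphere invariant
  (no protein heavy atom strictly inside, 10⁻⁶ Å slack), so the
  detector's contract does not depend on the perturbation.
* Groups of five or more (near-)cospherical atoms produce several
  tetrahedra sharing one circumsphere; geometrically identical spheres
  are kept once.

Each cavity gets five descriptors — sphere count, mean sphere radius,
hydrophobic fraction (spheres with ≥ 3 carbon/sulfur tangent atoms),
polarity fraction, and a seeded Monte-Carlo volume of the sphere
union — and a transparent linear score over their standardized values.
The weights are package defaults (identified by a `weights_id`), not a
trained model: the trained coefficients behind the external fpocket
Score are unpublished, so pocketmap keeps its internal score simple and
monotone (bigger, more hydrophobic cavities rank higher) and treats
reported fpocket Scores as a separate scale. The conventional interop
cutoff Score ≥ 16.8 — the value above which 95% of known ligand sites
in a large curated complex set are recovered — is therefore applied
only to parsed fpocket output, never to the internal score.
`calibrate_score_threshold()` reproduces the calibration rule itself:
the largest threshold retaining at least the requested fraction
(default 95%) of known-site scores.

## From cavity to patch

A *patch* is the unit of comparison: the surface protein atoms around
a (pseudo-)ligand, carrying two kinds of points:

* **shape points** — the surface-atom centers;
* **pseudocenters** — typed interaction points from a residue/atom
  rule table with five types: hydrogen-bond donor, acceptor, anion,
  cation and hydrophobe. Asp/Glu carboxylates and the Arg guanidinium
  collapse to centroids; Ser/Thr/Tyr hydroxyls emit both a donor and
  an acceptor; aromatic rings collapse to one hydrophobe centroid so
  atom-rich rings do not dominate the color overlap (per-atom mode is
  available). Histidine defaults to neutral (two acceptor nitrogens)
  with a switch to the protonated cation form, since no protonation
  assignment is performed.

With a bound ligand, the patch is all surface atoms within 4 Å of a
ligand heavy atom. Without one, the cavity's *pseudo-ligand* — its
alpha-sphere tangent atoms restricted to the surface set (for parsed
fpocket pockets, the pocket-lining atom serials) — stands in for the
ligand, and the patch is all surface atoms within the *site size*
(0.3 Å) of a pseudo-ligand atom. At 0.3 Å that is effectively the
pseudo-ligand set itself plus exact-overlap neighbours; the patch
grows monotonically with site size, which trades retrieval quality
against comparison cost.

Surface atoms are defined by Shrake–Rupley accessibility ≥ 0.5 Å²
(probe 1.4 Å, 960 deterministic Fibonacci-lattice points per atom,
Bondi-type radii, 1.7 Å fallback for unknown elements). Accessibility
is computed over protein heavy atoms only, so a bound ligand never
masks its own pocket. Because the point lattice is fixed, areas are
bit-reproducible but rotation invariant only to quadrature error
(about 0.1–0.2% of the total at these point counts) — the invariance
test asserts 2·10⁻³ relative agreement at 2,000 points, which is the
honest accuracy of the quadrature, and any consumer needing tighter
invariance should raise `n_points`.

## PatchScore

Patch similarity is scored by Gaussian overlap. For point sets with
width parameter γ the overlap is the exact double sum

O(A, B) = Σᵢ Σⱼ δ(typeᵢ, typeⱼ) (π / 2γ)^{3/2} exp(−(γ/2) dᵢⱼ²),

computed once for shape (all pairs) and once for *color* (only
equal-type pseudocenter pairs), each normalized to a Tanimoto
coefficient T = O(A,B) / (O(A,A) + O(B,B) − O(A,B)). The score is

**PatchScore = 3 · T_color + 1 · T_shape ∈ [0, 4]**,

0 meaning complete dissimilarity and 4 perfect similarity. The same
3:1 combination is the alignment objective: the optimizer searches the
six rigid degrees of freedom for the transform of one patch that
maximizes it. Because the Tanimoto is symmetric, a patch compared with
a strict subset of itself cannot reach 4 — size matching is inherent.

Design choices worth knowing:

* **Gaussian widths.** γ_shape = 0.3 Å⁻², γ_color = 0.5 Å⁻² — color
  is more localized, so pharmacophore matches must be tighter than
  shape matches. These are package defaults, not values taken from any
  reference tool; both are arguments of every comparison function.
* **Deterministic multi-start.** Starts are the centroid-superposed
  principal-axes alignments of the shape points *and* of the
  pseudocenters (color carries ¾ of the objective weight, so a
  color-based start is as informative as a shape-based one), each with
  its three 180° axis flips — eight starts, no randomness, so
  similarity matrices are exactly reproducible. Each start is refined
  by Nelder–Mead with fresh-simplex restarts plus a BFGS polish; a
  start reaching the maximum attainable score (4) short-circuits the
  rest.
* **Degenerate inputs.** A patch with no pseudocenters contributes
  color 0 (the objective reduces to shape); self-overlaps are always
  positive for non-empty point sets.

`all_vs_all()` fills the symmetric matrix once per unordered pair
(canonical id order, so scores are exactly symmetric), records
individual pair failures as missing values rather than aborting, and
can append per-pair results to a plain-text store from which an
interrupted run resumes.

## Retrieval evaluation

Given a query patch and a labelled database, retrieval quality is
summarized by three standard early-recognition metrics:

* **AUROC** — trapezoidal area under the ROC curve with tied scores
  grouped; equal to the Mann–Whitney probability (ties ½). 1 is
  perfect, 0.5 random.
* **EF@5%** — positive rate in the top ⌈0.05 n⌉ items over the global
  positive rate; ceiling keeps the metric defined for small n, and
  ties at the cutoff resolve by stable input order.
* **BEDROC (α = 20)** — exponentially down-weighted positive ranks,
  Σ exp(−α·rank/N) over positives, normalized by its exact discrete
  extremes (all positives first / last). This makes a perfect ranking
  exactly 1 and an inverted one exactly 0; it agrees with the analytic
  Truchon–Bayly normalization to O(1/N), which the test suite checks
  against an independent implementation.

The retrieval protocol labels database patches by protein identity
with per-structure deduplication: for every structure sharing the
query's identity, only its best-scoring patch counts as a positive and
its sibling patches are *ignored* — removed from numerator and
denominator alike. Treating siblings as negatives would punish correct
retrieval of a structure that simply contributes several overlapping
patches, so "ignored" is a first-class label here.

## Mapping binding-site space

The all-against-all matrix is turned into a map in four steps, with
the defaults matching a conservative, conservation-first analysis:

1. **Conservation filter** — keep patches with ≥ 5 off-diagonal
   PatchScores ≥ 2.0 (single pass; the rule is not iterated). This
   removes sites seen in only one or two structures of a target, which
   carry little comparative information.
2. **Hierarchical clustering** — average linkage on Euclidean
   distances between PatchScore row vectors, first within each target
   (feature vectors restricted to same-target columns, capturing local
   structure), then globally over all retained columns. Dendrograms
   are always exported; flat labels require a cut, and since no
   natural cut count exists the cut is a caller-supplied `k`.
3. **DBSCAN** — density clustering with noise on the same row-vector
   feature space, ε = 7 and minimum neighbourhood size 10 (self
   included). The feature space makes ε dimensionally consistent:
   distances are between vectors of scores in [0, 4]. An alternative
   — running DBSCAN on (4 − score) dissimilarities directly — is a
   one-line change (`dist` of the score matrix vs. of its rows) but
   changes the meaning of ε; the row-vector convention is the package
   default because it matches the hierarchical feature space. Border
   points reachable from several clusters join the lowest-numbered
   one, making labels independent of input order.
4. **Links** — for every pair of (target, cluster) groups, the maximum
   member-pair PatchScore; links ≥ 2.0 are flagged "highlighted" (the
   red-ribbon convention of circular cluster maps). Within-target
   pairs are emitted too, marked by a `same_target` column, so the
   renderer can drop them if the display should show only
   cross-target similarity.

Exports are plain text (reordered matrix + id list for heat maps,
Circos karyotype/link files, JSON summary) plus an optional built-in
PNG heat map; text outputs are byte-stable for identical inputs.

## The synthetic generator: what it does and does not emulate

All tests run on generated data. `make_pocket_protein()` builds a
two-layer spherical shell of pseudo-residues (Fibonacci lattice,
~3–4 Å spacing, 0.15 Å positional jitter), carves each requested
pocket as a capsule-shaped invagination, lines it with single-atom
residues realizing the requested pharmacophore types (~3 Å spacing,
so linings are solvent-exposed like real pocket walls), and places a
small rigid pseudo-ligand at the pocket center, scaled to roughly fill
the pocket the way a drug-like ligand does. Ground truth — lining
atom indices, pocket centers, ligand atoms — is returned and can be
written as a JSON sidecar next to the PDB.

The generator is a pure function of its arguments: same seed, same
bytes. Families of related structures add i.i.d. Gaussian coordinate
noise (`make_structure_family`), and labelled score rankings with
perfect, random or graded enrichment feed the metric definitions.

What the toy structures deliberately are **not**: realistic protein
geometry. There are no bonded chains, no rotamers, no realistic
packing density, and the shell interior is hollow (the radius window
keeps bulk-void spheres out, but small background sphere clusters do
occur and are part of the test conditions). Passing the pipeline tests
therefore shows that detection, patching, scoring and mapping are
correct *as algorithms* and that planted signal of realistic magnitude
is recovered; it does not validate performance on crystallographic
data, which additionally depends on protonation, alternate
conformations and detection consistency across related structures.

## Problem sizes used by the test suite

The suite's end-to-end experiment uses three synthetic targets of 15
structures each (~400 atoms per structure): two targets share a
polar-lined pocket archetype, the third carries an all-hydrophobe
pocket. The full pipeline — detection, cavity patches,
all-against-all PatchScores (~10³ alignments), conservation filter,
per-target DBSCAN, link table — must highlight cross-target links
only between the two planted-archetype clusters. Metric-definition
checks use 100 random rankings of n = 10,000 with 1,000 positives;
oracle-equivalence checks compare Gaussian overlap, AUROC, DBSCAN and
average linkage against brute-force reference implementations on
small instances. These sizes keep the whole suite within a coffee
break on one CPU while leaving every stage's contract exercised
end to end.

## Known limitations

* The internal cavity score is a transparent linear stand-in with
  documented monotonicity, not a trained ranking model; its absolute
  values are not comparable to fpocket Scores (the `weights_id` field
  exists precisely to prevent accidental threshold mixing).
* SASA rotation invariance is limited by quadrature (see above).
* The alignment optimizer is local with deterministic multi-starts;
  pathological patch pairs (large, nearly symmetric point sets with
  conflicting shape and color optima) can settle below the global
  optimum. The score is still a valid lower bound and exactly
  symmetric.
* Hydrogens are parsed and flagged but ignored by accessibility and
  typing; protonation/tautomer assignment is out of scope.
* Retrieval-quality numbers on real structure databases depend on
  upstream preparation and cannot be reproduced from synthetic data;
  the package reproduces the metric machinery and its definitional
  anchors instead.
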