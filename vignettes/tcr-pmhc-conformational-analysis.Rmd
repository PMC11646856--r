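---
title: "Measuring apo-holo conformational change in TCR:pMHC-I interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring apo-holo conformational change in TCR:pMHC-I interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrflex)
```

# The scientific question

When an αβ T cell receptor binds a class I peptide-MHC, three things can
in principle move: the TCR's six CDR loops, the MHC's antigen-binding
domain, and the presented peptide. `tcrflex` separates and quantifies
those motions from pairs of unbound (*apo*) and bound (*holo*) crystal
structures that share a common IMGT numbering, and distinguishes two
qualitatively different kinds of loop motion:

* **bulk movement** — the loop rides on a change of its anchoring
  relative to the framework; the loop's own shape is preserved;
* **plastic deformation** — the loop's internal shape changes.

The package's measurements operationalise this distinction as a pair of
RMSDs: a *movement* RMSD taken after superposing the structures on a
reference frame that excludes the loop (the TCR framework regions, or
the β-sheet floor of the MHC groove), and a *deformation* RMSD taken
after additionally superposing the loop onto itself, which removes all
rigid-body content. Dihedral D-scores give an internal-coordinate view
of the same distinction, and per-residue heavy-atom profiles localise
deformation along the loop.

# Correspondence and curation

All residue correspondence is by IMGT (number, insertion code) — never
by sequence alignment. This is only sound because inputs are assumed
pre-renumbered with one consistent IMGT numbering; the package
deliberately does not renumber (a `renumber` hook on `read_structure()`
lets an external numberer rewrite numbers at ingestion). Unmatched
residues are simply excluded from a comparison.

Curation removes structures with resolution strictly above 3.50 Å
(records at exactly 3.50 Å are kept — the rule is "greater than") and
structures in which any analysis-critical residue (CDR residues for
TCR-containing records, peptide residues for pMHC-containing records)
lacks any of the four backbone atoms N, Cα, C, O. Side-chain gaps never
reject a structure, because every headline metric is a backbone metric.
Alternate locations resolve to the highest-occupancy conformer and only
model 1 of multi-model files is used.

Apo and holo structures are matched into entities by identity keys: the
concatenated six CDR sequences for a TCR, the peptide sequence plus
allele name for a pMHC. All apo × holo combinations of an entity are
kept; redundancy is handled downstream by entity normalisation (every
(entity, region, comparison, metric) cell is collapsed to its mean
before any statistic), so heavily crystallised entities cannot dominate.

## Region definitions

The IMGT delimitations are configurable via `region_config()` and
default to CDR1 = 27–38, CDR2 = 56–65, CDR3 = 105–117, framework =
positions 1–128 minus the CDRs. The groove floor is the one genuinely
open choice: we default to MHC positions 1–49 and 94–139, which span the
β-strands under the peptide in the α1/α2 domain, and expose the set as a
plain position list precisely because it is a documented judgement call,
not a community standard.

# Superposition and metrics

Rigid fits are least-squares (Kabsch) on matched backbone atoms, with
the reflection corrected so the rotation is always proper. A fit refuses
point sets whose centred cross-covariance has a singular value below
1e-10: coincident or collinear selections have no well-defined rotation,
and failing loudly beats returning an arbitrary frame. (Three-point and
planar selections also trip this guard; all built-in selections —
frameworks, floors, 40-atom loop anchors — are well-conditioned 3-D
sets.)

The D-score sums `2(1 − cos Δφ) + 2(1 − cos Δψ)` over residues matched
by IMGT position. Angles missing on either side (chain termini, chain
breaks — detected as peptide-bond C–N distances above 2.5 Å) are
skipped, never imputed, and the number of contributing angle pairs is
reported alongside the score. The raw sum is the default (bounded by
8·n); a length-normalised variant is available through
`dscore(..., normalize = TRUE)` since the raw sum grows with loop
length.

# Loop clustering

Loop conformations are compared after superposition on the backbone of
the five anchor residues flanking each side of the loop (40 atoms), so
the distance sees only the loop's shape and its pose relative to its own
stem, not the rest of the molecule. The distance itself is dynamic time
warping over the residue sequences:

* local cost = mean Euclidean distance over the residue pair's four
  backbone atoms (not Cα-only, to retain backbone-shape sensitivity);
* monotone warping with pinned endpoints, symmetric step pattern with
  diagonal weight 2 and horizontal/vertical weight 1;
* the accumulated cost is divided by `n + m`.

The weighting deserves a note. With unit steps the minimising path is
not unique and "divide by path length" is ill-defined under dynamic
programming; with the diagonal counted as two steps the total step
weight of *every* boundary-pinned monotone path is exactly `n + m`, so
the normalisation is path-independent, the optimum is well-defined, and
for equal-length loops where the identity warping wins the distance
reduces to the mean per-residue backbone distance. This is what makes
the measure comparable across loop lengths.

Clustering of the pairwise distance matrix is HDBSCAN with minimum
cluster size 5. No R implementation of HDBSCAN was available to build
on, so the package implements the published algorithm directly: core
distances (distance to the `min_samples`-th neighbour, the point itself
included, `min_samples = min_cluster_size`), mutual-reachability
distances, the single-linkage hierarchy (equivalent to the minimum
spanning tree construction), tree condensation under the minimum
cluster size, and Excess-of-Mass cluster selection with the root
excluded. Determinism comes from sorting loops by id before clustering;
heights of zero (duplicate conformations) are capped at 1e-12 before
inversion to λ. Clusters containing more than two unique sequences are
*canonical*, smaller sequence diversity makes a *pseudo* cluster, and
unassigned loops are *noise*; because the algorithm cannot emit clusters
below the minimum size, pseudo clusters implicitly require at least
`min_cluster_size` members.

Apo and holo loops of one loop type are pooled into a single clustering
so that labels are comparable across states — without a joint embedding
the apo→holo shift classification would compare incommensurable labels.
The shift taxonomy has exactly eleven categories (same/shifted canonical,
same/shifted pseudo, each cross transition, and stable noise) and is
exhaustive and mutually exclusive over label pairs by construction.

# Contacts and anchors

Contacts are heavy-atom pairs between CDR-loop atoms and pMHC atoms at
distance strictly below 5 Å, found with a cell-list spatial index whose
cell edge equals the cutoff (the index is provably equivalent to the
all-pairs scan, and the test suite and acceptance script verify the
equivalence on random complexes). Counting is at atom-pair granularity;
per-position loop fractions are computed per complex and then averaged
across complexes, mirroring the entity normalisation of the RMSD
analyses. A per-residue counting mode was considered and rejected as the
default because atom-pair counting weights large interfaces more
faithfully; the fingerprint machinery is agnostic to the choice.

Peptide motifs are simplified by banding per-position amino-acid
proportions at over 60% (*dominant*), over 30% (*high*), over 20%
(*medium*), over 10% (*low*) and at most 10% (*very low*); boundaries
are half-open with "over" read strictly, so exactly 0.60 is *high*.
Dominant/high positions are assumed to be groove anchors. Mode
assignment looks only at p2, the middle position (p5 for nonamers,
⌈N/2⌉ otherwise) and the C-terminus: {2, mid, C} ⊆ anchors gives
`P2_P5_P9`; anchor sets inside {2, C} — including single-end cases,
assumed anchored by another residue type at the missing end — give
`P2_P9`; anything else falls back to the nearer group by symmetric set
distance and is flagged. Anchors at other positions are recorded but do
not determine the mode.

# Statistics

Kruskal–Wallis and Wilcoxon rank-sum tests are delegated to the standard
`stats` implementations; the package adds the all-tied contract (H = 0,
p = 1, where the rank test is undefined), Bonferroni-corrected
significance levels of `0.05 / n_comparisons` for post-hocs, and entity
normalisation upstream of every test. Binding modes use the 0.5/1.0 Å
thresholds (`rigid` if any apo:holo value < 0.5 Å and none > 1.0 Å,
`flexible` for the mirror case, `intermediate` otherwise) with an
explicit `dual` flag for entities that show both behaviours across pMHC
contexts. Background comparisons sample a repertoire table uniformly
without replacement, 10 samples of 1000 unique TCRs by default, under a
caller-supplied seed; gene-level enrichment is
`100 · (dataset − background) / background` with allele suffixes
stripped before counting.

The "expected noise" guide level used when reporting movement summaries
defaults to 0.5 Å — deliberately the same value as the rigid-mode
threshold, since both encode the scale of coordinate differences
expected between independent crystal forms; it is a report parameter,
not an analysis input.

# The synthetic-data generator

The generator exists so that every stage has inputs with *known* answers.
It emulates:

* IMGT-numbered TCR and pMHC structures with idealised backbone geometry
  (internal-coordinate chain building, planar peptide bonds, consecutive
  Cα spacing ≈ 3.8 Å), seeded dihedral jitter, and valid region
  annotations;
* apo/holo pairs with planted motions. Rigid perturbations translate or
  rotate a whole loop, so the framework-aligned RMSD equals the planted
  magnitude and the loop-superposed RMSD is zero. Internal deformations
  are per-residue displacements, constant within a residue (so dihedral
  changes stay well-defined), with magnitudes following a weight profile
  (`midpeak`, `bimodal`, or `uniform`) and directions rotating along the
  loop; a final exact projection (with a magnitude-restoring fixed-point
  iteration) makes the field orthogonal to the rigid-body modes of the
  loop backbone. That orthogonality is what makes the validation sharp:
  the identity transform is then the optimal Kabsch fit, so the
  closed-form `sqrt(Σ dᵢ²/n)` of the applied field *is* the superposed
  RMSD, to machine precision rather than approximately. Flanking anchor
  residues are never displaced;
* loop families with planted cluster structure (rigid template offsets
  far exceeding within-family Gaussian noise, sequence multiplicity
  steering canonical vs pseudo labels);
* peptides whose anchor residues are pulled against the groove floor in
  either the p2–p9 or the p2–p5–p9 pattern, with motif tables planted to
  match the generated peptide sequences;
* background repertoires with controllable gene-usage frequencies.

What the generator does **not** emulate is equally important for
interpreting green tests: there is no side-chain realism beyond Cβ, no
crystallographic noise model beyond isotropic jitter, no correlation
between loop sequence and loop structure, and the docked complexes place
CDR loops individually over their binding sites rather than folding a
compact variable domain. Passing tests therefore demonstrate that the
*measurement machinery* is exact and the *decision rules* behave as
specified — they do not certify biological conclusions on real
crystallographic data, which bring disorder, alternate conformations,
numbering idiosyncrasies and genuine physics.

# Numerical choices and edge cases

* Kabsch degeneracy threshold 1e-10 on the smallest singular value;
  fewer than three atoms is an error.
* DTW on an empty loop is an error; duplicate loop ids are an error.
* Contact boundary is strict (`< 5 Å`) and honoured to machine
  precision; dominance threshold is strict (`> 1%`); dominant-loop ties
  break by the fixed loop order CDR1a, CDR2a, CDR3a, CDR1b, CDR2b,
  CDR3b and are logged in an attribute.
* Fewer points than the minimum cluster size yields all-noise, not an
  error; an empty contact list yields an empty fingerprint.
* Entities lacking either an apo or a holo form are excluded from
  comparison tables but kept in the manifest with a note.
* All generators and samplers take explicit integer seeds; pipeline
  stages reset the seed per stage, so stage outputs are bit-reproducible
  independently of execution order.

# Problem sizes

The shipped validation works at deliberately small scale: toy variable
domains of ~130 residues per chain, 9-mer peptides, 50 rigid-recovery
pairs, 100-case D-score and DTW oracle sweeps (loops of length ≤ 6 for
exhaustive path enumeration), 3 + 1 planted loop families of 8 members,
20 random 500-atom complexes for the contact oracle, 1000-replicate
permutation nulls, and a 2-entity end-to-end pipeline run executed twice
for bit-identity. These sizes keep a full validation under a couple of
minutes on one CPU while leaving every property sharply testable.

# Known limitations

* Region semantics assume class I geometry; class II MHCs, CD1/MR1 and
  γδ TCRs are out of scope.
* mmCIF files, crystallographic symmetry and biological assemblies are
  not handled; inputs are plain PDB files.
* The DTW step pattern and local cost are stated choices, not community
  constants; both are configurable at the code level and documented
  here because published descriptions of "length-independent DTW loop
  distances" underdetermine them.
* The native HDBSCAN implementation covers the precomputed-distance
  case used here (Excess-of-Mass selection, no single-cluster mode);
  it is not a general-purpose replacement for the reference library.
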