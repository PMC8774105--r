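---
title: "Detecting and mapping methionine-aromatic bridge clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and mapping methionine-aromatic bridge clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metbridge)
```

## The motif and the model

Methionine's thioether (CG–SD–CE, i.e. CH2–S–CH3) engages aromatic side
chains through a mixture of S–π, S-lone-pair–π and CH–π contacts, each
worth roughly 1–3 kcal mol⁻¹. An *n*-bridge cluster is one methionine
whose neighborhood contains the faces of *n* aromatic residues (Phe,
Tyr, Trp); the 3-bridge is the interesting case: small enough to be
common, large enough that the whole thioether — sulfur and both carbon
arms — participates.

`metbridge` operationalizes the motif in three layers:

* a **geometric contact criterion** between one Met and one aromatic
  residue,
* a **graph-theoretic cluster definition** on top of the contacts,
* a **canonical reference frame** in which cluster geometry from
  different structures becomes comparable.

## Contact criterion and its parameters

A contact exists when the configured Met-to-ring distance is at most
`cutoff_distance` (default **6.0 Å**, inclusive). The deliberately long
cutoff keeps weak, peripheral interactions; most real contacts sit at
2–4 Å from the ring once measured from the methyl/methylene arms. The
angular filter is **disabled by default** (`angle_cutoff_deg = 360`):
the criterion is purely distance-based, and the two lone-pair angles
are reported on each contact for downstream analysis rather than used
as a gate. When an angle cutoff is enabled, a contact passes if the
smaller of the two angles is within it.

Two distance metrics are supported because the literature uses both and
the choice is material near the cutoff:

* `sd_to_nearest_midpoint` (default): distance from SD to the nearest
  midpoint of a bonded ring-atom pair. This is the convention of the
  earlier Met-aromatic screening algorithm that bridge surveys build
  on.
* `sd_to_centroid`: distance from SD to the unweighted ring centroid,
  the quantity the frame analysis works with.

Every contact records **both** distances, so the metric choice is
auditable after the fact. The Met-side reference point is always SD;
proximity of the CH2/CH3 arms to a ring is an *output* of the frame
analysis, not part of the detection criterion.

Inter-chain contacts are included by default (`interchain = TRUE`), and
selenomethionine is excluded by default (`include_mse = FALSE`, SE
standing in for SD when enabled). Both are exposed as flags because
survey conventions differ and the counts are sensitive to them.

### Numerical choices

* The cutoff comparison is inclusive and carries a **1e-9 Å guard**:
  distances equal to the cutoff up to floating-point representation are
  kept. This is far below the 1e-3 Å precision of the coordinate
  formats; it only serves to make "exactly 6.000 Å" behave as the
  inclusive rule promises.
* Lone-pair directions are estimated in the plane spanned by the
  CG-SD-CE anti-bisector and the wedge normal, opened to the
  tetrahedral angle (cos⁻¹(−1/3)); swapping CG and CE swaps the two
  estimates.
* A thioether whose CG-SD-CE wedge is within **1°** of collinear is
  rejected as degenerate (with the residue named) rather than fed into
  an unstable frame; real methionines sit near 100°.

## The bridge graph

Contacts from one structure become edges of a bipartite graph (Met
nodes vs aromatic nodes, built on `igraph`). An *n*-bridge is a Met
with degree ≥ *n*. Two counting conventions exist when a Met has more
than *n* partners; both are implemented:

* **maximal** (default): one cluster per qualifying Met, carrying all
  its partners. This matches counting "how often the motif occurs per
  methionine".
* **subsets**: every *n*-subset emitted, for sensitivity analysis of
  the convention.

Clusters are keyed per (structure, model, Met residue): the same
residue number in two chains gives two clusters. Partner order within a
cluster is deterministic (chain, then residue number).

## The canonical Met frame

To compare cluster geometry across structures, each cluster's six
3-tuples — CG, SD, CE and the aromatic centroids C1..Cn — are mapped
into a Met-centered frame:

1. translate so SD is the origin;
2. **Q1**: with α the angle between SD→CE and the x-axis (the arccos of
   their direction cosine), rotate about the axis cross(SD→CE, x̂) so
   that SD–CE becomes colinear with +x;
3. **Q2**: rotate about x̂ by −β, where β = atan2(CG_z, CG_y) after Q1,
   bringing CG into the x,y-plane.

Quaternions are right-handed, scalar-first, active; the composition is
Q2·Q1 with Q1 applied first. The ± choice in β is resolved by requiring
**CG_y ≥ 0** — the CH2 arm points along +y — which fixes the frame
uniquely for every non-degenerate thioether under proper rigid motions.
A SD–CE bond that is already anti-parallel to x̂ (zero cross product) is
handled by a fixed half-turn about ẑ, not an error. Mirror images are
*not* silently absorbed: an improper motion of the input flips exactly
the sign of the local z-coordinates.

The construction is validated in the test suite to 1e-9 Å over 10⁴
random poses (canonicalization, distance preservation, rigid-motion
invariance) and the acceptance script re-measures the worst
canonicalization error at run time.

## Survey statistics

* **Composition tallies** run over the ten size-3 multisets of
  {PHE, TYR, TRP}, all keys always present. A cluster with more than
  three partners is tallied by its **three nearest** partners by
  contact distance (a `"skip"` mode is available); the convention is a
  package choice, stated here because published tallies rarely say.
* **EC classes** use the first digit of the first listed EC number of a
  structure's header (`EC1`..`EC7`), `"unclassified"` when absent or
  malformed. Multi-EC entries thus resolve deterministically by header
  order. Both per-structure and per-cluster weightings are available
  since aggregate percentages differ between the two.
* **Distance histograms** use half-open, left-closed bins [lo, hi) from
  zero, so boundary values are unambiguous; totals are conserved.
* **B-factor context** compares the mean B over all atoms of the
  cluster residues with the per-residue mean-B distribution of the
  protein (standard amino acids only), reported as a **midrank
  percentile** — stable under ties and invariant to affine rescaling of
  the B column. An all-zero B column flags the context uninformative
  rather than producing a meaningless rank.

Aggregation over a survey is deterministic: files are processed in
sorted identifier order, unparseable entries are isolated, counted as
failed and excluded from denominators, and repeated runs on the same
inputs are byte-identical.

## Coordinate input conventions

PDB files are read through `bio3d`; mmCIF `atom_site` records through a
small by-name category reader (field order in the wild is not fixed, so
values are resolved by tag name). In both dialects:

* only **model 1** of multi-model files is used (X-ray survey
  convention);
* hydrogens are dropped; detection uses heavy atoms only;
* alternate locations collapse to the **highest-occupancy** conformer,
  ties resolving toward altloc "A", with a warning;
* only PHE/TYR/TRP residues qualify as aromatic sites — never
  heteroaromatic ligands;
* Trp centroids use all 9 indole heavy atoms by default (a
  6-membered-ring-only option exists); Trp ring-bond midpoints are the
  10 bonds of the fused bicycle with the shared CD2–CE2 bond counted
  once;
* residues missing required atoms are skipped with a warning naming
  them; implausible thioether bond lengths (outside 1.0–2.5 Å) and
  markedly non-planar rings (> 0.25 Å out-of-plane) warn but keep the
  site.

## What the synthetic generator emulates

`build_structure()` plants a canonical methionine (bond lengths
1.81/1.79 Å, 100° wedge — fixture conventions, not claims about
proteins), aromatic rings at requested SD–centroid spherical
coordinates with arbitrary ring orientations, ALA decoys outside an
exclusion radius, per-residue B-factors, EC header labels, and defect
variants for each parser rule (altloc pairs, missing ring atoms,
selenomethionine, multi-model files). A seeded rigid motion is applied
so fixtures never sit in the canonical frame by accident. Ring atoms
are snapped so planted SD–centroid distances survive the 0.001 Å
fixed-column format to about 1e-4 Å; the `"grid"` pose (axis-permutation
rotation plus grid translation) preserves grid-aligned distances
exactly, which is what makes sharp cutoff-boundary tests possible at
all. Truth tables store *achieved* (post-rounding) geometry.

`build_survey()` allocates planted structures and compositions
deterministically (largest remainder), so a 200-structure survey at a
12% rate contains exactly 24 planted clusters. Non-planted structures
carry 0–2 in-range partners plus out-of-range aromatics: enough to
exercise lower bridge orders without creating accidental 3-bridges.
In-range partners are planted at 3.5–5.0 Å and out-of-range aromatics
beyond 9.5 Å so that presence/absence is unambiguous under **both**
distance metrics (a ring centroid just under 6 Å can still have all
midpoints beyond it, and vice versa).

What the fixtures do **not** emulate: full backbones and packing,
crystal symmetry, correlated B-factor structure, sequence context, or
physically realistic decoy environments. Passing the planted-survey
checks therefore demonstrates the correctness of detection, counting,
frame mapping and aggregation — not the field-realism of any particular
detection threshold on experimental coordinates.

## Problem sizes used in the checks

The bundled checks run at desk scale, chosen to make every comparison
exact: a 200-structure planted survey (12% rate), 100 structures for
the brute-force contact oracle, 10⁴ random poses for the frame contract
in the tests and 2000 in the acceptance script, and boundary fixtures
at 5.999/6.000/6.001 Å. A full-scale replication — tens of thousands of
culled PDB entries — uses the same `run_scan()` entry point with
`fetch_structure()` or a local mirror, and should report both distance
metrics and both counting modes, since published totals rarely pin down
either convention.

## Known limitations

* mmCIF reading covers the `atom_site`, `entity`, `refine`, `reflns`
  and `entry` categories needed here; exotic files using multi-line
  semicolon text inside those categories are not supported.
* EC annotation is taken from coordinate-file headers only; entries
  whose annotation lives solely in external databases count as
  unclassified, which inflates that bin relative to database-joined
  surveys.
* The lone-pair directions are an idealized tetrahedral estimate from
  heavy-atom geometry, not an electronic-structure quantity; they are
  reported for orientation analysis, not used for filtering by
  default.
* Bridge enumeration is star-shaped by construction (one Met plus its
  partners); longer alternating chains are visible in the interaction
  graph but not enumerated as motifs.
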