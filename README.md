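# metbridge

Survey tools for **methionine–aromatic "n-bridge" clusters** in protein
structures: sites where the thioether of a methionine (the
CG–SD–CE / CH2–S–CH3 group) is surrounded by the π faces of *n* aromatic
residues (Phe, Tyr or Trp). These weak S–π / CH–π contact networks — on
the order of 1–3 kcal mol⁻¹ per pairwise contact — recur across all
enzyme classes and have proposed roles in redox chemistry and in
balancing local stability against flexibility. `metbridge` is aimed at
structural bioinformaticians who want to detect these motifs in PDB/mmCIF
coordinate sets, examine their geometry in a common reference frame, and
tabulate survey-level statistics.

## What it computes

1. **Contact detection.** A Met and an aromatic residue are in contact
   when the distance from SD to the ring (to the nearest ring-bond
   midpoint by default, or to the ring centroid) is ≤ 6.0 Å; no angular
   criterion is applied by default (cutoff angle 360°). Both distance
   variants and the angles between the SD→ring vector and two
   lone-pair direction estimates are reported on every contact.
2. **Bridge enumeration.** Contacts form the edges of a bipartite
   residue interaction graph (Met nodes vs aromatic nodes). An
   *n*-bridge is a Met with aromatic degree ≥ *n*; the survey's subject
   is *n* = 3.
3. **Canonical Met frame.** Each cluster is mapped into a common frame
   by a two-quaternion construction: translate SD to the origin; rotate
   by Q1 about cross(SD→CE, x̂) through the angle α between SD→CE and
   the x-axis, making SD–CE colinear with +x; rotate by Q2 about x̂
   through −β so that CG lies in the x,y-plane with y ≥ 0. Aromatic
   ring centroids mapped with Q2·Q1 become comparable points
   (x, y, z) around the thioether.
4. **Survey statistics.** Composition tallies over the ten possible
   {Phe,Tyr,Trp} triples, enzyme-class (EC 1–7 / unclassified)
   breakdowns, SD–ring distance histograms, and per-cluster B-factor
   context (cluster mean vs the protein's per-residue distribution).
5. **Synthetic fixtures.** A generator that writes valid PDB files with
   clusters planted at exact SD–centroid spherical coordinates, decoy
   residues, defect variants (altlocs, missing ring atoms,
   selenomethionine, multi-model) and a ground-truth table, so the whole
   pipeline is testable offline.

## Worked example

```r
library(metbridge)

d  <- file.path(tempdir(), "demo")
sv <- build_survey(d, n_structures = 25, planting_rate = 0.2, seed = 42)
res <- survey_run(d)
print(res$summary)
#> Survey of 25 structure(s) at bridge order 3
#>   clusters: 5 in 5 structure(s) (20.0%)
#>   compositions: PHE-PHE-PHE=1, PHE-PHE-TRP=1, PHE-PHE-TYR=1, PHE-TRP-TYR=1, PHE-TYR-TYR=1

head(res$cluster_table[, c("structure_id", "met_number", "composition",
                           "min_distance", "max_distance")], 3)
#>   structure_id met_number composition min_distance max_distance
#> 1        S0001          1 PHE-PHE-PHE     3.016409     3.812947
#> 2        S0004          1 PHE-PHE-TYR     2.996289     3.617991
#> 3        S0005          1 PHE-TYR-TYR     2.904422     3.306223
```

Five of the twenty-five generated structures carry a planted 3-bridge
(the requested 20% rate), and the pipeline recovers each one: the
composition key names the three aromatic partners and the distance
columns give the range of SD-to-ring distances within the cluster.
`res$local_points` holds the ring centroids of every cluster in the
canonical Met frame, ready for spatial-distribution plots, and
`res$summary$ec_counts` the enzyme-class breakdown.

To scan your own files, point `run_scan()` (or
`inst/scripts/metbridge-cli.R scan`) at a directory of PDB/mmCIF files,
optionally with an ID list; `fetch_structure()` can download entries
from the RCSB if network use is wanted.

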