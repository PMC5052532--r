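---
title: "Interaction fingerprints, pose triage and binding-site geometry: methods"
author: "siftr package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction fingerprints, pose triage and binding-site geometry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siftr)
```

## Motivation and scope

Docking a compound library into a receptor produces many geometrically
plausible poses whose scores alone are poor predictors of true binding.
A widely used remedy in nuclear-receptor screening campaigns is to
*triage poses by their interaction pattern*: encode each protein-ligand
complex as a structural interaction fingerprint (SIFt), compare
fingerprints with the Tanimoto coefficient, cluster poses jointly with a
panel of reference crystal complexes, and keep the poses that fall in a
reference-anchored cluster and satisfy a small set of anchor-residue
rules.  This package implements that machinery, together with the
quantitative binding-site geometry used to characterise the resulting
complexes: H-bond network tables, gate-keeper chi1 rotamer calls,
van der Waals clash scans and grid flood-fill cavity volumes.

Docking itself, compound standardisation, substructure searching and
frequent-hitter filtering are out of scope: scores and structures are
consumed, never produced.

## The fingerprint model

For a fixed, ordered panel of binding-site residues, each residue
contributes a block of nine bits, one per interaction class, in this
fixed order: any contact, backbone, side chain, polar, aromatic,
hydrophobic, H-bond donor, H-bond acceptor, charged.  A fingerprint is
the concatenation of the blocks, so its length is `9 * |panel|`, and two
fingerprints are comparable only when built on the same panel.  Two
conventions deserve emphasis because published descriptions usually omit
them:

* **Bit perspective.**  `hbond_donor` means the *residue* donates to the
  ligand; `hbond_acceptor` means the residue accepts.  This residue-
  centric reading matches the per-residue layout of the fingerprint.
* **Hierarchy.**  The contact bit dominates its block: it is set
  whenever any other class is detected for that residue, so
  `bit(contact) >= max(other bits)` always holds.  Every contact is
  additionally classified backbone or side chain (or both).

Similarity is the Tanimoto coefficient `Tc = |a AND b| / |a OR b|`.
`Tc` of two all-zero fingerprints is mathematically undefined; the
package returns 0 with a warning, because an all-zero fingerprint means
"no binding-site engagement" and must not silently cluster as identical
to another disengaged pose.  Note that `1 - Tc` violates the triangle
inequality in general; the clustering below needs only a dissimilarity,
not a metric.

## Geometric detector definitions

Crystal structures and docked poses typically carry no hydrogens, so
every detector is defined on heavy atoms.  The reference implementations
of fingerprint screening protocols ship inside commercial suites and do
not publish their thresholds; the defaults here are literature-standard
geometric criteria, fixed once and all exposed through
`default_interaction_params()`:

| class        | definition                                                        | default |
|--------------|-------------------------------------------------------------------|---------|
| contact      | any heavy-heavy distance                                          | 4.5 A |
| backbone     | contact involving N, CA, C, O, OXT                                | 4.5 A |
| sidechain    | contact involving any other residue atom                          | 4.5 A |
| polar        | residue N/O/S to ligand N/O                                       | 3.5 A |
| aromatic     | ring centroid-centroid, both rings planar (RMS <= 0.15 A)          | 5.5 A |
| hydrophobic  | apolar carbon (no bonded N/O) to apolar carbon                    | 4.5 A |
| H-bond       | donor-acceptor distance, plus antecedent-donor-acceptor angle >= 90 degrees | 3.5 A |
| charged      | charged-group atom to oppositely charged ligand atom              | 4.0 A |

The H-bond angle uses the donor's bonded heavy-atom antecedent as a
proxy for the missing hydrogen; when no antecedent exists (an isolated
polar atom, a water oxygen) the criterion reduces to the distance test.
The `charged` class requires *opposite* formal signs - salt-bridge
semantics; like-sign proximity is not an interaction the fingerprint
rewards.

Ligand chemistry is perceived from geometry alone, because PDB ATOM
records carry no connectivity: bonds are inferred when
`d <= r_cov(i) + r_cov(j) + 0.45` A, rings are minimal cycles of size
3-7 in that bond graph, a carbon bonded to two terminal oxygens is read
as an anionic carboxylate (acceptor-only oxygens), and a nitrogen with
at most one heavy neighbour - i.e. at least two hydrogen-bearing free
valences - as a cationic amine (donor-only).  Ether/ester oxygens accept
only; terminal oxygens with a single neighbour may both donate and
accept, since the hydrogen cannot be located.  This covers the
acidic-head-group chemotypes this machinery is aimed at without
attempting a full protonation model.  Histidine is treated as aromatic
by default and as additionally cationic only when `his_charged` is set.

## Clustering and reference anchoring

Poses and references are clustered agglomeratively on `d = 1 - Tc`.
The linkage is selectable; the default is average linkage, the common
choice for fingerprint Tanimoto clustering, which also guarantees
monotone merge heights.  Determinism matters more than the particular
tie-break: leaf ids are sorted lexicographically before the distance
matrix is formed, so tied merges always resolve the same way and the
result is invariant to input row order.  Heights are reported as raw
linkage distances with no ultrametric correction, and dendrograms
export to Newick with the conventional halved-height branch lengths
(two leaves merged at height 0.6 serialize as `(a:0.3,b:0.3);`).

Cluster numbering after a cut is arbitrary, so "the pose belongs to the
reference cluster" is operationalised as *reference anchoring*: cluster
hits jointly with the reference fingerprints, cut at a user-chosen `k`
(no automatic `k` selection is attempted - in practice the cut is chosen
by inspecting the dendrogram), and flag each hit whose cluster contains
at least one reference.

## Triage rules

`triage_criteria()` bundles three tests, and a pose passes only if every
*enabled* test passes:

1. **Reference co-clustering**, as above.
2. **Anchor residues**: a named list of residues, each with the
   interaction classes that satisfy it; the criterion passes when at
   least one anchor residue carries at least one of its classes.  This
   expresses rules of the form "an H-bond with the beta-sheet serine
   and/or the helix-5 arginine"; for an arginine anchor the default
   recommendation is to accept `charged` as well as either H-bond
   direction, since salt bridges and H-bonds are reported
   interchangeably for guanidinium-carboxylate pairs.
3. **Buried fraction**: the fraction of ligand heavy atoms with at
   least one protein heavy atom within 4.5 A.  This is a deliberately
   coarse proxy for the human judgement of "surface complementarity /
   overall pose quality" - it is *not* equivalent to visual inspection,
   and poses can be exported for that purpose instead.

Score funnels are pure bookkeeping: `percentile_filter()` retains the
best `ceiling(fraction * n)` ids (ties broken by id, so results are
stable), and staged funnels compose, retaining
`ceiling(f2 * ceiling(f1 * n))`.

## Geometry analyses

* `chi1()` computes the N-CA-CB-gamma torsion (IUPAC sign convention)
  and bins it as gauche-minus `[-120, 0)`, gauche-plus `(0, 120]`, trans
  otherwise.  The field aliases map gauche-minus to the "folded g*"
  rotamer and trans to "extended": for a gate-keeper phenylalanine the
  extended rotamer closes the accessory sub-pocket and the folded g*
  rotamer opens it.  The alias mapping is configurable in reports since
  open/closed language varies between papers.
* `hbond_table()` lists every ligand-protein donor/acceptor pair inside
  the H-bond thresholds (distances reported to 0.1 A, the precision at
  which such distances are conventionally printed) and water bridges: a
  water oxygen within H-bond distance of both a ligand polar atom and a
  protein polar atom.
* `clash_scan()` reports atom pairs closer than the Bondi van der Waals
  sum minus a 0.4 A tolerance.  Published "steric clash" judgements are
  qualitative; fixing Bondi radii and a standard tolerance makes the
  package's verdicts reproducible (a 2.2 A carbon-oxygen pair overlaps
  a 3.22 A vdW sum by 0.62 A).
* `cavity_volume()` flood-fills a cubic grid (default spacing 0.4 A)
  from a seed point, blocking voxels within `r_vdw + probe` (probe
  1.4 A, water-sized) of any protein atom, bounded by the protein's
  bounding box plus 8 A.  A fill that reaches the boundary raises an
  open-pocket warning and reports the capped volume.  Dedicated
  pocket-volume programs use different definitions (and differ among
  themselves); volumes from this routine are comparable across
  structures analysed with it, but only qualitatively comparable with
  volumes printed by other software.

## Synthetic data: what it emulates and what it does not

Two generators make every detector and the clustering testable without
any external data, and a third supports the cavity routine:

* `make_toy_complex()` plants one ideal-geometry scaffold residue per
  requested interaction class around a small ligand, each site 30 A
  from the next, at analytically prescribed distances (by default
  mid-range values well clear of the decision boundaries; requests
  within 0.15 A of a boundary are rejected, as are contradictory ones
  such as an H-bond planted at 6 A).  Residues come from an internal
  Z-matrix template library and are placed by rigid transforms only, so
  the record set a correct detector must emit is known by construction;
  a seeded random rigid rotation of each site makes the 50-seed
  agreement suite a genuine invariance test.
* `make_planted_bitstrings()` draws one prototype per cluster over the
  8 non-contact bits of each block (density 0.3), derives the contact
  bit as the block OR - so all generated strings satisfy the hierarchy
  invariant - and applies independent bit flips (default probability
  0.05) to make members.  The default scale, 3 clusters of 10 strings
  of length 225 (a 25-residue panel, the size of a typical reference
  panel of crystal complexes), matches the regime in which this kind of
  pose triage is used.
* `make_cavity_structure()` packs carbon pseudo-atoms on concentric
  spherical shells whose probe-expanded inner surface sits at the
  requested cavity radius, densely enough (0.8 A spacing) that the
  flood fill cannot leak; an optional cylindrical hole produces a
  deliberately open pocket.

These fixtures emulate geometry, not chemistry: scaffold residues are
isolated and strain-free, the toy ligand is a disconnected set of small
motifs, planted bit strings have independent noise whereas real
fingerprint bits are correlated within residues, and no attempt is made
to generate realistic ligand chemotypes or docked-pose ensembles.
Passing tests therefore demonstrate that the detectors, the algebra and
the clustering behave exactly as specified on controlled input - not
that the default thresholds reproduce any particular commercial
implementation on real complexes.

A separate pair of *synthetic stand-in* sites
(`make_synthetic_reference_sites()`) plants the binding-site geometry
reported for a naphthalene-carboxylate PPAR pan-agonist in the
PPARalpha and PPARgamma ligand-binding domains: the gate-keeper PHE at
chi1 = -67 degrees, the alpha-subtype H-bond network (2.7, 2.7, 2.8,
2.5 A), the gamma-subtype guanidinium salt bridge (2.7/2.9 A) with the
beta-sheet serine out of range, a 2.2 A methyl-serine clash, and a
water bridge (2.7/2.8 A).  They exercise the full
parse-measure-report pipeline end to end.  Because they are built from
ideal templates rather than deposited coordinates, they validate the
pipeline, not the crystal structures; `validate_reference_geometry()`
accepts any parsed structure, so users holding the deposited entries can
run the same report against the real coordinates.

## Numerical choices and degenerate inputs

* Alternate locations: only blank/'A' conformers are kept (dropped ones
  are listed in a warning); hydrogens are dropped on input.  Author
  residue numbering is never altered, and panels align across
  structures by exact (chain, number, insertion-code) identity only -
  cross-subtype correspondences must be supplied explicitly, never
  guessed from sequence.
* Torsions are undefined for collinear triples (error, not NaN); ring
  planarity uses the RMS residual of a least-squares plane.
* Ties: percentile filters and cluster leaf order break ties by id;
  `cutree` labels follow canonical leaf order.
* The acceptance-scale problem sizes - 50 seeded toy complexes, 100
  clustering replicates of 30 strings, a 4 A sphere at 0.4 A grid
  spacing - were chosen so the whole validation runs in seconds on one
  CPU while leaving each estimate's error an order of magnitude below
  its tolerance.

## Known limitations

* No pi-cation or halogen-bond detection; water bridges are measured in
  the geometry tables but are deliberately not a fingerprint bit.
* Ligand protonation is rule-based (carboxylates, primary amines);
  exotic warheads will fall back to neutral donor/acceptor typing.
* The buried-fraction proxy cannot reproduce a human "pose quality"
  call, and the visual-inspection stage of a real campaign (the step
  that shrinks a hit list between clustering and purchasing) is
  intentionally not modelled, so published intermediate compound counts
  from such campaigns are not reproducible quantities.
* Cavity volumes depend on the blocking definition; compare like with
  like.

## A worked example

```{r example}
tc <- make_toy_complex(c("charged", "polar", "aromatic"), seed = 7)
panel <- tc$panel
rec <- detect_interactions(tc$structure, tc$ligand, panel)
fp <- build_sift(rec, panel, "toy")
sift_long(fp)
```

```{r cluster}
pb <- make_planted_bitstrings(n_clusters = 3, members = 5, seed = 7)
tree <- hierarchical_cluster(sift_matrix(pb$fps))
table(cut_tree(tree, 3), pb$labels)
```
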