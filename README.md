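# siftr

Structural interaction fingerprints, pose triage and binding-site
geometry for protein–ligand complexes.

## The problem

Structure-based virtual screening produces hundreds of docked poses
whose scores alone rank true binders poorly. A proven post-processing
strategy — standard in nuclear-receptor campaigns, where a large
promiscuous pocket accommodates many false poses — is to triage poses by
their *interaction pattern* rather than their score: encode every
complex as a structural interaction fingerprint (SIFt), cluster the
poses together with a panel of reference crystal complexes, and keep the
poses that cluster with the references and make the anchor interactions
known from experimental structures. `siftr` implements this machinery
for R, plus the quantitative structural measurements used to
characterise the resulting complexes (H-bond networks with water
bridges, gate-keeper χ1 rotamer calls, van der Waals clash scans, grid
flood-fill cavity volumes).

## The model

For an ordered binding-site panel of residues, each residue contributes
nine bits recording which interaction classes the ligand realises:

```
[contact, backbone, sidechain, polar, aromatic, hydrophobic,
 hbond_donor, hbond_acceptor, charged]
```

(`hbond_donor` = the residue donates to the ligand). A fingerprint is
the concatenated bit string of length 9 × |panel|; the contact bit
dominates its block. Similarity between fingerprints *a*, *b* is the
Tanimoto coefficient

> Tc(a, b) = |a ∧ b| / |a ∨ b| ∈ [0, 1],

poses are clustered agglomeratively (average linkage by default) on
d = 1 − Tc, and a pose is *reference-anchored* when its cluster, cut at
a chosen k, contains at least one reference complex. Triage combines
reference anchoring, anchor-residue rules (e.g. "H-bond to the β-sheet
serine and/or salt bridge to the helix-5 arginine") and a
buried-fraction proxy for pose quality. All detector thresholds are
documented defaults exposed via `default_interaction_params()`; the
methods vignette (`vignettes/sift-triage-methods.Rmd`) derives every
choice.

Deterministic generators (`make_toy_complex()`,
`make_planted_bitstrings()`, `make_cavity_structure()`,
`make_synthetic_reference_sites()`) build miniature complexes with
planted interactions, bit-string families with planted clusters, closed
cavity shells and synthetic reference-geometry sites, so the entire
pipeline is testable offline.

## Worked example

```r
library(siftr)

tc  <- make_toy_complex(c("charged", "aromatic"), seed = 7)
rec <- detect_interactions(tc$structure, tc$ligand, tc$panel)
rec[, c("seqnum", "resname", "kind", "distance")]
#>   seqnum resname        kind distance
#> 1      1     ARG     contact 2.900000
#> 2      1     ARG   sidechain 2.900000
#> 3      1     ARG       polar 2.900000
#> 4      1     ARG hbond_donor 2.900000
#> 5      1     ARG     charged 2.900000
#> 6      2     PHE     contact 4.207342
#> 7      2     PHE   sidechain 4.207342
#> 8      2     PHE    aromatic 4.200000
#> 9      2     PHE hydrophobic 4.207342

build_sift(rec, tc$panel, "pose_007")
#> <sift_fp> pose_007: 9/18 bits set over 2 panel residues
```

The planted arginine–carboxylate salt bridge at 2.9 Å yields exactly
the five classes a salt bridge implies (contact, sidechain, polar,
residue-donated H-bond, charged); the stacked phenylalanine ring at a
4.2 Å centroid separation yields the aromatic/hydrophobic block. The
geometry side, on the synthetic reference-site stand-ins:

```r
ss <- make_synthetic_reference_sites()
chi1(residue_atoms(ss$alpha$structure, "A", 273))
#> <chi1> PHE A:273: -67.0 deg (gauche_minus / folded_g_star)

cavity_volume(make_cavity_structure(4), c(0, 0, 0), spacing = 0.4)
#> <cavity> 270.8 A^3 (4232 voxels at 0.4 A, probe 1.4 A)
```

The χ1 = −67° call is the "folded g*" rotamer that opens a gate-keeper
phenylalanine's accessory sub-pocket; the flood-fill volume of a
synthetic 4 Å spherical cavity lands within about 1% of the analytic
268.1 Å³.

A thin command-line wrapper over the same functions ships in
`inst/scripts/sift-tools.R` (`chi1`, `hbonds`, `mindist`, `clash`,
`cavity`, `sift`, `triage`, `fixture-complex`, `fixture-bits`).

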