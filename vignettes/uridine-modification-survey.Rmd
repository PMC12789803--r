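---
title: "Surveying uridine modifications in RNA 3D structures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying uridine modifications in RNA 3D structures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urimod)
```

`urimod` asks a single scientific question at scale: when a uridine in an
RNA structure is replaced by one of its common natural modifications —
pseudouridine (PSU), 5-methyluridine (5MU), 3-methyluridine (UR3),
2′-O-methyluridine (OMU), 4-thiouridine (4SU) or 5,6-dihydrouridine (H2U) —
does the surrounding motif keep its three-dimensional shape and its
interaction pattern? This vignette documents the models and procedures the
package implements, the parameters that matter, the numerical choices made
where a published workflow leaves the details open, and what the synthetic
test bed does and does not establish about real data.

## The workflow

The pipeline (`run_pipeline()`) runs eight stages, each available as a
standalone function:

1. **Parse** mmCIF (preferred) or PDB files into a uniform atom table with
   author chain identifiers and author residue numbers. Author numbering is
   authoritative throughout because motif provenance identifiers
   (`ENTRYID_sequence_chain_start`) are built from it.
2. **Filter** by experimental quality: X-ray and cryo-EM entries pass iff
   resolution ≤ 3.0 Å, boundary inclusive; an X-ray/EM entry without a
   recorded resolution is excluded. NMR entries are never resolution
   filtered — their redundancy is a multi-model redundancy, handled next.
3. **Select the NMR representative.** The ensemble's average structure is
   computed by iterated superposition (below) and the member with the
   lowest all-atom RMSD to that average stands for the ensemble. Only this
   model enters any later stage.
4. **Annotate** hydrogen bonds, base stacking, base pairs and
   secondary-structure elements geometrically (below).
5. **Call conformations** per modified residue: pseudorotation phase,
   amplitude, pucker class, glycosidic angle and syn/anti class.
6. **Clip hairpin motifs** — the loop plus its first closing base pair, so a
   clipped pentaloop is seven residues long — re-screening every clipped
   residue for completeness.
7. **Match canonical counterparts** in a local library by exact sequence
   after reverting every modification to U, including the closing pair, and
   reduce each same-sequence group on both sides to its
   sequence-representative structure (SRS).
8. **Compare and tabulate**: Kabsch superposition on the name-matched atom
   correspondence, the ≤ 1.0 Å similarity call, per-position interaction
   differencing, and the survey tables (structures by method, residues, and
   the SSE / RNA-type / pucker / glycosidic distributions per modification).

Every excluded entry carries exactly one reason code — `RESOLUTION`,
`MISSING_ATOMS`, `PROCESSING`, `INCOMPLETE_SSE` or `CLIP_FAIL` — and the run
is deterministic given fixed inputs.

## Geometric models

### Superposition and mean structures

Rigid-body superposition uses the Kabsch algorithm: SVD of the
cross-covariance matrix with the usual determinant sign correction so that
reflections are excluded. Chirality preservation is not optional for
nucleic acids — a mirrored ribose is a different molecule — so the proper
rotation is enforced even where a reflected fit would score lower. The
independent check used in the tests is Horn's quaternion eigenvalue method,
a genuinely different derivation of the same optimum.

The "average structure" of an ensemble needs an alignment frame that no
single convention fixes. We iterate: superpose all members onto the current
mean (member 1 initially), recompute the per-atom arithmetic mean, and stop
when the mean moves less than 1e-4 Å (at most 20 iterations; non-convergence
is a warning, never silent). The member-1 initial frame makes the procedure
deterministic; the convergence criterion makes it insensitive to member
order, which a property test asserts. RMSD-to-mean is measured with a fresh
superposition per member, not with distances in the averaging frame — the
two differ once the mean has drifted from any single member's frame.

### Sugar pucker

The five ribose ring torsions ν0 (C4′–O4′–C1′–C2′) through ν4
(C3′–C4′–O4′–C1′) are condensed to a pseudorotation phase *P* and amplitude
νmax by the Altona–Sundaralingam relations. For torsions that follow the
cosine closed form exactly, the implementation recovers *P* and νmax to
machine precision, because the phase is taken from a two-argument
arctangent of algebraically exact combinations — this identity is what the
1000-draw round-trip test exercises. Classes are the ten canonical
envelope/twist forms at 36° intervals (C3′-endo ideal phase 18°, C2′-endo
162°, …); assignment is nearest-ideal-phase, i.e. 36°-wide bins with edges
at 0°, 36°, 72°, …

Below an amplitude floor of 5° the ring is effectively planar and no class
is meaningful; such residues are reported `UNSPECIFIED`. The floor is a
package choice (configurable) — annotation tools report an unspecified
category without publishing a quantitative criterion, so ours is explicit.

### Glycosidic angle

χ is measured over O4′–C1′–N1–C2 for pyrimidines and O4′–C1′–N9–C4 for
purines. Pseudouridine is a C-glycoside — the base is attached through
C1′–C5 — so its χ is measured over O4′–C1′–C5–C4, mirroring the pyrimidine
pattern across the rewired bond; the atoms used are recorded per residue.
H2U keeps the standard pyrimidine atoms: saturating C5=C6 does not remove
N1. *syn* means χ ∈ [−90°, +90°], and both boundaries are closed — the
convention "between +90° and −90°" does not state edge behaviour, so the
package fixes it and asserts it in a test.

One mathematical point is worth recording: with the IUPAC sign convention
(cis = 0, clockwise positive looking from the second to the third atom),
the signed dihedral is *invariant* under full atom-order reversal,
φ(l,k,j,i) = φ(i,j,k,l); it is mirror reflection that negates it. The test
suite asserts both identities.

### Contacts, pairs and secondary structure

Hydrogen bonds are donor/acceptor heavy-atom pairs within 4.0 Å, boundary
inclusive. The test is distance-only: the screen has removed hydrogens, so
no angle at the donor is available without placing them, and the package
does not guess hydrogen positions. The donor and acceptor lists ship
per component — notably PSU's free N1 is a donor, UR3's methylated N3 is
not, and OMU's methylated O2′ leaves the donor list.

Base stacking requires three conditions at once: minimum inter-ring
heavy-atom distance ≤ 4.0 Å, angle between base-plane normals ≤ 30°, and
ring-centroid separation ≤ 5.5 Å. All three are configurable; the H2U ring,
though non-aromatic, is still treated as a ring for this geometry and
flagged saturated.

Base pairs require at least two base–base hydrogen bonds and near-coplanar
bases: inter-plane angle ≤ 45° *and* a centroid offset from the partner's
plane of ≤ 2.5 Å. The second condition is the package's answer to a real
degeneracy: two stacked bases are also "coplanar" in the angle-only sense
(parallel normals) and can sit within hydrogen-bonding distance, but one
base lies a full helical rise above the other's plane, while true pairing
partners lie in a common plane. Pairs are classified Hoogsteen when any
bond runs through a purine N7, WCF for canonical A:U / G:C donor–acceptor
patterns confined to both Watson–Crick–Franklin edges, wobble for the
analogous G:U pattern, and OTHER otherwise.

Helices are runs of ≥ 2 consecutive nested WCF/wobble pairs; pseudoknots
are resolved to a maximal nested subset, greedily by helix length with ties
to the 5′-most helix, because hairpin extraction requires a nesting. A
hairpin is the maximal unpaired run enclosed by the innermost pair of a
helix with both strands on one chain; the clip is that loop plus the
closing pair, so clipped length = loop size + 2.

## Comparison across chemistry differences

"All-atom RMSD" between a modified and an unmodified motif is defined on
the intersection of heavy-atom names at each aligned position: the 5MU
methyl (C5M), the UR3 methyl (C3U) and the OMU 2′-O-methyl (CM2) have no
uridine counterpart and are dropped (and reported); 4SU's S4 has no O4
partner by name; PSU and H2U share uridine's full heavy-atom name set, so
nothing is dropped — for PSU this means the base atoms are compared by
name even though N1 and C5 have exchanged spatial roles, which is precisely
the structural signal of the isomerization. Superposition uses all clipped
atoms (loop and closing pair). The similarity call is `rmsd ≤ threshold`
with the 1.0 Å default, and the boundary is inclusive by construction.

Interaction differencing normalizes each contact to (motif position,
interaction kind, partner descriptor), where an in-motif partner is its
position and canonical base, an out-of-motif nucleotide is
`<base>(tertiary)` and a protein residue its 3-letter code. Distances are
deliberately dropped from the identity so that a bond that merely shortens
is "shared", not "lost + gained". Interactions are computed in the parent
structure by default, because tertiary and protein contacts are part of
the biology; a motif-only mode exists.

When several modified variants map to one canonical sequence, each modified
SRS is compared against the single unmodified SRS of that exact canonical
sequence — counterpart matching includes the closing pair, since published
motif pairs match on the full clipped sequence.

## Key parameters

| Parameter | Default | Units | Where | Rationale |
|---|---|---|---|---|
| `max_resolution` | 3.0 | Å | filter | balances quality and dataset size; ≤ is inclusive |
| `contact_cutoff` | 4.0 | Å | H-bonds, stacking | heavy-atom criterion, hydrogens removed |
| `similarity_threshold` | 1.0 | Å | comparison | standard for calling RNA motifs same-shaped |
| `stack_normal_max` | 30 | ° | stacking | parallel-plane requirement |
| `stack_centroid_max` | 5.5 | Å | stacking | excludes coplanar pairing partners |
| `coplanar_max` | 45 | ° | base pairs | separates pairing from oblique contacts |
| `vertical_max` | 2.5 | Å | base pairs | separates pairing from stacking |
| `amplitude_floor` | 5 | ° | pucker | below this the ring is effectively planar |
| `misc_share` | 0.01 | fraction | reporting | SSE categories strictly below 1% collapse to MISC |

All are keys of `pipeline_config()`.

## The synthetic test bed

`build_hairpin()` constructs idealized hairpins from first principles:
planar polygon base templates; pair frames in which the canonical
donor–acceptor distances are optimized to 2.8–3.0 Å with a van der Waals
floor on all other cross-base contacts; an A-form stem (rise 2.81 Å, twist
32.7°); sugars built on a pentagon model whose out-of-plane displacements
are calibrated so the as-built ring reproduces a requested pseudorotation
state essentially exactly; and χ enforced by rotation about the glycosidic
bond. Loops are laid on a circular arc bridging the stem with bases
pointing outward, which keeps loop bases unpaired by construction.
Modifications are applied as chemistry edits: methyl additions for 5MU,
UR3, OMU; O4→S4 at a 1.68 Å C=S bond for 4SU; an out-of-plane C5/C6 pucker
for H2U; and for PSU a 180° rotation of the base about the N3–C6 axis, the
textbook isomerization that brings C5 to the glycosidic position with atom
names travelling along.

`generate_dataset()` emits a labeled corpus of 58 entries: per
modification, three X-ray conformers of one hairpin sequence (an SRS
group), an EM and a five-model NMR ensemble of a second sequence, one entry
planted beyond the resolution cutoff and one with a deliberately incomplete
residue; PSU and 5MU additionally contribute a stem-modified entry so the
SSE distribution is not trivially 100% hairpin. The library side carries
two canonical conformers per first family plus decoys; the 4SU library
family is planted in a shifted loop conformation (tilted arc plus two syn
base flips) so that exactly one comparison pair is structurally distinct.
Coordinate noise is 0.05 Å for crystal-like entries and 0.3 Å for NMR
models with the planted representative at a tenth of that — values chosen
once as representative of coordinate uncertainty at the resolutions
emulated. The manifest records the ground truth of the emitted coordinates —
conformational classes are measured after noise, on the planted
representative model, at the serialized coordinate precision, because the
ground truth of a perturbed structure is its perturbed conformation — and
the end-to-end test requires the survey to reproduce it exactly.

What passing these tests shows: the bookkeeping, geometry and decision
rules are implemented correctly, and recovery is robust to at least 0.25 Å
of isotropic coordinate noise (a separate 50-replicate property). What it
does not show: performance on real deposited structures, whose pathologies
— non-ideal pair geometries, modified residues the dictionary does not
cover, chain discontinuities, alternate conformers of whole segments,
crystal contacts — the generator deliberately does not emulate. The
accession-backed spot checks (`spot_check_accessions()`) exist for exactly
that reason and run whenever the eight parent entries are supplied locally.

## Numerical and edge-case choices

* Alternate locations resolve to the highest-occupancy location; ties break
  on the alphabetically first alternate identifier; absent occupancy means
  1.0. Duplicated atom records without alternate identifiers are
  unresolvable and reject the residue.
* Multi-model X-ray/EM entries use model 1 only; per-model logic applies to
  NMR.
* Representative ties (RMSD within 1e-9 Å) go to the lowest index.
* The pair-frame optimizer accepts bond lengths within ~0.08 Å of target;
  the idealized-polygon bases cannot close all three G:C bonds exactly once
  clash floors are enforced, and that tolerance is chemically immaterial.
* The hydrogen-bond, similarity and resolution boundaries are all closed
  (≤), each asserted by a dedicated test.
* Hairpin clipping demands contiguous author numbering on one chain; a gap
  is `INCOMPLETE_SSE`, a screen failure inside the clip is `CLIP_FAIL`.

## Problem sizes

The shipped checks use 100 seeded point sets (n = 10–100) for the
superposition oracle, 1000 pseudorotation draws, 100 ten-model ensembles
for representative recovery, hairpin loops of 4–10 nt for annotation, and
the 58-entry corpus for the end-to-end survey — sizes at which every
property is exercised many times over while a full run of suite plus
acceptance script stays comfortably interactive.

## Known limitations

* No Leontis–Westhof 12-family pair classification, no helical parameters,
  no backbone suite rotamers, no BI/BII.
* Hydrogen bonds are distance-only; with hydrogens removed there is no
  angle term at the donor, so borderline contacts may differ from
  hydrogen-aware annotators.
* The Hoogsteen call is an edge-atom heuristic and may differ from
  annotation tools on borderline geometries; the external-annotation
  cross-check interface exists for auditing such cases.
* Counterpart search against online motif databases is replaced by
  exact-sequence matching over a local library; fuzzy matching is out of
  scope.
* The modification dictionary ships the six uridine modifications; other
  components pass through parsing but are rejected by the screen as
  `UNKNOWN_COMPONENT` rather than silently analysed.
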