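---
title: "Classifying active, substrate-binding-competent kinase conformations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying active, substrate-binding-competent kinase conformations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinactive)
```

## The problem

Typical protein kinase domains share the bilobal PKA-like fold: an
N-lobe of five beta strands plus the C-helix, and a helical C-lobe. The
catalytically active state must satisfy three requirements at once —
binding ATP, coordinating Mg²⁺, and presenting an unobstructed groove for
the protein substrate. The first two are captured by well-known features
of the DFG motif and the N-lobe salt bridge; the third depends on the
conformation of the activation loop, the segment running from the DFG
motif to the APE motif, whose N- and C-terminal ends form the substrate
binding surface. A structure can satisfy the ATP-site criteria and still
be unable to bind substrate; `kinactive` therefore evaluates six criteria
jointly.

## The criteria

Each criterion is a pure function of heavy-atom coordinates and a
per-chain *motif map* giving the author residue numbers of the conserved
motifs (β3 Lys, C-helix Glu, HRD, DFG, APE, HPN7). Activation-loop
positions are addressed from both ends: DFGn is the n-th residue from
DFG-Asp, APEn the n-th counting backwards from the terminal APE-Glu.
This double-ended indexing is what lets one rule set cover loops of
different lengths.

1. **Spatial (DFGin).** The DFG-Phe ring position is classed by the
   distances of its Cζ atom to two N-lobe anchors: the Cα of "Glu4"
   (four residues after the C-helix Glu) and the Cα of the β3 Lys.
   DFGin means near the C-helix pocket (≤ 11 Å) and away from the Lys
   (≥ 11 Å); DFGout the converse (> 11 Å and ≤ 14 Å); anything else is
   DFGinter. The two 11 Å / 14 Å anchors are package defaults exposed in
   `active_config()`: they reproduce the clear separation of the two
   clusters in substrate-bound versus inhibitor-bound structures, but a
   user recalibrating against their own reference set can move them
   without touching code. When the DFG-Phe position holds a non-aromatic
   residue (Leu/Met/Val occur), the anchor falls back to the side-chain
   heavy atom most distal from Cα.

2. **Dihedral (BLAminus).** The backbone of X-D-F of the XDFG motif must
   occupy the Ramachandran regions B, L, A respectively, and the Phe χ¹
   must be gauche-minus, χ¹ ∈ (−120°, 0°). The g⁻ rotamer points the ring
   down into the C-helix pocket; the g⁺ rotamer of the inactive BLAplus
   states pushes the C-helix out and breaks the salt bridge. The common
   pathology `ABAminus` — a peptide flip of the X-D amide that points the
   X carbonyl away from the HRD His — fails this criterion.

3. **Salt bridge.** min(Nζ–Oε1, Nζ–Oε2) < 3.6 Å between the β3 Lys and
   C-helix Glu. Skipped for kinases that lack the pair (WNK kinases,
   which move the catalytic Lys; MAP3K12/13, which carry Asp in place of
   the Glu). If the mapped positions hold other residue types the
   nearest equivalent terminal atoms are measured and the report notes
   the substitution.

4. **HRD.** His in region A and Arg in region L. The strained HRD-loop
   backbone is braced by hydrogen bonds from a conserved Asp in the
   αF-helix; where that Asp is absent (PIM1-3, HASPIN, PKDCC, the LMTK
   family) the criterion is skipped rather than measured, because the
   geometry it tests is not expected to hold.

5. **ActLoopNT.** The activation loop is "extended" at its start when
   residue 6 (DFG6) forms a backbone-backbone hydrogen bond with the
   residue preceding the HRD motif — the central pair of the short β6/β9
   strands. Pass: min(N–O, O–N) < 3.6 Å. This positions DFG4, the
   residue that contacts the substrate phosphoacceptor.

6. **ActLoopCT.** The substrate-facing C-terminal segment. APE7 and APE6
   form a short helical turn (regions A, A) — or the type-II-turn peptide
   flip (B, L), which preserves the backbone trajectory and is accepted.
   APE8 must be in region B. Then the groups diverge. Non-TYR kinases
   (whose APE8 is usually Ser/Thr hydrogen-bonding into the catalytic
   loop): APE8 χ¹ must be g⁻ when APE8 is Ser/Thr; the APE9-Cα to
   HRD-Arg carbonyl-O distance (a Cα–H···O contact) must be < 6 Å; and
   the Cβ positions of APE10/11/12 must sit at < 8 Å, (8, 14) Å and
   (7, 14) Å from DFG4-Cα — bounds that separate substrate-compatible
   packing from the swapped or distended loop ends seen in
   unphosphorylated structures. TYR kinases bind substrate as a short
   beta strand against this segment, so instead APE9 and APE10 must be in
   region B and the APE9 distance bound relaxes to < 8 Å, with no
   Cβ-distance bounds. Kinases with no APE motif at all (HASPIN, TP53RK,
   PKDCC) skip the criterion entirely.

**Verdict.** Any criterion "out" ⇒ Inactive, even if others are
unmeasurable — a single violated requirement is decisive. Otherwise, if
the spatial/dihedral/salt-bridge/HRD group is unmeasurable ⇒ None; if the
two loop criteria are unmeasurable ⇒ None; else Active. Skipped criteria
count as neither passes nor failures. Pseudokinases are not auto-detected;
callers mark them and receive `Pseudo-skip`.

The three regulatory-spine distances (HRD-His/DFG-Phe, DFG-Phe/Glu4,
Glu4/HPN7 minimum side-chain distances, intact when all < 5 Å) are
computed and reported because they are standard descriptive quantities,
but they are deliberately not a criterion: they are almost always intact
when the six criteria pass, and the exceptions involve residues that
contact neither ATP nor substrate.

## Ramachandran conventions and boundary closure

Regions: A = φ ∈ (−180°, 0°), ψ ∈ (−100°, 50°); B = φ ∈ (−180°, 0°),
ψ ∈ (50°, 180°); L = φ ∈ (0°, 180°), ψ ∈ (−50°, 100°). The intervals as
stated are open, which leaves boundary points unassigned; for a
deterministic partition the package closes A at ψ = 50 (A owns the A/B
boundary), closes B at ψ = 180 with ψ = −180 wrapped to +180, and closes
L at φ = 180 and ψ = 100. Boundary values have measure zero on real
coordinates, so the choice does not affect practical classifications —
but it makes `rama_region()` a total, single-valued function, which the
property suite asserts by enumeration. All distance cutoffs use strict
comparisons: "<" for upper bounds, ">" for lower bounds.

χ¹ is the N–Cα–Cβ–Xγ torsion with the standard γ-atom priority
(OG, OG1, CG, CG1, SG); Ala and Gly have none, and a missing χ¹ where one
is required propagates as "none", not as failure. Where APE10/11/12 is
glycine, its Cβ is reconstructed at the ideal tetrahedral position
(`virtual_cbeta()`), since the criterion is Cβ-based and glycine does
occur at these positions.

## Structure handling

Parsing (PDB and mmCIF) is delegated to `bio3d`; cell and symmetry
records, which bio3d does not expose, are parsed directly (CRYST1 and
REMARK 290 for PDB; `_cell`, `_symmetry` and operator loops for mmCIF),
with a built-in operator table for common protein space groups as the
fallback when a file states only the Hermann–Mauguin symbol. Author
residue numbering is canonical throughout, because motif maps are curated
in author numbering. Alternate locations keep the highest-occupancy
conformer (ties go to altloc A); hydrogens are ignored (all criteria are
heavy-atom based); for multi-model files only the first model is used.
These altloc/NMR conventions are package decisions — single-conformer
usage matches how such classifications are normally curated.

Crystal-symmetry expansion applies every operator combined with every
lattice translation of the (2·shell+1)³ block, excluding the identity
image, and tags each copy with (operator index, lattice offset). The
substrate/autophosphorylation search then looks for Ser/Thr/Tyr hydroxyl
oxygens within 4.5 Å of a mapped chain's HRD-Asp carboxylate in any other
chain or image. 4.5 Å is deliberately generous — a search cutoff, not a
hydrogen-bond definition, and no angle term is applied. Domain-swapped
activation-loop dimers produce false positives in this search: the
swapped hydroxyl approaches the HRD-Asp *from below*, occupying the same
position as the enzyme's own intramolecular APE8 hydroxyl. The package
operationalizes that qualitative signature as: candidate hydroxyl within
1.5 Å (strict) of the enzyme's APE8 γ-oxygen site, measured when APE8 is
Ser/Thr or reconstructed at the ideal g⁻ position otherwise. The 1.5 Å
radius is a declared heuristic, exposed in `active_config()`.

## Scoring predicted models

For AlphaFold-style models the activation-loop confidence is the
intramolecular ipSAE:

$$\mathrm{ipSAE}_{\mathrm{Actloop}} \;=\; \max_{\substack{i \notin \mathrm{loop} \\ \mathrm{pLDDT}_i > 60}} \; \mathrm{mean}_{j \in \mathrm{loop}} \; \frac{1}{1 + (\mathrm{PAE}_{ij}/d_0)^2}$$

with PAE in Å and d0 fixed at 4 Å so that scores are comparable across
loops of different lengths. The score is in (0, 1], monotone
non-increasing in every PAE entry of an eligible row, and invariant to
everything outside those rows — properties the test suite asserts.
The pLDDT gate is strict (> 60) by default with a switch for ≥, since
the difference is measure-zero; pLDDT comes from the B-factor column of
the model coordinates or a JSON field. Aligned residues can be restricted
to the motif map's domain span so that flanking tag residues never carry
the maximum. `select_best_model()` restricts candidates to Active and
takes the highest score; exact ties go to the lexicographically lowest
model name, a pure determinism rule.

## Superposition and RMSD conventions

Model/reference comparisons superpose on the C-terminal domain — the
paired Cα atoms of the 40 residues following APE1, requiring at least 20
pairs — by least squares (Kabsch, with the determinant sign corrected so
mirror inputs still yield a proper rotation). The activation-loop RMSD is
then measured over paired backbone atoms (N, Cα, C, O) *without
refitting*, so loop displacement is measured in the frame of the C-lobe.
Three windows: `full` (the whole DFG..APE span), `ntct` (first 9 + last
15 residues — the segments that actually contact substrate), and
`nt5ct15` (first 5 + last 15 — the window used to screen template
similarity at 1.5 Å). Residues are paired by motif-anchored loop index
(DFGn↔DFGn, APEn↔APEn), never by sequence alignment: this matches the
double-ended indexing convention, tolerates length differences by
truncating the loop middle, and deduplicates atoms when the windows of a
short loop overlap.

## What the synthetic fixtures are — and are not

`build_toy_kinase()` exists so that every criterion, including the
crystal-symmetry paths, is testable without downloading a single
structure. It favors geometric exactness over global realism:

* the activation loop is built as two ideal-geometry peptide arms
  (context + DFG1..DFG9, and APE15..APE1 continuing into a 45-residue
  C-terminal helix for the superposition window), with the loop middle
  left unmodeled — as in a disordered loop;
* requested dihedrals are exact by construction (natural-extension chain
  building, verified to < 1°);
* the conserved motifs outside the loop — β3 Lys, C-helix Glu, Glu4,
  HPN7 and the xHRD-His-Arg-Asp mini-chain — are free-floating satellite
  residues placed by deterministic rigid-body optimization so that each
  requested pairwise distance is realized to < 0.05 Å, verified post hoc
  with the same measurement functions the classifier uses, and a build
  error is raised when a request is geometrically unsatisfiable.

Default requests realize an all-criteria-passing geometry sitting well
away from every boundary (e.g. salt bridge 3.0 Å against the 3.6 Å
cutoff, APE10 distance 7.0 Å against 8 Å), which is what makes the
0.05 Å-noise robustness test meaningful. Single-violation presets move
exactly one quantity across its boundary (e.g. salt bridge to 4.5 Å, or
the APE8 χ¹ to +55°), so each flips exactly one criterion.

Passing tests on these fixtures therefore demonstrates that the
*measurements and decision logic* are correct. They do not demonstrate
anything about real kinases: the fixtures have no packed hydrophobic
core, no sterically consistent global fold, and their satellites are not
covalently anchored. Conclusions about real structures additionally rest
on the exemplar block of the acceptance suite, which measures deposited
PDB entries when network access is available.

## Numerical choices and problem sizes

Rigid placements are solved by Nelder–Mead over the six rigid-body
parameters with seeded deterministic restarts; every random stream in the
fixture generator derives from the spec's integer seed through a local
linear-congruential generator, leaving R's global RNG untouched, so two
builds from the same spec are byte-identical. The property suite runs on
fixtures of ~450 atoms, 1000 random torsion quadruples, and symmetry
blocks of up to 53 copies; the full test suite completes in about a
minute on one CPU. These sizes were chosen because every property being
asserted (oracle equivalence, partition coverage, monotonicity,
determinism) is scale-free — a larger fixture would test the same code
paths at the same tolerances.

## Known limitations

* Motif maps are input, not inference: the regex-based
  `detect_motifs_from_sequence()` helps bootstrap one and reports
  ambiguity explicitly, but HRD-His can be Tyr/Phe/Leu and DFG-Phe can be
  Leu/Trp/Met/Val, so curated numbering is always preferable.
* "C-helix-in" as an independent label is not implemented; the salt
  bridge distance is the measured proxy, and chains with a broken bridge
  but otherwise intact geometry are simply Inactive (or skipped where the
  exception list applies).
* The dihedral label reports full region-letter composition
  (e.g. `BLBplus`) but the classifier only distinguishes BLAminus from
  everything else; the finer inactive-state nomenclature is out of scope.
* The fixture builder cannot realize mutually inconsistent distance sets
  (it errors instead); in particular three collinear anchors
  over-determine a placement, which is why the fixture's APE11–15 stretch
  alternates extended and helical dihedrals.
* Assembly records (`_pdbx_struct_assembly`) are ignored; symmetry
  expansion always derives from the cell and operators.
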