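# kinactive

Structural classification of **active, substrate-binding-competent
conformations of typical protein kinase domains**, for structural
bioinformaticians and modelers who need to decide whether an experimental
structure or a predicted model of a kinase could actually bind ATP,
Mg²⁺ *and* a protein substrate.

Most "active/inactive" annotations of kinase structures consider only the
ATP site. A kinase can be DFGin with an intact salt bridge and still
present an activation loop that blocks the substrate groove. `kinactive`
labels one kinase chain **Active**, **Inactive** or **None** (missing
atoms) from six jointly required criteria measured on the conserved
motifs of the fold:

| Criterion | Measurement | Pass condition (defaults) |
|---|---|---|
| spatial | DFG-Phe Cζ vs C-helix Glu4-Cα and β3 Lys-Cα | DFGin: d(Phe,Glu4) ≤ 11 Å and d(Phe,Lys) ≥ 11 Å |
| dihedral | Ramachandran regions of X-D-F of the XDFG motif + Phe χ¹ | `BLAminus`: regions (B, L, A), χ¹ ∈ (−120°, 0°) |
| saltbr | β3 Lys Nζ to C-helix Glu Oε1/Oε2, whichever is shorter | < 3.6 Å (skipped for WNK, MAP3K12/13) |
| hrd | Ramachandran regions of HRD His and Arg | His in A, Arg in L (skipped without the αF-helix Asp) |
| actloopNT | backbone N–O distance, activation-loop residue 6 (DFG6) vs the residue before HRD | min(N–O, O–N) < 3.6 Å |
| actloopCT | APE7/APE6 regions (A,A) or the peptide-flipped (B,L); APE8 region B; then per group: non-TYR — APE8 χ¹ g⁻ when Ser/Thr, APE9-Cα/HRD-Arg-O < 6 Å, APE10-Cβ/DFG4-Cα < 8 Å, APE11 ∈ (8,14) Å, APE12 ∈ (7,14) Å; TYR — APE9/APE10 regions B, APE9 distance < 8 Å | all applicable sub-features |

Region definitions: A = φ ∈ (−180°, 0°), ψ ∈ (−100°, 50°);
B = φ ∈ (−180°, 0°), ψ ∈ (50°, 180°); L = φ ∈ (0°, 180°), ψ ∈ (−50°, 100°).
Any failed criterion ⇒ Inactive; no failure but unmeasurable atoms ⇒
None; otherwise Active. The regulatory spine (HRD-His/DFG-Phe/Glu4/HPN7
stacking) is reported but is not a criterion.

The package also provides:

* **ipSAE activation-loop confidence** for AlphaFold-style models:
  `max over residues i outside the loop with pLDDT_i > 60 of
  mean over loop residues j of 1 / (1 + (PAE_ij / d0)²)`, with d0 = 4 Å,
  plus best-model selection (highest-scoring Active model);
* **substrate / autophosphorylation pose detection**: Ser/Thr/Tyr
  hydroxyls within 4.5 Å of the HRD-Asp carboxylate of another chain,
  including crystal-symmetry mates from the 3×3×3 block of unit cells,
  with a domain-swap exclusion flag;
* **activation-loop RMSD benchmarking**: least-squares superposition on
  the Cα atoms of the 40 residues after the APE motif, backbone
  (N, Cα, C, O) RMSD over the full loop, the first-9 + last-15 window, or
  the first-5 + last-15 template screen window;
* a **deterministic synthetic fixture generator** (`build_toy_kinase`)
  that realizes requested dihedrals and motif distances exactly, so every
  criterion is testable without downloading structures.

## Worked example

```r
library(kinactive)

fx <- build_toy_kinase(toy_kinase_spec())   # an all-criteria-passing fixture
classify(fx$model, fx$map)
#> CAMK_TOY1 toy_nonTYR chain A: Active
#>   spatial    in (DFGin)
#>   dihedral   in (BLAminus)
#>   saltbr     in (3.00 A)
#>   hrd        in
#>   actloopNT  in (2.90 A)
#>   actloopCT  in
#>              [ APE7_6:in APE8:in APE8_chi1:in APE9_dist:in APE10_dist:in APE11_dist:in APE12_dist:in ]

s <- synth_prediction_scores(30, 10:20, "uniform", pae_value = 4)
ipsae_actloop(s, 10:20)
#> ipSAE(activation loop) = 0.5000  [d0 = 4 A, 19 aligned residues, argmax i = 1]
```

The classification header gives the verdict; each line below it is one
criterion with its state and the measured value it rests on (the salt
bridge here is 3.00 Å, under the 3.6 Å cutoff). The ipSAE value of 0.5 is
the closed form for a uniform predicted-aligned-error of exactly d0 = 4 Å.

For real structures, supply the conserved-motif residue numbers as a CSV
(one row per chain: `kinase_id, chain_id, res_dfg_asp, res_ape_glu,
res_hrd_his, res_saltbridge_lys, res_saltbridge_glu, ...`) and run either
the functions (`read_structure()`, `classify_batch()`) or the CLI:

```sh
exec/kinactive classify --structures 4ekk.pdb --motif-map motifs.csv --out labels.tsv
exec/kinactive score --pae model_pae.json --structure model.pdb --motif-map motifs.csv
exec/kinactive rmsd --mobile model.pdb --reference 2phk.pdb --motif-map motifs.csv --mode ntct --out rmsd.tsv
```

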