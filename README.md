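# vhhpb — Protein Block assessment of nanobody comparative models

Nanobodies (VHH domains, the single variable domains of camelid
heavy-chain-only antibodies) are attractive modeling targets: one
immunoglobulin fold of ~120–130 residues, four conserved framework regions
(FR1–FR4) and three antigen-binding loops (CDR1–CDR3). Comparative models
of a VHH stand or fall with the template choice, and the damage is local —
the long CDR3 loop above all — which global Cα RMSD alone cannot localise.

`vhhpb` is an R package for assessing ensembles of VHH backbone models. Its
core is the 16-letter **Protein Blocks (PB) structural alphabet**: every
window-complete residue is assigned the letter (`a`–`p`; `m` ≈ α-helix,
`d` ≈ central β-strand) whose prototype of 8 φ/ψ dihedrals over a
5-residue window is nearest in wrapped angular RMSD. Over an ensemble of
models this yields per-position statistics:

- **Neq** = exp(−Σₓ fₓ ln fₓ), the equivalent number of PBs (1 = one
  conformation, 16 = uniform over the alphabet);
- **ΔNeq**, the per-position Neq difference between two ensembles;
- **ΔPB** = Σₓ |f¹ₓ − f²ₓ| ∈ [0, 2], the per-position L1 distance between
  two PB distributions (0 identical, 2 disjoint);
- **PB maps**, the position × letter frequency matrices.

Around this core the package provides: PDB backbone I/O and dihedral
computation, SVD least-squares Cα superposition with global and
region-wise RMSD (region-local or framework-frame fitting), CDR
loop-termini Cα distances, simplified Ramachandran fractions, FR/CDR
region annotation with curated overrides, Needleman–Wunsch global
alignment and identity matrices, the four classical template-selection
scenarios (`bestSeqIdTemp`, `bestStructTemp`, `3bestSeqIdTemp`, `All`)
with score-based best-model selection and PIR alignment output, and a
deterministic **synthetic backbone-ensemble generator** (internal-coordinate
rebuild with position-dependent von Mises dihedral noise, optional
anchored-loop construction) so the entire analysis is testable without
external structures or a modeling engine.

## Worked example

Assess two synthetic modeling scenarios of a 60-residue β scaffold whose
CDR3-like window (positions 45–54) samples loosely (von Mises κ = 2,
≈ 45° angular spread) or tightly (κ = 50), frameworks held at κ = 500:

```r
library(vhhpb)
kappa <- rep(500, 60); kappa[45:54] <- 2
cfg <- list(
  sequence = strrep("A", 60), reference_pb = strrep("d", 60),
  regions = list(FR1 = c(1, 10), CDR1 = c(11, 14), FR2 = c(15, 24),
                 CDR2 = c(25, 28), FR3 = c(29, 44), CDR3 = c(45, 54),
                 FR4 = c(55, 60)),
  scenarios = list(
    loose_loop = list(kappa = kappa, anchor = "CDR3", n_models = 100),
    tight_loop = list(kappa = pmax(kappa, 50), anchor = "CDR3", n_models = 100)),
  seed = 1)
report <- assess_ensemble(cfg)
report
#> <assessment_report> 60-residue query, 2 scenario(s)
#>   loose_loop: best model_058, global rmsd 1.897 A
#>   tight_loop: best model_039, global rmsd 0.752 A

sc <- report$scenarios$loose_loop
round(sc$neq[45:54], 2)                  # Neq inside the CDR3 window
#> 2.57 2.45 3.38 3.38 2.71 3.60 3.64 3.22 5.56 3.45
round(rbind(local = sc$region_rmsd_local, frame = sc$region_rmsd_frame), 3)
#>         FR1  CDR1   FR2  CDR2   FR3  CDR3   FR4
#> local 0.161 0.089 0.192 0.027 0.196 1.279 0.042
#> frame 0.588 0.480 0.898 0.934 0.935 4.860 0.086
round(sc$ramachandran, 1)
#>     favored     allowed unfavorable
#>        96.6         1.7         1.7
```

Reading it: the selected loose-loop model sits 1.9 Å from the native while
the tight-loop one reaches 0.75 Å; the loop's conformational sampling is
visible position-by-position (Neq 2.5–5.6 inside the window against ≈ 1.1
in the frameworks), and framework-frame RMSD is elevated only in CDR3 —
the local-conformation signature that global RMSD alone would blur.
Comparing the two scenarios per position (`compare_scenarios(report)`)
gives ΔNeq up to 3.0 and ΔPB up to 0.9, concentrated in the window.

Template selection works on plain identity/RMSD matrices:

```r
fam <- generate_vhh_like_family(6, 64, seed = 2)   # VHH-like family, ~64% identity
im  <- build_identity_matrix(fam)
select_templates("vhh_001", im, scenario = "3bestSeqIdTemp")
#> <scenario_result> vhh_001 / 3bestSeqIdTemp: vhh_005,vhh_002,vhh_004 (SI/MSI 61.9)
```

To run the PB machinery on a real structure, read a chain and assign:

```r
ch <- read_pdb_chain("some_vhh.pdb", chain_id = "B")
pb <- assign_pb_sequence(compute_backbone_dihedrals(ch))
pb_string(pb)
```

Extracting a CDR range of such an assignment (e.g. with curated region
bounds via `annotate_regions(seq, override = ...)`) reproduces published
per-case PB signatures of crystal structures, and `pb_mismatch_count()`
scores model-versus-native signatures with undefined positions masked.

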