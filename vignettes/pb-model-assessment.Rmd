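---
title: "Assessing nanobody comparative models with the Protein Blocks alphabet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing nanobody comparative models with the Protein Blocks alphabet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vhhpb)
```

## The problem

Camelid heavy-chain-only antibodies carry a single variable domain (VHH, a
nanobody) of roughly 120--130 residues: four framework regions (FR1--FR4,
mostly beta-strands of the immunoglobulin sandwich) alternating with three
antigen-binding loops (CDR1--CDR3). Comparative modeling predicts a VHH
structure from one or more template structures, and the choice of template
drives the result: the backbone conformations of the CDR loops -- above all
the long, variable CDR3 -- are the hard part, while global Calpha RMSD alone
hides exactly those local differences.

This package implements the assessment side of that problem. It quantifies
*where* and *how much* an ensemble of models differs in local backbone
conformation, using the Protein Blocks structural alphabet, alongside the
classical global/region-wise RMSD and loop-geometry measures, and it
implements the four standard template-selection strategies so their outcomes
can be compared. Model *generation* (a modeling engine and its scoring
function) is deliberately out of scope: external per-model quality scores
are consumed as input, and a synthetic backbone-ensemble generator stands in
for the modeling engine so that the entire analysis chain is testable,
deterministic, and free of downloads.

## Protein Blocks and the per-position statistics

The Protein Blocks (PB) alphabet discretises local backbone conformation
into 16 prototypes labelled `a`..`p`. Each prototype is a vector of 8
dihedral angles over a five-residue window centred on the assigned residue,
in the order psi(i-2), phi(i-1), psi(i-1), phi(i), psi(i), phi(i+1),
psi(i+1), phi(i+2). Letter `m` is the repetitive alpha-helix prototype and
`d` the central beta-strand; `a`--`c` and `e`--`f` are strand caps,
`g`--`j` coils, `k`--`l` helix N-caps and `n`--`p` helix C-caps. Assignment
computes, at every window-complete position, the angular RMSD (RMSDA: root
mean square of the 8 per-component differences, each wrapped to
[-180, 180] degrees) to each prototype and takes the minimum; ties --
measure-zero on real data -- break alphabetically. Positions without a
complete window (the two first, the two last, anything adjacent to a
missing dihedral) receive the placeholder `Z`. The prototype table ships as
package data (`extdata/pb_prototypes.tsv`) and is the canonical published
table; the package's assignments agree letter-for-letter with the
independent `biotite` implementation, which the test suite checks by
calling the system Python when available.

For an ensemble of models of one query, the per-position frequency vector
$f_x$ over the 16 letters (placeholder `Z` excluded from counts) gives:

* **Neq**, the equivalent number of PBs,
  $N_{eq} = \exp(-\sum_{x=1}^{16} f_x \ln f_x)$, with $0\ln 0 = 0$: 1 when a
  single letter is observed, 16 for the uniform distribution -- an
  exponential Shannon entropy measuring conformational sampling at each
  position;
* **delta-Neq**, the per-position difference of Neq between two ensembles.
  The package keeps it signed (A minus B, order fixed by the caller) and
  leaves taking magnitudes to the presentation layer, since the sign
  convention is otherwise arbitrary;
* **delta-PB**, $\sum_{x=1}^{16} |f^1_x - f^2_x|$, the L1 distance between
  two per-position PB distributions: 0 for identical distributions, 2 for
  disjoint support, and exactly twice the total-variation distance (a
  per-position metric, which the test suite asserts on random profiles);
* **PB maps**, the position-by-letter frequency matrix itself.

Positions where every model is `Z` are reported as explicit "no data"
(`NA`) rather than silently zero.

## Geometry: superposition, region RMSD, loop termini, Ramachandran

Rigid superposition minimises $\sum \lVert R x + t - y\rVert^2$ over proper
rotations via the standard SVD solution with reflection correction,
numerically equivalent to the McLachlan least-squares method. The test
suite confirms optimality against a brute-force axis-angle rotation-grid
oracle on small point sets.

Region-wise RMSD is reported in two documented conventions, because
published per-region figures rarely state theirs: `local_fit` superposes on
each region's own Calpha atoms (regions are then mutually independent;
this is the default), while `frame_fit` superposes once on all FR Calpha
atoms and measures each region in that frame, so CDR values include
displacement relative to the scaffold. CDR loop-termini geometry is the
Euclidean Calpha distance between the first and last residues of the
region -- the anchor-to-anchor span whose conservation between native and
model is diagnostic for loop modeling.

Backbone quality is summarised by Ramachandran fractions over three
deliberately simple, shipped region polygons
(`extdata/ramachandran_regions.tsv`): a favored set (core beta/PPII basin
including its psi wrap-around tail, and the core right-handed alpha basin),
an allowed set (generous extensions plus the left-handed alpha basin), and
the unfavorable remainder. These coarse basins are documented data, not a
statistical validator; they are meant for aggregate percentages of the
"over 90% favored / about 1% unfavorable" kind, not per-residue validation.

## Region annotation

`annotate_regions()` accepts curated FR/CDR bounds (`override`) and
validates them as a contiguous, ordered, exhaustive partition -- the
recommended route, since no single CDR delimitation scheme (Kabat, Chothia,
IMGT) is universal and case-study bounds are usually published per
structure. Without an override, a conservative anchor heuristic locates the
two conserved framework cysteines (near positions 22 and 96) and the FR4
`WGxG` motif, and derives CDR bounds at fixed offsets from those anchors
(CDR1 the 4th--14th residue after the first cysteine; CDR2 a fixed window
after CDR1; CDR3 from two residues past the second cysteine to the residue
before the motif tryptophan). The heuristic fails loudly -- "annotation
failed, supply override" -- rather than guessing when anchors are absent.

## Alignment, identity, and the four template-selection scenarios

Pairwise global alignment is Needleman--Wunsch with affine gaps (BLOSUM62,
gap open 10, gap extend 0.5 by default), delegated to
`Biostrings::pairwiseAlignment()`; an independent dynamic-programming
oracle in the test suite confirms the scoring convention (a length-k gap
costs open + k*extend, end gaps penalised). Percent identity is defined as
identical columns over all alignment columns after excluding terminal-gap
columns. This definition is stated because published identity values
depend on the aligner's convention; it is stable under the CDR3 length
mismatches that dominate difficult VHH cases and is recomputable from the
aligned strings.

The four template-selection scenarios operate on an identity matrix (plus
an RMSD matrix where structural knowledge is assumed): `bestSeqIdTemp`
(argmax identity -- the realistic default), `bestStructTemp` (argmin RMSD
to the query's solved structure -- a theoretical upper bound, since it
peeks at the answer), `3bestSeqIdTemp` (top three identities jointly,
reported with their mean, MSI), and `All` (every candidate, ranked). Best
models are picked from externally supplied lower-is-better scores with
lexicographic tie-breaks. A PIR-dialect writer emits the
modeling-engine-ready alignment file, merging multiple pairwise alignments
on the query coordinates (master--slave, insertions pooled per query
position and left-justified).

## The synthetic ensemble generator

The generator defines the study conditions under which every statistical
claim in the test suite is evaluated, so its construction and defaults are
spelled out:

* **Conformations come from dihedrals.** A reference conformation is given
  as a PB string (each letter contributing its prototype's central phi/psi)
  or directly as a dihedral series, and rebuilt to Cartesian backbone
  coordinates with ideal bond geometry (N--CA 1.458, CA--C 1.525, C--N
  1.329 Angstrom; standard angles; all omega torsions trans). The
  build/measure round trip is exact to better than 1e-6 degrees. Noise is
  applied in dihedral space -- independent von Mises deviates (mean 0,
  per-position concentration kappa, sampled by the Best--Fisher rejection
  method) -- because PBs are dihedral-defined, so the PB-level effect of
  noise is controlled directly. A kappa of 500 corresponds to an angular
  standard deviation of about 2.6 degrees (tight framework), kappa = 2 to
  about 45 degrees (a disordered loop); 100 models per ensemble is the
  default, matching common practice for comparative-model ensembles.
* **Free vs anchored construction.** Rebuilding a chain from noised
  dihedrals propagates every local perturbation rigidly downstream (a
  lever arm). That is the faithful consequence of internal-coordinate
  noise, and it is the default. But real model ensembles hold the
  framework fixed while loops vary, so for framework-referenced statistics
  the generator also offers an anchored-loop construction
  (`generate_ensemble(spec, anchor = c(start, end))`): the rebuilt chain is
  split at the window, the piece carrying the window is fitted rigidly to
  the reference over the upstream positions, the downstream piece over the
  downstream positions, and the two are spliced. Diversity is then
  confined to the window at the cost of a geometric discontinuity at the
  downstream splice, exactly as in classical anchored loop decoys.
* **Only the repetitive prototypes are closed-loop fixed points.** A
  homogeneous run of `m` or `d` rebuilt from central angles re-assigns to
  itself exactly; the 14 transitional letters do not, because their
  8-angle windows are not periodic -- flattening, say, prototype `a` to a
  repeat of its central angles produces an extended-like window nearer to
  `d`. This is a property of the alphabet, not an implementation artifact;
  closed-loop recovery is therefore asserted on `m` and `d` runs, the only
  letters for which a homogeneous run is structurally meaningful.
* **Synthetic scores.** Each model's quality score is
  `score_scale * RMSD(model, reference) + N(0, score_noise)` -- a
  lower-is-better potential correlated with true quality, emulating the
  empirical score--RMSD correlation that makes score-based model selection
  work. With score noise small relative to the RMSD spread, the selected
  model's true RMSD falls in the best quartile with high probability (the
  suite checks > 0.9 over 20 seeds).
* **Sequence families.** `generate_vhh_like_family()` mutates a fixed
  125-residue VHH-like ancestor (conserved cysteines at positions 22 and
  100, `WGQG` at 115) at a per-position rate solved analytically from the
  target mean pairwise identity via `(1-p)^2 + p^2/19`; the default target
  of 64% reflects the typical redundancy-filtered diversity of a VHH
  structural dataset. At 20 sequences the realised mean identity sits
  within about 3 points of the target.
* **Determinism.** One seed governs each ensemble; the draw order is fixed
  (per model: phi deviates for residues 2..L, psi deviates for 1..L-1,
  then the score noise), so identical specs reproduce bit-identical
  coordinates. The orchestration layer derives scenario seeds as
  `seed + scenario_index - 1`.

What the generator does *not* emulate: side chains, physical loop closure,
bond-length/angle variation, packing or solvation effects, and any
sequence-structure coupling (noise amplitude is positional, not
sequence-dependent). Passing tests therefore demonstrate the correctness
and sensitivity of the *assessment machinery* under controlled conditions,
not the accuracy of any modeling engine on real nanobodies.

## The orchestration layer

`assess_ensemble()` runs the whole chain for one query under named
scenarios from a single config (R list, YAML or JSON): reference build,
region validation, ensemble generation, PB assignment, profile/Neq,
score-based best-model selection, global and region RMSD (both modes), CDR
termini distances, Ramachandran fractions. Reports store seed and config
hash, are written only after the full computation succeeds, and re-running
the same config reproduces every number bit-identically.
`compare_reports()` / `compare_all()` / `compare_scenarios()` produce the
per-position delta-Neq and delta-PB tables for report or scenario pairs and
flag positions with delta-PB above 1 (more than half the maximal
disagreement).

```{r example, eval = FALSE}
cfg <- list(
  sequence = strrep("A", 60),
  reference_pb = strrep("d", 60),
  regions = list(FR1 = c(1, 10), CDR1 = c(11, 14), FR2 = c(15, 24),
                 CDR2 = c(25, 28), FR3 = c(29, 44), CDR3 = c(45, 54),
                 FR4 = c(55, 60)),
  scenarios = list(
    single_template = list(kappa_fr = 500, kappa_cdr = 2, n_models = 100),
    multi_template  = list(kappa_fr = 500, kappa_cdr = 10, n_models = 100)),
  seed = 1)
report <- assess_ensemble(cfg)
compare_scenarios(report)
```

## Numerical choices and degenerate inputs

* Angles live in (-180, 180]; all wrapped differences map to [-180, 180].
* Torsions with near-collinear contributing atoms (below 1e-9 of the local
  length scale) are undefined, with a warning, rather than numerically
  wild.
* Alternate locations in PDB input resolve per atom to the
  highest-occupancy record; ties prefer the blank altloc, then `A`, then
  alphabetical. Multi-MODEL files are indexed by `model_index`.
* Non-standard residues with full backbones are accepted and mapped to
  `X`; HETATM records are excluded.
* Superposition requires at least 3 non-collinear pairs; `local_fit`
  region RMSD requires regions of at least 3 residues.
* Assignment tie-breaks, best-model tie-breaks and template-ranking
  tie-breaks are all lexicographic, making every selection deterministic.
* Problem sizes in the test suite (ensembles of 50--100 models of 25--60
  residues, 20-sequence families, 10-mer alignment oracles, a 10-degree
  axis / 1-degree angle rotation grid) were chosen as the smallest sizes at
  which each statistical signature is unambiguous.

## Known limitations

* The anchor heuristic for region annotation is intentionally crude;
  curated overrides are expected for real chains, and full
  Kabat/IMGT/Chothia renumbering is out of scope.
* Percent identity follows this package's documented convention; values
  from other aligners (e.g. profile-based ones) can differ by a few points,
  so identity matrices from mixed sources should not be compared blindly.
* The Ramachandran polygons are coarse basins suitable for aggregate
  fractions only.
* The mirror-image degeneracy of purely dihedral descriptions is resolved
  by construction (proper rotations only, IUPAC torsion signs verified
  against independent implementations), but models supplied as
  coordinates are trusted to be proper-chirality structures.
* delta-Neq's sign is a package convention (first minus second); published
  figures typically show magnitudes.
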