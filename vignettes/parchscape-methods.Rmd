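---
title: "Methods: hydropathy landscapes of nucleosomes with parchscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydropathy landscapes of nucleosomes with parchscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parchscape)
```

## The model

PARCH (Protocol for Assigning a Residue's Character on a Hydropathy
scale) scores a residue group by the resilience of its hydration shell
under a thermal ramp: the structure is position-restrained (force
constant 10,000 kJ mol⁻¹ nm⁻², kept as metadata here) and annealed from
300 to 800 K at 0.1 K/ps, i.e. over 5 ns. Groups that dewet early in
the ramp are hydrophobic and score near zero; groups that retain shell
water to the end are hydrophilic and score high (values up to ~12 for
strongly hydrated DNA backbone). Protein residues receive one value;
each DNA residue receives two — one for the sugar-phosphate backbone
(BB) and one for the nucleobase (NB) — because the two moieties have
sharply different hydration chemistry.

`parchscape` takes the hydration signal as input (per-group water-count
series, or water-oxygen coordinate frames) and defines the PARCH value
operationally as

> pv = scale × mean(shell water count over the final
> `windowFraction` of frames),

with `scale = 1` and `windowFraction = 0.1` by default, the shell being
all water oxygens within `rShell = 4` Å of any heavy atom of the group.
This trailing-window average is a documented stand-in: the published
PARCH normalization lives in the method's original papers, and the
operation signature (`computePV`) is deliberately narrow so an
alternative formula can replace it without touching anything else. The
defaults reproduce the reported value *ranges* (backbone ~1–12,
nucleobases ~0.3–0.4 — water-count magnitudes), which is what the rest
of the pipeline consumes. Frames are equally weighted; the annealing
schedule links frame time to temperature but no temperature weighting
is applied.

Running the annealing MD itself (solvation, thermostats, equilibration)
is out of scope by design.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| proximal cutoff | 3 | Å | DNA within this distance (any heavy atom) of protein is *proximal* |
| contact cutoff | 8 | Å | COG–COG histone–DNA contact criterion |
| inner cutoff | 20 | Å | dinucleosome inner/outer inter-unit criterion; sensitive to compaction state, so exposed as a parameter |
| `rShell` | 4.0 | Å | first-hydration-shell scale around heavy atoms |
| `windowFraction` | 0.1 | — | trailing fraction of frames averaged into pv |
| schedule | 300→800 K, 0.1 K/ps | — | the protocol ramp; 5 ns duration follows arithmetically |
| methyl bond length | 1.50 | Å | standard aromatic C–CH₃ bond |
| KDE bandwidth | Silverman | PV units | conventional rule-of-thumb; fix a numeric bandwidth for bit-reproducible archival runs |
| mode prominence | 0.05 × max density | — | suppresses sampling ripples without hiding genuine secondary modes |
| ΔPV zero tolerance | 0.05 | PV units | deadband so float noise is not given a polarity |

All "within X Å" criteria are **inclusive** (distance = cutoff counts as
within), fixed so tests can assert exact boundaries. All distance
computations use heavy atoms only: the crystal and cryo-EM structures
this pipeline targets resolve hydrogens inconsistently, so including
them would make classifications depend on hydrogen placement software.

## Structure handling

Legacy PDB input is parsed with `bio3d`; residue kinds
(PROTEIN/DNA/WATER/ION/OTHER) are a pure table lookup on the residue
name, testable exhaustively over the packaged table. For alternate
locations the highest-occupancy conformer is kept, ties broken by
alt-loc character order; multi-model files keep the first model with a
warning. The DNA backbone/nucleobase partition templates are frozen
against the chemical component dictionary; sugar atoms including the
glycosidic C1′ are assigned to the backbone, so NB is exactly the base
ring plus exocyclic substituents. Atoms missing from a residue (5′
termini) are skipped silently; atoms missing from the *template* are an
error, because a silently mis-binned atom would corrupt both moiety
scores.

The PARCH-annotated output dialect appends the per-atom value as a
fixed-width field in columns 67–72, after the B-factor. The original
description does not define this format, so the dialect is a repository
convention — which is why every annotated PDB is accompanied by a TSV
sidecar (chain, seq_id, icode, res_name, moiety, pv) that is the
authoritative machine-readable artifact.

For methylation, the placed methyl carbon is named `C5M` and the
residue renamed to the standard component id `5CM` (the legacy label
`FMC` is accepted on input; the dictionary's own methyl name `C5A` is
accepted by the partition). Placement is deterministic: in the
least-squares plane of the pyrimidine ring, along the external bisector
of the C4–C5–C6 angle, 1.50 Å from C5. Methyl hydrogens are not added
(heavy-atom model throughout). A methyl landing within 1.8 Å of a
non-bonded atom is kept but flagged — in production use such contacts
are relaxed by the downstream MD that is outside this package.

In paired ΔPARCH analyses, residues are matched by
(chain, seqid, icode, moiety); name changes across the pair (DC↔5CM)
are allowed, renumbered pairs are handled by an explicit per-chain
offset map, and unmatched records are reported rather than dropped.
Histone-only systems produced by `stripDNA` retain waters and ions by
default (flags to drop): retaining crystallographic solvent is the
conservative choice when a pairing protocol does not state otherwise.

## Statistics

Density estimates use a Gaussian kernel with Silverman's rule-of-thumb
bandwidth — the field's defaults, adopted here as explicit package
conventions. The evaluation
grid spans `[min − 4h, max + 4h]` with step ≤ h/5 — slightly wider than
the minimum needed, so that the trapezoidal integral of the density is
1 within 10⁻³ even for samples piled against the truncation boundary at
0. Modes are interior local maxima with topographic prominence at least
5% of the global maximum; plateaus collapse to their first grid point,
and a grid edge never limits prominence.

Two-group comparisons use the two-sided Mann–Whitney U test
(`stats::wilcox.test`): exact enumeration when both samples have ≤ 20
observations and no ties, the normal approximation with tie and
continuity corrections otherwise. The test is a design choice —
nonparametric and standard for violin-plot group comparisons — with
the conventional star annotation: `****` p < 0.0001, `***` p < 0.001,
`**` p < 0.01, `*` p < 0.05, else `ns`. Quantile summaries use linear
interpolation between order statistics (type 7), stated here so
summaries are bit-reproducible. No multiple-testing correction is
applied: each analysis makes a single planned comparison.

## The synthetic generators

The synthetic module stands in for the study's MD data and is
first-class, tested code.

**Toy structures.** `buildToyNucleosome` lays two complementary
147-residue DNA strands (standard atom names, idealized planar bases)
on a superhelix of radius 42 Å, pitch 24 Å, 1.65 turns — textbook
nucleosome geometry — around a pseudo-octamer of eight CA-only chains,
two per histone type. Acidic-patch positions carry their canonical
GLU/ASP identities; four residues per chain are relocated to 2.5 Å
from a DNA phosphate and named ARG, emulating minor-groove arginine
anchors so that the proximal/distal classifier has a non-trivial answer.
The builder guarantees no inter-chain heavy-atom contact below 2 Å.
`buildToyDinucleosome` stacks two such units along z (default
separation 60 Å) with a straight linker (default 6 bp) whose residues
belong to the unit of their half of the strand, split at the midpoint.
One consequence worth stating: with any covalent linker present, the
residues flanking the midpoint are always mutually within 20 Å, so the
"everything OUTER at large separation" regime exists only for
`linkerBp = 0`.

**Planted trajectories.** `genHydrationTrajectory` inverts the scorer:
window frames equal the planted value plus optional iid Gaussian noise,
earlier frames decay from a hydrated plateau to mimic dewetting, and
the real-valued series is quantized to integer counts by error
diffusion, which preserves segment sums to within rounding. Counts are
integers, so achievable window means live on a 1/m lattice (m = window
frames); `plantedSystem` therefore stores the *realized*
(lattice-quantized) planted table, against which recovery is exact at
zero noise. Under noise σ the window-mean error is ~σ/√m plus a
quantization term ≤ 1/(2m).

**Presets.** `samplePreset` draws from truncated normal mixtures whose
*locations* encode the reported regimes — nucleosomal backbone
0.5·N(1, 0.4²) + 0.5·N(5, 1.2²); fragment backbone N(4, 1²);
nucleobase N(0.35, 0.05²) — while the weights, spreads and planted
effect sizes (methylated backbone N(4.5, 1.2²) shifted by −0.8;
dinucleosome inner backbone shifted −1.5 from outer N(5, 1.2²)) are
synthetic choices, fixed once and recorded in `presetParameters()`.
Components are truncated at 0 individually (negative draws redrawn
within their component), so component frequencies match the stated
weights exactly.

**What passing tests do and do not show.** The synthetic systems
exercise the *code*: classifier correctness against brute-force
oracles, exact generator/scorer consistency, and the statistical
machinery at planted effect sizes. They do not validate the physics:
toy geometry is not a physical model, preset spreads are not measured
distributions, and the planted shifts are calibrated to be detectable
at the preset sample sizes. Conclusions about real nucleosomes require
real annealing trajectories.

## Problem sizes and runtime choices

The test suite uses the full 147-bp toy where the claim concerns the
default build, and a 12-bp toy (still 8 protein chains, 24 DNA
residues, ~500 trajectory frames) where the claim concerns the
pipeline's arithmetic; oracle-equivalence sweeps run 100 randomized
small structures. The acceptance script draws 5000-value preset samples
for density statistics and 200/500 per group for the rank-sum
comparisons — the sizes at which those analyses are defined in the
package. The whole suite runs in about a minute on one CPU.

## Known limitations

* The PARCH value formula is the documented trailing-window stand-in,
  not the published normalization; swap `computePV` to change it.
* No mmCIF input, no symmetry expansion, no hydrogen placement.
* Linker assignment in dinucleosomes (strand-midpoint split) is a
  package convention; other per-nucleosome assignments of linker DNA
  are defensible.
* The arginine-anchor set ships empty (`inst/extdata/
  arginine_anchors.tsv`): anchor identities are structure-specific
  configuration, not package constants.
* `classifyInnerOuter` requires exactly two labelled units;
  higher-order oligonucleosomes are out of scope.
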