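---
title: "Alpha-satellite monomer and higher-order repeat analysis with alphoidr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alpha-satellite monomer and higher-order repeat analysis with alphoidr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphoidr)
```

## The problem

Primate centromeres consist of α-satellite DNA: ~171-bp monomers repeated
head-to-tail over hundreds of kilobases. Two monomer lineages exist —
A-type monomers binding the pJα protein through the 17-bp motif
`CTAPyGGTGPuAAAAGGAA`, and B-type monomers binding CENP-B through the
CENP-B box `PyTTCGTTGGAAPuCGGGA`. Arrays are either *monomeric*
(neighbouring monomers 10–40% divergent, no larger structure) or organized
into *higher-order repeats* (HORs): a unit of 2–30+ monomers repeated with
very high inter-unit identity. HOR composition and order define
suprachromosomal families (SFs). For gorilla these are SF1 (dimeric,
gJ1–gJ2 = A–B), SF2 (octameric,
gD1.0–gD1.3–gD1.4–gD2.1–gD1.2–gD2.0–gD1.1–gD2.2 = B-B-B-A-B-A-B-A,
periodically including a 189-bp extra-long monomer) and SF3 (pentameric,
gW1–gW5 = B-B-B-A-A). The package turns the corresponding sequence-level
analyses — segmentation, motif annotation, typing, HOR detection, family
assignment, insertion characterization, consensus building and
distance-based phylogenetics — into reusable, tested components.

All coordinates are 0-based half-open internally; BED is written as-is and
GFF3 converts to 1-based closed at serialization only.

## The extended alphabet

Consensus sequences use `{A,C,G,T}`, the IUPAC degeneracy codes, and three
*gap codes* expressing "base or absent": `F` = -/A, `I` = -/C, `J` = -/G.
No published code exists for -/T; the consensus builder uses `O` by
default, configurable via `t_gap_symbol`. During alignment a degenerate
symbol scores as a match against any base of its expansion set; `N` scores
neutrally (0) against everything. Gap-code symbols score as their base
(`F`=A, `I`=C, `J`=G): a standard affine-gap alignment cannot make a
position individually skippable at no cost, and only one consensus
(the A-type, 4 of 172 positions) contains gap codes, so the approximation
is negligible in practice — the recovery properties below all hold under
it.

## Segmentation

`segment_monomers()` uses a deterministic anchor-and-extend scheme:

1. *Orientation.* The strand giving the better local alignment of the
   reference consensus wins; both strands scoring under 50 means no
   alphoid signal (random 1-kb sequence scores ~10–30 under the
   +1/−2/5/2 scheme).
2. *Phase.* The best placement of the whole reference in the array
   (`global-local` alignment) anchors the first boundary. The anchor
   start is snapped to the nearest strong match (≤ 3/20 mismatches) of
   the reference's first 20 bp — the most conserved alphoid stretch, the
   region the classical α-27 amplification primer targets.
3. *Extension.* From each committed boundary a window of `max_len + 30`
   bases is scanned. The next cut is placed at a strong reference-head
   match in the admissible length range `[min_len, max_len]` when one
   exists, otherwise at the end of the reference's alignment inside the
   window. The leftward pass runs the same procedure on the reversed
   strings, so both directions only ever extend from a committed
   boundary.

Cut points are shared between adjacent monomers, so the emitted intervals
tile the array exactly. Flanking fragments shorter than `min_flank_keep`
(default 100 bp) are dropped; other flanks and out-of-range intervals are
flagged `partial` and excluded from downstream statistics.

The head-snapping rule exists because pure alignment extension has a
near-tie around the 189-bp insertion monomer: skipping the 18-bp
insertion gap and clipping ~20 bp from a monomer edge score within a few
points of the correct decomposition. Anchoring cuts on the conserved
monomer head resolves the tie in favour of the true boundary; at zero
noise all family fixtures then segment exactly, and at 2% substitution
boundary recovery within ±3 bp exceeds 99%.

Defaults: `min_len = 140`, `max_len = 220` (bracketing the observed
167–189 bp consensus range around the canonical 171), alignment scores
+1 match, −2 mismatch, gap open 5, gap extend 2 — the standard BLASTN-like
scheme used for alphoid comparisons.

## Motif scanning and A/B typing

`scan_prd()` slides both degenerate 17-mers over the monomer and keeps the
hit with fewest mismatches (ties: pJα first); hits worse than
`max_mismatch_call = 5` are discarded. `full_intact` requires all 17
positions to satisfy the pattern; `core_intact` requires the core
positions only. For the CENP-B box the default core is the nine essential
nucleotides, positions {2,3,4,5,10,13,14,15,16} of the 17-mer (the
`TTCG…A…CGGG` residues); no canonical core is established for the pJα
motif, so its default core is all non-degenerate positions and the spec
object records that the default was used (`core_default`). Both are
overridable. Motifs spanning monomer junctions are not scanned; the
simulator never splits a motif across monomers.

`classify_ab()` computes p-distances to the A- and B-type consensuses and
assigns the strictly nearer type; a tie margin `delta` (default 0) and an
assignment ceiling `max_assign_dist = 0.40` (the top of the monomeric
divergence range) leave ambiguous or degenerate monomers undetermined.
On the published units this reproduces the family compositions exactly:
SF2 yields three A and five B monomers, SF3 two A and three B.

## HOR detection

`periodicity_profile()` computes the full pairwise p-distance matrix of
the ordered monomers (a quantitative dot plot) and averages its
diagonals: `d[k]` is the mean distance between monomers `i` and `i + k`.
Distances come from global pairwise alignment with pairwise deletion, so
the 18-bp insertion block of a 189-bp monomer aligns as gaps and is
automatically excluded when compared against a 171-bp partner — no
special-casing is needed for SF2.

`call_hor()` returns the smallest lag `k` with

* `d[k] ≤ max_dist` (default 0.10, between within-HOR divergence, below
  ~6%, and the ≥10% of monomeric arrays),
* `d[k] ≤ dominance × median{d[j] : j not a multiple of k}` (default
  0.5), and
* at least `min_units = 2` complete units.

Lag 1 denotes a fully homogenized (effectively monomeric) array; no
qualifying lag denotes a monomeric array. Because a zero at the
fundamental period propagates to all its multiples, the smallest-`k` rule
returns the fundamental period. The criterion the original TRF/dot-plot
analysis used is not stated; this explicit threshold pair is the
package's declared operationalization, and a brute-force oracle
(partitioning monomers into congruence classes per candidate unit size)
agrees with it on all tested arrays. Arrays are treated as linear; no
wrap-around pairs are formed.

## SF assignment

`assign_monomer_sf()` returns the nearest of the sixteen unit consensuses
(general consensuses excluded; ties go to the lexicographically smallest
name and are flagged). `assign_array_sf()` assigns a family only on
concordant evidence: HOR period equals the family's unit count, at least
`majority = 0.8` of monomers have their nearest consensus inside the
family, and optionally the succession of nearest-unit labels matches the
family's published order up to cyclic rotation. The 0.8 default tolerates
truncated units — the pentameric family in particular rarely forms long
uninterrupted stretches. HOR-less arrays whose monomers sit nearest gM1
(or that reach no family majority) are `monomeric`; everything else is
`unassigned`. A user-supplied consensus set (e.g. the twelve human
consensuses, which are not shipped because their sequences are not
printed in the source material) can be plugged in via `cset`.

## The 189-bp insertion

`characterize_insertion()` aligns an extra-long monomer to a B-type
reference and reports the inserted block. The published event is a tandem
duplication that interrupts the CENP-B box at its 13th conserved
position, copies 22 bp upstream (the unfinished box plus nine bases) and,
with a 4-bp downstream deletion, nets +18 bp while regenerating a
complete, core-intact box. A 22-bp duplication plus 4-bp deletion and an
18-bp clean duplication are degenerate descriptions of the same sequence;
the report records the raw gap structure in `notes` so either reading can
be recovered. Because an affine aligner places gaps arbitrarily inside a
tandem repeat, the duplication seam is re-located by scanning positions
within ±25 bp of the reported block and periods 14–40 for the
minimum-edit tandem junction (≤ 4 edits per copy); `copies` is then the
rounded ratio of total inserted length to the duplication unit. On the
printed 189-bp consensus against gD1.0 this yields net insertion 18,
unit 22 bp, 1 copy, box break at pattern position 14 (i.e. intact
through 13) and a regenerated core-intact box; simulated two- and
three-copy monomers round-trip exactly.

## Consensus building

`align_monomers()` projects every monomer into the coordinates of a
reference via pairwise global alignment — a deterministic substitute for
progressive multiple alignment that is adequate for near-identical
monomers and keeps the contract testable. Insertions relative to the
reference open new columns only when shared by more than half of the
rows; rarer insertions are retained as per-row metadata, and
`reconstruct_monomer()` rebuilds every input exactly from row plus
metadata. `build_consensus()` then applies the majority rule per column:
a symbol above 50% is emitted (a majority gap deletes the column);
otherwise the ambiguity code covering the symbols at frequency
≥ `min_component_freq` (default 0.2, filtering sporadic substitutions —
published code sets span 2–3 bases) is written, using the gap codes for
gap-containing pairs. Exactly-50% columns are never collapsed to a single
base; columns too ambiguous for any code become `N`. Whether the original
consensus code sets were frequency-filtered is unknown; the filter is
therefore exposed as a parameter.

## Phylogenetics

`p_distance()` implements pairwise deletion: only columns where both rows
carry a concrete base are compared. `nj_tree()` is a standard Saitou–Nei
agglomeration with two determinism guarantees: ties in the Q criterion
break on the lexicographically smallest pair of cluster labels, and
negative branch lengths are clamped to zero with a count recorded in
`attr(tree, "clamped")`. On additive matrices it reproduces all path
lengths to 1e−9 and matches an independent NJ implementation
topologically. `bootstrap_support()` resamples alignment columns with
replacement, rebuilds the tree per replicate and reports bipartition
recovery percentages; it is deterministic given `seed`.

## The simulator

`simulate_array()` generates arrays whose ground truth is known exactly,
emulating the published statistical structure:

* HOR families concatenate the family's consensus monomers in their
  published succession, resolve ambiguity codes once per array, tile the
  unit `n_units` times and apply i.i.d. substitutions (`sub_rate`;
  within-HOR divergence in real arrays is below 2%, so 0–2% is the
  realistic regime and the default tests use 0, 1 and 2%).
* Monomeric arrays draw every monomer from gM1 and mutate each at its own
  rate, uniform in [0.10, 0.40] — the published divergence range of
  HOR-less arrays.
* SF2 can carry 1–3 copies of the gD1.4 duplication unit
  (`insertion_copies`), modelling the further duplicated/triplicated
  insertions observed in shotgun contigs.
* `revcomp = TRUE` emits the minus strand; truth boundaries always refer
  to the forward-normalized array.
* `indel_rate` defaults to 0 (no indel rate is reported for real arrays);
  when positive, monomers are mutated independently so truth coordinates
  stay exact.
* `protect_motifs` optionally shields the 17-bp PRD of each source
  monomer from substitutions, letting motif-conservation statistics be
  varied independently of overall divergence.

What the simulator does *not* emulate: molecular-drive homogenization
(unequal crossover, gene conversion), array-scale rearrangements,
N-runs and sequencing artefacts of real shotgun contigs, and
between-array divergence gradients. Passing tests therefore demonstrate
correctness of the algorithms under the published divergence regimes,
not performance on arbitrary real-genome contigs.

## Numerical and testing choices

Problem sizes in the test-suite were chosen for desk-scale runs while
keeping every threshold at its contract value: boundary recovery uses 20
replicates at 2% substitution across the three families (≥ 99% within
±3 bp); HOR recovery a 3-family × {0, 2%} × 3-seed grid (≥ 95%);
consensus recovery 10 replicates of 20 copies at 5% noise (exact
recovery); NJ additivity 20 random 7-taxon trees (1e−9); the A/B
bipartition check 40 simulated monomers. The acceptance script
regenerates its fixtures from the printed consensus set at the given
seed; all its outputs are integers fixed by the published family
structures (periods 2, 8, 5; lengths 189 and 18 bp), so they are
insensitive to the seed.

## Known limitations

* Segmentation assumes a single alphoid reference per array; chimeric
  arrays mixing radically different satellites are out of scope, and
  arrays with long N-runs should be pre-filtered.
* The reference-projected alignment is not a full progressive MSA;
  columns distant from the reference model (e.g. long shared insertions
  at different positions) may fragment.
* `nj_tree()` is an O(n³) pure-R implementation intended for up to a few
  hundred leaves; the pipeline's tree stage is leaf-capped (default 500)
  for that reason.
* Dataset-wide census numbers from the original survey (total monomer
  counts, PRD tallies, the full 2521-leaf tree) depend on a specific
  archive retrieval set and are deliberately not reproduced.
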