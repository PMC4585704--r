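# alphoidr

Analysis of primate centromeric **α-satellite (alphoid) DNA** in R.

Primate centromeres are built from ~171-bp monomers repeated head-to-tail.
Monomers come in two ancestral types — A-type, carrying the 17-bp pJα
motif `CTAPyGGTGPuAAAAGGAA`, and B-type, carrying the CENP-B box
`PyTTCGTTGGAAPuCGGGA` — and arrays are either *monomeric* (10–40%
divergence between neighbours) or organized into *higher-order repeats*
(HORs): multi-monomer units repeated with near-identity, which define the
suprachromosomal families (SFs). In gorilla, SF1 is dimeric (gJ1–gJ2,
A–B), SF2 is uniquely octameric
(gD1.0–gD1.3–gD1.4–gD2.1–gD1.2–gD2.0–gD1.1–gD2.2) and periodically
includes a 189-bp monomer created by a tandem duplication that interrupts
and then regenerates the CENP-B box, and SF3 is pentameric (gW1–gW5,
B-B-B-A-A).

`alphoidr` implements this analysis stack for anyone working with
satellite arrays from clones, shotgun contigs or assemblies:

* **Segmentation** — orientation normalization and anchor-and-extend
  decomposition of an array into monomers against a reference consensus.
* **Classification** — degenerate 17-mer PRD scanning with core/full
  conservation scoring, and A/B typing by p-distance to the type
  consensuses.
* **HOR detection** — monomer-lag periodicity profiles (diagonal means of
  the pairwise p-distance "dot plot") and a dominance-tested period call.
* **SF assignment** — nearest-consensus per monomer plus concordance of
  period, composition majority and cyclic unit order.
* **Insertion characterization** — detection of extra-long (~189 bp)
  monomers and reconstruction of the duplication unit, copy number (1–3),
  box break position and regenerated CENP-B box.
* **Consensus building** — majority-rule (>50%) consensus over an
  extended alphabet: IUPAC codes plus the gap codes `F` (-/A), `I` (-/C),
  `J` (-/G).
* **Phylogenetics** — p-distance with pairwise deletion, deterministic
  neighbor-joining and column-resampling bootstrap.
* **Simulation** — ground-truth synthetic arrays generated from the
  built-in gorilla consensus set, so every stage is testable without any
  sequence download.

The 19 published gorilla alphoid consensus sequences ship as package data
(`gorilla_consensuses()`).

## Worked example

Simulate a gorilla SF2 array (4 octameric units, 1% substitution noise),
then run the pipeline stages:

```r
library(alphoidr)

sim <- simulate_array(sim_params("SF2", n_units = 4, sub_rate = 0.01,
                                 seed = 7))
mon <- segment_monomers(sim$array)
nrow(mon)
#> [1] 32
table(mon$length)
#>
#> 168 171 189
#>   4  24   4

hor <- detect_hor(mon)
hor$label; hor$period
#> [1] "octameric"
#> [1] 8

asn <- lapply(mon$sequence, assign_monomer_sf)
assign_array_sf(asn, hor)$sf
#> [1] "SF2"

long <- detect_long_monomers(mon)
rep <- characterize_insertion(long$sequence[1], bref = "gD1.0")
rep$net_insertion; rep$copies; rep$regenerated_box_core_intact
#> [1] 18
#> [1] 1
#> [1] TRUE
```

The array segments into 32 monomers at the exact unit boundaries (the
168-bp gD1.3 and the 189-bp gD1.4 insertion monomer appear once per
unit), the HOR detector calls the octameric period, the array is
assigned to SF2, and the extra-long monomer carries the 18-bp net
insertion with a regenerated, core-intact CENP-B box.

`run_pipeline()` chains all stages over a FASTA of arrays and writes
monomer BED, classification TSV, per-family consensus FASTA and a JSON
report.

## Scope

The package operates on sequences; wet-lab stages of satellite
characterization (FISH, restriction mapping, cloning) and dataset-wide
census numbers tied to specific archive retrievals are out of scope.
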