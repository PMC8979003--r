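---
title: "Methods: mitochondrial transcription-unit annotation and mirror-tree co-evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitochondrial transcription-unit annotation and mirror-tree co-evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotrx)
```

## The model

`mitotrx` annotates transcription on circular, AT-rich fungal mitogenomes
under three assumptions drawn from the biology of Hypocrealean
entomopathogens:

1. **Promoter-anchored polycistrons.** All genes are transcribed from the
   same strand in a small number of polycistronic precursors. Each
   precursor starts at the "+1" base immediately 3' of a short degenerate
   promoter motif lying in an intergenic region, and extends around the
   circle until the next promoter's +1. Segmentation therefore needs only
   the ordered set of transcription start sites (TSSs): every top-level
   gene belongs to the arc `[tss_i, tss_{i+1})` holding its start
   coordinate.
2. **TAAATT 3'-end processing.** The 3' termini of mRNAs and the large
   rRNA coincide with `5'-TAAATT-3'` hexamers a short, variable distance
   downstream of the coding end. tRNAs are excluded: their ends are
   processing sites of a different kind.
3. **tRNA punctuation.** Precursors mature by excision of their embedded
   tRNAs; cutting at every tRNA 5' and 3' boundary releases the mature
   mRNA/rRNA fragments.

Coordinates are 0-based, half-open, forward strand throughout; on a
circular genome all arithmetic is modulo the length, and a feature whose
`end` is below its `start` wraps the origin. File formats (FASTA, GFF3,
GenBank) use their native 1-based inclusive convention and are converted
at the boundary, which confines off-by-one risk to two functions.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| promoter motif | `WTAGWWHWWHD` | IUPAC 11-mer | the order-level degenerate consensus; both printed literals (`ATAGTTATTAT`, `TTAGAATATTAT`) contain a window matching it and ship as presets |
| `max_mismatch` | 0 | positions | the motif is already degenerate; allowing mismatches on a 72% AT background floods the scan with chance hits |
| `threshold_frac` (PWM) | 0.8 | fraction of max score | conservative equivalent of the exact IUPAC match for PWM-mode scanning |
| strand | sense only | – | both genomes are transcribed as same-strand polycistrons; `strands = "both"` is available for other taxa |
| terminator motif | `TAAATT` | 6-mer | the processing hexamer; scanned exactly |
| `window_nt` | 250 | nt | covers the observed 1–218 nt distance range with margin |
| PWM pseudocount | 0.25 | counts/base | small-sample smoothing for promoter alignments of ~6–12 instances |
| consensus `t_major` / `t_cover` | 0.75 / 0 | frequency | majority call vs. minority coverage when rebuilding a consensus from instances |
| distance model | p-distance, pairwise deletion | – | matches the default distance pipeline of the original mirror-tree method; Poisson correction available |

One caveat worth stating: the property "a `t_cover = 0` consensus matches
every instance it was built from" is guaranteed only at `t_major = 1`. A
majority call at lower thresholds deliberately drops minority bases, so an
instance carrying the minority base no longer matches exactly. The test
suite checks the invariant in the regime where it holds.

## Promoter and terminator calling

`find_promoters()` scans only intergenic sequence, on the sense strand.
When one region holds several hits the hit **closest to the downstream
gene's start** is retained — mitochondrial promoters sit directly upstream
of the first gene of their unit, so the most-downstream match is the
biologically meaningful anchor. The TSS is `position + motif length`
(mod L).

`find_terminators()` searches, for each top-level mRNA/rRNA, the
`window_nt` bases after the coding 3' end and keeps the **nearest** hit
(at most one call per feature). `distance_nt` counts the bases between
coding end and motif start, so an abutting motif has distance 0 and the
published "1 nt" corresponds to a 1-base gap.

## Segmentation and maturation

`segment_units()` assigns genes to promoter arcs as above. The nearest
terminator called for the unit's **last** mRNA/rRNA gene, if it lies
before the next TSS, is attached. A unit's span runs from its TSS to the
terminator motif end or the last gene end, whichever is farther: units can
legitimately end in trailing tRNAs beyond the mRNA terminator, and the
span must contain every assigned gene. Labels are roman numerals assigned
in circle order starting from the rnl-bearing unit, mirroring the
experimental map's convention; all comparisons are rotation- and
label-invariant regardless. A gene whose span wraps past the next TSS is
kept in the arc of its start (with a warning) — a deterministic tie-break
for pathological configurations.

`mature_transcripts()` places cut points at every tRNA 5' and 3' boundary.
Fragments are typed by content (tRNA fragments span exactly their gene;
fragments holding coding genes become mRNA/rRNA products, nested genes
riding along with their parent). Two adjacent tRNAs leave a gene-less
fragment between their cut points; it is reported with kind `"spacer"`
rather than silently discarded so that product spans **tile each unit
exactly** — the conservation invariant the tests verify. A terminator call
falling inside a fragment is recorded in `signals_used` as the fragment's
3'-end signal.

## What the simulator emulates — and what it does not

`simulate_genome()` reproduces the statistical structure the pipeline is
built for: a ~25 kb circle at 72% A+T; the canonical gene map (14 mRNAs,
rnl/rns with rps3 nested in rnl, 25 tRNAs in clusters) in the real circle
order, partitioned into six units; promoter instances planted at the 3'
end of the unit-leading intergenic regions with 5' UTRs drawn uniformly
from 10–100 bp; and TAAATT terminators planted 1–218 nt downstream of
every mRNA/rRNA. Intergenic gaps are drawn from 30–500 bp and then
rescaled (respecting per-gap minima) so genes and gaps tile the circle
exactly; the generator reports a deficit error when the configuration
cannot fit.

By default the background is **rejection-scrubbed**: every chance
sense-strand window matching the promoter consensus or the terminator
hexamer is destroyed by a single base change (planted signals, start and
stop codons stay untouched), iterating until none remain. On a 72% AT
background roughly a hundred such windows arise per genome, so scrubbing
shifts composition by only a few tenths of a percent. This separates
correctness tests (decoy-free: precision = recall = 1 is the expected
outcome) from robustness experiments, which can re-enable chance matches
via `decoy_rate`.

The simulator does **not** model introns, codon usage, indels,
strand-mixed gene order, gene overlaps, or promoter/terminator sequence
degradation. Passing the planted-recovery tests therefore demonstrates
algorithmic correctness of the scanning/segmentation machinery, not
real-data sensitivity: on real genomes the 0-mismatch consensus scan is a
calibrated choice whose mismatch tolerance deserves sensitivity analysis.

`simulate_coevolving_pair()` draws a random topology (`ape::rtree`) with
branch lengths uniform on `(0, tree_depth)` substitutions/site and evolves
sequences by a single-rate 20-state uniform-exchange (Poisson) process —
the simplest process for which the Poisson distance is the matching
estimator. `"shared-tree"` mode evolves both proteins on one tree
(co-evolution); `"independent"` mode draws a second tree. At
`tree_depth = 0` all rows are identical and the mirror-tree correlation is
deliberately an error (zero variance), not a number.

## Numerical choices

* PWM scores are log2 odds (bits) against the background; windows holding
  ambiguity codes are disqualified rather than guessed.
* Percentage comparisons against printed integers round half away from
  zero; composition excludes ambiguous symbols from numerator and
  denominator.
* Neighbor joining delegates to `ape::nj`; negative branch lengths are
  clamped to zero with the total deficit reported. On additive matrices
  the reconstructed tree's cophenetic distances reproduce the input to
  numerical precision (checked exhaustively for all three 4-taxon
  topologies and random 5–8 taxon trees).
* The mirror-tree score restricts both matrices to their shared taxa in
  alphabetical order and correlates upper triangles; fewer than 4 shared
  taxa or a zero-variance triangle is an error, never `NA`.
* In-silico PCR measures amplicons from the forward primer's 5' end
  through the reverse primer's 5' end inclusive, reports the shortest
  product per forward site, and treats absent primer sites as an empty
  result, not an error.

## Problem sizes

The shipped tests and the acceptance script use: 50 simulated genomes
(seeds 1–50 equivalent) for planted-signal recovery and unit-partition
accuracy; 100 seed pairs per mode at 20 taxa and 300 sites for the
mirror-tree separation; 2 kb regions for scanner/oracle equivalence; and
5–8 taxon trees for the neighbor-joining round-trips. These sizes give
stable statistics (binomial error on a 50-genome recovery rate is ~±3%)
while keeping a full run in well under a minute per stage.

## Known limitations

* The promoter search is alignment-anchored consensus matching, not de
  novo motif discovery; novel taxa with divergent promoters need their own
  instance sets (`build_consensus()` / `build_pwm()` accept any curated
  alignment).
* GenBank parsing covers the flat-file subset these mitogenome records
  use (simple and `complement()` locations; `join()` collapsed to its
  overall range).
* The experimental reproduction of the published genome statistics needs
  local copies of the two GenBank records; the corresponding test reports
  failures until they are supplied under `inst/extdata/accessions/`.
* Wrapped (origin-crossing) features are fully supported internally but
  cannot be expressed in GFF3 output; exports of such features error
  rather than silently relocating them.
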