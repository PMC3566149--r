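---
title: "Methods: models, parameters and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented by `mrenet`, the meaning
of every tunable parameter, the coordinate and numerical conventions, and
the scope of the synthetic data generator. It is a methods reference, not
a tutorial; the worked example lives in the README, and every numeric
claim made here is asserted by the test suite or recomputed by
`scripts/acceptance.R`.

## Coordinate conventions

All internal interval arithmetic is 0-based, half-open (`[start, end)`),
matching BED. GTF input/output shifts by one base at the boundary
(`read_gtf()` subtracts 1 from starts; `write_gtf()` adds it back).
Spliced transcript coordinates count from the transcript 5' end: for a
minus-strand transcript the exon blocks are concatenated in genomic order
and then reversed, so genomic position `g` maps to
`L - 1 - offset(g)` where `L` is the spliced length
(`genomic_to_transcript()` / `transcript_to_genomic()` are exact
inverses on every exonic base, which the tests verify by enumeration).

## Cluster calling

A *miRNA recognition element* is a maximal contiguous run of genomic
positions whose merged per-base read depth is at least `min_depth`
(default 5), computed per chromosome and strand (`ignore_strand = TRUE`
pools strands). Depth is computed with `IRanges::coverage()` and runs
are sliced at the threshold; the test suite checks equivalence against an
independent per-base brute-force oracle across random instances at
`min_depth` 1, 2, 5 and 10, and pins the boundary case: five identical
reads produce exactly one element, four produce none. Per-library
*support* is the number of reads from each Argonaute library overlapping
the element by at least one base; a read spanning two elements counts
toward both.

## Annotation overlap

Elements are intersected with exon annotation via
`GenomicRanges::findOverlaps()` (stranded by default,
`same_strand = FALSE` to relax). Each overlapping (element, exon) pair
yields one annotation row whose `tx_start`/`tx_end` is the element span
clipped to the exon and mapped to spliced coordinates, oriented 5'→3' on
the transcript. Biotype classing is binary: `protein_coding` is mRNA,
all other biotypes are treated as lncRNA classes (processed transcripts,
antisense, lincRNA, ncRNA hosts, noncoding, retained introns).

## Duplex scoring model

`align_duplex()` is a local Smith–Waterman alignment of the miRNA
(reversed, so the duplex is antiparallel) against the target site with a
three-state affine-gap DP (match state plus one insertion state per
sequence; gap-to-gap transitions between the two insertion states are
disallowed). Pair scores:

| pair              | score |
|-------------------|------:|
| Watson–Crick      | +5    |
| G:U wobble        | +1    |
| other             | −3    |
| gap open          | −9    |
| gap extend        | −4    |

A gap of length $L$ costs $-9 - 4(L-1)$. Every column whose miRNA base
falls in seed positions 2–8 (counted from the miRNA 5' end) has its pair
score multiplied by 4 — this applies to matches, wobbles and mismatches
alike. Scores floor at 0 (empty alignment). Ties are broken
deterministically: maximal score, then shortest alignment, then smallest
target start.

Two closed forms anchor the parameterization and are asserted exactly by
the tests and the acceptance script: a perfect 22-nt complement scores
$22 \cdot 5 + 7 \cdot 5 \cdot (4 - 1) = 215$, and converting one seed
Watson–Crick pair to a G:U wobble costs $(5 - 1) \cdot 4 = 16$, giving
199. The DP is checked against an exhaustive memoized recursion (and that
recursion against pure enumeration) on short sequences.

## Hybridization energy model

`duplex_energy()` evaluates a *reduced* nearest-neighbor model on the
alignment returned by `align_duplex()`:

- Watson–Crick stack free energies (ΔG°37, kcal/mol) from the standard
  RNA nearest-neighbor set, with rotational symmetry generated from the
  ten unique stacks;
- a flat −0.5 kcal/mol for any stack involving a G:U wobble;
- +4.09 duplex initiation;
- +0.45 per terminal A:U or G:U end;
- interior loops/bulges: $+3.9 + 0.3(L-1)$ affine penalty.

This is deliberately not a full Turner model (no loop-sequence terms, no
dangles, no special tetraloops): it is monotone in the ways the pipeline
needs (more Watson–Crick stacking never raises the energy; defects never
lower it — both property-tested) and calibrated so that genuine
full-length duplexes clear the −20 kcal/mol gate while short or defective
ones do not. Energies are reported in kcal/mol at 37 °C.

## Target prediction

`predict_targets()` extracts each annotated element ±15 nt of flank
(clipped at transcript bounds), aligns every miRNA, and keeps hits
satisfying **both** gates: score ≥ 160 and energy ≤ −20 kcal/mol.
Reported hit coordinates are transcript coordinates of the aligned
target span. Both thresholds, the flank and the seed window are
parameters of `scoring_params()`.

## Positional preference

`relative_position()` uses the midpoint rule: the midpoint of the
annotation's spliced span divided by the spliced transcript length,
clamped to $[0, 1)$ so a midpoint exactly at the 3' end falls in the last
bin. `bin_elements()` counts annotations in `n_bins` equal bins (default
ten 10% bins). Under uniform placement the per-bin counts are
Binomial($n$, $1/10$); the tests check a 1000-draw profile stays within
4σ per bin, and that a fully 3'-biased generator run puts all mass in
the final bin.

## Ortholog mapping

`map_orthologs()` locally aligns each query against both strands of each
target chromosome (linear gap model: match +1, mismatch −1, gap −2,
implemented via `Biostrings::pairwiseAlignment`; scores verified against
a hand-written Smith–Waterman oracle). For the best hit:

- `identity_pct` = matching columns / alignment columns × 100;
- `alignment_pct` = aligned query bases / query length × 100.

Hits below `identity_min` (default 90%) are dropped. Minus-strand
coordinates are mapped back to the forward frame.

## Network assembly

`build_network()` collapses multiple hits of a miRNA on one transcript
to a single unweighted edge and joins them with externally validated
miRNA–mRNA pairs; an edge present in both carries evidence `"both"`. A
validated pair naming a transcript typed lncRNA is an error (class
conflict), not a silent relabel. `network_stats()` reports typed node
counts, degrees and connected components (via igraph, union-find-checked
in the tests).

## Synthetic data generator: scope and limitations

`generate_bundle()` produces, deterministically per seed: one toy
chromosome (default 60 kb); 10 lncRNA + 5 mRNA multi-exon transcripts on
random strands; 5 random miRNAs (20–23 nt); 20 planted sites, each the
exact reverse complement of a miRNA placed wholly inside one exon; reads
(32 nt) fully covering each site at depth 5–20, assigned multinomially to
four Argonaute libraries; optional uniform background reads, T→C
conversions and a positional-bias parameter β (each site constrained to
the final decile of its transcript with probability β). Read envelopes of
distinct sites are kept disjoint by a read-length margin so each pile
yields its own cluster. Infeasible geometries (e.g. a genome too short
for the transcripts, or β = 1 on transcripts with no exonic space in the
final decile) raise errors rather than silently degrading.

Limitations: the generator plants perfect or seed-only complements, not
graded mismatch spectra; background reads are uniform, not
expression-weighted; T→C conversion models PAR-CLIP chemistry only as a
loss channel for the exact-match mapper (`map_reads_exact()`); and the
toy genome has a single chromosome. It is designed to make every
pipeline stage testable with known ground truth, not to be a realistic
PAR-CLIP simulator.

## Determinism

Every stochastic step (generator, acceptance driver) derives from a
single integer seed; reruns are byte-identical, which the tests assert
file-by-file for both the generator output and the full pipeline output
directory.
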