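---
title: "Detecting phased siRNA (PHAS) loci: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting phased siRNA (PHAS) loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasr)
```

## The biology and the statistical problem

Plant phasiRNAs are secondary siRNAs cut head-to-tail in 21-nt (or
24-nt) increments from a long RNA after a miRNA- or siRNA-guided
cleavage event sets the register. Because DCL4/DCL5 process the
RDR-made double-stranded precursor from the cleavage point outward, the
5' ends of phasiRNAs from one locus fall into a single residue class
modulo the register length — a *phase register* — on the sense strand,
and two nucleotides upstream of it on the antisense strand (the 2-nt 3'
overhang of the siRNA duplex).

Detecting a PHAS locus is therefore a counting problem: among the
unique small-RNA reads mapped inside a window, are implausibly many of
them stacked into one of the 21 (or 24) possible registers?

## The window model

`scan_windows()` slides a window of nine register cycles (189 nt at a
21-nt register) along each reference in steps of three cycles (63 nt),
so consecutive windows overlap by 126 nt. The overlapping placement is
deliberate: disjoint windows separated by gaps would miss loci
straddling window boundaries. Within each window, every alignment gets
a *phase coordinate* — its leftmost 0-based position, plus 2 for
minus-strand reads (`register_position()`) — and for each of the 21
candidate offsets the number of distinct register-length reads in that
register is tallied; the offset maximising it wins, with ties broken
toward the smallest offset so results are deterministic.

A window is a candidate only if it holds at least 10 unique reads, more
than half of them register-length (strictly more: exactly half fails),
and at least 3 unique register-length reads in the maximal register.

## The phasing P-value

For a candidate window with `n` unique register-length reads, of which
`k` sit in the best register, the null model treats the `21m` positions
of an `m`-cycle window as an urn with `m` in-phase positions:

$$p(k) \;=\; \sum_{X=k}^{\min(n,m)}
  \frac{\binom{20m}{\,n-X\,}\binom{m}{X}}{\binom{21m}{n}}$$

i.e. the upper tail of a hypergeometric distribution. `phas_pvalue()`
computes the tail by direct log-binomial (`lchoose`) summation; the
test suite checks it against an exact-rational summation (arbitrary
precision fractions) and against the upper hypergeometric tail to a
relative error of 1e-9 over the full working grid (m in 3..9, n up to
40). A 21-nt window is positive when `p < 0.001`, strictly. Two
defensive clamps are applied before evaluation: `k` is capped at `m`
and `n` at `21m`, because distinct reads on the two strands can in
principle stack beyond the urn's support (never observed at desk
scale).

The upper limit of the tail is `min(n, m)`: terms beyond either bound
have zero probability, so the sum is the same whether one writes the
limit as `m` or as `min(n, m)`.

## The phasing score (24-nt mode)

24-nt windows (span 216 nt, step 72 nt) are called by a log-scale score
rather than the P-value:

$$\mathrm{score} = (\mathrm{occ} - 2)\,
  \ln\!\left(1 + 10\,\frac{\sum P}{1+\sum U}\right)$$

where `occ` is the number of the window's nine cycle positions (of the
chosen phase) holding at least one unique register-length read,
`sum(P)` the total in-phase read count, and `sum(U)` the number of
unique register-length reads out of phase. We use the occupied-register
count in the exponent — the symbol is defined that way where the
formula is introduced in the literature this score descends from, even
though it is sometimes typeset as `k` — and clamp the score to zero
below three occupied registers. The 24-nt cutoff is a score of at least
15. The same window filter applies with "21 nt" read as "register
length".

## Locus assembly and annotation

Positive windows on one reference chain into a locus when their starts
differ by a multiple of the register length *and* by no more than one
window span (adjacency), and their chosen offsets fall in the same
genomic residue class. The merged locus keeps the union extent, minimum
P-value, maximum score, and collects its *member reads*: the
register-length alignments whose phase coordinate lies in the locus and
matches its residue class.

Classification against gene models uses the union of member-read
intervals (the *footprint*), not the window-grid extent, which can
overhang an annotation by up to two window steps purely from grid
placement. A locus footprint entirely inside primary-isoform exons is
`exon`, entirely inside introns `intron`, both `exon_intron`, and a
locus overlapping no gene span `intergenic`. Loci sharing a gene merge
into one gene-level record. For intron-class loci, mean RNA-seq
coverage over the producing intron below 1 read/nt calls a bona fide
(excised) intron and at or above 5 reads/nt a retained intron; the band
between is left `unknown`. The 1/5 thresholds are this package's
choices — the distinction in the source analyses was qualitative ("no"
vs "good" coverage).

## Triggers and targets

The duplex scorer (`align_srna_target()`, Rcpp) enumerates every
registration of the sRNA against the reverse-oriented target with at
most one single-nucleotide bulge on either side, under plant-target
penalties: mismatch 1.0, G:U wobble 0.5, bulge 2.0, all doubled at sRNA
positions 2–13. The predicted cleavage is the target base paired to
sRNA position 10 (slicing between 10 and 11). Cutoffs: 4 for triggers,
3 for targets, 1.5 for the stringent target flag. Note that the
position-weighted score is intentionally orientation-specific — the
5'-seed doubling and the wobble discount do not survive joint
reverse-complementation — so the strand-symmetry property is stated
(and tested) for the structural variant with uniform weights and
wobble treated as mismatch, where it holds exactly.

Trigger search scans 200-nt flanks anchored on the locus *footprint*
(again, the window grid would otherwise bury the cleavage site inside
the called extent) on both sides, restricted to 21/22-nt sRNAs above
10 RPM. A candidate is in phase when its cleavage coordinate falls in
the locus residue class modulo the register. Out-of-phase candidates
survive filtering only as known miRNAs that are whitelisted or
degradome-validated. Two distinct 21-nt hit sites label the locus
`two_hit`; a single 22-nt hit `one_hit_22`; a single 21-nt hit stays
`unclassified`. Degradome validation requires at least 2 degradome 5'
ends within 1 nt of the predicted cleavage. Hairpin plausibility for
putative miRNAs folds ±150 nt of context with the ViennaRNA `RNAfold`
program when it is on the PATH and otherwise reports `no_engine`.

Target prediction scans abundant (>= 10 RPM) phasiRNAs of positive
loci against each spliced transcript **in both orientations**: the
phasing precursor passes through an RDR-synthesised double-stranded
intermediate and phasiRNAs of either polarity are loaded into AGO, so a
sense-strand phasiRNA legitimately matches its own precursor through
the antisense orientation. Without this, half of every locus's
phasiRNAs could never self-target. Relations: `cis` (originating gene),
`same_family` (same entry in the supplied gene-family map), `trans`.

## Differential production

Per locus key (gene id where known, coordinates otherwise), the
register-length abundance of two libraries is compared as
`(rpm_b + 0.1) / (rpm_a + 0.1)` — the 0.1 RPM pseudocount is this
package's zero-handling choice. Status transitions take precedence:
a locus called in A but not B is `lost_PHAS` (B keeps `siRNA_only`
status if residual reads remain, `silent` otherwise), the reverse
`gained_PHAS`; otherwise a ratio beyond 5-fold in either direction is
`induced`/`suppressed`, else `stable`. The construction is exactly
antisymmetric under swapping the libraries.

## What the synthetic generator emulates — and what it does not

`make_library()` builds a seeded 200-kb genome with 26 multi-exon genes
(gene 2 is a structural duplicate of gene 1 copied at ~85% identity,
giving a two-member family), and plants 30 21-nt loci — 10 exonic, 8
intronic, 6 exon–intron junction, 6 intergenic — of 10 duplex cycles
each. Counts decay geometrically (factor 0.8 from a first-cycle count
of 40), strands are balanced, and the trigger (22-nt one-hit or 21-nt
two-hit with the 5' site copied to the locus 3' end) is written into
the genome so that its cleavage site scores 0 and sits exactly in
phase; trigger sRNAs and degradome 5'-end reads at every true cleavage
are added to the library. 10% of locus reads (fidelity 0.9) are
corrupted into degradation products: both their position (±1–10 nt) and
their length (18–26 nt) are jittered. Length jitter matters: real
off-phase degradation is not composed of exact 21-mers, and exact
21-mers falling into single registers by chance would otherwise let a
fully corrupted locus (fidelity 0) still be called occasionally.
Background noise (~30% of unique reads, drawn from random genomic
positions at lengths 18–26) and rRNA-stub contamination (5% of the raw
library) complete the read set. Everything is reproducible
byte-for-byte under a fixed seed.

The generator does **not** model sequencing error, composition bias,
expression-level variation between genes, multi-chromosome assemblies,
or mixed 21/22-nt DCL products. Passing tests on it therefore
demonstrate the correctness of the statistics and the bookkeeping —
register arithmetic, duplex geometry, threshold semantics, merging,
classification — not robustness to the full messiness of real
libraries.

## Numerical and procedural choices

* Internal coordinates are 0-based half-open everywhere; GFF3 and SAM
  are converted at the boundary, and the conversion is tested as a
  bijection.
* Phase-offset ties break to the smallest offset; gene-assignment ties
  break to the smaller gene id; merged loci keep min/max statistics.
* Translation invariance of detection is exact for shifts that are
  multiples of the 63-nt step; for other shifts the grid samples
  different frames, and the guarantee is at detection level (the locus
  is still called, in the shifted residue class).
* Recovery scoring (used by the tests): a planted locus is recovered
  when a called locus of the same register length overlaps at least
  half of it; precision counts called loci matching no truth locus.
* Problem sizes used by the test-suite and the acceptance script — the
  200-kb/30-locus default conditions, an 80-kb two-mode run for the
  21/24-nt separation, and a 100-kb noise-free run for target
  classification — were chosen as the smallest instances on which
  every class and code path is exercised with comfortable read depth.

## Known limitations

Multi-mapped reads contribute their full count at every retained
placement (no fractional weighting), mirroring the upstream convention;
highly repetitive regions can therefore inflate abundance. Loci are
called strand-blind (both strands contribute to one locus), so
overlapping antiparallel transcription units are not separated.
Mismatch-tolerant and spliced alignment are out of scope: reads
crossing splice junctions of expressed precursors will not map, which
slightly disfavours junction loci in transcript-space scans (the
genome-space scan used here is unaffected).
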