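---
title: "Methods: profiling scnRNA and heterochromatin boundaries at IESs"
author: "scnBoundary authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling scnRNA and heterochromatin boundaries at IESs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnBoundary)
```

## The problem

During sexual reproduction of *Tetrahymena*, the developing somatic
macronucleus removes thousands of internal eliminated sequences (IESs) from
its genome. Targeting is RNAi-directed: 26-32 nt small RNAs (scnRNAs)
mark IESs for heterochromatin formation, and heterochromatin in turn drives
the production of more scnRNAs — a positive feedback loop that must be
stalled exactly at IES edges. When boundary-protecting factors are lost,
scnRNA production and heterochromatin spread from IESs into the flanking
MAC-destined sequences (MDSs), and MDS DNA can be ectopically eliminated.

This package quantifies that boundary precision from mapped sequencing
reads. It works on a *segmented genome*: an ordered, gap-free tiling of
each chromosome into MDS, type-A IES and type-B IES segments. Type-A IESs
(and their MDS flanks) template the Early-scnRNAs of early conjugation;
type-B IESs produce scnRNAs only via the feedback loop at late stages, so
26-32 nt reads mapping to type-B IESs identify Late-scnRNAs.

## The measurements

**Length filter and anchors.** scnRNA analyses keep reads of 26-32 nt
(inclusive). Each read is counted at a single base: its 5' end for 100-bp
individual-locus profiles, or its 13th nucleotide for 10-bp boundary
meta-profiles and 50-bp heatmap bins (the 13th nt is the center of a
typical scnRNA and the position engaged by the Argonaute effector). ChIP
fragments, which are unstranded and not length-filtered, are counted at
their midpoints. All coordinates in files and tables are 0-based half-open
(BED convention); anchors are computed in that frame
(`five_prime = start` or `end - 1`; `nt13 = start + 12` or `end - 13`).

**Boundary windows.** Every IES contributes two boundaries. Each boundary
carries a 500-bp window immediately inside the IES and a 500-bp window
immediately outside in the flank, both abutting the edge. Windows are the
unit of the meta-profiles and of the boundary statistic. An IES shorter
than 500 bp cannot fill its inside window; rather than truncating (which
would make ratios incomparable across boundaries) such windows are flagged
ineligible and excluded. The same flag is applied when a chromosome end
truncates the outside window. Outside windows that overlap a neighboring
IES are *kept* but flagged (`overlaps_foreign_ies`), since excluding them
is an analysis choice, not a fact of the data; `excludeForeign = TRUE`
switches the policy.

**Meta-profiles.** Anchor counts from all eligible boundaries of one IES
type are compiled on a common offset axis running from -500 (far outside)
to +500 (far inside). Right boundaries are mirrored
(`offset = boundary - 1 - anchor`) so positive offsets always point into
the IES, and the strand of mirrored reads is flipped so the sense/antisense
panels remain boundary-relative. Counts are summed across boundaries and
then normalized; summing before normalizing (rather than averaging
per-boundary profiles) weights each read equally and is recorded in the
output metadata. Reflecting the whole genome end-for-end leaves
meta-profiles built from the 5'-end or 13th-nt anchor exactly invariant —
the package's test of the mirroring arithmetic. (The fragment-midpoint
anchor can shift by 1 bp under reflection when `start + end` is odd; ChIP
profiles are therefore not bit-exact under this transformation, which has
no bearing on the scnRNA statistics.)

**Normalization.** scnRNA profiles are reads per million (RPM); the
denominator is the number of reads passing the 26-32 nt filter in the
library, recorded in every output so results remain interpretable if a
different convention is preferred. Multi-mapping is not resolved: each
alignment record counts once. ChIP enrichment is the per-bin ratio of
RPM-normalized ChIP counts over RPM-normalized input counts; bins with
zero input are masked (`NA`), never reported as 0 or infinity.

## The broken boundary index

For one boundary, with `MDS` the anchor count in the 500-bp outside window
and `IES` the count in the 500-bp inside window,

$$\mathrm{BBI} \;=\; \frac{\mathrm{MDS}_{sample}/\mathrm{IES}_{sample}}
                          {\mathrm{MDS}_{wt}/\mathrm{IES}_{wt}}$$

the sample's outside/inside ratio normalized by a matched wild-type
control. A BBI of 1 means no disturbance; replicate wild-type libraries
give a distribution centered at 1, and boundary-mutant libraries shift it
upward. Choices the formula itself does not fix:

* **Pseudocount.** 1 is added to all four counts (configurable). Without
  it the statistic is undefined at zero counts; with it the BBI converges
  to the raw ratio-of-ratios as counts grow (relative deviation < 1% by
  counts of 10^3).
* **Eligibility.** Boundaries whose *control inside* count is below 10 raw
  reads are flagged out of summaries and ranking: when the control
  denominator is that small the ratio is dominated by shot noise.
* **Strands** are pooled; the boundary statistic does not separate them.
* **Ranking unit.** Boundaries (the statistic's native unit) are ranked;
  ties are broken by genomic order (chrom, position, side) so ranking is a
  deterministic permutation. A `perIes` mode keeps each IES's max-BBI
  boundary for users who want IES-level lists.
* **Heatmap rows.** The top-N rows are selected once, from a designated
  reference strain's ranking, and the same rows are profiled in every
  strain — the display that makes mutant panels comparable. The reference
  is explicit configuration, never inferred.

## The synthetic-data generator

`simConfig()` / `makeGenome()` / `simulateScnrna()` / `simulateChip()`
produce toy genomes and libraries with the statistical structure the
analysis assumes, so the whole pipeline is exercisable without any
external data. What it emulates:

* **Stage-dependent origin.** `early_3h` draws reads from type-A IES
  bodies and their MDS flanks; `post_selection_6h` then removes MDS-mapped
  reads with probability `selectionEfficiency` (scnRNA selection);
  `late` draws from type-A and type-B IES bodies
  (`lateTypeBFraction` splitting the two).
* **Read placement.** Body reads are transcript fragments of their source
  IES: the whole read interval lies within the segment, so no anchor of an
  undisturbed late-stage read falls in MDS. Flank reads and displaced
  reads are 5'-anchored in the MDS and may straddle the edge, as genuinely
  spreading reads do.
* **Spreading.** At configured boundaries a fraction `f` of
  boundary-proximal reads (within 500 bp) is displaced outside, at a
  distance drawn from a one-sided exponential with mean `lambda`,
  truncated at the adjacent MDS segment so displaced reads never land in a
  neighboring IES. The exponential is a minimal one-parameter kernel — the
  phenomenon's real spatial profile is only known graphically — and it is
  isolated behind `cfg$spread` so alternatives can be added.
* **Lengths and strands.** Read lengths follow a unimodal 26-32 nt
  distribution (default mode at 28-29 nt) with a `contaminantFraction`
  drawn uniformly from 20-25 and 33-40 nt to exercise both filter edges;
  strands are Bernoulli(0.5).
* **ChIP.** Input midpoints are uniform over the genome; ChIP midpoints
  have `chipEnrichment`-fold higher per-base density on IES bodies, with
  fragment lengths uniform on 150-250 bp. The meta-ratio plateau recovers
  the enrichment parameter.
* **Mutant archetypes.** Boundary-confined spreading (short `lambda`,
  subset of boundaries), long-range spreading (large `lambda`), and global
  elevation (`globalScale > 1`) reproduce the qualitative contrasts of
  boundary-factor, demethylase and global-repressor mutants respectively.

Defaults that required a choice: `earlyFlankFraction = 0.3` and
`earlyLambda = 200` bp (early-stage flank transcription is substantial but
boundary-proximal), IES lengths 1-3 kb and MDS spacers 1-3 kb (typical
segment scale for this genome), and a 5% contaminant fraction. These are
statements of the emulated conditions, chosen once, not fitting targets.

What the generator does *not* emulate: nucleotide sequence (only
coordinates, lengths, strands), repeat-induced multi-mapping, ligation and
PCR biases, the kinetics of heterochromatin assembly, or the empirical
shape of mutant spreading profiles. Passing tests therefore demonstrate
the correctness of the measurement machinery on data with known structure,
not that real libraries satisfy the generator's assumptions.

## Numerical and degenerate-input policy

* Half-open bins everywhere: an anchor exactly on a bin edge belongs to
  the following bin; bin count is `ceiling(span / bin_size)`.
* Zero-input ChIP bins are masked `NA` and counted in the manifest.
* Empty libraries construct fine but error at normalization time, naming
  the library.
* Degenerate IESs (shorter than the window) never raise exceptions; they
  produce ineligible windows.
* All simulator randomness flows through one seed
  (`withr::with_seed`, Mersenne-Twister), and reruns of the assembled
  analyses are byte-identical; outputs embed parameters and input
  checksums rather than timestamps.

## Problem sizes used in the checks

The package's own verification runs at desk scale: genomes of 440 IESs
with two replicate libraries of ~5.3 x 10^5 filtered reads for the
replicate-null check of the BBI median; 10^6 fragments per library for
ChIP enrichment recovery at 2/5/10-fold; 200-boundary genomes with
spreading injected at 10% of boundaries for the ranking-recovery check;
and exhaustive enumeration of all count tuples 0-20 for the BBI formula.
These sizes give the quoted tolerances comfortable statistical headroom
while keeping the full suite under a minute.

## Known limitations

* The pipeline consumes already-mapped records (BED6); alignment,
  deduplication and multi-mapper resolution are upstream concerns.
* The RPM denominator convention (filtered, mapped reads) and the
  sum-then-normalize meta-profile convention are recorded choices where
  the field has no single standard.
* Published IES counts for this genome differ slightly between the ChIP
  (3,715 type-A) and small-RNA (3,722 type-A) meta-analyses; the source
  of that 7-IES discrepancy is not documented and is not emulated here —
  eligibility filtering is governed solely by the explicit window rule.
* BBI distributions are summarized, not tested: the package deliberately
  stops short of significance claims about between-strain shifts.
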