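---
title: "Read-depth deletion screening and recessive prioritization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-depth deletion screening and recessive prioritization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelscreen)
```

This vignette is the package's own account of its models, its defaults and
the reasoning behind them, and of what the synthetic cohorts do and do not
demonstrate about real data.

## The read-depth deletion model

A targeted capture panel sequences a set of baited regions (exons plus
flanks) across many barcoded samples pooled on one lane. Per-base depth at
a position is driven by three multiplicative factors: the sample's overall
library size, the target's capture efficiency (a property of the bait, so
shared across samples), and the local copy number. The screen isolates the
third factor:

1. **Windowing.** Targets are tiled from their start with windows of
   `window` bp advancing by `step` bp; the last window of a target is
   truncated at the target end and windows never span targets. Defaults
   `window = 100`, `step = 100` (non-overlapping): window counts are then
   independent and binning conserves total depth exactly, which the tests
   pin; a sliding window is available via `step < size`.
2. **Library-size normalization.** Each sample's window means are rescaled
   so its total equals the cohort median total.
3. **Pooled reference.** The reference depth at each window is the *median*
   of the normalized window means across all samples. A mean or sum would
   let one deletion carrier depress the reference under its own deleted
   exons; the median is unaffected as long as carriers are a minority at
   any window. All samples (the test sample included) are pooled by
   default; `exclude_self = TRUE` is available when leave-one-out
   references are preferred.
4. **Log2 ratio.** `M = log2((count + c)/(reference + c))` with pseudocount
   `c = 0.5` depth units, clamped to [−5, +5]. The pseudocount keeps
   zero-count windows finite; the clamp bounds homozygous-deletion windows
   at −5, still far below every calling threshold. When a sample is
   compared against a reference built from itself the pseudocount cancels
   and `M` is identically zero.
5. **Mean shift.** `M` is centred to mean zero over the whole panel. This
   removes residual library-scale offsets; its cost is that a deletion
   spanning a fraction q of the panel's windows is pulled toward zero by
   q·|signal|. On a many-gene panel q is a few percent and the bias is
   ~0.02 log2 units; on a single-gene track a 9-of-43-exon deletion would
   lose ~20% of its signal, which is why the screen should always be run
   panel-wide.
6. **Exon aggregation.** A window belongs to an exon iff it overlaps it by
   ≥ 1 bp. Per exon the mean and the 25th/75th percentiles of `M` are
   reported; quantiles use linear interpolation between order statistics
   (R type 7), pinned so that exon summaries are bit-stable across
   environments.

### Calling thresholds

Exons are flagged when `mean_M ≤ −0.65` **and** `q75_M ≤ −0.2`; maximal
runs of flagged exons merge into one call (single-exon calls allowed).
Rationale for the defaults, all exposed as arguments:

* `het_M = −0.65` sits between the diploid baseline (0) and the
  heterozygous signal (−1), biased toward specificity: at 100× depth and
  100 bp windows the per-window noise SD is ~0.02–0.05 log2 units, so
  diploid exons essentially never reach −0.65 while het-deleted exons
  (≈ −0.95 after the mean shift) always do.
* the `q75_guard = −0.2` requires three quarters of an exon's windows to be
  depressed, so one noisy window cannot create a call.
* `hom_M = −3` separates homozygous loss (clamped toward −5) from
  heterozygous loss (−1).
* mosaic mode lowers the flag threshold to `mosaic_M = −0.2`, trading
  specificity for sensitivity to diluted deletions; calls with run mean
  above −0.8 are then classed `mosaic` rather than `het`.

### Mosaic fraction

If a fraction f of genomes carry a one-allele loss diluted by normal
diploid cells, expected relative depth is `1 − f/2`, so
`M = log2(1 − f/2)` and the inverse `f = 2(1 − 2^M)` (clamped to [0, 1]) is
reported for het/mosaic calls. f ≈ 1 reads as a constitutional het
deletion; the equimolar two-sample pool (one allele lost in a four-copy
background) has `M = log2(3/4) ≈ −0.415` and f = 0.5. The forward/inverse
identity is exact and property-tested to 1e−9.

### Sex chromosomes and gains

Copy-number expectations are diploid everywhere: a hemizygous X-linked gene
in a male sample would read `M ≈ −1` against a mixed-sex reference without
being a pathogenic deletion. Modelling per-sample expected X copy number is
a known limitation, not implemented. Gains (duplications) are not called;
the symmetric rule (`mean_M` above a positive threshold) would be
straightforward but is out of the screen's validated scope.

## Variant annotation

The annotator is deliberately minimal — enough to drive the funnel, not a
general-purpose engine. Effect classes are assigned in priority order:
indel overlapping the CDS (frameshift when length change mod 3 ≠ 0, else
in-frame); coding SNV (stopgain / nonsynonymous / synonymous via the
standard genetic code, with the variant's ref allele checked against the
transcript CDS — a mismatch is an input error, not a silent guess);
canonical splice (the 2 intronic bases at each junction, the GT/AG
dinucleotides); then intronic/UTR/intergenic by position. Substitutions
that destroy the terminal stop are classed nonsynonymous (the class
enumeration carries no stop-loss member). The implementation classifies
from the affected codon only; the test suite checks it against a
brute-force oracle that rebuilds the whole CDS, translates both alleles
end-to-end with Biostrings and compares proteins, on 1,000 random SNVs over
random transcripts on both strands.

HGVS c. positions number coding bases from the A of ATG; intronic positions
are exon-edge offsets (`c.N+k` from the preceding exon's last base,
`c.M−k` from the following exon's first base, whichever offset is smaller,
ties to `+`), UTR positions `c.−k`/`c.*k`. Every position form has an exact
inverse (`cdna_to_genomic()`), property-tested as a round trip.

Indels are **not** left-normalized on input: normalization requires the
genomic sequence around the indel, and the package models sequence only for
the spliced CDS. Callers should provide left-aligned VCFs (standard caller
output); classification itself depends only on CDS overlap and length, not
on placement within a repeat.

## Pseudogene-shadowed regions

Reads from highly similar pseudogene copies map onto the functional locus
and dilute the apparent allele fraction of true variants there — with one
functional copy among `copy_factor` near-identical copies, a heterozygous
variant is expected near `0.5/copy_factor` rather than 0.5. Declared
regions (5-column BED) therefore flag variants whose fraction falls in
`[af_floor, flag_af_below) = [0.05, 0.35)`: below 0.35 is diluted relative
to a clean heterozygote, above 0.05 is unlikely to be noise at 100×.
Flagged variants bypass the allele-fraction filter. The copy-factor model
is this package's formalization; the quantitative expectation should be
treated as a flag for manual review, not a genotype call.

## The filtering funnel and recessive prioritization

Stage order and defaults: (1) all variants; (2) on panel genes; (3)
nonsynonymous, stopgain, frameshift, in-frame indel or canonical splice
(truncating classes are retained with "NS/SS" because the funnel must never
discard a truncating allele); (4) both database frequencies absent or
≤ 2% (absence counts as novel and passes); (5) disease genes; (6)
pathogenic clue. The allele-fraction filter (31%, or 12% in mosaic mode,
matching the detection thresholds a mosaic-aware run needs) is applied
before the funnel. Counts are non-increasing by construction and
property-tested on 1,000 random variant tables.

A *pathogenic clue* is: frameshift or stopgain (truncating ⇒ pathogenic),
canonical splice, or a missense with damaging verdicts from at least
`predictor_quorum` external predictors. The quorum defaults to 2 of 3 —
demanding a single verdict makes every disputed missense a clue, demanding
all three lets one permissive predictor veto; set `predictor_quorum = 1` to
reproduce the any-evidence reading. Clues are counted per variant (a
homozygous variant is one clue but two alleles).

Per disease gene the findings logic is: homozygous clue (allele fraction
≥ 0.7, the midpoint between het 0.5 and hom 1.0 under depth noise) ⇒
biallelic; two het clues ⇒ biallelic compound (phase unknown — segregation
is follow-up work, out of scope); one het clue + any deletion call in the
gene ⇒ biallelic; homozygous-class deletion alone ⇒ biallelic; a single
het clue **or a heterozygous deletion alone** ⇒ `one_allele` with the
escalation flag. Escalation lists the gene's intronic/UTR variants absent
from both frequency databases — the hiding place of deep-intronic second
alleles — rather than auto-promoting them, because intronic pathogenicity
needs functional follow-up.

## What the simulator emulates — and what it does not

`cohort_spec()` pins the study conditions: 11 samples (one pooled lane of
barcoded libraries), Poisson per-base depth with mean 100 (the typical
median depth of such a run), a 15-gene panel whose first two genes have 43
and 38 exons (the shapes of the largest FA genes, where multi-exon and
last-exon deletions occur), exons 90–240 bp, introns 250–600 bp, targets =
exons ± 50 bp flanks, and lognormal per-target capture efficiency with
sigma 0.3 *shared across samples* — the bait-driven bias whose cancellation
by a pooled reference is the reason the method works. Deletions are planted
across whole exon-target spans (breakpoints beyond the flanks); mixtures
round the weighted depth sum and re-derive allele fractions from weighted
allele depths. Background variation is a panel-wide pool of 600 alleles
with population frequencies (80% common at 3–50%, 20% rare below 2%, a
subset mirrored in-house), carried by each sample under Hardy–Weinberg —
roughly 200–300 called variants per sample, a desk-scale analogue of the
thousands seen on a full capture design. All randomness derives from the
spec seed through fixed per-stream offsets, so identical specs are
byte-identical.

Deliberately absent, and therefore untested by passing suites: GC and
mappability artifacts, overdispersed (non-Poisson) depth, read-level errors
and mapping ambiguity, pseudogene *sequence* (regions are declared, not
sequence-derived), intron-wide enrichment beyond the 50 bp flanks, and
population structure. Recovery rates measured on these cohorts are
best-case; real panels add systematic noise that the median reference and
the q75 guard mitigate but do not remove.

## Numerical and testing choices

Degenerate inputs have pinned behaviour: empty BED/depth files are legal
(empty or all-zero semantics), an all-zero sample is a library-size error
naming the sample, an empty ratio track cannot be normalized, a gain-side
ratio is rejected by the mosaic-fraction estimator, and summaries from
mixed genes are rejected by the caller. Exon summaries on windowless exons
report `n_windows = 0` with `NA` statistics and never flag.

The test suite simulates at the study conditions (depth 100, window =
step = 100, the 15-gene panel) with 50 seeds for the deletion-recovery and
end-to-end prioritization properties and 20 random transcripts × 1,000
SNVs for the annotation oracle; these sizes give binomial noise well below
the asserted 95% recovery thresholds while keeping the suite fast. The
acceptance script averages the pooled-sample mosaic signal over 20 seeds.
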