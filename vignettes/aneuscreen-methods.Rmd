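---
title: "Methods: coverage-based aneuploidy detection and causal-interval mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-based aneuploidy detection and causal-interval mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneuscreen)
```

aneuscreen analyses screens for conditionally beneficial mutations in
haploid yeast, where the events of interest range from single-base changes
to duplication of an entire chromosome. This vignette is the package's own
account of its models and the choices behind them.

## The mutation caller and reference refinement

Mutations are called from per-site pileups by a read-fraction rule: a site
is called when its depth reaches `min_depth` and a *single* non-reference
allele (a base, an insertion or a deletion) accounts for at least
`min_fraction` of the reads. The boundary is inclusive — 9 alternate reads
out of 10 is exactly 0.90 and is called. In a haploid genome a true mutation
should be carried by essentially all reads, so the 90% default separates
real variants from sequencing error without base-quality modelling; a
variant present on one copy of a disomic chromosome sits near 50% and is
deliberately not called.

`min_depth` (default 10) is our addition: a fraction threshold alone would
let a single read constitute a "100%" call. It is configurable via
`caller_params()`. Multi-allelic sites are evaluated per allele — at most
one allele can reach 90% — and a tie of two alternates below threshold
yields no call.

Progenitor strains differ from the community reference by standing genetic
variation, which would otherwise masquerade as mutations in every mutant
derived from that progenitor. `refine_reference()` therefore alternates
calling differences and integrating them into the genome
(`integrate_variants()`), conceptually remapping the progenitor's reads to
the updated genome each cycle, for up to 10 cycles. Convergence is defined
as a cycle that finds zero new variants (the cycle cap alone does not pin
down a stopping rule, so we chose the natural fixed-point definition).
Indels are applied right-to-left so earlier coordinates remain valid, and a
coordinate map records shifts (deleted positions map to `NA`). The
fixed-point property — refining the refined genome finds nothing — is
tested, as is the exact 10-cycle stop under an adversarial pileup provider.

Coding effects are classified by translating the affected codon on the
feature's strand with the standard genetic code; features whose length is
not a codon multiple are a hard error rather than a silent misread.
Cross-mutant deduplication keys on `(chrom, pos, ref, alt)`.

## Coverage scaling and ploidy classification

Coverage is averaged in `window_bp` windows (default 1,000 bp, chosen so
the smallest toy chromosome still has tens of windows) and scaled to the
genome-wide per-site mean, so euploid regions sit at 1 and the
length-weighted mean of scaled values is exactly 1 — an identity the tests
check to machine precision.

Classification uses a separate euploid baseline *b*: the **median of
per-chromosome median scaled values**, not the genome mean. A disomic
chromosome that is a large fraction of the genome inflates the mean and
drags all scaled values down; the median-of-medians is immune so long as
most chromosomes are euploid (the tests verify <1% baseline error with 3 of
16 chromosomes disomic). This robustness degrades by construction when half
the chromosomes — or half of one of only two chromosomes — are duplicated;
the package targets karyotypes with many mostly-euploid chromosomes.
Display scaling (the coverage plot) keeps the genome-mean convention.

Per-window copy number is `round(scaled / b)` clipped to `[1, cn_max]`;
values within ±0.15 of a half-integer are counted as low-confidence in the
call. A chromosome is a whole duplication when ≥ `whole_chrom_fraction`
(default 0.95) of windows share a modal copy number above 1. Otherwise a
single-changepoint scan fits a two-level piecewise-constant model by least
squares over all splits leaving at least `min_segment_windows` (default 10)
windows per side; ties take the leftmost split for determinism, and the
scan is tested against an exhaustive brute-force oracle on short noisy
tracks. A segmental call requires the two segments to round to different
copy numbers; the breakpoint is reported at the left edge of the right
segment. One changepoint per chromosome suffices for terminal arm
duplications, the event class this screen observed; multi-breakpoint
segmentation is out of scope, as are mosaic (sub-integer) copy numbers and
GC/mappability correction.

A cohort summary counts a mutant as disomic for a focal chromosome arm when
its call reaches copy number ≥ 2 and covers the arm — any whole-chromosome
call, or a segmental call whose duplicated span contains the arm.
Percentages are rounded to integers.

## PCD construct design and interval inference

A PCD construct is three segments in order: a homology arm ending at the
insertion position (default 450 bp, the midpoint of the conventional
300–600 bp range), a selection cassette, and a telomere seed of six
`CCCCAA` repeats. Primers are emitted 5'→3' with 30-base overlap-fusion
tails; tests verify that trimming tails and concatenating reconstructs each
source sequence. The packaged cassette is a deterministic *synthetic*
stand-in (`inst/extdata/kanmx_synthetic.fa`); any real cassette FASTA can
be substituted.

Truncation at position *p* deletes everything distal to *p*, so phenotype
reversion implies the causal element lies at or beyond *p*. Panels are
planned at roughly even spacing (default 50 kb) including both region ends;
inference returns the half-open interval
`[max reverting position, min retaining position)` — half-open because the
retaining truncation's own position was deleted without effect. A
non-monotone pattern names the conflicting strains instead of guessing; a
panel with no retaining position returns a right-censored interval. The
containment property (the interval always contains a hidden causal
coordinate under monotone phenotypes) is tested over 1,000 random panels.

## The phenotype and qPCR arithmetic

The MIC is the literal lowest no-growth dose; growth at every tested dose
yields a censored `> max` result, and growth above a no-growth dose is
reported with a warning rather than smoothed away. The screen filter keeps
a candidate when its MIC exceeds the progenitor's by at least 1 mM
(initial) or 0.5 mM (confirmation), inclusive; censored candidates are kept
and flagged. "Grew on doses at least X higher" is operationalized as a MIC
difference ≥ X.

qPCR copy number uses the ΔΔCq model with a fixed efficiency of 2
(configurable): `dCq = mean(target Cq) − mean(reference Cq)` per sample and
relative quantity `efficiency^−(dCq_sample − dCq_calibrator)`. The
estimator is unbiased in log space, which the tests confirm by simulation.
Replicate summaries average technical replicates within each biological
replicate first and form a 95% t interval over biological replicates; a
single biological replicate returns its mean with the CI flagged undefined.

## What the simulator emulates — and what it does not

The synthetic-data module generates genomes by i.i.d. base draws at a
target GC fraction, plants SNVs, small indels (≤ 50 bp), disomies and
segmental duplications, and emits dense pileups in which expected depth is
`mean_depth × copy_number` — exactly under `noise = "none"`, Poisson
otherwise — with base errors substituted uniformly over the three
alternatives. Strain-vs-reference differences in the pileup are recovered
by a greedy anchored diff that is exact for sparse events (planted events
are kept ≥ ~100 bp apart); copy-number intervals are interpreted in
reference coordinates, so fixtures never combine indels and duplications on
the same chromosome.

Deliberately not modelled: individual reads, base qualities, mapping
artifacts, duplicate reads, GC bias, repetitive sequence, or
mitochondrial/2-micron molecules. Passing tests therefore demonstrate the
*arithmetic* of calling, scaling, changepoint detection and filtering —
not robustness to alignment pathology in real short-read data, which is
the province of the upstream aligner and the `read_mpileup()` adapter
contract.

Default problem sizes are miniatures chosen so a full
simulate → refine → call → ploidy → summarize run finishes in seconds: the
default karyotype is a sixteen-chromosome, ~1.2 Mb (1/10-scale) genome, and
the packaged cohort fixture uses four chromosomes (~283 kb) with ten
mutants. The packaged fixtures are pinned at seed 42 and plant the screen's
published composition — 39 unique point mutations in a 22/8/9
nonsynonymous/synonymous/intergenic split, three of them shared between two
mutants to exercise deduplication, and a 14 + 9 + 14 per-cross pass
structure for the confirmation filter. These compositions are study
conditions, not tuning knobs.

## Known limitations

- The greedy diff underlying pileup simulation requires planted events to
  be separated by more than its anchor length; it is a fixture mechanism,
  not a general aligner.
- The baseline estimator assumes most chromosomes are euploid; karyotypes
  with pervasive aneuploidy need an external baseline.
- Segmental detection fits one changepoint; nested or interstitial
  multi-segment events are reported as the best single step.
- Interval inference assumes a monotone truncation phenotype; epistasis or
  mislabelled strains surface as a structured error, not a repair.
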