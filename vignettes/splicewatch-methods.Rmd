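---
title: "Quantifying intron retention and cryptic splicing with splicewatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intron retention and cryptic splicing with splicewatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicewatch)
```

## The problem

In several repeat-expansion disorders, a gene is transcribed but its
message is mis-processed. The motivating case is the *FMR1* locus in
fragile X syndrome: cells carrying an expanded CGG tract can still
produce *FMR1* RNA, yet much of it retains intron 1 or splices from the
exon 1 donor to a cryptic acceptor inside intron 1, creating a
pseudo-exon and a truncated, non-functional message. The analytical
question is narrow and quantitative: *of the reads that inform on the
exon 1–exon 2 splicing event, what fraction supports intron retention,
and does that fraction differ between groups of samples?*

splicewatch answers this for one configured two-exon event at a time. It
is deliberately not a genome-wide intron-retention scanner: everything
is anchored to a single locus configuration, which keeps the counting
rules explicit and auditable.

## Read categories

Alignment records overlapping the analysis region (exon 1 through exon 2,
padded by the junction window) are assigned exactly one category by the
first matching rule:

1. **canonical_junction** — some CIGAR `N` skip matches the intron. In
   the default *windowed* mode both skip boundaries must fall within
   `window_bp` bases of the annotated donor and acceptor; in *exact*
   mode the skip must coincide with the intron. At least
   `min_overhang_bp` aligned bases are required on each side of the
   skip.
2. **cryptic_junction** — some skip starts within the donor window but
   ends strictly inside the intron, short of the acceptor window: the
   exon 1 → pseudo-exon signature. The same overhang rule applies.
3. **intron_contained** — no `N` operation, and every aligned block lies
   fully inside the intron. A deletion (`D`) does not break a block; a
   spliced read can never be "fully contained".
4. **unclassified** — everything else: reads straddling an exon–intron
   boundary without a skip, exon-only reads, reads whose skips match no
   rule.

Rule order matters: junction evidence outranks containment, and
mutually exclusive, exhaustive assignment makes the category counts sum
to the total by construction. Classification is a pure function of
(record, locus, configuration); no randomness, no state.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window_bp` | 50 bases | tolerance around each splice site for skip boundaries |
| `junction_match` | `windowed` | windowed vs exact skip matching |
| `min_overhang_bp` | 1 base | aligned bases required on each side of a junction skip |
| `min_mapping_quality` | 0 | MAPQ threshold (no filter by default) |
| `include_duplicates` | `TRUE` | duplicate records are counted |
| `count_mode` | `per_record` | each mate counted independently |

The windowed default reflects how junction reads are extracted in
practice — a window around the splice sites absorbs minor alignment
jitter — while exact mode is available for strict reproduction. A
window configured against a donor offset smaller than `window_bp` would
make canonical and cryptic calls collide; the cryptic rule therefore
requires the acceptor to land *beyond* the acceptor window, so the two
junction categories are disjoint for any window.

On filtering, the defaults are permissive (no MAPQ cut, duplicates
kept, secondary/supplementary dropped) — the counting emulates a plain
samtools-style extraction. `per_fragment` mode collapses a read pair to
one count, resolving mate disagreement as unclassified; it exists for
sensitivity analysis, since whether mates should be counted separately
is a genuine judgement call. We default to `per_record` because
record-level extraction is what coordinate-sorted BAM tooling
naturally produces.

## PSI and splicing efficiency

With `junction` = canonical-junction count and `intron` =
intron-contained count,

$$\mathrm{PSI} = \frac{\text{intron}}{\text{junction} + \text{intron}},
\qquad
\text{efficiency} = \frac{\text{junction}}{\text{junction} + \text{intron}}
= 1 - \mathrm{PSI}.$$

Two deliberate choices:

* **Cryptic-junction reads are excluded from both terms.** The PSI
  formula names only junction and intron reads; cryptic reads support a
  *different* aberrant product and are reported as their own category
  and in the junction table. Folding them into either term would change
  PSI by an amount that depends on the pseudo-exon's position, which is
  exactly the kind of silent convention this package avoids.
* **An empty denominator yields `NA`, never 0.** A transcriptionally
  silenced locus produces no informative reads; reporting PSI = 0 there
  would be indistinguishable from perfect splicing. `NA` propagates
  through summaries (undefined replicates are excluded and counted) and
  renders affected group comparisons "not testable" without failing the
  run.

The PSI confidence interval is Clopper–Pearson (exact binomial) at a
configurable level, default 95%, computed from the beta-quantile form.

## Group comparisons

Pairwise differences are tested with a two-sided Fisher exact test on
the 2×2 table of pooled junction/intron counts. Two conventions are
documented because exact-test variants differ:

* **Pooling.** Counts are summed across replicates within a group
  before testing. A count-based exact test is only defined for one
  table per pair; per-replicate PSI mean ± SD (n−1 denominator) is
  reported alongside so between-replicate spread stays visible.
  Pooling makes p-values sharp at sequencing depth — they reflect read
  counts, not biological replication — which is why the replicate
  summary should always accompany them.
* **Two-sidedness.** The point-probability rule: conditional on the
  margins, sum the hypergeometric probabilities of all tables no more
  probable than the observed one. The comparison uses a relative
  tolerance of 1 + 1e−7 to absorb floating-point ties between equally
  probable tables, matching standard implementations. The hypergeometric
  mass itself comes from `stats::dhyper`; the test suite verifies
  agreement with exhaustive enumeration over *every* 2×2 table with
  grand total ≤ 100 to < 1e−12 absolute.

The reported odds ratio is the sample odds ratio (ad)/(bc) — `Inf` when
only the off-diagonal is empty, `NA` for 0/0 — not the conditional MLE
that some implementations return; it is the quantity readers compute
from the printed table. No multiple-testing adjustment is applied by
default (pairwise tests over a handful of groups are conventionally
reported raw); Bonferroni and Benjamini–Hochberg are available by flag.

## Coordinates

Configs are written 1-based inclusive, the convention of SAM, GFF and
genome browsers, so printed coordinates (commas allowed) paste directly
into a config file. All internal arithmetic is 0-based half-open, which
makes interval overlap and skip comparison free of ±1 bookkeeping: the
donor site is the first intronic base, the acceptor site one past the
last, and a canonical skip is exactly `[donor, acceptor)`. The
conversion is lossless (a property test round-trips random configs),
and chromosome dialects (`chrX` vs `X`) are matched after stripping the
optional prefix unless strict mode is set.

One configuration subtlety deserves a note: descriptions of this kind
of extraction sometimes attach a junction-window width and an intron
interval to the same sentence, and the two are easy to conflate. In
splicewatch they are distinct keys — `intron1` is the retained
interval; `window_bp` is the tolerance around each splice site — and
the contiguity invariants (`exon1` end + 1 = `intron1` start, etc.) are
validated on load so a misread configuration fails loudly.

## The simulator and its oracle

`simulate_reads()` draws error-free reads from a three-isoform mixture
over a relocatable toy locus (defaults: 500/2000/500 base
exon1/intron/exon2, pseudo-exon at donor offsets [100, 400)):

* canonical — exon 1 spliced to exon 2, reads crossing the junction
  gain an `N` of the full intron length;
* mis-spliced — exon 1 joined to the pseudo-exon, junction-crossing
  reads gain an `N` equal to the pseudo-exon's donor offset;
* retained — unspliced pre-mRNA, pure `M` alignments.

Isoform choice is (1−f−r, f, r); start positions are uniform over the
mature transcript; paired-end mates come from one fragment whose length
is drawn from the normal density discretized and truncated to
[read length, transcript length], with the mate placed at the fragment
end. Defaults (150-base paired reads, 20,000 fragments, fragment length
300 ± 50) emulate a standard poly(A) short-read library scaled to desk
size; tests use 10,000 fragments, a size chosen so binomial recovery
bounds are tight while a full seed sweep stays fast.

`expected_psi()` is the analytic companion: it enumerates **every**
(isoform, start) template, classifies each with the *production*
classifier, and integrates the category indicators over the exact start
and fragment-length distributions the simulator samples from (the
per-mate start sums are cumulative-sum identities, so the enumeration
is exact, not Monte Carlo). Because the simulator also records an
independent geometric truth label per read, two different checks fall
out:

* truth-label agreement — the classifier must reproduce the simulator's
  labels exactly on error-free reads;
* parameter recovery — pooled PSI over a simulated sample must fall
  within 3 binomial standard errors of the enumerated expectation
  (checked over seeds 1–20 for f ∈ {0, 0.1, 0.5, 0.9} × r ∈ {0, 0.2},
  with r reduced to 0.1 at f = 0.9 to keep the mixture proper).

What the simulator does **not** model — and therefore what passing
tests do not establish about real data: sequencing errors, soft
clipping and alignment ambiguity near splice sites, non-uniform
coverage (positional bias, GC bias), strand assignment, multi-mapping,
expression-level mixtures beyond the three isoforms, and any isoform
other than the configured event. The classifier's window and overhang
parameters exist precisely because real alignments are noisier than
simulated ones; their effect on real data must be judged there.

A `soft_clip`-style decoration hook was considered and deliberately
left out: clipped bases consume no reference, so they cannot change any
counting decision, and the raster-oracle tests already cover clipped
CIGARs.

## Tracks

Coverage counts base-aligned operations only (`M`, `=`, `X`): skips,
deletions and clips contribute nothing. Deletion bases are a judgement
call — they consume reference but carry no read base — and excluding
them keeps "depth" equal to "read bases stacked here", the quantity a
browser user expects; the choice is documented so outputs are exactly
reproducible. Pair scaling divides both tracks of a user-declared pair
by the single pair-wide maximum (so the deeper track peaks at 1.0), and
an all-zero pair is returned unscaled and flagged rather than divided
by zero. bedGraph output is run-length merged, 0-based half-open,
zero runs omitted.

The junction table aggregates every `N`-derived skip into (donor,
acceptor, count) rows labelled canonical/cryptic/other by the same
windows as the classifier; the per-read overhang requirement is not
applied to the aggregate, since a junction's support is the set of all
skips at those coordinates.

## Numerical and engineering choices

* Classification, simulation and enumeration are fully vectorized over
  records; a 10,000-fragment sample simulates and classifies in well
  under a second.
* Tie order after coordinate sorting is made deterministic
  (position, then query name, then flag) so repeated runs produce
  byte-identical text outputs regardless of upstream sort stability.
  The run manifest carries a timestamp and is the one file excluded
  from the byte-identity guarantee.
* All simulator randomness flows from a single seed with a documented
  stream order, and the caller's RNG state is restored afterwards.
* SAM parsing, region queries, CIGAR range arithmetic, FASTA and
  bedGraph I/O are delegated to Rsamtools / GenomicAlignments /
  Biostrings / rtracklayer; SAM *writing* for simulated records is done
  directly (a simulator knows its own fields), and its output is
  round-tripped through the standard readers in the tests.
* Degenerate inputs have defined behaviour throughout: header-only
  files give zero counts and `NA` PSI with a clean exit; an all-zero
  contingency table is an error; a malformed CIGAR reports the parse
  offset.

## Known limitations

Single-locus scope; no EM-style isoform abundance estimation; no
beta-binomial or GLM modelling of replicate overdispersion (pooled
Fisher tests are depth-driven); no CRAM input; strandedness is recorded
but not used in counting by default. These are boundaries, not
oversights — each is the point where a different tool (or a different
model) should take over.
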