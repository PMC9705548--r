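---
title: "Methods: pre-tRNA architecture and tRNA-seq 3'-end classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre-tRNA architecture and tRNA-seq 3'-end classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pretrna)
```

## The biology in brief

RNA polymerase III transcribes pre-tRNAs that carry a 5'-leader, a
3'-trailer ending in the uridylate stretch encoded by the poly-T
terminator, and sometimes an intron. La-family proteins bind the nascent
UUU-3'OH end, protect it from exonucleases, and chaperone processing:
RNase P removes the leader (cleaving at the -1/+1 position), RNase Z the
trailer, and the CCA end is added post-transcriptionally onto the
discriminator base N73 — the 3'-most nucleotide of the mature tRNA body.
Two genomic signals therefore summarise a species' pre-tRNA processing
landscape: how far the terminator sits from N73 (the trailer length), and
what base sits at N-1, the last leader position, which can pair with N73
and thereby inhibit RNase P cleavage. In sequencing data the complementary
signal is the 3' end of each read: reads ending in CCA are mature tRNAs,
reads ending in a run of Ts are uridylate-tailed precursors.

`pretrna` implements both sides — the genomic architecture scan and the
read-level 3'-end classification — plus a reference-row conservation
annotator for protein alignments and a seeded generator that produces
genomes and read sets with exported ground truth.

## Gene catalog

Internally every coordinate is 0-based half-open. BED12 is consumed
natively (introns are the gaps between blocks); GtRNAdb-style tab files
use 1-based inclusive coordinates and are converted on ingest. A single
internal convention with documented converters avoids the classic
off-by-one family of bugs. Minus-strand genes are reverse-complemented so
that every stored sequence reads 5'&rarr;3' along the transcript: the last
base of `mature_sequence` is N73, the last base of `upstream_flank` is
N-1, and `downstream_flank` starts immediately 3' of N73.

Default flank windows are `L_up = 20` and `L_down = 60` nt. The downstream
window must contain the trailer (capped at 20 nt in all statistics) plus a
terminator run, with margin; the upstream window comfortably covers the
logo window below. Genes whose flanks are truncated at a contig edge are
kept but flagged `short_flank`. Genes with an undetermined anticodon
(`NNN`) or isotype (`Und`) stay in the catalog but are excluded from
architecture statistics by default; `summarize_species()` reports both the
total and the determined count so either denominator is available.

## Trailer scanning and architecture statistics

`scan_terminator()` reports the smallest offset `d >= 0` at which `k`
consecutive Ts begin (default `k = 4`; 5-7 for sensitivity analyses). Runs
longer than `k` count from their start; a run may not span an ambiguous
`N`. Trailers longer than 20 nt are excluded from the summary statistics,
and genes with no terminator inside the downstream window are counted
separately rather than silently dropped. Standard deviations are sample
(n-1) throughout. The histogram mode breaks ties toward the smaller
length so that reporting is deterministic.

Cross-species comparisons use the classic one-way fixed-effects ANOVA
(`F = MS_between / MS_within`) with Tukey HSD post-hoc comparisons from
the studentized-range distribution. These are ordinary linear-model fits
and are delegated to `stats::lm`/`aov`/`TukeyHSD`; the test suite
cross-checks them against hand-computed sums of squares and direct
`ptukey` evaluation. `anova_from_summary()` reconstructs the same F from
per-group (n, mean, SD) summaries — useful when only a published summary
table is available, with the caveat that rounding of the printed summaries
propagates into F (a reconstruction from 1-decimal summaries of a
2,600-gene data set can move F by several percent, as the acceptance
script's reconstruction shows).

Leader composition is summarised as a position frequency matrix over
`N-W..N-1` (default `W = 10`; the window is configurable because leader
annotations rarely state boundaries). The matrix can be conditioned on the
discriminator base, and the conditioned counts always partition the
unconditioned ones. All logo and pairing analyses work in the DNA alphabet
(T, not U), matching genomic coordinates. `pairing_avoidance()` quantifies
leader/trailer pairing pressure: for each N73 base `b` it compares the
observed frequency of a Watson-Crick complementary N-1 with the frequency
expected under independence (the marginal N-1 frequency of
`complement(b)`).

## Read fishing and 3'-end binning

Baits are the `B`-nt 3' suffixes of spliced mature sequences (default
`B = 36`, the length of the canonical Gln-TTG example bait), taken after
collapsing identical-sequence isodecoders. Uniqueness across isoacceptors
is a hard requirement — a collision aborts with the colliding pair named,
because silently mis-assigning reads between isoacceptors would corrupt
every downstream count. Distinct isodecoder sequences within one
isoacceptor get separate bait entries whose counts are aggregated per
isoacceptor.

Fishing is exact substring matching, mirroring the zero-mismatch matching
philosophy of the upstream alignment step this pipeline accompanies. Reads
matching two or more baits are discarded as ambiguous (and counted for
audit) rather than multi-counted. The rightmost bait occurrence anchors
tail classification, guarding against bait-like sequence earlier in a long
read; the suffix after the bait is `CCA` (mature), `T^n` (bin `Un`, capped
at `U10` — longer tails are binned into `U10` rather than dropped, since
the bin scheme enumerates only ten), or anything else (`UNCLASSIFIED`,
including an empty suffix).

CPM divides each count by the total number of fished reads in the
replicate over 1e6, so classified plus unclassified CPM sums to exactly
1e6 per replicate. A per-bin denominator (each 3'-end bin normalised to
1e6 across isoacceptors) is available behind the `denominator = "bin"`
flag for comparison, since either reading of "per bin for each replicate"
is defensible; the per-replicate reading is the default because it keeps
bins comparable within a library.

Enrichment sums the premature bins U1..U10 before the IP/input ratio, and
reports `log2(fold + 1)`. The alternative reading `log2(fold) + 1` is
rejected because it is undefined at fold 0, which occurs in real tables. A
pseudocount (default 0.01 CPM) is added to numerator and denominator so
ratios stay defined at zero input; with several replicates the arithmetic
mean CPM per side is taken first. Cumulative tail tables use the
&ge;-length convention (all tails at least L long), which is monotone
non-increasing in L; the ==-length convention is available. Tail presence
uses a strict `CPM > log10(2)` (&asymp; 0.30103) threshold, so a CPM of
exactly 0.30 scores absent. The presence comparison between conditions is
a two-way ANOVA (condition x tail length) on per-replicate counts of
present isoacceptors, with type-II sums of squares for unbalanced
replicate structure and Bonferroni-corrected per-length Welch t-tests.

## Conservation annotation

Residues are conserved substitutions when they fall in the same of five
side-chain groups: {D, E, N, Q}, {K, R, H}, {F, W, Y}, {V, I, L, M},
{S, T}. Glycine, alanine, cysteine and proline belong to no group, so for
example G/A is *not* conserved despite both being small. Annotation is
per-cell against a chosen reference row (not column consensus), which
matches the "relative to a reference sequence" reading of three-tone
alignment figures; a column-majority mode was considered and rejected as
the default because it changes meaning when taxa are added. Gaps never
count as identical or conserved, and columns where the reference itself is
gapped are flagged unalignable.

## The synthetic generator: what it emulates, and what not

`species_profile()` defaults describe a Tetrahymena-like complement:
geometric trailer lengths with `p = 0.4` (mean 1.5 nt, so the modal
trailer is 0), a terminator run of 6 Ts, N-1 marginal composition with
~75% adenine, discriminator composition A 0.50 / G 0.25 / C 0.15 / T 0.10,
and pairing avoidance `alpha = 0.9`: the N-1 probability of the
Watson-Crick complement of N73 is multiplied by `1 - alpha` and the
distribution renormalised. Mature lengths are a rounded normal
(mean 74, SD 3.4) clipped to 66-82 nt; 10% of genes carry one intron
(10-30 nt) inserted after transcript position 37, the canonical intron
location.

Deliberate idealisations, which bound what passing tests show about real
data:

* Trailer bases are drawn from {A, C, G}, so the drawn trailer length is
  *exactly* the first k-T offset. Real trailers contain Ts and can
  terminate earlier than annotated; the scanner itself is oracle-tested on
  unconstrained random sequence separately.
* Each isoacceptor family shares one mature sequence (pure isodecoder
  copies), so bait collapse is exact. Real isodecoders differ.
* Discriminators are drawn per isoacceptor family, so the effective sample
  size for discriminator composition is the number of families (default
  40), not the number of genes; family-level frequencies wobble
  accordingly in small simulations.
* No sequencing error by default (`error_rate = 0`), matching an
  exact-match pipeline; the knob exists to demonstrate degradation.

`read_sim_config()` defaults: input libraries are 80% mature / 20%
premature at 1e5 reads per replicate, wild-type tails decay as
`0.55^n` over U1..U10 and knockout tails as `0.85^n` (a shift toward
longer tails), and `ip_enrichment_factor = 3`. The factor is defined as
the *realized* premature CPM fold: IP replicates draw premature reads with
probability `factor x (1 - mature_fraction)`, so the expected premature
log2(fold + 1) is exactly `log2(4) = 2`. The naive alternative —
multiplying the premature sampling weight by the factor and renormalising
— realises a smaller fold than the nominal factor and was rejected.
Expression weights default to gene copy number (shared by every replicate
and library of an experiment, since expression is a property of the
strain, not the replicate); `draw_expression_weights()` adds log-normal
noise. Recovery experiments that bound *per-isoacceptor* error use uniform
weights so every isoacceptor carries comparable depth — with copy-skewed
weights the binomial error of a rare isoacceptor dominates any pipeline
error.

## Numerical and reporting choices

* Terminator scan: only the run start matters; empty flanks report
  not-found plus a `short_flank` flag rather than erroring.
* ANOVA degenerates (zero within-group variance everywhere) raise a
  classed invariant error instead of returning an unstable F.
* The presence threshold is compared strictly (`>`), and the mode
  tie-break, CPM denominators and cumulative convention are all
  deterministic, so re-running any subcommand on identical inputs
  produces byte-identical outputs; run manifests record parameters and
  MD5 checksums but no timestamps for the same reason.
* Catalog TSVs round-trip bit-exactly; every simulated artifact embeds its
  seed and a profile hash in a header comment.

Test problem sizes were chosen to keep the whole suite fast while leaving
comfortable statistical margins: 1e4 random flanks x 5 run lengths for the
scanner oracle, a 500-gene species for architecture recovery (3-standard-
error bands), and 2 input + 2 IP replicates of 1e5 reads for enrichment
recovery (observed per-isoacceptor error &approx; 0.04 on the log2 scale
against a 0.1 band).

## Known limitations

* Published per-species gene sets are not bundled; cross-species results
  on real genomes require the user to supply genome + annotation files
  (the `architecture` subcommand then reproduces the full analysis).
* The fisher is exact-match by design: reads with modifications-induced
  misincorporations inside the bait region are not recovered, matching
  the stringency (and the blind spots) of a zero-mismatch pipeline.
* No genome alignment, embedded-gene correction, differential expression
  or TPM quantification: those belong to the established upstream tools
  this package is designed to sit beside, not replace.
* De novo tRNA gene finding, CCA-addition modelling, modification calling,
  RNase P cleavage-site prediction and thermodynamic folding are out of
  scope.
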