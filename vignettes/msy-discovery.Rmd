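---
title: "Discovering and dating a male-specific Y region: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and dating a male-specific Y region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(msyscan)
```

`msyscan` asks a sharp question of a species with no known sex chromosomes:
do its males carry a small, old, male-specific Y region (MSY)? The package
combines four independent lines of evidence — male-restricted transcripts,
a half-coverage genomic segment, diverged XY gametolog pairs, and enrichment
of Y-linked markers — and dates the region with a synonymous molecular
clock. This vignette explains the models behind each stage, the parameters
that matter, what the synthetic-data generator does and does not emulate,
and the numerical choices a maintainer should know about.

## The biological model

In a male-heterogametic (XY) system the MSY is hemizygous: males carry one
copy, females none, while the X-linked counterpart is present twice in
females and once in males. Three measurable consequences drive the
pipeline:

1. Y-restricted transcripts exist in males only, and their genomic depth is
   half the diploid background in males and zero in females.
2. Read depth along the X-linked region shows a male:female ratio near 0.5.
3. X and Y gene copies (gametologs) stopped recombining when the MSY arose
   and have since diverged independently; their synonymous divergence, read
   against a dated species tree, dates the event.

The climate component addresses the upstream hypothesis: species whose sex
is set by incubation temperature (TSD) breed in a characteristic thermal
envelope. A cold-climate breeder that would sit 3–4 SDs below the TSD
cohort mean, yet comfortably inside the genotypic-sex (GSD) distribution,
is a candidate for a hidden genetic system with thermal override — which
the genomic stages then test directly.

## Subtraction: parameters and assumptions

`subtract_reads()` removes any male RNA read sharing a canonical k-mer
(default `k = 25`) with the female transcriptome. Canonicalization (the
lexicographic minimum of a k-mer and its reverse complement) makes the test
strand-agnostic. The strictest reading — one shared k-mer suffices for
removal — is deliberate: with error-free reads it is also the exact-match
rule's superset, since any full-length match of a read at least k long
implies shared k-mers. Reads shorter than k are discarded and counted.

`assemble_candidates()` is a unitig assembler: maximal non-branching paths
in the de Bruijn graph of read k-mers, both strands, deduplicated by
canonical orientation, with unitigs under `min_len = 200` bp dropped. It is
intentionally minimal — adequate for high-identity subtraction output, and
*not* a general transcriptome assembler: no error correction, no bubble
popping, no splice graphs. Its output is invariant to read order because
start nodes are processed in lexicographic order and each unitig is emitted
in its lexicographically smaller orientation.

`classify_by_genomic_coverage()` retains a contig iff mean male genomic
depth falls in the inclusive window `[4, 14]` (the one-copy band under 20×
diploid sequencing, where a single-copy element is expected near 10×) and
female depth is at most `female_max = 0`. Zero female coverage is taken
literally; the `female_max` knob exists for noisy real data. Matching is
ungapped at ≥ 99% identity over ≥ 90% of the read, located by exact 25-mer
anchors at the read ends: with at most one tolerated mismatch in a
125-150 bp read, at least one terminal k-mer is always intact, so the
anchor search is lossless. Reads overlapping a contig end by less than 90%
of their length are not counted, which biases depth slightly downward on
short contigs (about 12% at 900 bp with 125-bp reads); the retention window
is wide enough that this does not matter at default depths.

## Coverage scan

`coverage_profile()` bins depth per sex (0-based half-open 100-kb bins, a
short final bin divided by its true width) and normalizes each sex by its
genome-wide median bin depth before taking the ratio, so library-size
differences cancel — calls are invariant under any global multiplicative
change to one sex's depth. Bins with zero female depth get an undefined
ratio and never enter calls. `detect_half_coverage()` segments maximal runs
of bins with ratio inside `[0.35, 0.65]`, bridging at most one off-band bin
per junction, and requires at least 3 in-band bins. The band is wide enough
to absorb binomial sampling noise at 10–20× (per-bin ratio SD ≈ 0.02 at
defaults) yet excludes the autosomal background at 1.0 by a large margin.
How exactly the boundaries of a half-coverage region should be delimited is
a genuinely open design point; run-based segmentation with the
single-gap-bridging rule is this package's choice, and partially
overlapping boundary bins (diluted toward ratio 0.75) are intentionally
left out of calls, which bounds the boundary error at one bin.

## Gametolog pairing

`find_x_gametolog()` aligns a candidate Y transcript end-to-end (match 1,
mismatch −1, gap open 4, extend 1; both orientations) against every female
transcript and accepts the best hit iff full-length identity lies in
`[90%, 99%)`. The window generalizes the 95–97% typical of gametologs tens
of Myr old: the upper bound excludes alleles of the same gene (approaching
100% identity), the lower bound excludes paralogs. Ties break by longest
alignment, then lexicographic id, making the result deterministic.
`check_copy_number()` verifies the dosage signature (female:male X depth in
`[1.4, 2.6]`, bracketing 2:1; Y covered by males only), returning
*indeterminate* — not an error — when there is no depth at all.

## The clock: NG86 and calibration

The dating estimator is Nei–Gojobori (1986) by design: a counting method is
fully specifiable and oracle-checkable, unlike a likelihood optimizer whose
result depends on unstated settings. The estimator sits behind a small
interface (`ng86_ds()`, `ds_matrix()`) so a codon-model ML variant can be
added without touching the dating logic. Conventions, since they vary
between implementations: changes to stop codons count as nonsynonymous
(every position contributes out of 3 possible changes, so `S + N = 3 ×`
codons exactly); multi-hit codon pairs average differences over all
orderings of the differing positions, a step being synonymous iff both
codons are sense codons for the same amino acid; codon columns containing
gaps, ambiguity codes, or stop codons are excluded. `ps ≥ 0.75` has no
finite Jukes–Cantor correction and raises a saturation error.

Branch lengths on the fixed gametolog topology are fitted by non-negative
least squares (`phangorn::nnls.tree`), which is the least-squares fit with
negative estimates clamped at zero. Dating itself works from the pairwise
dS values: with a calibration taxon whose divergence from the X lineage is
`T_cal` Myr, the per-lineage rate is `r = (dS(X, cal)/2) / T_cal`, averaged
across calibrations when several are given, and the age is
`(dS(X,Y)/2) / r`, clamped to `[0, max(T_cal)]`. The calibration ages
bracketing the estimate are carried along as a sanity annotation. Working
from the distance matrix rather than the fitted branch lengths keeps the
point estimate and the bootstrap on the same footing; for the small,
nearly additive gametolog trees involved the two differ negligibly.

`bootstrap_age()` resamples codon columns (not genes) with replacement,
`n = 100` rounds by default, and reports the 2.5/97.5 percentile interval.
Column-level resampling matches the unit of independence in the NG86 count
and lets replicates be computed from cached per-column site and difference
counts, so the bootstrap costs milliseconds even on multi-kilobase
concatenations. The resampling seed is recorded in the result.

## Climate extraction

The per-species statistic is the *median* of the cell-by-month temperature
multiset over the species' range and breeding season (an even-cardinality
median is the mean of the central pair); the *mean* is exposed as an option
because both summaries are in circulation and they differ on skewed
seasonal distributions — both are one call apart. The 30-year climatology
question (how to collapse multiple years into one monthly surface) is out
of scope here: the generator emits a single monthly surface, and a real
analysis would average years upstream. Class summaries use the sample mean
and SD (n−1); z-scores are invariant under any affine temperature-unit
change applied jointly to the grid and the statistics. A species exactly at
the 3-SD threshold is flagged, with a 1e-8 epsilon guarding the comparison
against floating-point representation error.

## Marker enrichment

Published Y-linked markers are short (17–70 bp), so `map_markers()` uses
near-exact search (mismatch rate ≤ 5%, no indels, both strands) rather than
a seeded aligner; every occurrence is found by definition. The 2×2
enrichment table contrasts unique hits inside/outside the MSY call against
the number of 100-kb bins inside/outside. The bin-count background is an
explicit modelling interpretation — the natural question being whether hits
concentrate beyond the region's share of the genome — and bp- or gene-based
backgrounds would be equally defensible; the unit is a parameter.
`fisher_exact_2x2()` computes the two-sided p by exhaustive hypergeometric
enumeration at fixed margins (tables no more probable than the observed
one, with a 1e-7 relative guard on floating ties, the same convention R's
`fisher.test` uses, against which the implementation is cross-checked in
the test suite).

## What the generator emulates — and what it does not

The generator's defaults are the package's study conditions: a 2.2-Mb
three-chromosome genome whose chr5 carries a 300-kb MSY with 14 gametolog
pairs of 300 codons; XY divergence truth `true_age = 116` Myr at a
per-lineage synonymous rate of 9e-4 /site/Myr with one calibration taxon at
184.9 Myr; 20× male and female DNA at 125 bp, 30× male RNA at 100 bp,
error-free; a 101-TSD / 99-GSD climate cohort (27 ± 4 °C vs 22 ± 5 °C, so
a 15 °C breeder is a 3-SD TSD outlier but an ordinary GSD species) with one
focal species planted exactly 3 sample SDs below the realized TSD mean; and
nine markers (four in the MSY, one autosomal, four absent). Problem sizes
were chosen so the full pipeline runs in about a minute on one core; the
test suite and acceptance script state the sizes they use.

Design choices worth knowing:

* **Third-position-only divergence.** Gametologs and outgroup orthologs
  diverge by substitutions at third codon positions only (uniform among the
  three alternative bases, stop codons redirected), so the per-position
  difference process is exactly Jukes–Cantor and NG86 recovery is unbiased
  by construction. Real gametologs also diverge nonsynonymously; the
  pipeline does not depend on that signal, so the generator omits it.
* **Guaranteed k-mer distinguishability.** Inside the genome (not in the
  standalone clock simulator), substituted third positions are placed by a
  renewal process with truncated-geometric gaps capped at 7 codons, with
  density calibrated to the Jukes–Cantor expected difference probability at
  the target dS. This preserves the marginal divergence while guaranteeing
  that every 25-mer differs between the X and Y copies — without it, chance
  runs of identical sequence would deterministically delete subtraction
  reads and fragment the assembly, and "every planted transcript is
  recovered" would not be a meaningful contract. The floor requires a
  per-codon density of at least 1/7, i.e. target dS ≳ 0.17; the default
  (dS ≈ 0.21, ~94% nucleotide identity) sits above it with margin.
* **Degenerate Y.** Outside its gene copies the Y MSY is fresh random
  sequence, and Y-derived DNA reads from inside the MSY are emitted as
  unplaced on the X coordinate system — emulating a diverged region a
  strict aligner would not place — which is what produces the half-coverage
  signal.
* **Focal planting against the realized cohort.** The focal species is set
  3 *sample* SDs below the generated TSD cohort's mean and excluded from
  the reference class (a species under test is not a member of the cohorts
  it is scored against). Planting against the population mean instead would
  make the recovered z fluctuate by ±0.2 at n ≈ 100 — the difference
  between testing the scoring arithmetic and testing the generator's
  sampling noise.
* **Uniform, error-free reads.** Coverage is uniform with reads fully
  contained in their source sequence (a ≈ read-length/2 depth taper at
  chromosome ends, negligible at 100-kb bins); an `error_rate` knob exists
  but defaults to 0 because the filters assume high-identity matching.

Consequently, passing tests demonstrate correctness of the *method* under
its stated model — exact filters, exact recovery, calibrated CIs — not
robustness to sequencing error, indels, repeats, alternative splicing,
population polymorphism, range-map error, or assembly/scaffolding noise,
none of which the generator emulates. On real data the subtraction counts
would be orders of magnitude larger and the retention window would need
re-deriving from the observed depth distribution.

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open everywhere (BED native). All randomness
flows through explicit integer seeds; the pipeline derives stage seeds from
the master seed, and rerunning a config reproduces `report.json` byte for
byte. Codon alignment ties resolve to leftmost gap placement via a fixed
traceback preference, so alignments are deterministic. Degenerate inputs
prefer empty results with warnings over errors where the input is valid but
uninformative (no reads to assemble, all-undefined coverage ratios, an
empty pair list); they raise errors where the request itself is ill-posed
(an all-zero contingency table, a zero-length MSY interval, saturated dS).

## Known limitations

The unitig assembler requires error-free, high-coverage reads; real
libraries need an external assembler upstream, with the package's contract
starting at the contig set. Reference-guided contig ordering (placing an
unscaffolded genome against a related chromosome-scale assembly) is
likewise upstream; the coverage scan takes reads already placed on a
coordinate system and accepts an external ordering table. Dating assumes a
single constant rate across lineages — rate variation and Bayesian
uncertainty are out of scope — and the NG86 correction caps usable
divergence at ps < 0.75. The climate stage uses cell sets as ranges;
polygon rasterization and niche modelling are not implemented.
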