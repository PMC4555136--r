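---
title: "Quantifying dietary-selenium effects on selenoprotein translation from ribosome profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dietary-selenium effects on selenoprotein translation from ribosome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Selenoproteins carry selenocysteine (Sec), inserted co-translationally at an
in-frame UGA codon. Because UGA is also the opal stop codon, every elongating
ribosome that reaches the UGA-Sec faces a branch: incorporate Sec and
continue, or terminate. Dietary selenium shifts this branch. Two consequences
follow for bulk measurements in liver:

* mRNA abundance of the stress-related selenoproteins (Gpx1, Selh, Selk,
  Sepw1, and to a lesser degree Sepp1 and Txnrd2) falls under selenium
  deficiency, while housekeeping selenoproteins (Gpx4, Txnrd1, Sephs2) are
  buffered;
* the efficiency of UGA-Sec readthrough falls, so ribosome density
  *downstream* of the UGA-Sec codon drops even when density upstream does
  not.

Ribosome footprints (RPFs, the ~26-36 nt fragments protected by a
translating ribosome) measure density directly. The package's core statistic
is therefore the RPKM of A-site-assigned footprints in a window downstream
of the UGA-Sec codon ("3' RPKM"), which tracks the flux of ribosomes that
actually produce full-length selenoprotein, and the 3'/5' RPKM ratio within
a sample, which estimates the readthrough efficiency itself.

## Coordinate model and windows

All arithmetic is done in transcript space: 0-based nucleotide coordinates,
half-open intervals, codon indices counted from the start codon (codon 0 =
AUG). Windows:

* **CDS core**: codons 15 through (stop - 3). The first 15 codons and the
  stop codon plus its two preceding sense codons are excluded to avoid
  initiation and termination artifacts. We read "last 3 codons" as the
  terminator triplet itself plus the stated flanks, which matches the window
  phrasing used for the 3'-of-Sec window below.
* **5' of Sec**: codons 15 through (sec - 6), i.e. the 5 codons immediately
  preceding the UGA-Sec are excluded along with the first 15 codons.
* **3' of Sec**: codons (sec + 2) through (stop - 3), i.e. from the second
  codon after the UGA-Sec to the third codon preceding the stop.

A window that is empty under these rules (a Sec codon within 20 codons of
the start, or near the C terminus as in the thioredoxin reductases, Selk,
Sels, Seli and Selo) makes the transcript *not analyzable* on that side; it
is flagged and excluded from ratio and fold-change tables rather than
smoothed, and carried in the run manifest. When a transcript has several Sec
codons (Sepp1 has ten), the windows split around the 5'-most one by default
- the first UGA dominates the loss of ribosomes, and the downstream window
then measures everything past it. The choice is exposed as `which_sec` for
sensitivity analysis.

A read is assigned to a window iff the first nucleotide of its A-site codon
(5' end + offset) lies inside the window. This makes windows disjoint and
additive, and it is what makes the 3'/5' ratio interpretable as a ratio of
per-codon fluxes.

## A-site offset and phasing

The offset from a footprint's 5' end to its A-site codon is inferred from
the start-anchored metagene profile. An initiating ribosome holds the start
codon in its P site; the first A-site codon is codon 1. The 3-nt comb of
footprint 5' ends therefore begins (offset - 3) nt upstream of the start
codon, and the inferred offset is `3 - onset`. For the canonical mammalian
geometry the comb begins at -13 and the offset is 16 nt. The onset detector
is deliberately explicit: the first window position whose fraction exceeds
twice the window mean and twice both immediate neighbours, confirmed by the
tooth one codon downstream. Requiring both teeth suppresses false onsets
from the +/-1 jitter shoulders; the neighbour test makes the detector exact
whenever the in-frame fraction exceeds 2/3, and inference is refused (with
instructions to supply the offset manually) when the dominant frame fraction
is below 1/3 + 0.1. A single global offset is applied to all footprint
lengths; a per-length table can be passed but the default mirrors the
one-step offsetting the quantification model assumes. RNA-Seq reads are run
through the same offsetting step for symmetry; under uniform fragmentation
this shifts every window count identically and cancels from all RPKM ratios.

Triplet phasing is summarized as the fraction of 5' ends on each codon
position, frame defined modulo 3 from the annotated CDS start (UTR "codon
positions" read off the CDS frame). Zero-read regions report NA fractions,
never 0/0/0.

## Quantification and error propagation

RPKM = count / (window length in kb) / (total mapped reads in millions),
with total mapped = uniquely aligned reads in the sample. Condition fold
changes are ratios of replicate means (n = 2 biological replicates per
diet), with the sample SD (divisor n - 1, the only defensible estimator at
n = 2). The fold-change SD uses first-order (delta-method) propagation for
a ratio of independent means,

    sd(f) = f * sqrt( (sd_num/mean_num)^2 + (sd_den/mean_den)^2 ),

computed in unfactored form so a zero numerator propagates a finite SD;
replicates are independent animals, so no covariance term. Zero denominator
means are flagged `undefined`, never pseudocounted. The delta formula is the
small-noise limit of the exact ratio distribution; the test suite checks it
against a Monte-Carlo gradient oracle at scaled-down noise, since the raw
ratio of normals has divergent tails.

## Read processing

Adapter trimming truncates at the first adapter occurrence - a full match
anywhere, or at least a 5-nt adapter prefix flush with the read's 3' end -
and discards reads shorter than 15 nt. Both defaults are configurable; they
are documented conventions, not values inherited from a published protocol.
Reads matching the rRNA reference at <= 2 mismatches are removed. Alignment
is exhaustive forward-strand Hamming alignment to the reduced (longest
isoform per gene) transcript set: a read is reported iff it has exactly one
position in its minimal-mismatch stratum at <= 2 mismatches; ties *across*
strata do not disqualify a unique best hit. The implementation seeds with
three disjoint 8-mers per read (pigeonhole: <= 2 mismatches leave at least
one seed exact; shorter reads fall back to a full scan), so it is exact and
is tested read-for-read against a brute-force scan. Footprint libraries are
length-filtered to 26-36 nt after trimming, matching the gel excision range
that defines an RPF. The per-sample ledger (input = length-filtered +
aligned + multi-mapped + unaligned) is written with every run.

## The synthetic experiment

The generator emulates the data-generating process of the two-diet liver
study so that the full chain is testable without the deposited data:

* **Design**: 2 diets (0 and 0.1 ppm Se as sodium selenite) x 2 biological
  replicates, one footprint and one total-RNA library each.
* **Footprints**: per-codon Poisson counts with uniform elongation; A-site
  codons run from codon 1 (initiation leaves the start codon in the P site)
  through the stop codon (termination occupies the A site), which is what
  produces the comb from -13 and its end 16 nt upstream of the stop.
  Readthrough is a single Bernoulli branch at the first UGA-Sec: rates are
  theta per codon upstream and theta * rho downstream. 5' ends sit at the
  canonical offset with probability phi = 0.9 and jitter +/-1 nt otherwise
  (a typical dominant-frame fraction for a good library; the study prints
  no number). Lengths are drawn from a discretized normal over 26-36 nt
  peaked at 30.
* **RNA**: uniform random fragmentation (random-hexamer priming model),
  fragment lengths 80-120 nt, no phasing, no asymmetry around the Sec codon.
* **Contamination and adapters**: 10% rRNA reads drawn from a synthetic
  rRNA pair, and every fragment shorter than the 50-cycle read carries the
  3' adapter, so depletion and trimming are genuinely exercised.
* **Reproducibility**: one RNG stream per sample keyed by (seed, sample),
  so libraries are byte-identical under a fixed seed and independent across
  samples.

The packaged transcriptome is *synthetic*: the 25-entry RefSeq panel (24
selenoprotein mRNAs plus Gapdh) keeps the real accessions, gene symbols and
approximate protein lengths and Sec positions, but sequences are random
single-ORF constructs; ten liver-abundant background mRNAs (Alb, Ttr, ...)
at unchanged abundance make up ~98% of each library. The background matters:
RPKM is a relative measure, and in the real study the denominator was a
genome-wide read total that dietary selenium barely moves. Without ballast,
the selenoprotein-wide shift would deflate every measured fold change by the
ratio of total translational output between conditions; with the ballast the
residual compositional bias is small against the sampling error at the
depths used.

Default abundances and effects encode the study conditions: mRNA fold
changes of 2-4x for the stress-related selenoproteins, ~1.5x for Sepp1 and
Txnrd2, < 1.5x elsewhere; readthrough efficiencies set so that the product
of mRNA and readthrough folds reproduces the per-gene 3' RPKM responses
(15x Gpx1, 13x Sepx1, 6x Sepw1, 5x Sephs2, 1.9x Gpx4, ~2x for the other
analyzable selenoproteins). Baseline abundances follow liver expression
tiers (Sepp1, Gpx1, Gpx4, Sepw1, Sepx1 and Gapdh high; Dio2/Dio3/Selv low).

What the generator does *not* model - and what passing tests therefore do
not establish about real data: sequence-dependent ligation and PCR bias,
codon-level pausing (density is uniform per codon), sequencing errors, UMI
structure, isoform mixtures, and reverse-strand or spliced alignment. The
simulator validates the estimators under their own assumptions; real-data
idiosyncrasies (notably non-uniform footprint recovery around the Sec codon)
are exactly why the 5'-flank and 3'-flank exclusion zones exist.

## Differential expression

Gene-level counts (uniquely aligned reads per mRNA) are filtered to genes
with > 1 CPM in >= 3 samples, normalized by trimmed-mean-of-M-values factors
(30% M-trim, 5% A-trim, inverse-variance weights, upper-quartile reference,
factors centered at geometric mean 1), and tested with a two-sided exact
negative-binomial test conditional on each gene's total pseudo-count after
quantile-based library-size equalization. The common dispersion is estimated
by conditional maximum likelihood on the equalized counts - common rather
than tagwise, because tagwise estimation is not stable with two replicates
per group. In the dispersion-to-zero limit the test reduces to the two-sided
binomial exact test, which the suite asserts, along with a 5% +/- 1% type-I
error on 10^4 simulated null genes and agreement of the TMM factors with the
reference implementation in edgeR (the cross-check, not the implementation).
FDR control is Benjamini-Hochberg step-up via `stats::p.adjust`. A gene is
called differentially expressed iff |fold| > 1.5 (two-sided) and FDR < 0.05;
these thresholds are parameters of `de_analysis()`. Replicate quality is
reported as the squared correlation of log2 normalized CPM between
biological replicates.

## Numerical and degenerate-input conventions

* Longest-isoform ties break by accession order, so reduction is
  deterministic and idempotent.
* Offset inference refuses aperiodic profiles rather than guessing.
* `total_mapped = 0` is an error (RPKM undefined), zero-count windows are
  RPKM 0, zero 5' RPKM flags the readthrough ratio `undefined`.
* All-zero genes get p = 1; the dispersion optimizer compares the interior
  optimum against the Poisson boundary and returns 0 when Poisson fits
  better.
* Multi-mapping reads are dropped and counted, never fractionally assigned.

## Problem sizes

The test suite simulates 2 x 10^5-10^6 footprints per sample for recovery
checks (readthrough grid, offset grid, study-condition fold changes) and
10^4 genes for null calibration; `scripts/acceptance.R` runs the
study-condition pipeline at 3 x 10^6 footprints and 8 x 10^5 RNA fragments
per sample and a 4 x 10^5-read readthrough grid. These sizes were chosen so
that Monte-Carlo error is small against each check's tolerance; the
sparsest quantity is Sepx1's deficient-diet 3' window, whose low
readthrough makes deep libraries necessary. Summary tables report the
median response of the remaining analyzable selenoproteins, a robust
representation of their common ~2-fold response. Genes whose summed 3' counts fall below 3000 in a run
are checked against their own 3-sigma Poisson band instead of the blanket
10% tolerance - with tens of counts, a tighter claim would be
statistically meaningless.

## Known limitations

* The aligner is exact but exhaustive; it is sized for desk-scale
  transcriptomes (dozens of mRNAs). Genome-scale reprocessing should import
  external transcript-space SAM/BAM via `import_alignments_sam()`.
* Readthrough is estimated as a density ratio under uniform elongation;
  pause sites or coverage bias between the flanks bias it.
* One global A-site offset is applied across footprint lengths.
* The exact-test path covers two-group designs only; no GLM/batch terms.
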