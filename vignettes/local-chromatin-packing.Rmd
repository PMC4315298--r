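---
title: "Local chromatin packing from kilobase-resolution Hi-C: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local chromatin packing from kilobase-resolution Hi-C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromapack)
```

`chromapack` analyses *local* chromatin packing — structure at the scale
of single genes — from restriction-enzyme Hi-C in compact, gene-dense
genomes. This vignette is the package's own account of the models it
fits, the parameters that matter, the numerical choices made where the
method definitions leave room, and what the synthetic validation does
and does not establish.

## Why a dedicated pipeline

Animal Hi-C analysis is dominated by TAD calling on matrices balanced
under an equal-visibility assumption (ICE and relatives). Both
ingredients fail in a genome like *A. thaliana*'s: TADs are not the
prevailing feature at 2–20 kb resolution, and the features that *are*
prevailing — kilobase-sized bins with excessive contacts over their
whole 6–50 kb neighbourhood ("positive strips") — are exactly what
equal-visibility balancing erases, because a strip looks like a
high-coverage bin. The pipeline therefore (i) normalizes by *modelling*
coverage biases with observable sequence covariates instead of forcing
uniform coverage, and (ii) replaces TAD calling with three
complementary local statistics: the strip index, the directionality
index with HMM segmentation, and pattern grammars over the decoded
states.

## Read-pair filtering

A restriction Hi-C library contains, besides true ligation junctions,
self-ligated fragments, undigested linear fragments and short inserts.
The classifier uses mapped geometry only:

| class | geometry |
|---|---|
| `valid_inter` | different chromosomes, `len1 + len2 + d1 + d2 < 600` |
| `valid_intra` (FR) | apparent insert `pos2 + len2 − pos1 > 600` |
| `self_ligation` (RF) | no cut site between the reads |
| `too_close` (RF) | cut site present but loci `< 1500` bp apart |
| `short_insert` (FR) | apparent insert `≤ 600` |

`d` is the distance from a read's 3' end to the first cut site
downstream in the read's orientation; reads beyond the last cut site
take the distance to the chromosome end. Three conventions are not
fixed by the rule set and are decided here: FF/RR pairs are kept as
`valid_intra` (neither self-ligation nor an undigested linear fragment
can produce them, so the two intra filters do not apply); the
"cut site between reads" test uses the closed gap between the inner
read ends; duplicates are exact coordinate+strand matches after
canonical side ordering, with no fuzzy window. Classification is
validated two ways: against an independent brute-force classifier
(exact agreement) and against generator truth (≥ 99% per class).

## Bias model and residual matrix

Counts `u_ij` are Poisson with

```
log λ_ij = β0 + β_len·log(L_i L_j) + β_gc·log(G_i G_j)
         + β_end·log(F_i F_j) + log(M_i M_j)
```

fitted per chromosome by IRLS over all unmasked off-diagonal bin pairs.
Covariates per bin: effective fragment length `L` (fraction of the bin
within `eff_flank` of a cut site), fragment-end GC `G` (GC of
`end_flank` windows around the bin's cut sites), fragment-end count `F`
(cut sites per bin — the covariate that captures how many ligatable
ends a bin offers), and mappability `M` as a fixed offset. Defaults
`end_flank = 200` bp and `eff_flank = 500` bp follow the conventions of
fragment-level bias modelling; neither is sharply identified and both
are exposed as parameters. Bins with mappability < 0.5 or effective
length < 0.1 are excluded from the fit; centromeric bins are fitted but
flagged out of all downstream pattern analysis; bins with a
non-positive covariate are auto-masked (their log is undefined).

Distance is deliberately absent from the model. Every downstream
statistic compares values at *equal* offset, which neutralises the
distance decay without modelling it; keeping decay out of the fit also
keeps the residuals interpretable as "contacts relative to what this
bin pair's sequence properties predict".

The residual type is configurable because "the residuals" of a Poisson
regression is ambiguous: the default is the Pearson residual
`(u − λ̂)/√λ̂`, which is variance-stabilized and comparable across the
decay range; `residual = "raw"` gives `u − λ̂`. Diagonal cells are
excluded from the fit (dominated by self-structure) and set to 0. The
fit is validated against a direct likelihood optimizer (BFGS on the
Poisson log-likelihood) to 1e−6 on a 12-bin instance — the smallest the
fit's own precondition of ten unmasked bins admits — and by a planted
bias-removal experiment: with per-bin biases proportional to the
end-count covariate, the residual matrix correlates better with the
bias-free expectation than the raw matrix does.

## Strip index

For focal bin `i` and each signed offset `o ∈ ±{3..25}` (6–50 kb at
2 kb), the value `v(i, i+o)` is ranked among the same-offset values of
the 100 nearest unmasked bins on each side — the "equivalent values" of
a local 400-kb context. Scores are `+3` at or above the 95th midrank
percentile, `+1` at the 80th, `−1` at or below the 20th, `−3` at the
5th, else 0; the index is the sum over the 46 offsets, bounded by
±138, and maximal runs at or beyond ±45 are called strips.

Numerical choices: percentiles use midrank tie handling, so a uniform
background scores exactly 0 at every offset (a strict-inequality rank
would mislabel ties); reference sets are strictly per-offset, never
pooled — this is what makes the statistic decay-free; masked neighbours
are skipped rather than zero-filled; edge behaviour is a
minimum-support rule (bins with fewer than 100 reference neighbours in
total are undefined) since the original edge handling is unstated.
Negative strips are called and reported symmetrically but flagged as a
sequencing-bias signature rather than biology.

## Directionality index and HMM

For each bin, `A` and `B` sum its normalized contacts with the 30
upstream and 30 downstream bins (60 kb at 2-kb bins);
`DI = sign(B − A)·((A−E)²/E + (B−E)²/E)` with `E = (A+B)/2`, set to 0
when `A = B` or `E ≤ 0`. On residual matrices `E ≤ 0` is common in
unstructured regions, which concentrates unstructured bins at DI = 0 —
the no-bias state absorbs them.

The three-state HMM uses Gaussian emissions on DI, with two
constraints the emission family's freedom would otherwise abuse:
the N state's mean is pinned at 0 (no bias *means* DI = 0), and the
U/D states are mirror-constrained (`μ_U = −μ_D`, shared σ) because
upstream and downstream bias are one phenomenon reflected. Without
these constraints, EM on a sign-symmetric heavy-tailed DI track
converges to three near-zero means distinguished only by variance,
making U/D labels arbitrary; with them, U/D frequencies on unstructured
maps agree within 0.05 and planted blocks decode cleanly. Parameters
are fitted by Baum–Welch (tolerance 1e−6, cap 500 iterations,
tercile-based deterministic initialization), decoding is the most
likely path (Viterbi), and excluded bins split chromosomes into
independent segments that share parameters but never share a pattern
match. A constant DI track short-circuits to all-N.

## Pattern grammars

All region types are literal sliding-window matches over per-segment
state strings, overlaps allowed, identical spans deduplicated:

* insulator-like: `XXUUDDXX` (type A, region `UD`), `XXUUNDDXX`
  (type B, `UND`), `XXUUNNDDXX` (type C, `UNND`);
* boundary-like: `UUUUU(D/N)(D/N)X` (region = last U + next bin) and
  `X(U/N)(U/N)DDDDD` (region = bin before the D run + first D);
* interior-like: the mirror patterns `X(D/N)(D/N)UUUUU` and
  `DDDDD(U/N)(U/N)X`.

`X` means "any decoded state", so flanking positions must exist and be
non-excluded: a core cannot sit within two bins of a segment end, and
no pattern spans a masked gap. Runs longer than five U/D still match
(their terminal five satisfy the window) — this falls out of literal
sliding-window matching and is not a separate "at least five" rule.
Extraction is verified against a brute-force per-window oracle on
random 10,000-state strings for all seven subtypes.

## Chromatin states

Mark enrichment per 400-bp bin is the fraction of the bin covered by
the mark's enriched intervals. Per mark, zero-coverage bins score 0 and
positive-coverage bins get quintile scores 0–4 by midrank percentile —
rank-based, hence invariant to monotone transforms of the input
enrichments, and well-defined under the "all 16 scores 0 ⇒ unclear"
rule precisely because zeros are pinned rather than ranked. Non-unclear
bins are clustered by k-means (Euclidean distance, k = 6, 50 restarts
under a fixed seed — the historical clustering tool's behaviour is not
bit-reproducible, so restarts + seed stand in for it). Cluster naming
is a separate step: centroids are matched to editable canonical
profiles (CS1/CS5 active euchromatin, CS2 Polycomb-like
H3K27me3/H3.1/H3.3, CS3/CS6 heterochromatin, CS4 unremarkable) by
cosine similarity solved as an optimal bijection, so permuting
centroids never changes the names. Expression grouping uses group 1 for
RPKM = 0 and octiles of the positive values — the published group
boundaries are not recoverable, so zero + octiles is the documented
stand-in.

## Synthetic data: what it emulates, what it does not

The generators plant exactly the structures the callers are designed to
detect: power-law distance decay with Poisson counts (matching the
fitted model's error family), multiplicative per-bin biases, strip bins
boosted symmetrically over ±50 kb, directionality blocks implemented as
multiplicative asymmetry inside the 60-kb DI window (the minimal
structure DI detects), six latent chromatin states with
state-conditional mark probabilities, and read-pair populations whose
mapped geometry realises each library class by construction. Default
study conditions: 2-kb bins, decay exponent −1, base count 50 at unit
distance, boost factors 3, read length 80 bp, GC 0.36 and one cut site
per ~250 bp (a four-cutter density).

What the generators do *not* emulate: mapping artifacts and chimeric
reads, copy-number and repeat structure, interchromosomal organisation
beyond a uniform background, correlated biases (each bias is
independent per bin), and the empirical DI distribution of real
chromatin (blocks here are clean rectangles). Passing the validation
suite therefore establishes that each statistic recovers the structure
it is defined to detect at realistic counting noise — not that real
*A. thaliana* maps will yield any particular number of calls. The
published full-depth analyses (tens of millions of read pairs) report
on the order of 1500 strip bins, ~430 insulator-like, ~1350
boundary-like and ~1470 interior-like regions; reproducing those
numbers requires the deposited sequencing data and is outside what
desk-scale synthetic validation can or should claim.

## Problem sizes and degenerate inputs

Validation sizes were chosen so the whole suite runs in about a minute
while keeping each statistic comfortably powered: 100-kb genomes for
digestion, 1000 labelled pairs for filter concordance, 500-bin
chromosomes (×5 seeds) for bias removal, 420-bin chromosomes (×5
seeds) for strip recovery, 50 planted junctions on a ~1300-bin
chromosome for insulator recovery, and 1200 bins × 16 marks (×5 seeds)
for state recovery.

Degenerate inputs are handled explicitly rather than by crash:
motif-free chromosomes digest to one fragment; empty pair sets filter
to empty censuses; constant-covariate fits fall back to an
intercept-only model (collinear terms dropped by the IRLS); chromosomes
too short for neighbour support yield all-undefined strip indices;
constant DI yields all-N without invoking EM; fewer than k distinct
score vectors is an error, not a silent k reduction.

## Known limitations

* The per-offset percentile reference assumes a locally stationary
  background; a strong gradient in contact decay across the 400-kb
  context (e.g. at pericentromere edges) can shift indices near it.
* The HMM's mirror constraint trades a little flexibility for label
  stability; genuinely asymmetric directionality landscapes would be
  better served by freeing `σ_U ≠ σ_D`.
* Interchromosomal counts are reported raw; the bias regression indexes
  a single chromosome and no cross-chromosome model is fitted.
* Region counts depend on the HMM's state granularity: merging or
  splitting of N runs moves pattern matches, so counts should be
  compared across samples only under identical HMM settings.
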