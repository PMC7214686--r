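---
title: "Classifying promoters by H3K4me1 peak-density shape: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying promoters by H3K4me1 peak-density shape: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promshape)
```

## The analytic idea

Metagene plots of ChIP-seq *signal* average many promoters together and so
cannot say whether an individual promoter carries a mark in one
configuration or another. `promshape` instead works on *peak calls*: each
peak is reduced to its center, each promoter to its transcription start
site (TSS), and the analysis operates on the resulting point geometry,
promoter by promoter.

Two shapes of H3K4me1 placement around the TSS are distinguished:

- **unimodal**: a single H3K4me1 peak centered on the TSS, co-occurring
  with both H3K4me3 and the Polycomb mark H3K27me3 — the poised (bivalent)
  configuration;
- **bimodal**: two H3K4me1 peaks displaced roughly 300–1000 bp on either
  side of the TSS, flanking a TSS-proximal H3K4me3 peak — the active
  configuration.

Everything in the package serves one of three questions: what does the
aggregate density of peak placement look like (profiles), which
configuration does each individual promoter have (classification), and is
the shape driven by chromatin state or by expression level (grouped rank
tests on promoters where the two disagree)?

## Geometry

All coordinates are internally 0-based half-open (BED-native); GTF input
(1-based inclusive) is converted on read, so a `+`-strand transcript
starting at GTF coordinate 1000 has its TSS at 999, and a `-`-strand
transcript ending at 2000 has its TSS at 1999.

Distances are **center-to-point**: a peak `[start, end)` is represented by
`floor((start + end) / 2)`, and the distance between a peak and a TSS is
the signed offset of that center from the TSS, oriented by gene direction
(negative = upstream). The same convention is applied in both query
directions — peak→nearest-TSS for profiles, TSS→nearest-peak for
classification — so magnitudes are comparable everywhere. Edge-to-point
distances are deliberately not used anywhere.

Nearest-neighbor queries are implemented as per-chromosome sorted arrays
with a bracketing binary search (`findInterval`), and the test suite holds
them to *exact* agreement with a brute-force scan over every subject,
including tie cases. Ties at equal |distance| are resolved
deterministically:

- `nearest_tss`: smaller chromosomal coordinate, then lexicographic
  transcript id;
- `nearest_peak`: the upstream (negative) hit first, then smaller center
  coordinate, then lexicographic peak name.

The two rules differ on purpose. For a TSS choosing among peaks,
"upstream" is well defined by that TSS's own strand, and preferring the
upstream candidate keeps the choice biologically interpretable. For a peak
choosing among TSS, each candidate TSS carries its own strand, so
"upstream" would flip meaning from candidate to candidate; a purely
positional rule is the only one that stays coherent. Either way the
tie-break only decides which of two equally distant neighbors is reported
— |distance|, the quantity every downstream stage consumes, is unaffected.

## Density profiles

Given the retained signed distances \(d_i\), the profile is the direct-sum
Gaussian kernel density estimate

\[ f(x) = \frac{1}{n h \sqrt{2\pi}} \sum_{i=1}^n
   e^{-(x - d_i)^2 / (2 h^2)} \]

evaluated on a fixed grid. Defaults, all configurable:

| parameter | default | unit | rationale |
|---|---|---|---|
| bandwidth `h` | 15 | bp | narrow enough to resolve the two flanking modes from the central one; deliberately fixed, no automatic (Silverman-type) bandwidth |
| grid | −2000 … +2000, step 10 | bp | the ±2 kb promoter neighborhood; 10 bp step resolves a 15 bp kernel without inflating output size |
| inclusion window | 2000 | bp | a peak contributes only if its nearest TSS is within 2 kb |

Normalization is over the *retained* distances: peaks with no TSS within
the window (distal enhancer peaks, most of the genome) are excluded before
smoothing and their count is reported. Including them would flatten the
promoter-proximal signal under an arbitrary amount of far-field mass and
make the profile depend on how much intergenic space the peak caller saw.
No boundary correction is applied at the grid edges; with all mass well
inside ±2 kb the trapezoidal integral of the profile is within 1% of 1
(a property the tests assert).

The `shape_summary` statistic quantifies the two configurations without a
formal bimodality test: `center_fraction` is the proportion of distances
with |d| < 300 bp, `flank_fraction` the proportion with
300 ≤ |d| ≤ 1000 bp. The 300 and 1000 bp boundaries are the displacement
band in which the flanking H3K4me1 modes sit; distances beyond 1000 bp
count toward neither fraction.

## Classification rules

**Poised peak lists.** A H3K4me3 peak is *poised* when it overlaps any
H3K27me3 peak by at least 1 bp, reported once with its original
coordinates (the `-wa` overlap convention; half-open abutment does not
count). `poised_k4me1` applies the same rule to H3K4me1 peaks against the
poised list.

**Two per-TSS rules** are implemented and labelled, because the direct
(H3K4me3-led) and the H3K4me1-led descriptions of the split are genuinely
different procedures and it is informative to run both:

- `by_k4me3`: poised iff the nearest H3K4me3 peak (within 2 kb) is
  bivalent; active iff a nearest H3K4me3 exists and is not; `other` iff no
  H3K4me3 within the window.
- `by_k4me1`: poised iff the nearest H3K4me1 peak overlaps a poised
  region; otherwise active iff the nearest H3K4me3 *center* is within
  500 bp of the TSS; otherwise `other`. Poised is evaluated first, so a
  promoter is never both.

The 500 bp bound is interpreted center-to-TSS, consistent with every other
distance in the package; an edge-based reading would make this one rule
use a different metric than the rest of the pipeline.

**Expression bins** partition TPM as B1: tpm ≤ 1, B2: 1 < tpm ≤ 5,
B3: 5 < tpm ≤ 10, B4: tpm > 10, boundaries inclusive on the lower bin.
Silent promoters (tpm = 0) fall in B1; there is no fifth bin. A TSS
without a TPM record keeps `tpm = NA` and is excluded from binned analyses
but retained in state classification — absence of quantification is not
zero expression. When several transcripts share one TSS coordinate they
are merged into a single record (the density and classification stages
iterate over distinct TSS points, and coordinate-identical duplicates
would multiply-count identical geometry); the merged TSS's TPM is the
*sum* of its members by default (total promoter output), with `max`
available.

**The joint map** bins each TSS's (d to nearest H3K4me1, d to nearest
H3K4me3) pair on a uniform 30 × 30 grid over ±2 kb. Only TSS with both
marks within the window contribute, and the count matrix sums exactly to
that number. 30 bins per axis is a conventional 2D-histogram default,
recorded in the output header; active promoters appear as lateral "wings",
poised promoters as a central cluster.

## Rank statistics

Group comparisons use the Kruskal-Wallis rank sum test computed
in-package: pooled mid-ranks, \(H_{raw} = \frac{12}{N(N+1)} \sum_i R_i^2 /
n_i - 3(N+1)\), tie correction \(H = H_{raw} / (1 - \sum (t^3 - t) /
(N^3 - N))\), and the upper chi-square tail with k−1 degrees of freedom
(via `pchisq`, i.e. the regularized incomplete gamma function). With no
ties the corrected and raw statistics coincide exactly; all-identical
input is a hard error rather than a silent zero; any group smaller than 5
triggers a warning that the chi-square approximation may be poor. The test
suite pins the implementation to `stats::kruskal.test` within 1e−8 on
random data, checks invariance under strictly monotone transforms, and
checks the empirical type-I error at α = 0.05 over 1,000 seeded label
permutations.

The test is applied to **absolute** distances |d| between TSS and nearest
H3K4me1 center. Both the unimodal and bimodal configurations are roughly
symmetric about the TSS, so signed distances center near zero in *both*
groups and would mask the contrast; the near/far distinction lives
entirely in |d|. The signed vectors are nevertheless carried alongside in
`distance_by_group` output for plotting and for anyone who wants the
signed analysis.

## The synthetic landscape

The simulator exists so every stage is exercisable, deterministically,
without downloading ChIP-seq data. It emulates the *geometry* the analysis
rests on, on a single linear chromosome (`chrS`) with TSS every 10 kb and
alternating strands (so strand-aware code is always exercised in both
orientations):

- **active** promoters (60% by default): one H3K4me3 peak with center
  offset ~ N(+100, 50) bp downstream in gene orientation, two H3K4me1
  peaks at ±U(300, 1000) bp, one H3K27ac peak, no H3K27me3;
- **poised** promoters (30%): overlapping H3K4me3 and H3K27me3 peaks
  (overlap ≥ 1 bp enforced by construction) and a single H3K4me1 peak at
  N(0, 100) bp from the TSS;
- **silent** promoters (10%): no peaks;
- **background** H3K4me1 peaks (one per gene on average) placed uniformly
  but kept > 2 kb from every TSS, standing in for distal enhancers;
- **TPM**: active ~ logN(μ=2, σ=1); poised ~ 70% exactly 0, 30%
  logN(μ=0.5, σ=1); silent 0. The two distributions overlap on purpose —
  if expression separated the states cleanly, the
  poising-versus-expression question would be untestable — and
  `make_discordant_subset` additionally forces chosen promoters into the
  opposite expression extreme without touching any peak.

State counts are exact (`round(fraction · n)`, assigned by a seeded
shuffle). Peak widths are uniform per mark (H3K4me1 300–700 bp, H3K4me3
400–800 bp, H3K27me3 500–1500 bp, H3K27ac 300–700 bp — typical peak-call
scales for these marks). The 10 kb spacing exceeds twice the largest
offset-plus-width, so a promoter's peaks can never be nearest to a
neighboring TSS; the tests assert this geometric ownership. Each
generation stage (state assignment, each mark, background, TPM) draws from
its own sub-seed derived from the master seed, so adding one mark cannot
perturb the draws of another, and identical configs produce byte-identical
output files.

What the simulator does **not** emulate — and what passing tests therefore
do not show about real data: peak-calling noise (missed or spurious
peaks), width/score correlation with signal strength, multiple
chromosomes and chromosome-name conventions, overlapping genes and
bidirectional promoters, copy-number or mappability artifacts, and any
sequence context. The recovery rates on the default landscape (≥99% for
both rules) certify the *pipeline logic*, not classification performance
on noisy peak calls.

## Numerical and degenerate-input choices

- KDE is the exact direct sum (no FFT binning); tests hold it to 1e−9
  against an independent double loop.
- `shape_summary`'s `bimodality_ratio` guards the denominator with
  ε = 1e−12 so a profile with zero central mass yields a large finite
  ratio instead of dividing by zero.
- Empty peak files parse to empty sets; an empty TSS set is an error (no
  distance is definable); an empty distance vector is an error rather than
  an empty profile.
- Parsing is total: every malformed line (wrong field count, non-integer
  coordinates, `start >= end`) is an error naming the line number —
  nothing is silently dropped.
- Chromosome names are never normalized (no `chr`-prefix guessing);
  instead any mismatch between inputs warns with the unshared names, and
  `strict` mode escalates the warning to an error. Silent zero-overlap is
  the characteristic failure mode of mixed-provenance genomics inputs.
- All randomness lives in the simulator config; the pipeline itself is
  deterministic, and reruns on identical inputs are byte-identical.

## Problem sizes

The test suite and the acceptance script run on simulated landscapes of
2,000 promoters (≈ 9,000 peaks across the four marks) for the recovery,
shape and rank-test properties, 60–200 random instances of up to 1,000
peaks/TSS for oracle-equivalence of the nearest-neighbor queries, and 100
random datasets plus 1,000 label permutations for the rank test — sizes at
which every property is stable across seeds while the whole suite stays
fast on a single CPU.

## Known limitations

- Peak calls are trusted as given; there is no signal-level reanalysis, no
  peak calling, and no use of peak scores or summit annotations (the
  narrowPeak summit column is parsed but not used — centers are computed
  from the interval, uniformly across formats).
- Classification is 1-nearest-neighbor by construction; a promoter with
  two relevant peaks at equal distance is decided by the documented
  tie-break, not by signal strength.
- The Kruskal-Wallis chi-square null is asymptotic; for the small groups
  this pipeline was not designed for, an exact or permutation null would
  be preferable.
- No multiple-testing correction is applied across cell types or marks;
  reported p-values are raw.
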