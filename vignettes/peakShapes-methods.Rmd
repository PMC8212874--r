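---
title: "Evaluating and classifying peak profiles with peakShapes"
author: "peakShapes maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating and classifying peak profiles with peakShapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Peak callers for protein-binding assays such as CLIP-seq return genomic
intervals, but say little about what the read coverage inside each interval
looks like. Two predicted binding sites with identical scores can carry
drastically different coverage profiles: a sharp, concentrated mountain of
reads (a specific binding event) or a broad, almost flat carpet (unspecific
binding, library artifacts, or a false positive). peakShapes quantifies and
classifies these profiles so that downstream analyses — motif discovery,
structure prediction, quality control — can be restricted to the peak
shapes that are informative for the question at hand.

```{r}
library(peakShapes)
```

## Specificity score: the negative-binomial CV

Each peak's per-nucleotide depths $x_1, \dots, x_n$ are treated as draws
from a negative binomial $X_i \sim \mathrm{NB}(r_i, p_i)$, with $r_i$ the
number of hits and $p_i$ the probability of a hit (the number-of-trials
parameterization, mean $r/p$ and variance $r(1-p)/p^2$). A plain variance
would scale with sequencing depth; the NB coefficient of variation

$$\mathrm{CV}_i = \sqrt{\frac{1 - p_i}{r_i}}$$

normalizes for the expected read count and is therefore comparable across
peaks. We estimate $(r_i, p_i)$ by moment matching, $p = m/(v+m)$ and
$r = m^2/(v+m)$ with $m$ and $v$ the empirical mean and variance. Under
this estimator the CV reduces *algebraically* to the empirical
$\mathrm{sd}/\mathrm{mean}$ of the depths — the test-suite checks this
identity to $10^{-9}$ on thousands of random profiles, and it also covers
underdispersed profiles ($v < m$) without any special case. Degenerate
inputs are pinned down explicitly: an all-zero profile and a constant
profile both get CV 0 (and a constant profile min–max-normalizes to all
zeros, an "empty-looking" but valid profile).

```{r}
d <- simulateProfile("sharp-spike", length = 77, amplitude = 50, noise = 0)
cvScore(estimateNB(as.numeric(d)))
cvScore(estimateNB(rep(50, 77)))   # constant profile
```

Scores are normalized across the peak set, by min–max by default, or by a
user-supplied cap `scaleMax` (`min(CV, s)/s`), which keeps normalized
scores comparable between experiments with different peak sizes and read
totals. An empirical threshold of 0.2 splits the set into specific (label
0) and unspecific (label 1) peaks. Whether the threshold should apply to
the raw or the normalized CV is genuinely ambiguous in practice; we default
to the **normalized** CV (the scale on which 0.2 is meaningful regardless
of the experiment's absolute CV range) and expose `thresholdBasis = "raw"`
for the other reading.

Two CV distributions (replicate vs control, or two pseudo-replicates
produced by `splitPseudoReplicates()`) are compared with a Wilcoxon
rank-sum test — exact for small untied samples, normal approximation with
tie correction otherwise.

### Border penalty

Windows that cover only the appendage of a broader read stack can score a
deceptively high CV. The optional border penalty multiplies the CV by
$1 - \min(1, (d_\mathrm{first} + d_\mathrm{last}) / (2\, d_\mathrm{max}))$:
1 when coverage falls to zero at both window borders, 0 for a flat plateau.
The exact functional form of this correction is a design choice of this
package; it is isolated behind `borderPenalty()` so an alternative can be
swapped in.

## Peak preparation

Peak callers often misplace the window relative to the read stack, and
dimension-reduction methods are not translation invariant, so badly
centered peaks would scatter identical shapes across the embedding. The
preparation stage therefore:

1. **Re-centers** each peak: coverage over the peak plus one search flank
   on each side is convolved with a Gaussian kernel and the window is moved
   to the convolution maximum (or the raw coverage summit with
   `maxTranslocate`, appropriate for single-nucleotide events such as iCLIP
   truncations). The kernel is a discrete Gaussian truncated at
   $\pm h$ with $\sigma = h/3$, $h$ defaulting to half the peak length —
   a window-scaled kernel keeps the centering scale-free. Ties take the
   left-most maximum; an all-zero window is left where it is.
2. **Harmonizes lengths**: all peaks are extended (or shrunk) symmetrically
   about their midpoint to a common length — the maximum observed length by
   default, or `peakLength` — removing length as a confounding feature. An
   odd remainder goes to the 5' side; windows that would overrun a
   chromosome edge slide inward, and peaks on contigs shorter than the
   target are dropped with a warning rather than failing the run.
3. **Recomputes coverage** over the final windows (strand-specific by
   default, since CLIP libraries are stranded; `strandMode = "ignore"`
   serves unstranded assays). Spliced BAM alignments contribute only their
   aligned blocks. Minus-strand profiles are reported 5'→3'.

The stage order (center → harmonize → coverage) makes preparation
idempotent: preparing an already-prepared peak set is a no-op, which the
suite checks, along with exact translation equivariance of the whole stage.

## Shape classification

Profiles are min–max normalized per peak (shape, not intensity, is the
feature of interest), then smoothed with a penalized cubic regression
spline. The spline's penalty is chosen by generalized cross-validation;
the user-facing `smoothingFactor` multiplies that penalty (values > 1
underfit — fewer apparent maxima and typically fewer clusters — values < 1
overfit). Smoothing both removes sampling noise and distributes the data
more uniformly on the manifold, which is the working assumption of the
embedding step. Three curve features are appended to each smoothed
profile: the number of local maxima (a plateau run counts once, window
boundaries are eligible), the trapezoidal area under the curve, and the
arc length $\sum_j \sqrt{1 + (x_{j+1}-x_j)^2}$. The features are z-scored
so they are commensurate with the $[0,1]$ profile values.

The profile+feature matrix is embedded into 2-D with UMAP (5000 epochs,
2 components, minimum distance 0.01, neighborhood size 5), run seeded and
single-threaded so that a fixed seed reproduces coordinates exactly; with
fewer than 6 profiles the neighborhood cannot be formed and the first two
principal components are used instead. The embedding is clustered with
k-means (100 initializations, up to 10000 iterations).

### Choosing k

When `kForced` is not given, k is selected by convergence of the total
within-cluster sum of squares: the smallest k at which the WSS drop from
k to k+1 falls below 5% *of the total sum of squares* (the WSS at k = 1).
Normalizing the drop by the total — rather than by the current WSS — keeps
the rule stable when clusters are tight and WSS approaches zero, where a
ratio of consecutive WSS values degenerates into noise. The Akaike
information criterion
$\mathrm{AIC}(k) = n d \ln(\mathrm{WSS}_k/(nd)) + 2kd$ (d = 2) is computed
alongside as a cross-check; both curves are stored in the result's
metadata and drawn by `plotKDiagnostics()` so a disagreement is visible,
and `kForced` overrides selection entirely. The upper bound `kMax`
defaults to 15.

### Sharp and broad peaks

Clustering and the CV are combined into a per-peak call: a cluster is
*sharp* when its median CV exceeds the median CV of the whole peak set
(strict, so a lone cluster is never sharp), and a peak is *sharp* when its
own CV exceeds 0.2 **and** its cluster is sharp. Everything else is broad.

## Synthetic data: what it emulates and what it does not

`simulateProfile()` generates the four canonical profile families used to
tune the classification — uniform, linear, unimodal Gaussian, bimodal
Gaussian (modes at 1/4 and 3/4 of the window) — plus plateau, constant and
sharp-spike shapes seen in real peak sets. Noise is multiplicative
log-normal on the expected curve, rounded to non-negative integer depths;
a relative sd of 5% and an expected depth of 50x over 77-nt windows with
50 peaks per family are the package's standard study conditions.
`profileToReads()` realizes a profile as a read stack (exact wherever the
target is stack-feasible), `simulateFixture()` writes a complete
single-chromosome data set (BED6 peaks, BED/BAM reads, chrom.sizes, truth
labels), and `splitPseudoReplicates()` reproduces the 50% read split — with
or without replacement — used to check CV robustness.

The simulator emulates shape, depth and sampling noise. It does **not**
emulate PCR duplicates, crosslink-site truncation patterns, spliced reads,
mappability gaps, or peak-caller boundary bias; passing tests demonstrate
that the method recovers known shapes and ranks specificities correctly
under clean sampling assumptions, not that it is immune to those
artifacts on real libraries.

## Numerical choices and problem sizes

* Coverage is computed by run-length-encoded coverage vectors
  (GenomicRanges machinery); a brute-force per-base counter exists in the
  test-suite as an independent oracle, never in the package path.
* k-means and UMAP seeds default to 42 and are recorded in the run
  manifest; two runs with the same inputs, flags and seed produce
  byte-identical final tables.
* The test-suite and the acceptance script run on deliberately modest
  problem sizes — 200 profiles for the shape-recovery checks, 63 deep
  peaks for the pseudo-replicate checks, 1000 random profiles for the CV
  identity — sizes at which every check completes comfortably on one CPU
  while still exercising the full pipeline.
* Degenerate inputs (all-zero profiles, constant profiles, n = k
  clustering, single-sample plots) are defined behaviors, not errors; see
  the individual help pages.

## Known limitations

* The CV threshold of 0.2 is empirical and its raw-vs-normalized basis is
  a documented ambiguity; both bases are supported.
* The border-penalty formula is a pragmatic boundary-depth heuristic.
* No cross-sample shape comparison mode: CVs and clusters are defined
  within one peak set, and comparing cluster identities across samples is
  out of scope.
* Automatic k selection on data without clear cluster structure tends
  toward small k; forcing k is the right tool when the expected number of
  shapes is known.

## A complete run

```{r, eval = FALSE}
fx <- simulateFixture(nPerFamily = 10, noise = 0.05, centerOffset = 5,
                      seed = 1)
pse <- runPeakShapeAnalysis(fx$peaks, fx$reads, fx$chromSizes,
                            outputDir = "peakshapes_out",
                            peakCorrection = TRUE, useBorderPenalty = TRUE,
                            smooth = TRUE, seed = 42)
pse
head(resultTable(pse))
```

The same pipeline is available from the shell via the bundled script
(`system.file("scripts", "peakshapes.R", package = "peakShapes")`).
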