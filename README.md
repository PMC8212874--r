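# peakShapes

Quality control and shape classification of binding-site peak profiles from
sequencing data such as CLIP-seq.

Peak callers return intervals, not shapes. Two predicted binding sites with
the same score can look completely different at nucleotide resolution: a
sharp mountain of reads over a specific binding event, or a broad, flat
carpet over an unspecific one. peakShapes is for anyone who wants to rank,
filter or group predicted peaks by what their coverage profile actually
looks like — before feeding them into motif discovery, structure
prediction, or a peak-caller benchmark.

## The method

**Specificity score.** Each peak's per-nucleotide depths are modeled as a
negative binomial X ~ NB(r, p) (r "hits", p "hit probability"; trials
parameterization, mean r/p, variance r(1−p)/p²). Its coefficient of
variation

    CV = sqrt((1 − p) / r)

normalizes the profile variance for the expected read count, so peaks of
different depth are comparable: high CV = sharp/specific, CV ≈ 0 =
broad/unspecific. (r, p) are moment-matched, under which the CV equals the
empirical sd/mean of the depths. CVs are min–max normalized across the
peak set (or capped with `scaleMax`), and an empirical threshold of 0.2
labels each peak specific (0) or unspecific (1). An optional border
penalty down-weights windows that only clip the edge of a broad read
stack.

**Shape clustering.** Peaks are re-centered on their coverage signal
(Gaussian-convolution maximum, or raw summit), extended to a common
length, min–max normalized, smoothed with a penalized regression spline,
and augmented with three curve features (number of maxima, area under the
curve, arc length). The resulting matrix is embedded into 2-D with UMAP
(5000 epochs, min_dist 0.01, neighborhood 5) and clustered with k-means
(100 starts), with k chosen by within-cluster-sum-of-squares convergence
and cross-checked by AIC — or forced by the user. A cluster is *sharp* if
its median CV exceeds the peak-set median; a peak is sharp if its CV > 0.2
and its cluster is sharp.

Everything is testable offline: `simulateProfile()` /
`simulateFixture()` generate profiles of known shape families (uniform,
linear, unimodal and bimodal Gaussian, plateau, constant, sharp-spike),
read stacks realizing them, and pseudo-replicate read splits.

## Worked example

```r
library(peakShapes)

fx <- simulateFixture(nPerFamily = 10, noise = 0.05, centerOffset = 5, seed = 1)
pse <- runPeakShapeAnalysis(fx$peaks, fx$reads, fx$chromSizes,
                            outputDir = NULL,
                            peakCorrection = TRUE, useBorderPenalty = TRUE,
                            smooth = TRUE, seed = 42)
pse
#> class: PeakShapeExperiment
#> peaks: 40, window width: 77 nt
#> assays: coverage, normalized, smoothed
#> CV: median 0.538, range [0.003, 0.923]; 30/40 labeled specific
#> shape clusters: k = 4 (selected); sharp peaks: 20

head(resultTable(pse)[, c("name", "cv", "cv_normalized", "specificity",
                          "cluster", "sharp")], 5)
#>      name        cv cv_normalized specificity cluster sharp
#>  peak_009 0.9230906     1.0000000           0       2     1
#>  peak_038 0.9183854     0.9948873           0       2     1
#>  peak_005 0.9157824     0.9920588           0       2     1
#>  peak_035 0.9002678     0.9752006           0       2     1
#>  peak_012 0.8992558     0.9741010           0       2     1
```

The fixture contains 10 peaks each of the four canonical shape families,
deliberately written 5 nt off their read stacks; the pipeline re-centers
them, selects k = 4 shape clusters, and the CV-sorted table puts the
unimodal (sharpest) peaks on top with specificity label 0 and the sharp
flag set, while flat/uniform profiles sink to the bottom with CV ≈ 0.

With an output directory, the run also writes `results/final_table.tsv`,
the CV and normalized-CV distribution histograms, the UMAP embedding and
k-optimization plots, per-cluster example/smoothed/mean profile panels,
and a `run_manifest.txt` recording all parameters and the seed.

The same pipeline runs from the shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","peakshapes.R",package="peakShapes"))')" \
    -a peaks.bed -b reads.bam -c genome.chrom.sizes \
    --peak_correction --scale_max 10 --border_penalty --sm -o out/
```

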