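Package: peakShapes
Title: Evaluation and Shape Classification of Peak Profiles from Sequencing Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores predicted binding-site peaks (e.g. from CLIP-seq peak
    calling) by the coefficient of variation of a per-peak negative-binomial
    read-count model, separating specific from unspecific binding sites, and
    classifies peak coverage profiles into shape clusters by per-peak
    normalization, penalized spline smoothing, curve features, UMAP embedding
    and k-means with automatic selection of the number of clusters. Includes
    peak re-centering by Gaussian convolution, peak-length harmonization,
    strand-aware per-base coverage from BAM or BED reads, a synthetic
    profile/read simulator for self-contained testing, quality-control plots
    and a command-line entry point.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    GenomicAlignments,
    Rsamtools,
    mgcv,
    uwot,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    jsonlite
biocViews: Sequencing, Coverage, PeakDetection, QualityControl, Clustering
Config/testthat/edition: 3
RoxygenNote: 7.3.3
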