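# Independent oracles and small fixture builders used across the suite.

# O(reads x positions) per-base counter: the reference for computeCoverage.
bruteCoverage <- function(reads, peak, strandMode = "same") {
    ps <- GenomicRanges::start(peak); pe <- GenomicRanges::end(peak)
    pchr <- as.character(GenomeInfoDb::seqnames(peak))
    pstr <- as.character(GenomicRanges::strand(peak))
    d <- numeric(pe - ps + 1L)
    for (i in seq_along(reads)) {
        r <- reads[i]
        if (as.character(GenomeInfoDb::seqnames(r)) != pchr) next
        rstr <- as.character(GenomicRanges::strand(r))
        if (strandMode == "same" && pstr %in% c("+", "-") && rstr != pstr) next
        for (pos in seq(ps, pe)) {
            if (pos >= GenomicRanges::start(r) && pos <= GenomicRanges::end(r))
                d[pos - ps + 1L] <- d[pos - ps + 1L] + 1
        }
    }
    if (pstr == "-") d <- rev(d)
    d
}

# Exhaustive-offset convolution: reference for the gaussian centering signal.
convOracle <- function(x, halfwidth) {
    k <- exp(-seq(-halfwidth, halfwidth)^2 / (2 * (halfwidth / 3)^2))
    k <- k / sum(k)
    n <- length(x)
    xp <- c(numeric(halfwidth), x, numeric(halfwidth))
    vapply(seq_len(n), function(i) sum(xp[i:(i + 2 * halfwidth)] * k), numeric(1))
}

# Draws from NB in the trials-for-r-successes parameterization
# (mean r/p, variance r(1-p)/p^2).
rnbinomTrials <- function(n, r, p) stats::rnbinom(n, size = r, prob = p) + r

randomReadFixture <- function(seed) {
    set.seed(seed)
    nReads <- sample(1:5, 1)
    reads <- GenomicRanges::GRanges(
        "chrT",
        IRanges::IRanges(start = sample(1:60, nReads, replace = TRUE),
                         width = sample(3:15, nReads, replace = TRUE)),
        strand = sample(c("+", "-"), nReads, replace = TRUE))
    nPeaks <- sample(1:3, 1)
    peaks <- GenomicRanges::GRanges(
        "chrT",
        IRanges::IRanges(start = sample(1:50, nPeaks, replace = TRUE),
                         width = sample(5:20, nPeaks, replace = TRUE)),
        strand = sample(c("+", "-"), nPeaks, replace = TRUE),
        name = sprintf("p%d", seq_len(nPeaks)))
    list(reads = reads, peaks = peaks)
}

# Minimal evaluated experiment from a coverage matrix.
pseFromMatrix <- function(cov, strand = "+") {
    n <- nrow(cov); w <- ncol(cov)
    peaks <- GenomicRanges::GRanges(
        "chrT", IRanges::IRanges(start = seq_len(n) * (w + 10L), width = w),
        strand = strand, name = sprintf("p%d", seq_len(n)))
    peakShapeExperiment(cov, peaks)
}
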