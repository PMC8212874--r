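#' Shape families available from the profile simulator
#'
#' The first four are the canonical test families used to tune the
#' classification (uniform, linear, unimodal Gaussian, bimodal Gaussian);
#' `plateau`, `constant` and `sharp-spike` extend the taxonomy with the
#' shapes seen in real CLIP peak sets (broad plateaus, constant coverage,
#' near-delta spikes).
#'
#' @export
shapeFamilies <- c("uniform", "linear", "unimodal-gaussian",
                   "bimodal-gaussian", "plateau", "constant", "sharp-spike")

#' Expected (noise-free) depth curve of a shape family
#'
#' Unit-amplitude curve of the named family over `length` positions.
#' Bimodal modes sit at 1/4 and 3/4 of the window (separation = half the
#' window); the unimodal bell has sd 0.15 of the window, the spike 0.03.
#'
#' @param family one of [shapeFamilies].
#' @param length profile length in nt.
#' @return Numeric vector in `[0, 1]`.
#' @export
expectedCurve <- function(family = shapeFamilies, length = 77L) {
    family <- match.arg(family)
    x <- (seq_len(length) - 0.5) / length
    switch(family,
        "uniform" = ,
        "constant" = rep(1, length),
        "linear" = x,
        "unimodal-gaussian" = exp(-(x - 0.5)^2 / (2 * 0.15^2)),
        "bimodal-gaussian" = {
            y <- exp(-(x - 0.25)^2 / (2 * 0.08^2)) +
                 exp(-(x - 0.75)^2 / (2 * 0.08^2))
            y / max(y)
        },
        "plateau" = ifelse(x >= 0.2 & x <= 0.8, 1, 0.05),
        "sharp-spike" = exp(-(x - 0.5)^2 / (2 * 0.03^2)))
}

#' Simulate one coverage profile of a known shape
#'
#' Draws integer per-base depths around the expected curve of the family
#' with multiplicative log-normal noise (depths stay non-negative integers
#' after rounding), deterministic for a fixed seed.
#'
#' @param family one of [shapeFamilies].
#' @param length profile length in nt (default 77).
#' @param amplitude expected maximal depth (default 50).
#' @param noise relative sd of the multiplicative noise, in `[0, 1)`.
#' @param seed optional RNG seed.
#' @return Integer vector of depths with attribute `family`.
#' @examples
#' simulateProfile("unimodal-gaussian", noise = 0.05, seed = 1)
#' @export
simulateProfile <- function(family = shapeFamilies, length = 77L,
                            amplitude = 50, noise = 0, seed = NULL) {
    family <- match.arg(family)
    stopifnot(length >= 4L, amplitude >= 1, noise >= 0, noise < 1)
    if (!is.null(seed)) set.seed(seed)
    mu <- expectedCurve(family, length) * amplitude
    if (noise > 0) {
        sigma <- sqrt(log(1 + noise^2))       # log-normal with relative sd ~ noise
        mu <- mu * exp(stats::rnorm(length, -sigma^2 / 2, sigma))
    }
    depths <- as.integer(pmax(0, round(mu)))
    attr(depths, "family") <- family
    depths
}

#' Reads realizing a target coverage profile
#'
#' Builds a read stack whose per-base coverage over the peak window
#' reproduces the target depths: at each position, as many reads start as
#' are needed to raise the running coverage to the target.  The
#' reproduction is exact wherever the target is stack-feasible (never
#' decreasing faster than started reads can expire); reads may extend past
#' the window end.
#'
#' @param target integer vector of target depths (the peak profile, 5'->3'
#'   in genomic orientation — pass `rev()` for a minus-strand target).
#' @param readLength read length in nt (default 10).
#' @param chrom chromosome name for the emitted reads.
#' @param offset 0-based genomic start of the peak window.
#' @param strand strand of the emitted reads.
#' @return A [GenomicRanges::GRanges] of read intervals.
#' @examples
#' profileToReads(c(1, 2, 2, 1), readLength = 3)
#' @export
profileToReads <- function(target, readLength = 10L, chrom = "chrS",
                           offset = 0L, strand = "+") {
    stopifnot(readLength >= 1L, all(target >= 0))
    n <- length(target)
    starts <- integer(0)
    counts <- integer(0)
    diffBuf <- numeric(n + readLength + 1L)  # running coverage via difference array
    cov <- 0
    for (j in seq_len(n)) {
        cov <- cov + diffBuf[j]
        need <- target[j] - cov
        if (need > 0) {
            starts <- c(starts, j)
            counts <- c(counts, need)
            diffBuf[j + readLength] <- diffBuf[j + readLength] - need
            cov <- cov + need
        }
    }
    gstart <- offset + rep(starts, counts)       # 1-based: offset + j
    GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = gstart, width = readLength),
        strand = strand,
        name = sprintf("read_%d", seq_along(gstart)),
        score = rep(0, length(gstart)))
}

#' Write read intervals as BED6
#'
#' @param reads `GRanges` of reads.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeReadsBed <- function(reads, path) {
    strand <- as.character(GenomicRanges::strand(reads))
    strand[strand == "*"] <- "."
    nm <- if (!is.null(reads$name)) reads$name else sprintf("read_%d", seq_along(reads))
    tab <- data.frame(as.character(GenomeInfoDb::seqnames(reads)),
                      GenomicRanges::start(reads) - 1L,
                      GenomicRanges::end(reads),
                      nm, 0, strand)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write read intervals as a sorted, indexed BAM
#'
#' Emits a minimal single-end alignment per read (ungapped, MAPQ 255, no
#' sequence) via an intermediate SAM, then converts, sorts and indexes.
#'
#' @param reads `GRanges` of reads.
#' @param path output BAM path (a `.bai` index is written alongside).
#' @param seqinfo [GenomeInfoDb::Seqinfo] providing the target chromosomes.
#' @return The BAM path, invisibly.
#' @export
writeReadsBam <- function(reads, path, seqinfo) {
    sam <- tempfile(fileext = ".sam")
    on.exit(unlink(sam))
    sq <- sprintf("@SQ\tSN:%s\tLN:%d", GenomeInfoDb::seqnames(seqinfo),
                  GenomeInfoDb::seqlengths(seqinfo))
    ord <- order(as.character(GenomeInfoDb::seqnames(reads)),
                 GenomicRanges::start(reads))
    reads <- reads[ord]
    flag <- ifelse(as.character(GenomicRanges::strand(reads)) == "-", 16L, 0L)
    rec <- sprintf("read_%d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                   seq_along(reads), flag,
                   as.character(GenomeInfoDb::seqnames(reads)),
                   GenomicRanges::start(reads),
                   GenomicRanges::width(reads))
    writeLines(c("@HD\tVN:1.6\tSO:coordinate", sq, rec), sam)
    dest <- sub("\\.bam$", "", path, ignore.case = TRUE)
    Rsamtools::asBam(sam, destination = dest, overwrite = TRUE,
                     indexDestination = TRUE)
    invisible(paste0(dest, ".bam"))
}

#' Split reads into two pseudo-replicates
#'
#' Reproduces the replicate-robustness check: half of the reads (by
#' default) go to each pseudo-replicate.  Without replacement the two
#' halves are a disjoint partition of the input; with replacement each half
#' is an independent sample of size `round(fraction * n)`.
#'
#' @param reads `GRanges` (or any vector-like) of reads.
#' @param fraction fraction assigned to the first replicate, default 0.5.
#' @param withReplacement sample with replacement instead of partitioning.
#' @param seed RNG seed.
#' @return A list with elements `a` and `b`.
#' @export
splitPseudoReplicates <- function(reads, fraction = 0.5,
                                  withReplacement = FALSE, seed = NULL) {
    n <- length(reads)
    if (n < 2L) stop("need at least 2 reads to split")
    if (!is.null(seed)) set.seed(seed)
    nA <- round(fraction * n)
    if (withReplacement) {
        list(a = reads[sample.int(n, nA, replace = TRUE)],
             b = reads[sample.int(n, n - nA, replace = TRUE)])
    } else {
        idx <- sample.int(n, nA)
        list(a = reads[idx], b = reads[-idx])
    }
}

#' Generate a complete self-contained fixture data set
#'
#' Writes a peak BED6, a reads file (BED or BAM), a chrom.sizes table and a
#' truth manifest (peak name -> shape family) for a synthetic single
#' chromosome.  Peaks are laid out with generous gaps so that centering
#' flanks never touch a neighboring read stack.  The defaults are the
#' standard study conditions used throughout the test-suite: 77-nt peaks,
#' 50x expected depth, 5% multiplicative noise, 50 peaks per family for the
#' four canonical families.
#'
#' @param dir output directory (created if needed).
#' @param families shape families to include.
#' @param nPerFamily peaks per family.
#' @param peakLength,amplitude,noise see [simulateProfile()].
#' @param readLength read length for [profileToReads()].
#' @param format `"bed"` or `"bam"` reads output.
#' @param centerOffset shift (nt) applied to the written peak coordinates
#'   relative to the read stacks, to exercise peak correction.
#' @param seed RNG seed.
#' @return A list with `peaks`, `reads`, `chromSizes`, `labels` (paths) and
#'   `truth` (data.frame of peak name and family).
#' @export
simulateFixture <- function(dir = tempfile("fixture"),
                            families = shapeFamilies[1:4],
                            nPerFamily = 50L, peakLength = 77L,
                            amplitude = 50, noise = 0.05,
                            readLength = 10L, format = c("bed", "bam"),
                            centerOffset = 0L, seed = 1L) {
    format <- match.arg(format)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    set.seed(seed)
    nPeaks <- length(families) * nPerFamily
    gap <- 4L * peakLength
    starts0 <- gap + (seq_len(nPeaks) - 1L) * (peakLength + gap)  # 0-based
    chromLen <- starts0[nPeaks] + peakLength + gap
    fam <- rep(families, each = nPerFamily)
    ord <- sample.int(nPeaks)          # interleave families along the chromosome
    fam <- fam[ord]
    allReads <- list()
    for (i in seq_len(nPeaks)) {
        prof <- simulateProfile(fam[i], length = peakLength,
                                amplitude = amplitude, noise = noise)
        allReads[[i]] <- profileToReads(prof, readLength = readLength,
                                        chrom = "chrS", offset = starts0[i],
                                        strand = "+")
    }
    reads <- do.call(c, allReads)
    truth <- data.frame(name = sprintf("peak_%03d", seq_len(nPeaks)),
                        family = fam, stringsAsFactors = FALSE)
    peakStarts <- starts0 + as.integer(centerOffset)
    peaks <- data.frame("chrS", peakStarts, peakStarts + peakLength,
                        truth$name, 0, "+")
    paths <- list(
        peaks = file.path(dir, "peaks.bed"),
        chromSizes = file.path(dir, "chrS.chrom.sizes"),
        labels = file.path(dir, "labels.tsv"))
    utils::write.table(peaks, paths$peaks, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    writeLines(sprintf("chrS\t%d", chromLen), paths$chromSizes)
    utils::write.table(truth, paths$labels, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    si <- GenomeInfoDb::Seqinfo("chrS", chromLen)
    paths$reads <- if (format == "bam") {
        writeReadsBam(reads, file.path(dir, "reads.bam"), si)
    } else {
        writeReadsBed(reads, file.path(dir, "reads.bed"))
    }
    c(paths, list(truth = truth))
}
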