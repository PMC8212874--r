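#' Centering configuration
#'
#' Settings for the peak-correction step that re-centers mis-placed peaks on
#' their coverage signal before length harmonization.
#'
#' @param enabled run the correction at all.
#' @param scheme `"gaussian"` re-centers on the maximum of the coverage
#'   convolved with a Gaussian kernel (robust for spread-out signal);
#'   `"summit"` re-centers on the raw coverage maximum (appropriate for
#'   single-nucleotide events such as iCLIP truncations).
#' @param kernelHalfwidth half support of the Gaussian kernel in nt
#'   (sigma = halfwidth/3, truncated at +/- halfwidth, normalized to sum 1).
#'   `NULL` defaults to half the peak window at call time.
#' @param searchFlank how far (nt) the window may slide in either direction;
#'   `NULL` defaults to the peak length.
#' @return A list of class `centeringConfig`.
#' @export
centeringConfig <- function(enabled = TRUE,
                            scheme = c("gaussian", "summit"),
                            kernelHalfwidth = NULL,
                            searchFlank = NULL) {
    scheme <- match.arg(scheme)
    if (!is.null(kernelHalfwidth) && kernelHalfwidth < 1)
        stop("kernelHalfwidth must be >= 1")
    if (!is.null(searchFlank) && searchFlank < 0)
        stop("searchFlank must be >= 0")
    structure(list(enabled = enabled, scheme = scheme,
                   kernelHalfwidth = kernelHalfwidth,
                   searchFlank = searchFlank),
              class = "centeringConfig")
}

# Discrete Gaussian kernel on -h..h, sigma = h/3, sums to 1.
.gaussKernel <- function(halfwidth) {
    x <- seq(-halfwidth, halfwidth)
    k <- exp(-x^2 / (2 * (halfwidth / 3)^2))
    k / sum(k)
}

#' Centering shift of a peak from its extended coverage profile
#'
#' Given the coverage over the peak window plus `searchFlank` nt on each
#' side (5'->3' orientation), returns the signed shift (nt, in 5'->3'
#' profile coordinates) that moves the window onto the signal center:
#' either the argmax of a Gaussian-convolved profile (`"gaussian"`) or the
#' raw argmax (`"summit"`).  Ties take the left-most maximum; an all-zero
#' profile yields shift 0.
#'
#' @param extendedDepths numeric vector of depths over peak + flanks.
#' @param config a [centeringConfig()].
#' @param peakLength length of the peak window in nt; the flank on each side
#'   is `(length(extendedDepths) - peakLength) / 2`.
#' @return Integer shift in profile coordinates, clamped to the flank.
#' @export
centerShift <- function(extendedDepths, config = centeringConfig(),
                        peakLength = NULL) {
    n <- length(extendedDepths)
    if (is.null(peakLength)) peakLength <- n %/% 3L  # default flank = peak length
    flank <- (n - peakLength) %/% 2L
    if (all(extendedDepths == 0)) return(0L)
    signal <- if (config$scheme == "gaussian") {
        h <- config$kernelHalfwidth
        if (is.null(h)) h <- max(1L, peakLength %/% 2L)
        kern <- .gaussKernel(h)
        as.numeric(stats::filter(extendedDepths, kern, method = "convolution",
                                 sides = 2, circular = FALSE))
    } else {
        extendedDepths
    }
    signal[is.na(signal)] <- -Inf
    center <- (n + 1L) %/% 2L  # left-of-center position for even n
    shift <- which.max(signal) - center               # which.max: left-most tie
    maxShift <- if (!is.null(config$searchFlank)) min(flank, config$searchFlank)
                else flank
    as.integer(max(-maxShift, min(maxShift, shift)))
}

#' Apply a centering shift to peak coordinates
#'
#' Translates a peak by a 5'->3' profile shift, mapping it to genomic
#' coordinates with the correct sign for the strand (on the minus strand a
#' positive 5'->3' shift moves the peak to lower genomic coordinates), and
#' clamps the result to chromosome bounds by sliding (length preserved).
#'
#' @param peaks `GRanges` to shift.
#' @param shift integer vector of 5'->3' shifts, recycled to `length(peaks)`.
#' @param seqinfo optional [GenomeInfoDb::Seqinfo] for bounds clamping.
#' @return The shifted `GRanges`.
#' @export
applyShift <- function(peaks, shift, seqinfo = NULL) {
    shift <- rep_len(as.integer(shift), length(peaks))
    genShift <- ifelse(as.character(GenomicRanges::strand(peaks)) == "-",
                       -shift, shift)
    out <- GenomicRanges::shift(peaks, genShift)
    .clampSlide(out, seqinfo)
}

# Slide ranges back inside [1, seqlength] without changing width.
.clampSlide <- function(gr, seqinfo = NULL) {
    st <- GenomicRanges::start(gr)
    w <- GenomicRanges::width(gr)
    st <- pmax(st, 1L)
    if (!is.null(seqinfo)) {
        len <- GenomeInfoDb::seqlengths(seqinfo)[as.character(GenomeInfoDb::seqnames(gr))]
        st <- pmin(st, pmax(1L, len - w + 1L))
    }
    GenomicRanges::ranges(gr) <- IRanges::IRanges(start = st, width = w)
    gr
}

#' Harmonize all peaks to a common length
#'
#' Extends (or shrinks) every peak symmetrically about its midpoint to a
#' common target length, removing peak length as a feature before
#' evaluation and classification.  The default target is the maximal peak
#' length in the set.  An odd-length difference puts the extra nucleotide on
#' the 5' side of the peak (left on `+`/unstranded, right on `-`).  Windows
#' running over a chromosome edge slide inward; peaks on chromosomes shorter
#' than the target are dropped with a warning.
#'
#' @param peaks `GRanges`.
#' @param targetLength common length in nt, or `NULL` for the maximum
#'   observed peak length.
#' @param seqinfo optional [GenomeInfoDb::Seqinfo] for bounds handling.
#' @return `GRanges` in which every peak has width `targetLength`.
#' @export
harmonizeLength <- function(peaks, targetLength = NULL, seqinfo = NULL) {
    if (is.null(targetLength)) targetLength <- max(GenomicRanges::width(peaks))
    targetLength <- as.integer(targetLength)
    if (targetLength < 1L) stop("targetLength must be >= 1")
    if (!is.null(seqinfo)) {
        len <- GenomeInfoDb::seqlengths(seqinfo)[as.character(GenomeInfoDb::seqnames(peaks))]
        fits <- len >= targetLength
        if (any(!fits)) {
            warning(sum(!fits), " peak(s) on chromosomes shorter than the ",
                    "target length were dropped")
            peaks <- peaks[fits]
        }
    }
    diff <- targetLength - GenomicRanges::width(peaks)
    minus <- as.character(GenomicRanges::strand(peaks)) == "-"
    five <- ceiling(diff / 2)   # 5' side gets the odd remainder
    three <- floor(diff / 2)
    left <- ifelse(minus, three, five)
    right <- ifelse(minus, five, three)
    GenomicRanges::ranges(peaks) <- IRanges::IRanges(
        start = GenomicRanges::start(peaks) - as.integer(left),
        end = GenomicRanges::end(peaks) + as.integer(right))
    .clampSlide(peaks, seqinfo)
}

#' Center and harmonize a peak set
#'
#' The full peak-preparation stage: (1) optional re-centering of each peak
#' on its coverage signal ([centerShift()] over the peak plus one
#' search-flank each side, then [applyShift()]); (2) harmonization of all
#' peaks to a common length ([harmonizeLength()]); coverage is then
#' recomputed over the final windows by the caller.
#'
#' @param peaks `GRanges` of raw peaks.
#' @param reads reads source as in [computeCoverage()] (needed only when
#'   centering is enabled).
#' @param seqinfo [GenomeInfoDb::Seqinfo] for bounds handling.
#' @param centering a [centeringConfig()].
#' @param targetLength see [harmonizeLength()].
#' @param strandMode see [computeCoverage()].
#' @return `GRanges` of processed, equal-width peaks.
#' @export
preparePeaks <- function(peaks, reads = NULL, seqinfo = NULL,
                         centering = centeringConfig(),
                         targetLength = NULL,
                         strandMode = "same") {
    if (isTRUE(centering$enabled)) {
        if (is.null(reads)) stop("reads are required for peak centering")
        flanks <- if (!is.null(centering$searchFlank))
            rep_len(centering$searchFlank, length(peaks))
        else GenomicRanges::width(peaks)
        ext <- peaks
        GenomicRanges::ranges(ext) <- IRanges::IRanges(
            start = pmax(1L, GenomicRanges::start(peaks) - flanks),
            end = GenomicRanges::end(peaks) + flanks)
        if (!is.null(seqinfo)) {
            len <- GenomeInfoDb::seqlengths(seqinfo)[
                as.character(GenomeInfoDb::seqnames(ext))]
            GenomicRanges::end(ext) <- pmin(GenomicRanges::end(ext), len)
        }
        prof <- computeCoverage(reads, ext, strandMode = strandMode)
        shifts <- vapply(seq_along(peaks), function(i)
            centerShift(prof[[i]], centering,
                        peakLength = GenomicRanges::width(peaks)[i]),
            integer(1))
        peaks <- applyShift(peaks, shifts, seqinfo)
    }
    harmonizeLength(peaks, targetLength, seqinfo)
}
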