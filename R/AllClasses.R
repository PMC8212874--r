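#' PeakShapeExperiment: peaks, per-base coverage and shape results
#'
#' `PeakShapeExperiment` extends
#' [SummarizedExperiment::RangedSummarizedExperiment] to hold the state of a
#' peak-profile analysis: the (centered, length-harmonized) peaks as
#' `rowRanges`, one row per peak, and a `"coverage"` assay whose columns are
#' the per-nucleotide read depths across the harmonized window, oriented
#' 5'->3' on the peak strand.  Downstream steps add the `"normalized"` and
#' `"smoothed"` assays and fill `rowData` with the per-peak results:
#' coefficient of variation (`cv`), normalized CV (`cvNorm`), border-penalty
#' factor (`penaltyFactor`), specificity label (`label`; 0 = specific,
#' 1 = unspecific), curve features (`nMaxima`, `auc`, `arcLength`), the 2-D
#' embedding (`umap1`, `umap2`), the k-means cluster id (`cluster`) and the
#' sharp/broad flags (`sharpCluster`, `sharpPeak`).
#'
#' The original (pre-centering, pre-harmonization) coordinates are kept in
#' `rowData` columns `origChrom`, `origStart`, `origEnd` so that the final
#' table can report both.
#'
#' @slot .. see [SummarizedExperiment::RangedSummarizedExperiment]; no new
#'   slots are added, the class exists to carry validity and methods.
#'
#' @seealso [peakShapeExperiment()], [evaluatePeaks()], [classifyShapes()]
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @exportClass PeakShapeExperiment
setClass("PeakShapeExperiment", contains = "RangedSummarizedExperiment")

setValidity("PeakShapeExperiment", function(object) {
    msg <- NULL
    if (!"coverage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'coverage' is required")
    else {
        cov <- SummarizedExperiment::assay(object, "coverage")
        if (any(cov < 0, na.rm = TRUE))
            msg <- c(msg, "coverage depths must be non-negative")
    }
    w <- GenomicRanges::width(SummarizedExperiment::rowRanges(object))
    if (length(w) && length(unique(w)) > 1L)
        msg <- c(msg, "all peaks must have the same (harmonized) width")
    if (length(w) && ncol(object) && w[1L] != ncol(object))
        msg <- c(msg, "number of coverage columns must equal the peak width")
    if (is.null(msg)) TRUE else msg
})

#' Construct a PeakShapeExperiment
#'
#' Bundles a set of equal-width peaks with their per-base coverage profiles.
#'
#' @param coverage integer matrix, one row per peak, one column per
#'   nucleotide of the harmonized window (5'->3' on the peak strand).  A
#'   list of equal-length numeric vectors (as returned by
#'   [computeCoverage()]) is also accepted.
#' @param peaks a [GenomicRanges::GRanges] of the processed peaks, one per
#'   coverage row, all of identical width equal to `ncol(coverage)`.
#' @param originalPeaks optional `GRanges` with the coordinates the peaks had
#'   before centering/harmonization; stored in `rowData`.
#'
#' @return A [PeakShapeExperiment].
#' @examples
#' peaks <- GenomicRanges::GRanges("chrS", IRanges::IRanges(c(1, 101), width = 10),
#'                                 strand = "+")
#' cov <- matrix(rpois(20, 5), nrow = 2)
#' pse <- peakShapeExperiment(cov, peaks)
#' @export
peakShapeExperiment <- function(coverage, peaks, originalPeaks = NULL) {
    if (is.list(coverage)) {
        len <- lengths(coverage)
        if (length(unique(len)) > 1L)
            stop("coverage profiles must all have the same length; ",
                 "run harmonizeLength() first")
        coverage <- do.call(rbind, lapply(coverage, as.numeric))
    }
    coverage <- as.matrix(coverage)
    if (nrow(coverage) != length(peaks))
        stop("one coverage row per peak required: ", nrow(coverage),
             " rows vs ", length(peaks), " peaks")
    if (is.null(names(peaks))) {
        nm <- if (!is.null(peaks$name)) make.unique(as.character(peaks$name))
              else sprintf("peak_%d", seq_along(peaks))
        names(peaks) <- nm
    }
    rownames(coverage) <- names(peaks)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(coverage = coverage), rowRanges = peaks)
    if (!is.null(originalPeaks)) {
        stopifnot(length(originalPeaks) == length(peaks))
        SummarizedExperiment::rowData(se)$origChrom <-
            as.character(GenomeInfoDb::seqnames(originalPeaks))
        SummarizedExperiment::rowData(se)$origStart <-
            GenomicRanges::start(originalPeaks) - 1L  # back to 0-based BED
        SummarizedExperiment::rowData(se)$origEnd <-
            GenomicRanges::end(originalPeaks)
    }
    methods::new("PeakShapeExperiment", se)
}
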