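#' Run the full peak-shape analysis
#'
#' The end-to-end pipeline: read the inputs, re-center the peaks on their
#' coverage signal (optional), harmonize all peaks to a common length,
#' compute per-base coverage over the final windows, evaluate every peak by
#' the negative-binomial CV, classify the profiles into shape clusters, and
#' write the result table, the run manifest and the QC plots.
#'
#' @param peaksFile BED6 file of predicted peaks.
#' @param readsFile BAM (indexed or indexable) or BED file of the reads the
#'   peaks were called from.
#' @param chromSizesFile two-column chrom.sizes table.
#' @param outputDir directory for `results/final_table.tsv`, `plots/` and
#'   `run_manifest.txt`; `NULL` to skip all file output.
#' @param peakCorrection re-center peaks before harmonization.
#' @param maxTranslocate use the raw coverage maximum (summit) instead of
#'   the Gaussian-convolution center.
#' @param useBorderPenalty,scaleMax,threshold,thresholdBasis
#'   see [evaluatePeaks()].
#' @param peakLength harmonized window length; `NULL` for the maximum
#'   observed peak length.
#' @param smooth,smoothingFactor,kMax,kForced see [classifyShapes()].
#' @param classify run the shape classification at all (the evaluation-only
#'   mode skips UMAP/k-means).
#' @param strandMode see [computeCoverage()].
#' @param seed RNG seed for embedding and clustering.
#' @return The processed [PeakShapeExperiment], invisibly.
#' @examples
#' fx <- simulateFixture(nPerFamily = 3, noise = 0, seed = 7)
#' pse <- runPeakShapeAnalysis(fx$peaks, fx$reads, fx$chromSizes,
#'                             outputDir = NULL, classify = FALSE)
#' head(resultTable(pse))
#' @export
runPeakShapeAnalysis <- function(peaksFile, readsFile, chromSizesFile,
                                 outputDir = NULL,
                                 peakCorrection = FALSE,
                                 maxTranslocate = FALSE,
                                 useBorderPenalty = FALSE,
                                 scaleMax = NULL,
                                 threshold = 0.2,
                                 thresholdBasis = "normalized",
                                 peakLength = NULL,
                                 smooth = TRUE, smoothingFactor = 1,
                                 kMax = 15L, kForced = NULL,
                                 classify = TRUE,
                                 strandMode = "same",
                                 seed = 42L) {
    si <- readChromSizes(chromSizesFile)
    peaks <- readPeaks(peaksFile, seqinfo = si)
    original <- peaks
    centering <- centeringConfig(
        enabled = peakCorrection,
        scheme = if (maxTranslocate) "summit" else "gaussian")
    prepped <- preparePeaks(peaks, reads = readsFile, seqinfo = si,
                            centering = centering, targetLength = peakLength,
                            strandMode = strandMode)
    if (length(prepped) < length(original))
        original <- original[original$name %in% prepped$name]
    prof <- computeCoverage(readsFile, prepped, strandMode = strandMode)
    pse <- peakShapeExperiment(prof, prepped, originalPeaks = original)
    pse <- evaluatePeaks(pse, useBorderPenalty = useBorderPenalty,
                         scaleMax = scaleMax, threshold = threshold,
                         thresholdBasis = thresholdBasis)
    if (classify)
        pse <- classifyShapes(pse, smooth = smooth,
                              smoothingFactor = smoothingFactor,
                              kMax = kMax, kForced = kForced, seed = seed)
    if (!is.null(outputDir)) {
        resDir <- file.path(outputDir, "results")
        plotDir <- file.path(outputDir, "plots")
        dir.create(resDir, recursive = TRUE, showWarnings = FALSE)
        dir.create(plotDir, recursive = TRUE, showWarnings = FALSE)
        writeResultTable(pse, file.path(resDir, "final_table.tsv"))
        plotCVDistributions(pse, dir = plotDir)
        if (classify) {
            plotClusterPanels(pse, dir = plotDir)
            suppressMessages(plotKDiagnostics(pse, dir = plotDir))
        }
        manifest <- c(
            sprintf("peakShapes version: %s",
                    as.character(utils::packageVersion("peakShapes"))),
            sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
            sprintf("peaks: %s", peaksFile),
            sprintf("reads: %s", readsFile),
            sprintf("chrom_sizes: %s", chromSizesFile),
            sprintf("peak_correction: %s", peakCorrection),
            sprintf("max_translocate: %s", maxTranslocate),
            sprintf("border_penalty: %s", useBorderPenalty),
            sprintf("scale_max: %s", if (is.null(scaleMax)) "none" else scaleMax),
            sprintf("threshold: %s (%s)", threshold, thresholdBasis),
            sprintf("peak_length: %s",
                    if (is.null(peakLength)) "auto (max)" else peakLength),
            sprintf("smoothing: %s (factor %s)", smooth, smoothingFactor),
            sprintf("k_max: %s, k_forced: %s", kMax,
                    if (is.null(kForced)) "none" else kForced),
            sprintf("strand_mode: %s", strandMode),
            sprintf("seed: %d", seed))
        writeLines(manifest, file.path(outputDir, "run_manifest.txt"))
    }
    invisible(pse)
}
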