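#' @include AllClasses.R AllGenerics.R
NULL

#' Accessors for PeakShapeExperiment results
#'
#' @param x a [PeakShapeExperiment].
#' @param ... ignored.
#'
#' @return `peakCoverage` the coverage matrix (peaks x positions); `peakCV`
#'   the per-peak coefficient of variation; `normalizedCV` the min-max (or
#'   scale-max) normalized CV; `specificityLabel` integer 0 (specific) / 1
#'   (unspecific); `shapeCluster` the k-means cluster id; `embeddingCoords`
#'   the n x 2 UMAP coordinates; `sharpPeaks` logical per-peak sharp flag;
#'   `kSelection` the list of k-selection diagnostics (`wss`, `aic`, `k`,
#'   `kAic`, `forced`).  Accessors return `NULL` before the corresponding
#'   pipeline stage has run.
#'
#' @name PeakShapeExperiment-accessors
#' @aliases peakCoverage peakCV normalizedCV specificityLabel shapeCluster
#'   embeddingCoords sharpPeaks kSelection
NULL

.rd_col <- function(x, col) {
    rd <- SummarizedExperiment::rowData(x)
    if (col %in% colnames(rd)) rd[[col]] else NULL
}

#' @rdname PeakShapeExperiment-accessors
#' @export
setMethod("peakCoverage", "PeakShapeExperiment", function(x, ...)
    SummarizedExperiment::assay(x, "coverage"))

#' @rdname PeakShapeExperiment-accessors
#' @export
setMethod("peakCV", "PeakShapeExperiment", function(x, ...) .rd_col(x, "cv"))

#' @rdname PeakShapeExperiment-accessors
#' @export
setMethod("normalizedCV", "PeakShapeExperiment", function(x, ...)
    .rd_col(x, "cvNorm"))

#' @rdname PeakShapeExperiment-accessors
#' @export
setMethod("specificityLabel", "PeakShapeExperiment", function(x, ...)
    .rd_col(x, "label"))

#' @rdname PeakShapeExperiment-accessors
#' @export
setMethod("shapeCluster", "PeakShapeExperiment", function(x, ...)
    .rd_col(x, "cluster"))

#' @rdname PeakShapeExperiment-accessors
#' @export
setMethod("embeddingCoords", "PeakShapeExperiment", function(x, ...) {
    u1 <- .rd_col(x, "umap1")
    if (is.null(u1)) return(NULL)
    cbind(umap1 = u1, umap2 = .rd_col(x, "umap2"))
})

#' @rdname PeakShapeExperiment-accessors
#' @export
setMethod("sharpPeaks", "PeakShapeExperiment", function(x, ...)
    .rd_col(x, "sharpPeak"))

#' @rdname PeakShapeExperiment-accessors
#' @export
setMethod("kSelection", "PeakShapeExperiment", function(x, ...)
    S4Vectors::metadata(x)$kSelection)

#' @importMethodsFrom methods show
#' @exportMethods show
setMethod("show", "PeakShapeExperiment", function(object) {
    cat("class: PeakShapeExperiment\n")
    cat(sprintf("peaks: %d, window width: %d nt\n",
                nrow(object), ncol(object)))
    cat("assays:", paste(SummarizedExperiment::assayNames(object),
                         collapse = ", "), "\n")
    cv <- peakCV(object)
    if (!is.null(cv))
        cat(sprintf("CV: median %.3f, range [%.3f, %.3f]; %d/%d labeled specific\n",
                    stats::median(cv), min(cv), max(cv),
                    sum(specificityLabel(object) == 0L), length(cv)))
    cl <- shapeCluster(object)
    if (!is.null(cl)) {
        ks <- kSelection(object)
        cat(sprintf("shape clusters: k = %d%s; sharp peaks: %d\n",
                    length(unique(cl)),
                    if (isTRUE(ks$forced)) " (forced)" else " (selected)",
                    sum(sharpPeaks(object))))
    }
})
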