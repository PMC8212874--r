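#' Plot CV and normalized-CV distributions
#'
#' One histogram per sample for the raw CV and for the normalized CV — the
#' first-look quality control: an unspecific binder (or a good input
#' control) piles up near 0, a specific binder shows mass at higher CV.
#'
#' @param evaluations a named list of [PeakShapeExperiment]s (or a single
#'   one), each an evaluated sample.
#' @param dir output directory for `cv_distribution.(png|pdf)` and
#'   `cv_normalized_distribution.(png|pdf)`; `NULL` to skip writing.
#' @return Invisibly, a list of the two ggplot objects.
#' @export
plotCVDistributions <- function(evaluations, dir = NULL) {
    if (methods::is(evaluations, "PeakShapeExperiment"))
        evaluations <- list(sample = evaluations)
    if (!length(evaluations)) stop("at least one evaluated sample required")
    df <- do.call(rbind, lapply(names(evaluations), function(nm) {
        data.frame(sample = nm, cv = peakCV(evaluations[[nm]]),
                   cvNorm = normalizedCV(evaluations[[nm]]))
    }))
    pRaw <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cv)) +
        ggplot2::geom_histogram(bins = 30, fill = "steelblue", color = "grey20") +
        ggplot2::facet_wrap(~sample) +
        ggplot2::labs(x = "coefficient of variation (CV)", y = "peaks",
                      title = "CV distribution") +
        ggplot2::theme_bw()
    pNorm <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cvNorm)) +
        ggplot2::geom_histogram(bins = 30, fill = "darkorange", color = "grey20") +
        ggplot2::facet_wrap(~sample) +
        ggplot2::labs(x = "normalized CV", y = "peaks",
                      title = "Normalized CV distribution") +
        ggplot2::theme_bw()
    if (!is.null(dir)) {
        .savePlot(pRaw, file.path(dir, "cv_distribution"))
        .savePlot(pNorm, file.path(dir, "cv_normalized_distribution"))
    }
    invisible(list(cv = pRaw, cvNorm = pNorm))
}

.savePlot <- function(p, stem, width = 7, height = 5) {
    dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
    ggplot2::ggsave(paste0(stem, ".png"), p, width = width, height = height,
                    dpi = 150)
    ggplot2::ggsave(paste0(stem, ".pdf"), p, width = width, height = height)
    invisible(NULL)
}

#' Per-cluster profile panels
#'
#' For every shape cluster: up to `nExamples` raw (normalized) example
#' profiles, their smoothed versions, and the positionwise mean profile,
#' with the cluster size annotated — the plot used to eyeball what shape
#' each cluster represents.
#'
#' @param x a classified [PeakShapeExperiment].
#' @param nExamples examples per cluster (default 4; capped at the cluster
#'   size).
#' @param dir output directory for `cluster_profiles.(png|pdf)`; `NULL` to
#'   skip writing.
#' @return Invisibly, the ggplot object.
#' @export
plotClusterPanels <- function(x, nExamples = 4L, dir = NULL) {
    cl <- shapeCluster(x)
    if (is.null(cl)) stop("run classifyShapes() first")
    normMat <- SummarizedExperiment::assay(x, "normalized")
    smMat <- SummarizedExperiment::assay(x, "smoothed")
    pos <- seq_len(ncol(normMat))
    pieces <- list()
    for (k in sort(unique(cl))) {
        idx <- which(cl == k)
        ex <- idx[seq_len(min(nExamples, length(idx)))]
        for (i in ex) {
            pieces[[length(pieces) + 1L]] <- data.frame(
                cluster = sprintf("cluster %d (n=%d)", k, length(idx)),
                peak = rownames(normMat)[i], pos = pos, kind = "example",
                value = normMat[i, ])
            pieces[[length(pieces) + 1L]] <- data.frame(
                cluster = sprintf("cluster %d (n=%d)", k, length(idx)),
                peak = rownames(normMat)[i], pos = pos, kind = "smoothed",
                value = smMat[i, ])
        }
        pieces[[length(pieces) + 1L]] <- data.frame(
            cluster = sprintf("cluster %d (n=%d)", k, length(idx)),
            peak = "mean", pos = pos, kind = "mean",
            value = colMeans(normMat[idx, , drop = FALSE]))
    }
    df <- do.call(rbind, pieces)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$value,
                                          group = .data$peak,
                                          color = .data$kind)) +
        ggplot2::geom_line(alpha = 0.8) +
        ggplot2::facet_wrap(~cluster, scales = "free_y") +
        ggplot2::scale_color_manual(values = c(example = "grey60",
                                               smoothed = "steelblue",
                                               mean = "firebrick")) +
        ggplot2::labs(x = "position in peak window (nt)",
                      y = "normalized coverage",
                      title = "Peak profile clusters") +
        ggplot2::theme_bw()
    if (!is.null(dir)) .savePlot(p, file.path(dir, "cluster_profiles"),
                                 width = 9, height = 6)
    invisible(p)
}

#' k-selection and embedding diagnostics
#'
#' Plots the within-cluster sum of squares and AIC against k with the
#' chosen k marked, and the 2-D embedding colored by cluster.  Skipped
#' (with a message) when k was forced, in which case only the embedding
#' scatter is produced.
#'
#' @param x a classified [PeakShapeExperiment].
#' @param dir output directory for `k_optimization.(png|pdf)` and
#'   `embedding.(png|pdf)`; `NULL` to skip writing.
#' @return Invisibly, a list of ggplot objects (`kOpt` may be `NULL`).
#' @export
plotKDiagnostics <- function(x, dir = NULL) {
    ks <- kSelection(x)
    if (is.null(ks)) stop("run classifyShapes() first")
    coords <- embeddingCoords(x)
    dfE <- data.frame(umap1 = coords[, 1L], umap2 = coords[, 2L],
                      cluster = factor(shapeCluster(x)))
    pEmb <- ggplot2::ggplot(dfE, ggplot2::aes(x = .data$umap1, y = .data$umap2,
                                              color = .data$cluster)) +
        ggplot2::geom_point(size = 1.5) +
        ggplot2::labs(title = "UMAP embedding of peak profiles") +
        ggplot2::theme_bw()
    pK <- NULL
    if (isTRUE(ks$forced) || is.null(ks$wss)) {
        message("k was forced; skipping the k-optimization plot")
    } else {
        stopifnot(all(diff(ks$wss) <= 1e-8 * max(ks$wss[1L], 1)))  # WSS non-increasing
        dfK <- data.frame(k = rep(seq_along(ks$wss), 2L),
                          value = c(ks$wss, ks$aic),
                          criterion = rep(c("WSS", "AIC"),
                                          each = length(ks$wss)))
        pK <- ggplot2::ggplot(dfK, ggplot2::aes(x = .data$k, y = .data$value)) +
            ggplot2::geom_line() + ggplot2::geom_point() +
            ggplot2::geom_vline(xintercept = ks$k, linetype = "dashed",
                                color = "firebrick") +
            ggplot2::facet_wrap(~criterion, scales = "free_y") +
            ggplot2::labs(x = "number of clusters k", y = NULL,
                          title = sprintf("k-means optimization (chosen k = %d)",
                                          ks$k)) +
            ggplot2::theme_bw()
        if (!is.null(dir)) .savePlot(pK, file.path(dir, "k_optimization"))
    }
    if (!is.null(dir)) .savePlot(pEmb, file.path(dir, "embedding"))
    invisible(list(kOpt = pK, embedding = pEmb))
}
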