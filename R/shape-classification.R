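#' Min-max normalize a coverage profile
#'
#' Maps a peak profile onto `[0, 1]` with `(x - min) / (max - min)` so that
#' only the shape of the profile, not the read-count intensity, enters the
#' classification.  A constant profile (max == min, e.g. constant peaks)
#' maps to all zeros — an empty-looking but valid profile.
#'
#' @param depths numeric vector.
#' @return Numeric vector in `[0, 1]`, same length.
#' @examples
#' normalizeProfile(c(0, 5, 10))  # 0 0.5 1
#' @export
normalizeProfile <- function(depths) {
    if (!length(depths)) stop("depths must be non-empty")
    rng <- range(depths)
    if (rng[1L] == rng[2L]) return(rep(0, length(depths)))
    (depths - rng[1L]) / (rng[2L] - rng[1L])
}

#' Smooth a normalized profile with a penalized regression spline
#'
#' Fits a penalized cubic regression spline (generalized cross-validation
#' picks the penalty) to the profile and evaluates it at every nucleotide.
#' Smoothing removes sampling noise and spreads the data more evenly on the
#' manifold that the UMAP embedding assumes.  `smoothingFactor` multiplies
#' the effective degrees-of-freedom penalty: values > 1 underfit (fewer
#' apparent maxima, fewer clusters downstream), values < 1 overfit.
#'
#' @param profile numeric vector (typically from [normalizeProfile()]).
#' @param smoothingFactor positive multiplier of the GCV penalty; default 1.
#' @return Smoothed vector, clipped to be non-negative, same length.
#'   Profiles shorter than 4 nt are returned unsmoothed with a warning.
#' @export
smoothProfile <- function(profile, smoothingFactor = 1) {
    if (smoothingFactor <= 0) stop("smoothingFactor must be positive")
    n <- length(profile)
    if (n < 4L) {
        warning("profile of length ", n, " too short to smooth; returned as is")
        return(profile)
    }
    if (length(unique(profile)) == 1L) return(profile)  # splines keep constants
    x <- seq_len(n)
    k <- max(10L, min(n - 1L, n %/% 3L))
    fit <- mgcv::gam(profile ~ s(x, k = k, bs = "cr"), method = "GCV.Cp")
    if (smoothingFactor != 1) {
        # scale the GCV-chosen penalty: factor > 1 underfits, < 1 overfits
        fit <- mgcv::gam(profile ~ s(x, k = k, bs = "cr"),
                         sp = fit$sp * smoothingFactor^2)
    }
    pmax(0, as.numeric(stats::predict(fit, newdata = data.frame(x = x))))
}

#' Curve features of a smoothed profile
#'
#' The three shape descriptors added to the profile before embedding:
#' number of local maxima (a plateau run of equal values counts once;
#' boundary positions are eligible), area under the curve (trapezoidal rule,
#' unit spacing) and arc length `sum(sqrt(1 + diff(x)^2))`.
#'
#' @param profile numeric vector (smoothed profile).
#' @return Named numeric vector `c(nMaxima, auc, arcLength)`.
#' @examples
#' curveFeatures(c(0, 1, 0))  # 1 maximum, auc 1, arc length 2*sqrt(2)
#' @export
curveFeatures <- function(profile) {
    n <- length(profile)
    r <- rle(profile)
    v <- r$values
    m <- length(v)
    nmax <- 0L
    if (m == 1L) {
        # single run = flat profile: a positive plateau spanning the window
        # is one plateau maximum, an all-zero profile has none
        nmax <- if (v[1L] > 0) 1L else 0L
    } else {
        for (j in seq_len(m)) {
            leftLower <- j == 1L || v[j - 1L] < v[j]
            rightLower <- j == m || v[j + 1L] < v[j]
            if (leftLower && rightLower) nmax <- nmax + 1L
        }
    }
    auc <- if (n > 1L) sum((profile[-1L] + profile[-n]) / 2) else 0
    arc <- if (n > 1L) sum(sqrt(1 + diff(profile)^2)) else 0
    c(nMaxima = as.numeric(nmax), auc = auc, arcLength = arc)
}

#' Feature matrix for embedding
#'
#' One row per peak: the smoothed profile values concatenated with the three
#' z-scored curve features (z-scoring keeps the features commensurate with
#' the `[0, 1]` profile values; a zero-variance feature column becomes 0).
#'
#' @param profiles matrix (peaks x positions) of smoothed profiles, or list
#'   of equal-length vectors.
#' @param features optional precomputed feature matrix (peaks x 3); computed
#'   with [curveFeatures()] when `NULL`.
#' @return Numeric matrix with `ncol(profiles) + 3` columns.
#' @export
buildFeatureMatrix <- function(profiles, features = NULL) {
    if (is.list(profiles)) {
        if (length(unique(lengths(profiles))) > 1L)
            stop("profiles must all have the same length")
        profiles <- do.call(rbind, profiles)
    }
    profiles <- as.matrix(profiles)
    if (is.null(features))
        features <- t(apply(profiles, 1L, curveFeatures))
    if (nrow(features) != nrow(profiles))
        stop("one feature row per profile required")
    z <- scale(features)
    z[, attr(z, "scaled:scale") == 0] <- 0
    z[is.na(z)] <- 0
    unname(cbind(profiles, z))
}

#' 2-D UMAP embedding of the profile feature matrix
#'
#' Reduces the profile + feature matrix to two dimensions with UMAP using
#' 5000 epochs, 2 components, minimum distance 0.01 and a local
#' neighborhood of 5.  The run is seeded and single-threaded, so a fixed
#' seed reproduces coordinates exactly.  With fewer than 6 rows (the
#' neighborhood cannot be formed) the first two principal components are
#' returned with a warning.
#'
#' @param featureMatrix numeric matrix, one row per peak.
#' @param seed integer RNG seed.
#' @param nNeighbors,minDist,nEpochs UMAP hyperparameters; the defaults are
#'   the tool's operating point and rarely need changing.
#' @return Numeric matrix `n x 2` (columns `umap1`, `umap2`).
#' @export
embedProfiles <- function(featureMatrix, seed = 42L, nNeighbors = 5,
                          minDist = 0.01, nEpochs = 5000) {
    featureMatrix <- as.matrix(featureMatrix)
    n <- nrow(featureMatrix)
    if (n < 6L) {
        warning("fewer than 6 profiles; falling back to PCA for the embedding")
        pc <- stats::prcomp(featureMatrix, center = TRUE, scale. = FALSE)
        coords <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
        if (ncol(coords) < 2L) coords <- cbind(coords, 0)
    } else {
        coords <- uwot::umap(featureMatrix, n_neighbors = nNeighbors,
                             n_components = 2, min_dist = minDist,
                             n_epochs = nEpochs, seed = as.integer(seed),
                             n_threads = 1, n_sgd_threads = 1,
                             verbose = FALSE)
    }
    dimnames(coords) <- list(NULL, c("umap1", "umap2"))
    coords
}

#' k-means clustering of embedded profiles with automatic k selection
#'
#' Clusters the 2-D embedding with k-means (100 random initializations,
#' up to 10000 iterations).  When `kForced` is `NULL` the number of
#' clusters is chosen as the smallest k at which the total within-cluster
#' sum of squares has converged — the WSS drop from k to k+1 falls below
#' `tol` of the total sum of squares — and the Akaike information
#' criterion `AIC(k) = n*d*ln(WSS_k/(n*d)) + 2*k*d` (d = 2) is recorded as
#' a cross-check (`kAic`).
#'
#' @param coords numeric matrix `n x 2` from [embedProfiles()].
#' @param kMax upper bound for the cluster search (default 15).
#' @param kForced exact number of clusters, overriding selection.
#' @param seed RNG seed for the k-means initializations.
#' @param tol convergence tolerance for the relative WSS decrease
#'   (fraction of total SS), default 0.05.
#' @return A list: `labels` (integer cluster per row), `k`, `wss` (by k),
#'   `aic` (by k), `kAic`, `forced`.
#' @export
clusterProfiles <- function(coords, kMax = 15L, kForced = NULL, seed = 42L,
                            tol = 0.05) {
    coords <- as.matrix(coords)
    n <- nrow(coords)
    d <- ncol(coords)
    nDistinct <- nrow(unique(coords))
    if (!is.null(kForced)) {
        if (kForced > n) stop("kForced exceeds the number of profiles")
        set.seed(seed)
        km <- .kmeansSafe(coords, kForced, nDistinct)
        return(list(labels = km$cluster, k = as.integer(kForced),
                    wss = NULL, aic = NULL, kAic = NULL, forced = TRUE))
    }
    kMax <- min(kMax, n)
    wss <- numeric(kMax); fits <- vector("list", kMax)
    set.seed(seed)
    for (k in seq_len(kMax)) {
        fits[[k]] <- .kmeansSafe(coords, k, nDistinct)
        wss[k] <- fits[[k]]$tot.withinss
    }
    totss <- wss[1L]
    aic <- n * d * log(pmax(wss, .Machine$double.eps) / (n * d)) +
        2 * d * seq_len(kMax)
    kSel <- kMax
    if (totss <= .Machine$double.eps) {
        kSel <- 1L
    } else {
        for (k in seq_len(kMax - 1L)) {
            if ((wss[k] - wss[k + 1L]) / totss < tol) { kSel <- k; break }
        }
    }
    list(labels = fits[[kSel]]$cluster, k = as.integer(kSel),
         wss = wss, aic = aic, kAic = which.min(aic), forced = FALSE)
}

# kmeans with nstart=100/iter.max=10000, capping k at the number of
# distinct points (duplicated rows otherwise break initialization).
.kmeansSafe <- function(coords, k, nDistinct) {
    k2 <- min(k, nDistinct)
    if (k2 >= nrow(coords)) {
        # one point per cluster: kmeans proper rejects k == n
        return(list(cluster = seq_len(nrow(coords)), tot.withinss = 0))
    }
    suppressWarnings(
        stats::kmeans(coords, centers = k2, nstart = 100, iter.max = 10000))
}

#' Sharp/broad flags for clusters and peaks
#'
#' A cluster is sharp when its median CV exceeds the median CV of the whole
#' peak set (strict inequality, so a single cluster is never sharp).  A peak
#' is sharp when its CV exceeds `cvThreshold` (default 0.2) *and* it falls
#' in a sharp cluster; all other peaks are broad.
#'
#' @param labels integer cluster id per peak.
#' @param cvs CV per peak (same order).
#' @param cvThreshold the CV cut-off in the conjunction, default 0.2.
#' @return A list: `sharpCluster` (logical per peak, whether its cluster is
#'   sharp), `sharpPeak` (logical per peak), `clusterMedians` (named by
#'   cluster id), `globalMedian`.
#' @export
flagSharp <- function(labels, cvs, cvThreshold = 0.2) {
    stopifnot(length(labels) == length(cvs))
    globalMed <- stats::median(cvs)
    meds <- tapply(cvs, labels, stats::median)
    clSharp <- meds > globalMed
    sharpCluster <- as.vector(clSharp[as.character(labels)])
    sharpPeak <- sharpCluster & cvs > cvThreshold
    list(sharpCluster = sharpCluster, sharpPeak = sharpPeak,
         clusterMedians = meds, globalMedian = globalMed)
}

#' Classify the peak profiles of a PeakShapeExperiment
#'
#' The full shape-classification stage: per-peak min-max normalization,
#' optional spline smoothing, curve features, UMAP embedding, k-means with
#' automatic (or forced) k and the sharp/broad rule.  Adds assays
#' `"normalized"` and `"smoothed"` and fills the classification columns of
#' `rowData`.
#'
#' @param x a [PeakShapeExperiment], evaluated with [evaluatePeaks()] (the
#'   sharp/broad rule needs CVs; without them only clustering is done).
#' @param smooth smooth the normalized profiles before featurization
#'   (recommended).
#' @param smoothingFactor see [smoothProfile()].
#' @param kMax,kForced,seed see [clusterProfiles()] and [embedProfiles()].
#' @param cvThreshold see [flagSharp()].
#' @return `x` with classification results filled in.
#' @export
classifyShapes <- function(x, smooth = TRUE, smoothingFactor = 1,
                           kMax = 15L, kForced = NULL, seed = 42L,
                           cvThreshold = 0.2) {
    cov <- peakCoverage(x)
    normMat <- t(apply(cov, 1L, normalizeProfile))
    smMat <- if (smooth)
        t(apply(normMat, 1L, smoothProfile, smoothingFactor = smoothingFactor))
    else normMat
    feats <- t(apply(smMat, 1L, curveFeatures))
    fm <- buildFeatureMatrix(smMat, feats)
    coords <- embedProfiles(fm, seed = seed)
    cl <- clusterProfiles(coords, kMax = kMax, kForced = kForced, seed = seed)
    SummarizedExperiment::assays(x)[["normalized"]] <- normMat
    SummarizedExperiment::assays(x)[["smoothed"]] <- smMat
    rd <- SummarizedExperiment::rowData(x)
    rd$nMaxima <- feats[, "nMaxima"]
    rd$auc <- feats[, "auc"]
    rd$arcLength <- feats[, "arcLength"]
    rd$umap1 <- coords[, 1L]
    rd$umap2 <- coords[, 2L]
    rd$cluster <- cl$labels
    cvs <- rd$cv
    if (!is.null(cvs)) {
        fs <- flagSharp(cl$labels, cvs, cvThreshold)
        rd$sharpCluster <- fs$sharpCluster
        rd$sharpPeak <- fs$sharpPeak
    }
    SummarizedExperiment::rowData(x) <- rd
    md <- S4Vectors::metadata(x)
    md$kSelection <- cl[c("k", "wss", "aic", "kAic", "forced")]
    md$classification <- list(smooth = smooth,
                              smoothingFactor = smoothingFactor,
                              kMax = kMax, kForced = kForced, seed = seed)
    S4Vectors::metadata(x) <- md
    x
}
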