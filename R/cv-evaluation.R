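#' Negative-binomial model of a peak's read counts
#'
#' Fits a negative binomial NB(r, p) to the per-nucleotide depths of one
#' peak by moment matching, in the "number of trials to reach r successes"
#' parameterization: mean m = r/p, variance v = r(1-p)/p^2, giving
#' p = m/(v + m) and r = m^2/(v + m).  Under this estimator the NB
#' coefficient of variation sqrt((1-p)/r) reduces algebraically to the
#' empirical sd/mean of the depths.
#'
#' Degenerate cases: an all-zero profile returns (r = 0, p = 1); a
#' zero-variance positive profile returns (r = m, p = 1).  Both yield CV 0.
#' Underdispersed profiles (v < m) need no special case: p stays in (0, 1]
#' and the sd/mean identity still holds.
#'
#' @param depths non-empty numeric vector of non-negative per-base depths.
#' @return A list with components `r`, `p`, `mean`, `var`.
#' @examples
#' estimateNB(c(8, 12, 10, 9, 11))
#' @export
estimateNB <- function(depths) {
    if (!length(depths)) stop("depths must be non-empty")
    m <- mean(depths)
    v <- stats::var(depths)
    if (length(depths) == 1L) v <- 0
    if (m == 0) return(list(r = 0, p = 1, mean = m, var = v))
    if (v == 0) return(list(r = m, p = 1, mean = m, var = v))
    list(r = m^2 / (v + m), p = m / (v + m), mean = m, var = v)
}

#' Coefficient of variation of a fitted negative binomial
#'
#' CV = sqrt((1 - p)/r).  Zero-variance fits (p = 1, including the all-zero
#' profile fallback r = 0) score 0.  High CV indicates a sharp, specific
#' profile; CV near 0 a broad, unspecific one.
#'
#' @param est a fit from [estimateNB()], or a list/vector with `r` and `p`.
#' @return Non-negative numeric scalar.
#' @examples
#' cvScore(list(r = 4, p = 0.5))  # sqrt(0.125)
#' @export
cvScore <- function(est) {
    r <- est$r; p <- est$p
    if (p >= 1 || r == 0) return(0)
    sqrt((1 - p) / r)
}

#' Border penalty for peaks riding the edge of a read stack
#'
#' Down-weights the CV of windows that cover only the appendage of a broad
#' read stack, i.e. whose coverage is high at the window borders relative
#' to the profile maximum.  The factor is
#' `1 - min(1, (d_first + d_last) / (2 * d_max))`: 1 for a profile falling
#' to zero at both borders (no penalty), 0 for a flat plateau.
#'
#' @param cv the raw CV of the peak.
#' @param depths the per-base depths the CV was computed from.
#' @return A list with `cv` (penalized) and `factor` (in `[0, 1]`).
#' @examples
#' borderPenalty(1.2, c(0, 2, 8, 2, 0))  # factor 1
#' borderPenalty(1.2, c(4, 6, 8, 6, 2))  # factor 0.625
#' @export
borderPenalty <- function(cv, depths) {
    dmax <- max(depths)
    ratio <- if (dmax == 0) 0 else (depths[1L] + depths[length(depths)]) / (2 * dmax)
    fac <- 1 - min(1, ratio)
    list(cv = cv * fac, factor = fac)
}

#' Normalize CV scores to [0, 1]
#'
#' Default mode rescales by the minimum and maximum of the score set,
#' `(CV - min) / (max - min)`, so the broadest peak maps to 0 and the
#' sharpest to 1.  With `scaleMax = s` the scores are instead capped and
#' divided, `min(CV, s)/s`, which keeps the normalization comparable across
#' experiments with different peak sizes and read totals.
#'
#' @param cvs numeric vector of non-negative CV scores.
#' @param scaleMax positive cap, or `NULL` for min-max normalization.
#' @return Numeric vector in `[0, 1]`; an all-equal input maps to all 0 in
#'   min-max mode.
#' @examples
#' normalizeCV(c(0, 1, 2))                 # 0, 0.5, 1
#' normalizeCV(c(1, 5, 20), scaleMax = 10) # 0.1, 0.5, 1
#' @export
normalizeCV <- function(cvs, scaleMax = NULL) {
    if (!length(cvs)) stop("at least one CV required")
    if (!is.null(scaleMax)) {
        if (scaleMax <= 0) stop("scaleMax must be positive")
        return(pmin(cvs, scaleMax) / scaleMax)
    }
    rng <- range(cvs)
    if (rng[1L] == rng[2L]) return(rep(0, length(cvs)))
    (cvs - rng[1L]) / (rng[2L] - rng[1L])
}

#' Label peaks specific (0) or unspecific (1)
#'
#' Applies the empirical specificity threshold (default 0.2): scores below
#' the threshold are labeled 1 (unspecific), scores at or above it 0
#' (specific).  By default the threshold is applied to the normalized CV;
#' `basis = "raw"` applies it to the raw CV instead.
#'
#' @param scores CV scores on the chosen basis.
#' @param threshold cut-off, default 0.2.
#' @param basis `"normalized"` or `"raw"`; on the normalized basis a
#'   threshold outside (0, 1) triggers a warning.
#' @return Integer vector of 0/1 labels.
#' @examples
#' labelSpecificity(c(0.19, 0.2, 1.0))  # 1 0 0
#' @export
labelSpecificity <- function(scores, threshold = 0.2,
                             basis = c("normalized", "raw")) {
    basis <- match.arg(basis)
    if (basis == "normalized" && (threshold <= 0 || threshold >= 1))
        warning("threshold ", threshold, " lies outside (0, 1) on the ",
                "normalized basis")
    as.integer(scores < threshold)
}

#' Compare two CV distributions
#'
#' Wilcoxon rank-sum (Mann-Whitney) test between the CV distributions of two
#' samples (e.g. CLIP replicate vs size-matched input control, or two
#' pseudo-replicates).  Uses the exact distribution for small untied samples
#' and the normal approximation with tie correction otherwise.
#'
#' @param cvsA,cvsB numeric vectors of CV scores.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (alternative: A shifted relative to B).
#' @return The p-value.
#' @export
compareCVDistributions <- function(cvsA, cvsB,
                                   alternative = c("two.sided", "greater", "less")) {
    alternative <- match.arg(alternative)
    if (!length(cvsA) || !length(cvsB)) stop("both samples must be non-empty")
    pooled <- c(cvsA, cvsB)
    if (length(unique(pooled)) == 1L) {
        warning("all pooled values identical; p-value = 1")
        return(1)
    }
    suppressWarnings(
        stats::wilcox.test(cvsA, cvsB, alternative = alternative)$p.value)
}

#' Evaluate all peaks of a PeakShapeExperiment
#'
#' Runs the full CV evaluation over every coverage profile: NB moment fit,
#' CV score, optional border penalty, normalization across the peak set and
#' specificity labeling.  Results land in `rowData(x)` (`cv`, `cvNorm`,
#' `penaltyFactor`, `label`).
#'
#' @param x a [PeakShapeExperiment].
#' @param useBorderPenalty apply [borderPenalty()] to each raw CV.
#' @param scaleMax see [normalizeCV()].
#' @param threshold,thresholdBasis see [labelSpecificity()].
#' @return `x` with evaluation columns filled in.
#' @export
evaluatePeaks <- function(x, useBorderPenalty = FALSE, scaleMax = NULL,
                          threshold = 0.2,
                          thresholdBasis = c("normalized", "raw")) {
    thresholdBasis <- match.arg(thresholdBasis)
    cov <- peakCoverage(x)
    cvs <- numeric(nrow(cov)); fac <- rep(1, nrow(cov))
    for (i in seq_len(nrow(cov))) {
        d <- cov[i, ]
        cv <- cvScore(estimateNB(d))
        if (useBorderPenalty) {
            bp <- borderPenalty(cv, d)
            cv <- bp$cv; fac[i] <- bp$factor
        }
        cvs[i] <- cv
    }
    cvn <- normalizeCV(cvs, scaleMax = scaleMax)
    basisScores <- if (thresholdBasis == "normalized") cvn else cvs
    rd <- SummarizedExperiment::rowData(x)
    rd$cv <- cvs
    rd$cvNorm <- cvn
    rd$penaltyFactor <- fac
    rd$label <- labelSpecificity(basisScores, threshold, thresholdBasis)
    SummarizedExperiment::rowData(x) <- rd
    md <- S4Vectors::metadata(x)
    md$evaluation <- list(borderPenalty = useBorderPenalty, scaleMax = scaleMax,
                          threshold = threshold, thresholdBasis = thresholdBasis)
    S4Vectors::metadata(x) <- md
    x
}
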