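test_that("profile normalization maps onto [0,1] and zeroes constants", {
    expect_equal(normalizeProfile(c(0, 5, 10)), c(0, 0.5, 1))
    expect_equal(normalizeProfile(c(7, 7, 7)), c(0, 0, 0))
    v <- c(0, 0.25, 1, 0.5)
    expect_equal(normalizeProfile(v), v)   # already spans [0,1]
})

test_that("spline smoothing preserves constants and tracks smooth curves", {
    expect_equal(smoothProfile(rep(0.4, 20)), rep(0.4, 20))
    expect_warning(out <- smoothProfile(c(1, 2, 3)), "too short")
    expect_equal(out, c(1, 2, 3))
    # noiseless unimodal bell sampled at 77 points is reproduced closely
    y <- expectedCurve("unimodal-gaussian", 77)
    sm <- smoothProfile(y)
    expect_lt(max(abs(sm - y)), 0.02)
    expect_true(all(sm >= 0))
})

test_that("a larger smoothing factor underfits a bimodal profile", {
    set.seed(4)
    y <- pmax(0, expectedCurve("bimodal-gaussian", 77) + rnorm(77, 0, 0.05))
    nm1 <- curveFeatures(smoothProfile(y, 1))["nMaxima"]
    nm10 <- curveFeatures(smoothProfile(y, 10))["nMaxima"]
    expect_equal(unname(nm1), 2)
    expect_lte(nm10, nm1)
})

test_that("curve features match hand geometry", {
    expect_equal(unname(curveFeatures(numeric(9))), c(0, 0, 8))
    expect_equal(unname(curveFeatures(c(0, 1, 0))), c(1, 1, 2 * sqrt(2)))
    two <- c(0, 1, 0, 0, 1, 0)
    expect_equal(unname(curveFeatures(two))[1], 2)
    # plateau run of equal values counts once; boundary maxima are eligible
    expect_equal(unname(curveFeatures(c(0, 2, 2, 2, 0)))[1], 1)
    expect_equal(unname(curveFeatures(c(5, 1, 0, 1, 5)))[1], 2)
})

test_that("the feature matrix has profile+3 columns with standardized features", {
    set.seed(9)
    profs <- matrix(runif(10 * 77), nrow = 10)
    fm <- buildFeatureMatrix(profs)
    expect_equal(dim(fm), c(10L, 80L))
    featCols <- fm[, 78:80]
    expect_true(all(abs(colMeans(featCols)) < 1e-10))
    perm <- sample(10)
    expect_equal(buildFeatureMatrix(profs[perm, ]), fm[perm, ])
})

test_that("the embedding is deterministic and separates distinct shape families", {
    set.seed(30)
    sharp <- t(replicate(50, as.numeric(simulateProfile("sharp-spike", 50, 40, 0.05))))
    flat <- t(replicate(50, as.numeric(simulateProfile("uniform", 50, 40, 0.05))))
    mat <- rbind(sharp, flat)
    normMat <- t(apply(mat, 1, normalizeProfile))
    fm <- buildFeatureMatrix(normMat)
    co1 <- embedProfiles(fm, seed = 5)
    co2 <- embedProfiles(fm, seed = 5)
    expect_identical(co1, co2)
    fams <- rep(c("sharp", "flat"), each = 50)
    cent <- rbind(colMeans(co1[fams == "sharp", ]),
                  colMeans(co1[fams == "flat", ]))
    between <- sqrt(sum((cent[1, ] - cent[2, ])^2))
    within <- mean(c(
        sqrt(rowSums(sweep(co1[fams == "sharp", ], 2, cent[1, ])^2)),
        sqrt(rowSums(sweep(co1[fams == "flat", ], 2, cent[2, ])^2))))
    expect_gt(between, within)
    # duplicated rows land next to each other
    dup <- rbind(fm, fm[1, , drop = FALSE])
    cod <- embedProfiles(dup, seed = 5)
    dDup <- sqrt(sum((cod[1, ] - cod[101, ])^2))
    expect_lt(dDup, stats::median(sqrt(rowSums(sweep(cod, 2, colMeans(cod))^2))))
})

test_that("tiny inputs fall back to principal components", {
    m <- matrix(rnorm(5 * 8), nrow = 5)
    expect_warning(co <- embedProfiles(m, seed = 1), "PCA")
    expect_equal(dim(co), c(5L, 2L))
})

test_that("k-means selection recovers well-separated blobs", {
    set.seed(8)
    centers <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10), ncol = 2, byrow = TRUE)
    coords <- do.call(rbind, lapply(1:4, function(i)
        cbind(rnorm(30, centers[i, 1], 0.3), rnorm(30, centers[i, 2], 0.3))))
    truth <- rep(1:4, each = 30)
    cl <- clusterProfiles(coords, kMax = 10, seed = 2)
    expect_equal(cl$k, 4L)
    expect_false(cl$forced)
    expect_true(all(diff(cl$wss) <= 1e-8))      # WSS non-increasing in k
    tab <- table(cl$labels, truth)
    expect_equal(sum(apply(tab, 2, max)), 120)  # perfect up to label permutation
    # forced k overrides selection
    clF <- clusterProfiles(coords, kForced = 3, seed = 2)
    expect_equal(clF$k, 3L)
    expect_equal(length(unique(clF$labels)), 3L)
    expect_true(clF$forced)
    # n = k: one point per cluster, zero WSS
    clN <- clusterProfiles(coords[1:5, ], kForced = 5, seed = 2)
    expect_equal(sort(unique(clN$labels)), 1:5)
    expect_error(clusterProfiles(coords[1:3, ], kForced = 5), "exceeds")
})

test_that("sharp/broad rule combines cluster medians with the CV threshold", {
    # single cluster: cluster median equals the global median, never sharp
    fs1 <- flagSharp(rep(1L, 10), runif(10, 0.5, 2))
    expect_false(any(fs1$sharpCluster))
    expect_false(any(fs1$sharpPeak))
    # two well separated CV clusters
    labels <- rep(c(1L, 2L), each = 10)
    cvs <- c(rep(0.05, 10), rep(1.0, 10))
    fs2 <- flagSharp(labels, cvs)
    expect_equal(unname(fs2$sharpCluster), labels == 2L)
    expect_equal(unname(fs2$sharpPeak), labels == 2L)
    # low-CV peak inside a sharp cluster stays broad
    cvs3 <- cvs; cvs3[20] <- 0.1
    fs3 <- flagSharp(labels, cvs3)
    expect_true(fs3$sharpCluster[20])
    expect_false(fs3$sharpPeak[20])
})

test_that("classification is invariant to profile amplitude", {
    set.seed(14)
    base <- t(vapply(rep(shapeFamilies[c(3, 4, 7)], each = 4),
                     function(f) as.numeric(simulateProfile(f, 41, 30, 0.05)),
                     numeric(41)))
    scaled <- base
    scaled[3, ] <- base[3, ] * 5   # same shape, 5x the depth
    n1 <- t(apply(base, 1, normalizeProfile))
    n2 <- t(apply(scaled, 1, normalizeProfile))
    expect_equal(n1, n2)
    expect_equal(curveFeatures(smoothProfile(n1[3, ])),
                 curveFeatures(smoothProfile(n2[3, ])))
})

test_that("classifyShapes fills assays, features, embedding and flags", {
    set.seed(2)
    fams <- rep(c("sharp-spike", "uniform"), each = 8)
    cov <- t(vapply(fams, function(f) as.numeric(simulateProfile(f, 41, 40, 0.05)),
                    numeric(41)))
    pse <- evaluatePeaks(pseFromMatrix(cov))
    pse <- classifyShapes(pse, kForced = 2, seed = 42)
    expect_true(all(c("normalized", "smoothed") %in%
                    SummarizedExperiment::assayNames(pse)))
    expect_equal(dim(embeddingCoords(pse)), c(16L, 2L))
    expect_true(all(shapeCluster(pse) %in% 1:2))
    # spikes have high CV, flat profiles near 0: spikes are the sharp ones
    expect_true(all(sharpPeaks(pse)[fams == "sharp-spike"]))
    expect_false(any(sharpPeaks(pse)[fams == "uniform"]))
    expect_identical(kSelection(pse)$forced, TRUE)
})
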