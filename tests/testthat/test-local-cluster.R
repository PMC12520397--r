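test_that("center seeding averages contiguous windows of the sample order", {
    set.seed(1)
    Z <- cbind(rnorm(100), rnorm(100))
    init <- initCenters(Z, 4)
    expect_equal(init$centers[1, ], colMeans(Z[1:25, ]))
    expect_equal(init$centers[2, ], colMeans(Z[26:50, ]))
    expect_equal(init$centers[4, ], colMeans(Z[76:100, ]))
    expect_equal(init$labels, rep(1:4, each = 25))

    # tail samples are appended to the last window
    Z7 <- cbind(seq_len(7), 0)
    i3 <- initCenters(Z7, 3)
    expect_equal(i3$labels, c(1L, 1L, 2L, 2L, 3L, 3L, 3L))
    expect_equal(i3$centers[3, 1], mean(5:7))

    expect_equal(initCenters(Z, 1)$centers[1, ], colMeans(Z))
    expect_equal(initCenters(Z, 100)$centers, Z)  # one sample per center
    expect_error(initCenters(Z, 101), "\\[1, n\\]")
})

test_that("label assignment searches a bounded center window", {
    centers <- rbind(c(0, 0), c(10, 0))
    Z <- rbind(c(1, 0), c(6, 0), c(9, 0))
    labs <- assignLabels(Z, centers, labels = c(1L, 1L, 2L), r = 1)
    expect_equal(labs, c(1L, 2L, 2L))
    # r >= k equals global nearest-center assignment
    set.seed(2)
    Zr <- cbind(rnorm(50), rnorm(50))
    cen <- rbind(c(-1, 0), c(0, 0), c(1, 0))
    global <- apply(Zr, 1, function(z)
        which.min(colSums((t(cen) - z)^2)))
    expect_equal(assignLabels(Zr, cen, rep(2L, 50), r = 3), global)
    # a sample sitting on its center stays put
    expect_equal(assignLabels(rbind(c(10, 0)), centers, 2L, r = 1), 2L)
})

test_that("center updates are member means and empty clusters persist", {
    Z <- rbind(c(0, 0), c(2, 2), c(5, 5))
    prev <- rbind(c(9, 9), c(8, 8))
    cen <- updateCenters(Z, c(1L, 1L, 1L), 2L, prev)
    expect_equal(cen[1, ], colMeans(Z))
    expect_equal(cen[2, ], c(8, 8))     # empty cluster keeps its center
    cen2 <- updateCenters(rbind(c(0, 0), c(2, 2)), c(1L, 1L), 1L, prev[1, , drop = FALSE])
    expect_equal(cen2[1, ], c(1, 1))
})

test_that("clustering converges to a local fixed point on separated blobs", {
    set.seed(5)
    Z <- rbind(matrix(rnorm(400, -3, 0.3), ncol = 2),
               matrix(rnorm(400, 3, 0.3), ncol = 2))
    st <- suppressWarnings(localCluster(Z, k = 2, r = 1))
    expect_true(st@converged)
    expect_lt(max(abs(st@centers[1, ] - colMeans(Z[st@labels == 1, ]))), 1e-12)
    # centers land on the blob means
    blobMeans <- rbind(colMeans(Z[1:200, ]), colMeans(Z[201:400, ]))
    expect_lt(max(abs(st@centers - blobMeans)), 0.05)

    # fixed point: another update round moves nothing
    cen2 <- updateCenters(Z, assignLabels(Z, st@centers, st@labels, st@r),
        st@k, st@centers)
    expect_lt(max(abs(cen2 - st@centers)), 1e-12)

    # post-convergence local optimality within the +/- r window
    labs <- st@labels
    for (off in -st@r:st@r) {
        cand <- pmin(pmax(labs + off, 1L), st@k)
        dNow <- rowSums((Z - st@centers[labs, ])^2)
        dCand <- rowSums((Z - st@centers[cand, ])^2)
        expect_true(all(dNow <= dCand + 1e-12))
    }

    # determinism
    st2 <- suppressWarnings(localCluster(Z, k = 2, r = 1))
    expect_identical(st@centers, st2@centers)
    expect_identical(st@labels, st2@labels)
})

test_that("pre-clustered data converges in a single iteration", {
    # samples already grouped in seeding order around distinct locations
    Z <- rbind(matrix(rnorm(100, -5, 0.1), ncol = 2),
               matrix(rnorm(100, 5, 0.1), ncol = 2))
    st <- suppressWarnings(localCluster(Z, k = 2, r = 1))
    expect_equal(st@iterations, 1L)
    expect_true(st@converged)
})

test_that("feature sampling honours m, small clusters, and the seed", {
    set.seed(6)
    Z <- cbind(rnorm(40), rnorm(40))
    st <- new("ClusterState", centers = matrix(0, 2, 2),
        labels = rep(1:2, each = 20L), k = 2L, r = 1L, iterations = 1L,
        changedFraction = 0, converged = TRUE)
    fs <- sampleFeaturePoints(Z, st, m = 3, seed = 9)
    expect_equal(nrow(featurePoints(fs)), 6L)
    expect_identical(featurePoints(sampleFeaturePoints(Z, st, m = 3, seed = 9)),
        featurePoints(fs))
    expect_equal(Z[fs@sourceIndices, ], featurePoints(fs))

    # clusters at exactly m members: everything is kept
    stAll <- new("ClusterState", centers = matrix(0, 20, 2),
        labels = rep(1:20, each = 2L), k = 20L, r = 1L, iterations = 1L,
        changedFraction = 0, converged = TRUE)
    expect_equal(nrow(featurePoints(sampleFeaturePoints(Z, stAll, m = 2))), 40L)

    # singleton cluster with m = 3 keeps its one point
    st1 <- new("ClusterState", centers = matrix(0, 2, 2),
        labels = c(1L, rep(2L, 39L)), k = 2L, r = 1L, iterations = 1L,
        changedFraction = 0, converged = TRUE)
    fs1 <- sampleFeaturePoints(Z, st1, m = 3, seed = 1)
    expect_true(1L %in% fs1@sourceIndices)
    expect_equal(nrow(featurePoints(fs1)), 4L)
})

test_that("feature counts scale as k * m when clusters are large enough", {
    # 12000 samples in 1200 clusters of 10: the m = 3 rule keeps 3600
    n <- 12000L; k <- 1200L
    set.seed(8)
    Z <- cbind(rnorm(n), rnorm(n))
    st <- new("ClusterState", centers = matrix(0, k, 2),
        labels = rep(seq_len(k), each = n %/% k), k = k, r = 2L,
        iterations = 1L, changedFraction = 0, converged = TRUE)
    fs <- sampleFeaturePoints(Z, st, m = 3, seed = 2)
    expect_equal(nrow(featurePoints(fs)), 3600L)
    expect_lte(nrow(featurePoints(fs)), k * 3L)
})
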