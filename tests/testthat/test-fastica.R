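test_that("centering subtracts column means exactly", {
    cs <- centerSamples(rbind(c(1, 2), c(3, 4)))
    expect_equal(cs$centered, rbind(c(-1, -1), c(1, 1)))
    expect_equal(cs$mean, c(2, 3))

    X <- cbind(rnorm(50), 7)           # constant column becomes zeros
    cs2 <- centerSamples(X)
    expect_true(all(cs2$centered[, 2] == 0))
    expect_lt(max(abs(colMeans(cs2$centered))), 1e-12)

    set.seed(1)
    X0 <- matrix(rnorm(40), 20)
    X0 <- sweep(X0, 2, colMeans(X0))   # already centered: unchanged
    expect_equal(centerSamples(X0)$centered, X0)
})

test_that("whitening yields identity covariance and consistent transforms", {
    set.seed(3)
    A <- matrix(c(2, 0.5, 0.3, 1), 2)
    X <- matrix(rnorm(4000), ncol = 2) %*% t(A)
    wd <- whitenSamples(X)
    expect_lt(max(abs(cov(wd@Z) - diag(2))), 1e-8)
    expect_lt(max(abs(wd@whitening %*% wd@dewhitening - diag(2))), 1e-10)

    # diagonal covariance: whitening is the inverse-sd diagonal
    set.seed(4)
    Xd <- cbind(rnorm(200000, sd = 2), rnorm(200000, sd = 1))
    wdd <- whitenSamples(Xd)
    expect_equal(abs(wdd@whitening), diag(c(0.5, 1)), tolerance = 0.02)

    # exactly diagonal covariance with distinct variances: whitening only
    # rescales the axes (no rotation), so Z is the column-standardized input
    X0 <- rbind(c(2, 1), c(-2, 1), c(2, -1), c(-2, -1))
    wd0 <- whitenSamples(X0)
    expect_equal(wd0@Z, sweep(X0, 2, apply(X0, 2, sd), "/"),
        tolerance = 1e-12)

    # near-collinear channels are rejected as degenerate
    x <- rnorm(100)
    expect_error(whitenSamples(cbind(x, x + 1e-12 * rnorm(100))),
        "degenerate")
})

test_that("unmixing matches the exhaustive negentropy oracle within 1 degree", {
    for (case in list(c(n = 20000, theta = 25, seed = 11),
                      c(n = 20000, theta = 70, seed = 12),
                      c(n = 30000, theta = 5,  seed = 13))) {
        Z <- uniformRotationMixture(case[["n"]], case[["theta"]],
            case[["seed"]])
        wd <- whitenSamples(Z)
        res <- fasticaUnmix(wd, seed = 21)
        expect_true(res@converged)
        oracleTheta <- negentropyGridAngle(wd@Z)
        icaTheta <- atan2(res@W[1, 2], res@W[1, 1])
        expect_lt(angleGapDeg(icaTheta, oracleTheta), 1)
    }
})

test_that("identity-mixed sources return a signed permutation", {
    # feed already-separated unit-variance sources straight in: no
    # whitening rotation, so W must be a signed permutation up to the
    # O(n^-1/2) sampling error of the contrast
    set.seed(7)
    n <- 200000
    Z <- cbind(runif(n, -sqrt(3), sqrt(3)), runif(n, -sqrt(3), sqrt(3)))
    Z <- sweep(sweep(Z, 2, colMeans(Z)), 2, apply(Z, 2, sd), "/")
    res <- fasticaUnmix(Z, seed = 3)
    expect_true(res@converged)
    P <- abs(res@W)
    # each row and column has one entry ~1 and one ~0
    expect_lt(max(abs(sort(as.vector(P)) - c(0, 0, 1, 1))), 1e-2)
    # rows orthonormal
    expect_lt(max(abs(res@W %*% t(res@W) - diag(2))), 1e-8)
})

test_that("unmixing is seed-reproducible and reports forced failure", {
    set.seed(8)
    Z <- whitenSamples(cbind(runif(2000), runif(2000)))@Z
    a <- fasticaUnmix(Z, seed = 5)
    b <- fasticaUnmix(Z, seed = 5)
    expect_identical(a@W, b@W)
    expect_identical(a@iterations, b@iterations)

    f <- fasticaUnmix(Z, tol = 0, maxIter = 1L, seed = 5)
    expect_false(f@converged)
    expect_false(any(f@compConverged))
})

test_that("the coefficient matrix is the dewhitened inverse with unit columns", {
    # identity whitening and identity W give the identity V
    wdI <- new("WhitenedData", Z = diag(2), whitening = diag(2),
        dewhitening = diag(2), mean = c(0, 0))
    resI <- new("SeparationResult", W = diag(2),
        V = matrix(NA_real_, 2, 2), converged = TRUE,
        compConverged = c(TRUE, TRUE), iterations = c(1L, 1L),
        seed = NA_integer_)
    expect_equal(coefficientMatrix(resI, wdI)@V, diag(2))

    set.seed(9)
    X <- matrix(rnorm(2000), ncol = 2) %*% matrix(c(1, 0.6, 0.2, 1), 2)
    wd <- whitenSamples(X)
    res <- fasticaUnmix(wd, seed = 2)
    V <- pigmentCoefficients(coefficientMatrix(res, wd))
    expect_equal(sqrt(colSums(V^2)), c(1, 1), tolerance = 1e-12)
    expect_true(all(V >= 0))
})

test_that("a known mixing matrix is recovered up to permutation and sign", {
    set.seed(10)
    Strue <- cbind(runif(20000, -1, 1), runif(20000, -1, 1))
    A <- cbind(c(0.3, 0.9), c(1, 0.7))
    X <- Strue %*% t(A)
    wd <- whitenSamples(X)
    res <- coefficientMatrix(fasticaUnmix(wd, seed = 6), wd)
    V <- pigmentCoefficients(res)
    An <- abs(sweep(A, 2, sqrt(colSums(A^2)), "/"))
    # optimal column pairing
    direct <- min(sum(V[, 1] * An[, 1]), sum(V[, 2] * An[, 2]))
    crossed <- min(sum(V[, 1] * An[, 2]), sum(V[, 2] * An[, 1]))
    expect_gt(max(direct, crossed), 0.999)
})
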