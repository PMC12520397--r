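#' Center samples
#'
#' Subtracts the column means.
#'
#' @param X n x 2 sample matrix.
#' @return list with `centered` (n x 2) and `mean` (length 2).
#' @export
centerSamples <- function(X) {
    stopIfNot(nrow(X) >= 2, "need at least 2 samples")
    mu <- colMeans(X)
    list(centered = sweep(X, 2L, mu), mean = mu)
}

#' Center and whiten samples
#'
#' Eigendecomposes the sample covariance \eqn{E\{XX^T\}} and maps the
#' centered data through \eqn{\Lambda^{-1/2} U^T}, so the output has
#' identity covariance.  Eigenvector signs are fixed by making each
#' eigenvector's largest-magnitude entry positive, which pins down an
#' otherwise arbitrary reflection and makes whitening reproducible.
#'
#' @param X n x 2 sample matrix (not necessarily centered; the subtracted
#'   mean is recorded).
#' @param maxCondition covariance condition-number bound beyond which the
#'   input is rejected as degenerate (the two log-difference channels are
#'   then too similar for separation -- the failure mode sub-block selection
#'   exists to prevent).
#' @return a [WhitenedData-class].
#' @examples
#' wd <- whitenSamples(matrix(rnorm(200), 100, 2))
#' cov(whitenedSamples(wd))
#' @export
whitenSamples <- function(X, maxCondition = 1e12) {
    cs <- centerSamples(X)
    S <- crossprod(cs$centered) / (nrow(X) - 1)
    eg <- eigen(S, symmetric = TRUE)
    stopIfNot(min(eg$values) > 0 &&
        max(eg$values) / min(eg$values) <= maxCondition,
        "degenerate input: channels too similar (covariance ill-conditioned)")
    U <- eg$vectors
    for (j in 1:2) {
        if (U[which.max(abs(U[, j])), j] < 0) U[, j] <- -U[, j]
    }
    M <- diag(1 / sqrt(eg$values)) %*% t(U)
    D <- U %*% diag(sqrt(eg$values))
    new("WhitenedData", Z = cs$centered %*% t(M), whitening = M,
        dewhitening = D, mean = cs$mean)
}

#' @rdname accessors
#' @export
setMethod("whitenedSamples", "WhitenedData", function(object) object@Z)

#' Negentropy FastICA on whitened 2-D samples
#'
#' Estimates the two unit unmixing vectors by the fixed-point iteration
#' \deqn{w^+ = E\{z\, g(w^T z)\} - E\{g'(w^T z)\}\, w}
#' with the canonical negentropy contrast \eqn{G(u) = \ln\cosh u}
#' (\eqn{g = \tanh}), using deflation: the second vector is Gram-Schmidt
#' orthogonalized against the first at every step.  A component converges
#' when \eqn{|1 - |w_{k+1} \cdot w_k|| < tol}; the run succeeds only if both
#' components converge within `maxIter` iterations.  Non-convergence is
#' reported, not raised: the convergence-rate experiments count exactly
#' these failures.
#'
#' Initial vectors are uniform random unit vectors from the seeded RNG --
#' the sole source of run-to-run variation.
#'
#' @param Z n x 2 whitened sample matrix (or a [WhitenedData-class]).
#' @param tol per-component convergence tolerance.
#' @param maxIter iteration budget per component.
#' @param seed optional integer seed for the initial vectors.
#' @return a [SeparationResult-class] with `V` unset (see
#'   [coefficientMatrix()]).
#' @examples
#' wd <- whitenSamples(cbind(runif(500), runif(500)) %*%
#'     matrix(c(1, 0.4, 0.3, 1), 2))
#' fasticaUnmix(wd, seed = 1)
#' @export
fasticaUnmix <- function(Z, tol = 1e-6, maxIter = 200L, seed = NULL) {
    if (is(Z, "WhitenedData")) Z <- Z@Z
    n <- nrow(Z)
    W <- matrix(0, 2L, 2L)
    iters <- integer(2L)
    conv <- logical(2L)
    withSeed(seed, {
        for (comp in 1:2) {
            theta <- stats::runif(1L, 0, 2 * pi)
            w <- c(cos(theta), sin(theta))
            if (comp == 2L) {
                w <- w - sum(w * W[1L, ]) * W[1L, ]
                nw <- sqrt(sum(w^2))
                if (nw < 1e-8) w <- c(-W[1L, 2L], W[1L, 1L]) else w <- w / nw
            }
            for (it in seq_len(maxIter)) {
                u <- Z %*% w
                g <- tanh(u)
                wNew <- c(crossprod(Z, g)) / n - mean(1 - g^2) * w
                if (comp == 2L)
                    wNew <- wNew - sum(wNew * W[1L, ]) * W[1L, ]
                nw <- sqrt(sum(wNew^2))
                if (nw < 1e-12) {
                    # contrast gradient vanished; restart from a fresh
                    # random direction (counts as an iteration)
                    theta <- stats::runif(1L, 0, 2 * pi)
                    wNew <- c(cos(theta), sin(theta))
                    if (comp == 2L) {
                        wNew <- wNew - sum(wNew * W[1L, ]) * W[1L, ]
                        wNew <- wNew / sqrt(sum(wNew^2))
                    }
                } else wNew <- wNew / nw
                delta <- abs(1 - abs(sum(wNew * w)))
                w <- wNew
                iters[comp] <- it
                if (delta < tol) {
                    conv[comp] <- TRUE
                    break
                }
            }
            W[comp, ] <- w
        }
    })
    new("SeparationResult", W = W, V = matrix(NA_real_, 2L, 2L),
        converged = all(conv), compConverged = conv, iterations = iters,
        seed = asSeed(seed))
}

#' Pigment coefficient matrix from an unmixing result
#'
#' Back-projects the separation matrix through the dewhitening transform,
#' \eqn{V = |(\Lambda^{-1/2} U^T)^{-1} W^{-1}|}, and normalizes each column
#' to unit Euclidean length.  The absolute value and normalization absorb
#' the sign/scale ambiguity inherent to ICA; column order is resolved later
#' by [orderPigmentColumns()].
#'
#' @param result a [SeparationResult-class].
#' @param whitened the [WhitenedData-class] the unmixing ran in.
#' @return the input `result` with its `V` slot filled (2x2, nonnegative,
#'   unit-norm columns).
#' @export
coefficientMatrix <- function(result, whitened) {
    stopifnot(is(result, "SeparationResult"), is(whitened, "WhitenedData"))
    W <- result@W
    stopIfNot(abs(det(W)) > 1e-10, "singular separation matrix")
    V <- abs(whitened@dewhitening %*% solve(W))
    V <- sweep(V, 2L, sqrt(colSums(V^2)), `/`)
    result@V <- V
    result
}

#' @rdname accessors
#' @export
setMethod("separationMatrix", "SeparationResult", function(object) object@W)

#' @rdname accessors
#' @export
setMethod("pigmentCoefficients", "SeparationResult",
    function(object) object@V)

setMethod("show", "SeparationResult", function(object) {
    cat("SeparationResult: converged =", object@converged,
        "(iterations:", paste(object@iterations, collapse = ", "), ")\n")
    if (!anyNA(object@V)) {
        cat("  V (columns unit-norm):\n")
        print(signif(object@V, 4L))
    }
})

setMethod("show", "WhitenedData", function(object) {
    cat("WhitenedData:", nrow(object@Z), "samples; mean removed:",
        signif(object@mean, 4L), "\n")
})
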