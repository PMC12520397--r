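#' Seed cluster centers evenly along the sample order
#'
#' Centers inherit a 1-D ordering from the samples' raster order: with
#' stride \eqn{\lfloor n/k \rfloor}, center \eqn{i} is the mean of the
#' samples in the \eqn{i}-th contiguous window (leftover tail samples are
#' appended to the last window).  This ordering is what the bounded
#' neighbor search in [assignLabels()] is defined over.
#'
#' @param Z n x 2 matrix of whitened samples in their raster order.
#' @param k number of centers, `1 <= k <= n`.
#' @return list with `centers` (k x 2 matrix) and `labels` (the initial
#'   window membership of each sample).
#' @examples
#' Z <- cbind(rnorm(100), rnorm(100))
#' initCenters(Z, 4)$centers
#' @export
initCenters <- function(Z, k) {
    n <- nrow(Z)
    stopIfNot(k >= 1 && k <= n, "k must lie in [1, n]")
    w <- n %/% k
    labels <- pmin.int((seq_len(n) - 1L) %/% w + 1L, k)
    centers <- updateCenters(Z, labels, k, matrix(0, k, 2L))
    list(centers = centers, labels = as.integer(labels))
}

#' Reassign samples to nearby centers
#'
#' For a sample currently in center \eqn{i}, only the centers with index in
#' \eqn{[i - r, i + r]} (clipped to \eqn{[1, k]}) are searched; the sample
#' takes the nearest by squared Euclidean distance, ties going to the lowest
#' center index.  The bounded window is what makes the clustering "local"
#' and cheap.
#'
#' @param Z n x 2 sample matrix.
#' @param centers k x 2 center matrix.
#' @param labels current integer assignment.
#' @param r search radius in center-index units; `r >= k` reduces to global
#'   nearest-center assignment.
#' @return integer vector of new labels.
#' @export
assignLabels <- function(Z, centers, labels, r) {
    k <- nrow(centers)
    n <- nrow(Z)
    offsets <- seq.int(-r, r)
    D <- matrix(Inf, n, length(offsets))
    cand <- matrix(0L, n, length(offsets))
    for (j in seq_along(offsets)) {
        ci <- pmin.int(pmax.int(labels + offsets[j], 1L), k)
        cand[, j] <- ci
        D[, j] <- (Z[, 1L] - centers[ci, 1L])^2 +
            (Z[, 2L] - centers[ci, 2L])^2
    }
    # candidates ascend in center index, so "first" breaks ties toward the
    # lowest index
    best <- max.col(-D, ties.method = "first")
    cand[cbind(seq_len(n), best)]
}

#' Update centers to their member means
#'
#' Center \eqn{i} becomes the mean of its members; a center with no members
#' keeps its previous position.
#'
#' @param Z n x 2 sample matrix.
#' @param labels integer assignment.
#' @param k number of centers.
#' @param prev k x 2 previous centers (returned for empty clusters).
#' @return k x 2 updated center matrix.
#' @export
updateCenters <- function(Z, labels, k, prev) {
    sums <- rowsum(Z, labels)
    counts <- tabulate(labels, nbins = k)
    idx <- as.integer(rownames(sums))
    centers <- prev
    centers[idx, ] <- sums / counts[idx]
    centers
}

#' Local clustering of whitened samples
#'
#' Alternates [assignLabels()] and [updateCenters()] from the even seeding
#' of [initCenters()] until fewer than 1% of the samples change cluster in
#' an iteration (or `maxIter` is reached, in which case the returned state
#' is flagged non-converged with a warning).  The procedure is fully
#' deterministic.
#'
#' @inheritParams initCenters
#' @param r neighbor search radius (center-index units).
#' @param maxIter iteration budget.
#' @param tolFraction label-change fraction below which the clustering is
#'   declared converged.
#' @return a [ClusterState-class].
#' @examples
#' Z <- rbind(matrix(rnorm(100, -3), 50), matrix(rnorm(100, 3), 50))
#' localCluster(Z, k = 2, r = 1)
#' @export
localCluster <- function(Z, k = 1200L, r = 2L, maxIter = 100L,
                         tolFraction = 0.01) {
    n <- nrow(Z)
    stopIfNot(k >= 1 && k <= n, "k must lie in [1, n]")
    if (k < 900 || k > 1500)
        warning("k outside the recommended 900-1500 range")
    init <- initCenters(Z, k)
    centers <- init$centers
    labels <- init$labels
    changed <- 1
    iter <- 0L
    converged <- FALSE
    while (iter < maxIter) {
        iter <- iter + 1L
        newLabels <- assignLabels(Z, centers, labels, r)
        changed <- mean(newLabels != labels)
        labels <- newLabels
        centers <- updateCenters(Z, labels, k, centers)
        if (changed < tolFraction) {
            converged <- TRUE
            break
        }
    }
    if (!converged)
        warning("local clustering did not meet the label-change rule in ",
            maxIter, " iterations")
    new("ClusterState", centers = centers, labels = as.integer(labels),
        k = as.integer(k), r = as.integer(r), iterations = iter,
        changedFraction = changed, converged = converged)
}

#' Sample feature points from each cluster
#'
#' Draws `m` members uniformly at random without replacement from every
#' cluster (all members when a cluster holds fewer than `m`).  The reduced
#' set -- at most `k * m` points -- is the input that stabilises the FastICA
#' fixed-point iteration.
#'
#' @param Z n x 2 sample matrix the clustering was run on.
#' @param state a [ClusterState-class].
#' @param m points per cluster (default 3).
#' @param seed optional integer seed for reproducible sampling.
#' @return a [FeatureSet-class].
#' @export
sampleFeaturePoints <- function(Z, state, m = 3L, seed = NULL) {
    stopifnot(is(state, "ClusterState"))
    stopIfNot(m >= 1, "m must be at least 1")
    withSeed(seed, {
        byCluster <- split(seq_len(nrow(Z)), state@labels)
        picks <- lapply(byCluster, function(idx) {
            if (length(idx) <= m) idx
            else idx[sample.int(length(idx), m)]
        })
        idx <- sort(unlist(picks, use.names = FALSE))
        new("FeatureSet", points = Z[idx, , drop = FALSE],
            sourceIndices = as.integer(idx), m = as.integer(m),
            seed = asSeed(seed))
    })
}

#' @rdname accessors
#' @export
setMethod("clusterCenters", "ClusterState", function(object) object@centers)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterState", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("featurePoints", "FeatureSet", function(object) object@points)

setMethod("show", "ClusterState", function(object) {
    cat("ClusterState: k =", object@k, ", r =", object@r, ",",
        length(object@labels), "samples\n")
    cat("  iterations:", object@iterations, "; changed fraction:",
        signif(object@changedFraction, 3L), "; converged:",
        object@converged, "\n")
})

setMethod("show", "FeatureSet", function(object) {
    cat("FeatureSet:", nrow(object@points), "points (m =", object@m, ")\n")
})
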