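#' Full pigment separation pipeline
#'
#' Runs the complete flow on an image region: log channel differences,
#' optional sub-block selection, centering and whitening, optional local
#' clustering with per-cluster feature sampling, FastICA, column ordering,
#' and synthesis of the melanin and hemoglobin images.  The three variants
#' correspond to the ablation ladder of the method: `plain_dlica` feeds all
#' region pixels straight to FastICA, `subblock_only` adds block selection,
#' and `subblock_plus_cluster` (the full method) adds clustering on top.
#'
#' Whitening (and hence the coefficient back-projection) always uses the
#' full set of samples entering the ICA stage; clustering only thins the
#' samples the fixed-point iteration averages over.  Synthesis, by
#' contrast, always runs on every pixel of the original region.
#'
#' @param image a [SkinImage-class].
#' @param region optional `c(row, col, height, width)` analysis window.
#' @param variant one of `"subblock_plus_cluster"` (default),
#'   `"subblock_only"`, `"plain_dlica"`.
#' @param q sub-block side length.
#' @param fraction retained block fraction.
#' @param k number of cluster centers (clamped to the sample count is NOT
#'   done; `k` must not exceed the post-selection sample count).
#' @param r cluster neighbor search radius.
#' @param m feature points per cluster.
#' @param tol,maxIter FastICA convergence tolerance and iteration budget.
#' @param clusterMaxIter local clustering iteration budget.
#' @param seed integer seed for the stochastic stages (feature sampling and
#'   FastICA initialisation).
#'
#' @return list with elements `separation` ([SeparationResult-class]),
#'   `ordering` ([OrderedCoefficients-class] or NULL), `maps`
#'   ([PigmentMaps-class], NULL when FastICA did not converge), `selection`
#'   ([SelectionResult-class] or NULL), `cluster` ([ClusterState-class] or
#'   NULL), and `config` (the parameters used).
#' @examples
#' img <- renderSkinImage(simulateScene(60, 60, seed = 4))
#' run <- separatePigments(img, variant = "plain_dlica", seed = 1)
#' run$separation
#' @export
separatePigments <- function(image, region = NULL,
                             variant = c("subblock_plus_cluster",
                                 "subblock_only", "plain_dlica"),
                             q = 5L, fraction = 0.25, k = 1200L, r = 2L,
                             m = 3L, tol = 1e-6, maxIter = 200L,
                             clusterMaxIter = 100L, seed = NULL) {
    variant <- match.arg(variant)
    stopifnot(is(image, "SkinImage"))
    if (!is.null(region)) image <- cropImage(image, region)
    lds <- channelDifferences(image)

    selection <- NULL
    icaSamples <- lds@data
    if (variant != "plain_dlica") {
        selection <- subblockSelect(lds, q = q, fraction = fraction)
        icaSamples <- selection@samples@data
    }

    wd <- whitenSamples(icaSamples)

    clusterState <- NULL
    Zin <- wd@Z
    if (variant == "subblock_plus_cluster") {
        clusterState <- suppressWarnings(
            localCluster(wd@Z, k = min(k, nrow(wd@Z)), r = r,
                maxIter = clusterMaxIter))
        fs <- sampleFeaturePoints(wd@Z, clusterState, m = m,
            seed = if (is.null(seed)) NULL else deriveSeed(seed, 1L))
        Zin <- fs@points
    }

    res <- fasticaUnmix(Zin, tol = tol, maxIter = maxIter,
        seed = if (is.null(seed)) NULL else deriveSeed(seed, 2L))
    config <- list(variant = variant, q = q, fraction = fraction, k = k,
        r = r, m = m, tol = tol, maxIter = maxIter, seed = asSeed(seed),
        nSamplesICA = nrow(Zin))
    if (!res@converged) {
        return(list(separation = res, ordering = NULL, maps = NULL,
            selection = selection, cluster = clusterState, config = config))
    }
    res <- coefficientMatrix(res, wd)
    ordering <- orderPigmentColumns(res@V)
    conc <- pigmentConcentrations(ordering, image)
    maps <- synthesizePigmentImages(ordering, conc, image)
    list(separation = res, ordering = ordering, maps = maps,
        selection = selection, cluster = clusterState, config = config)
}
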