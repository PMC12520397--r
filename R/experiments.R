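#' Convergence-rate benchmark across method variants
#'
#' For each scene, variant and input size: prepares the variant's sample
#' pool (all region pixels for `plain_dlica`; the pixels of the selected
#' sub-blocks otherwise), takes the first `size` samples of the pool
#' (contiguous raster prefix, for determinism), whitens, optionally
#' clusters and samples feature points, then runs FastICA `repeats` times
#' with fresh seeded initialisations and counts the runs in which both
#' components converge.  "Input size" is the number of samples entering the
#' ICA stage before clustering.
#'
#' The desk-scale defaults (sizes 4,000--20,000 step 4,000, 20 repeats)
#' keep a full report in the minutes range; the full protocol grid
#' (4,000--75,000 step 500, 100 repeats) is available by passing the
#' corresponding `inputSizes` and `repeats`.
#'
#' @param scenes list of [SkinScene-class] objects (or a single scene).
#' @param inputSizes integer vector of ICA input sizes; sizes exceeding a
#'   pool are skipped with a warning.
#' @param repeats FastICA runs per (scene, variant, size).
#' @param variants subset of `c("plain_dlica", "subblock_only",
#'   "subblock_plus_cluster")`.
#' @param seed master seed; per-run seeds are derived from it via a counter
#'   and logged.
#' @param q,fraction,k,r,m,tol,maxIter stage parameters (defaults are the
#'   method's standard settings).
#' @return data.frame with one row per (scene, variant, size): columns
#'   scene, variant, size, repeats, successes, rate, seed.
#' @examples
#' sc <- simulateScene(80, 100, seed = 1)
#' convergenceRate(sc, inputSizes = 2000, repeats = 3,
#'     variants = "plain_dlica", seed = 1)
#' @export
convergenceRate <- function(scenes,
                            inputSizes = seq(4000L, 20000L, by = 4000L),
                            repeats = 20L,
                            variants = c("plain_dlica", "subblock_only",
                                "subblock_plus_cluster"),
                            seed = 1L, q = 5L, fraction = 0.25, k = 1200L,
                            r = 2L, m = 3L, tol = 1e-6, maxIter = 200L) {
    stopIfNot(repeats >= 1, "repeats must be at least 1")
    if (is(scenes, "SkinScene")) scenes <- list(scenes)
    variants <- match.arg(variants, several.ok = TRUE)
    rows <- list()
    counter <- 0L
    for (si in seq_along(scenes)) {
        img <- renderSkinImage(scenes[[si]])
        lds <- channelDifferences(img)
        pools <- list()
        if ("plain_dlica" %in% variants) pools$plain_dlica <- lds@data
        if (any(variants != "plain_dlica")) {
            sel <- suppressWarnings(
                subblockSelect(lds, q = q, fraction = fraction))
            for (v in setdiff(variants, "plain_dlica"))
                pools[[v]] <- sel@samples@data
        }
        for (v in variants) {
            pool <- pools[[v]]
            for (size in inputSizes) {
                if (size > nrow(pool)) {
                    warning("size ", size, " exceeds the ", v,
                        " pool (", nrow(pool), " samples); skipped")
                    next
                }
                X <- pool[seq_len(size), , drop = FALSE]
                wd <- whitenSamples(X)
                Zin <- wd@Z
                if (v == "subblock_plus_cluster") {
                    cs <- suppressWarnings(localCluster(wd@Z,
                        k = min(k, size), r = r))
                    counter <- counter + 1L
                    fs <- sampleFeaturePoints(wd@Z, cs, m = m,
                        seed = deriveSeed(seed, counter))
                    Zin <- fs@points
                }
                succ <- 0L
                for (rep in seq_len(repeats)) {
                    counter <- counter + 1L
                    res <- fasticaUnmix(Zin, tol = tol, maxIter = maxIter,
                        seed = deriveSeed(seed, counter))
                    if (res@converged) succ <- succ + 1L
                }
                rows[[length(rows) + 1L]] <- data.frame(
                    scene = si, variant = v, size = size,
                    repeats = repeats, successes = succ,
                    rate = succ / repeats, seed = seed)
            }
        }
    }
    do.call(rbind, rows)
}

#' One-parameter sensitivity sweep
#'
#' Varies a single parameter of the full method -- the sub-block side `q`,
#' the number of cluster centers `k`, or the retained block `fraction` --
#' while holding the other two at their defaults (q = 5, k = 1200,
#' fraction = 0.25), and reports the convergence rate per value per scene.
#'
#' @param parameter one of `"q"`, `"k"`, `"fraction"`.
#' @param values values to sweep (validated: q >= 1, k >= 1, fraction in
#'   (0, 1]).
#' @param scenes list of [SkinScene-class] objects (or a single scene).
#' @param repeats FastICA runs per value per scene.
#' @param inputSize ICA input size (capped at each pool's size).
#' @param seed master seed.
#' @param tol,maxIter FastICA settings.
#' @return data.frame with columns scene, parameter, value, repeats,
#'   successes, rate.
#' @export
sensitivitySweep <- function(parameter = c("q", "k", "fraction"), values,
                             scenes, repeats = 10L, inputSize = 8000L,
                             seed = 1L, tol = 1e-6, maxIter = 200L) {
    parameter <- match.arg(parameter)
    stopIfNot(length(values) >= 1, "values must be non-empty")
    bad <- switch(parameter,
        q = any(values < 1),
        k = any(values < 1),
        fraction = any(values <= 0 | values > 1))
    stopIfNot(!bad, paste("invalid", parameter, "value"))
    if (is(scenes, "SkinScene")) scenes <- list(scenes)
    rows <- list()
    counter <- 0L
    for (si in seq_along(scenes)) {
        img <- renderSkinImage(scenes[[si]])
        lds <- channelDifferences(img)
        for (val in values) {
            q <- if (parameter == "q") as.integer(val) else 5L
            k <- if (parameter == "k") as.integer(val) else 1200L
            fraction <- if (parameter == "fraction") val else 0.25
            sel <- suppressWarnings(
                subblockSelect(lds, q = q, fraction = fraction))
            pool <- sel@samples@data
            size <- min(inputSize, nrow(pool))
            wd <- whitenSamples(pool[seq_len(size), , drop = FALSE])
            cs <- suppressWarnings(
                localCluster(wd@Z, k = min(k, size), r = 2L))
            counter <- counter + 1L
            fs <- sampleFeaturePoints(wd@Z, cs, m = 3L,
                seed = deriveSeed(seed, counter))
            succ <- 0L
            for (rep in seq_len(repeats)) {
                counter <- counter + 1L
                res <- fasticaUnmix(fs@points, tol = tol,
                    maxIter = maxIter, seed = deriveSeed(seed, counter))
                if (res@converged) succ <- succ + 1L
            }
            rows[[length(rows) + 1L]] <- data.frame(
                scene = si, parameter = parameter, value = val,
                repeats = repeats, successes = succ, rate = succ / repeats)
        }
    }
    do.call(rbind, rows)
}
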