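#' Generate smooth chromophore concentration fields
#'
#' Builds a pair of nonnegative concentration maps for a synthetic skin
#' patch: melanin as compact Gaussian spots (freckle-like) and hemoglobin as
#' broader diffuse regions (vascular flushing), both on a constant baseline.
#' Spot centers for the two pigments are drawn independently, so the two
#' fields are statistically independent sources -- the assumption ICA rests
#' on.
#'
#' The number and size of features controls how close the two fields come
#' to empirical independence: a field with few large features has few
#' effective degrees of freedom, and the chance sample correlation between
#' the two pigments then biases the separation.  The defaults (many small
#' melanin spots, somewhat fewer and broader hemoglobin regions -- 80% of
#' `nSpots` at twice `spotScale`) keep the empirical correlation of the
#' default-size scene near zero.
#'
#' @param height,width field dimensions in pixels (at least 16).
#' @param nSpots number of melanin Gaussian blobs (0 gives constant
#'   fields); the hemoglobin field uses `round(0.8 * nSpots)` blobs.
#' @param spotScale standard deviation, in pixels, of the melanin spots;
#'   hemoglobin regions use twice this scale.
#' @param baseLevel constant baseline concentration added to both fields.
#' @param seed optional integer seed; the caller's RNG state is restored.
#'
#' @return list with matrices `cM` and `cH`.
#' @examples
#' maps <- makeConcentrationMaps(64, 64, nSpots = 5, seed = 1)
#' range(maps$cM)
#' @export
makeConcentrationMaps <- function(height, width, nSpots = 200, spotScale = 3,
                                  baseLevel = 0.3, seed = NULL) {
    stopIfNot(height >= 16 && width >= 16,
        "height and width must be at least 16")
    stopIfNot(nSpots >= 0, "nSpots must be nonnegative")
    stopIfNot(baseLevel >= 0, "baseLevel must be nonnegative")
    withSeed(seed, {
        cM <- baseLevel + blobField(height, width, nSpots, spotScale,
            ampRange = c(0.5, 1.5))
        cH <- baseLevel + blobField(height, width, round(0.8 * nSpots),
            2 * spotScale, ampRange = c(0.3, 0.9))
        list(cM = cM, cH = cH)
    })
}

# Sum of n Gaussian blobs at uniform random positions.
blobField <- function(height, width, n, scale, ampRange) {
    f <- matrix(0, height, width)
    if (n == 0) return(f)
    rows <- seq_len(height)
    cols <- seq_len(width)
    for (i in seq_len(n)) {
        u <- stats::runif(1L, 1, height)
        v <- stats::runif(1L, 1, width)
        a <- stats::runif(1L, ampRange[1L], ampRange[2L])
        f <- f + a * exp(-(rows - u)^2 / (2 * scale^2)) %o%
            exp(-(cols - v)^2 / (2 * scale^2))
    }
    f
}

#' Generate a smooth log-shading field
#'
#' Shading models the multiplicative illumination factor induced by surface
#' shape; it is stored on the log scale, where it adds the same value to
#' every channel of a pixel and therefore cancels exactly in channel
#' differences. The field is a small sum of random plane waves with spatial
#' period of order `smoothness`, centered to mean zero and scaled to a
#' peak-to-peak range of exactly `2 * amplitude`.
#'
#' @param height,width field dimensions in pixels.
#' @param amplitude half the peak-to-peak range in log units; 0 yields the
#'   uniform-illumination field of zeros.
#' @param smoothness characteristic spatial scale in pixels.
#' @param seed optional integer seed.
#'
#' @return numeric matrix, the log-shading field.
#' @examples
#' s <- makeShadingField(64, 64, amplitude = 0.3, smoothness = 32, seed = 3)
#' max(s) - min(s)  # 0.6
#' @export
makeShadingField <- function(height, width, amplitude = 0.3, smoothness = 60,
                             seed = NULL) {
    stopIfNot(amplitude >= 0, "amplitude must be nonnegative")
    stopIfNot(smoothness > 0, "smoothness must be positive")
    if (amplitude == 0) return(matrix(0, height, width))
    withSeed(seed, {
        nWaves <- 6L
        freq <- stats::runif(nWaves, 0.3, 1) / smoothness
        dir <- stats::runif(nWaves, 0, 2 * pi)
        phase <- stats::runif(nWaves, 0, 2 * pi)
        amp <- stats::runif(nWaves, 0.5, 1)
        rows <- seq_len(height)
        cols <- seq_len(width)
        f <- matrix(0, height, width)
        for (j in seq_len(nWaves)) {
            phiRow <- 2 * pi * freq[j] * sin(dir[j]) * rows
            phiCol <- 2 * pi * freq[j] * cos(dir[j]) * cols
            f <- f + amp[j] * cos(outer(phiRow, phiCol, `+`) + phase[j])
        }
        f <- f - mean(f)
        f * (2 * amplitude / (max(f) - min(f)))
    })
}

#' Default per-channel pigment coefficients
#'
#' A 3x2 matrix of per-channel coefficients \eqn{v_m(i), v_h(i)} (rows R, G,
#' B). The derived 2x2 difference matrix (see [trueCoefficients()]) has
#' column ratios \eqn{v_{21}/v_{11} = 3} and \eqn{v_{22}/v_{12} = 0.7},
#' inside the ratio intervals used to identify the melanin and hemoglobin
#' columns, so column ordering on synthetic data is deterministic.
#'
#' @return 3x2 numeric matrix with dimnames.
#' @export
defaultVChannel <- function() {
    matrix(c(1.0, 0.1, 0.7,   # melanin:    R, G, B
             1.2, 0.5, 0.2),  # hemoglobin: R, G, B
        nrow = 3L, ncol = 2L,
        dimnames = list(c("R", "G", "B"), c("m", "h")))
}

#' Simulate a synthetic skin scene
#'
#' Assembles concentration maps, a log-shading field and rendering constants
#' into a [SkinScene-class] whose rendered image follows the log-linear skin
#' reflectance model (see [renderSkinImage()]).  The default dimensions
#' (600 x 300) mirror a typical forehead analysis window for this kind of
#' imagery.
#'
#' @inheritParams makeConcentrationMaps
#' @param shadingAmplitude half peak-to-peak log-shading range.
#' @param shadingSmoothness shading spatial scale in pixels.
#' @param vChannel 3x2 per-channel pigment coefficient matrix (rows R, G, B).
#' @param eBarLog length-3 baseline log irradiance per channel (R, G, B).
#' @param seed optional integer seed governing all randomness in the scene.
#'
#' @return a [SkinScene-class].
#' @examples
#' sc <- simulateScene(64, 64, seed = 1)
#' sc
#' @export
simulateScene <- function(height = 600, width = 300, nSpots = 200,
                          spotScale = 3, baseLevel = 0.3,
                          shadingAmplitude = 0.3, shadingSmoothness = 60,
                          vChannel = defaultVChannel(),
                          eBarLog = c(-0.2, -0.35, -0.5), seed = NULL) {
    withSeed(seed, {
        maps <- makeConcentrationMaps(height, width, nSpots, spotScale,
            baseLevel)
        shading <- makeShadingField(height, width, shadingAmplitude,
            shadingSmoothness)
        new("SkinScene", cM = maps$cM, cH = maps$cH, shadingLog = shading,
            vChannel = vChannel, eBarLog = eBarLog, seed = asSeed(seed))
    })
}

#' @describeIn simulateScene the 2x2 pigment coefficient matrix implied by
#'   the scene's per-channel coefficients: rows are the (B-R, G-R) channel
#'   differences evaluated as \eqn{v(R) - v(B)} and \eqn{v(R) - v(G)};
#'   columns melanin, hemoglobin.
#' @param object a [SkinScene-class].
#' @export
setMethod("trueCoefficients", "SkinScene", function(object) {
    v <- object@vChannel
    out <- rbind(v[1L, ] - v[3L, ], v[1L, ] - v[2L, ])
    dimnames(out) <- list(c("B-R", "G-R"), c("m", "h"))
    out
})

#' @rdname accessors
#' @export
setMethod("concentrationMaps", "SkinScene", function(object) {
    list(cM = object@cM, cH = object@cH)
})

#' @rdname accessors
#' @export
setMethod("shadingField", "SkinScene", function(object) object@shadingLog)

#' Render a scene to an RGB image
#'
#' Applies the forward model per channel,
#' \deqn{C_i = \exp(-v_m(i) c_m - v_h(i) c_h + \log p + \bar{E}_i^{\log}),}
#' then rescales all channels by a single global factor so intensities lie
#' in (0, 1]. The factor is recorded in the image's `rescale` slot; being
#' global, it shifts every log channel equally and leaves the (B-R, G-R)
#' observables untouched.
#'
#' @param scene a [SkinScene-class].
#' @return a [SkinImage-class] (bit depth tagged 16).
#' @examples
#' img <- renderSkinImage(simulateScene(64, 64, seed = 1))
#' range(pixelValues(img))
#' @export
renderSkinImage <- function(scene) {
    stopifnot(is(scene, "SkinScene"))
    d <- dim(scene@cM)
    px <- array(0, c(d, 3L))
    for (i in 1:3) {
        px[, , i] <- exp(-scene@vChannel[i, 1L] * scene@cM -
            scene@vChannel[i, 2L] * scene@cH +
            scene@shadingLog + scene@eBarLog[i])
    }
    mx <- max(px)
    s <- if (mx > 1) 1 / mx else 1
    px <- px * s
    if (max(px) - min(px) < 1e-12)
        warning("rendered image has degenerate dynamic range (constant)")
    new("SkinImage", pixels = px, bitDepth = 16L, rescale = s)
}

#' Write a scene and its ground truth to disk
#'
#' Writes the rendered image (8-bit PNG for quick viewing plus a lossless
#' 16-bit TIFF), the ground-truth concentration and shading maps as 32-bit
#' float TIFFs, and a JSON sidecar holding the true coefficient matrix,
#' baseline irradiance, seed and rescale factor.
#'
#' @param scene a [SkinScene-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the named files written.
#' @export
writeScene <- function(scene, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    img <- renderSkinImage(scene)
    files <- c(
        image_png = file.path(dir, "image.png"),
        image_tiff = file.path(dir, "image.tif"),
        cm = file.path(dir, "cm.tif"),
        ch = file.path(dir, "ch.tif"),
        shading = file.path(dir, "shading_log.tif"),
        meta = file.path(dir, "scene.json"))
    png::writePNG(img@pixels, files[["image_png"]])
    tiff::writeTIFF(img@pixels, files[["image_tiff"]], bits.per.sample = 16L)
    tiff::writeTIFF(scene@cM / max(scene@cM, 1), files[["cm"]],
        bits.per.sample = 32L)
    tiff::writeTIFF(scene@cH / max(scene@cH, 1), files[["ch"]],
        bits.per.sample = 32L)
    sh <- scene@shadingLog - min(scene@shadingLog)
    tiff::writeTIFF(sh / max(sh, 1), files[["shading"]],
        bits.per.sample = 32L)
    meta <- list(vTrue = trueCoefficients(scene), vChannel = scene@vChannel,
        eBarLog = scene@eBarLog, seed = scene@seed, rescale = img@rescale,
        cmMax = max(scene@cM), chMax = max(scene@cH))
    jsonlite::write_json(meta, files[["meta"]], auto_unbox = TRUE,
        digits = NA)
    invisible(files)
}

setMethod("show", "SkinScene", function(object) {
    d <- dim(object@cM)
    cat("SkinScene:", d[1L], "x", d[2L], "px\n")
    cat("  cM range:", signif(range(object@cM), 4L), "\n")
    cat("  cH range:", signif(range(object@cH), 4L), "\n")
    cat("  shading p2p (log):",
        signif(max(object@shadingLog) - min(object@shadingLog), 4L), "\n")
    cat("  seed:", object@seed, "\n")
})

setMethod("show", "SkinImage", function(object) {
    d <- dim(object@pixels)
    cat("SkinImage:", d[1L], "x", d[2L], "x 3, bit depth", object@bitDepth,
        ", rescale", signif(object@rescale, 4L), "\n")
})
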