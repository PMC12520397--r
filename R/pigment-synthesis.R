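#' Identify the melanin and hemoglobin columns of V
#'
#' Evaluates the row ratios \eqn{(v_{21}/v_{11},\; v_{22}/v_{12})}.  If
#' \eqn{v_{21}/v_{11} \in (1, 6.33]} and \eqn{v_{22}/v_{12} \in [0.48, 1)},
#' column 1 is melanin and column 2 hemoglobin; otherwise the columns are
#' swapped.  If the swapped order also fails both conditions (degenerate V),
#' the order whose ratios are closest to the intervals is kept and a warning
#' is emitted.  A zero denominator counts as a condition failure, not an
#' error.
#'
#' @param V 2x2 nonnegative coefficient matrix with unit-norm columns, from
#'   [coefficientMatrix()].
#' @return an [OrderedCoefficients-class].
#' @examples
#' V <- cbind(c(1, 3), c(1, 0.7))
#' V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
#' orderPigmentColumns(V)@swapped
#' @export
orderPigmentColumns <- function(V) {
    stopIfNot(all(dim(V) == 2L), "V must be 2x2")
    ratioOf <- function(M) c(M[2L, 1L] / M[1L, 1L], M[2L, 2L] / M[1L, 2L])
    ok <- function(r) {
        is.finite(r[1L]) && r[1L] > 1 && r[1L] <= 6.33 &&
        is.finite(r[2L]) && r[2L] >= 0.48 && r[2L] < 1
    }
    swappedV <- V[, 2:1, drop = FALSE]
    r1 <- ratioOf(V)
    r2 <- ratioOf(swappedV)
    if (ok(r1)) {
        new("OrderedCoefficients", vStar = V, swapped = FALSE, ratios = r1,
            fallback = FALSE)
    } else if (ok(r2)) {
        new("OrderedCoefficients", vStar = swappedV, swapped = TRUE,
            ratios = r2, fallback = FALSE)
    } else {
        # neither order satisfies both conditions: keep the order whose
        # ratios are nearest the target intervals
        gap <- function(r) {
            d <- function(x, lo, hi) {
                if (!is.finite(x)) return(Inf)
                max(0, lo - x, x - hi)
            }
            d(r[1L], 1, 6.33) + d(r[2L], 0.48, 1)
        }
        warning("no column order satisfies the ratio conditions; ",
            "keeping the closest order")
        if (gap(r2) < gap(r1))
            new("OrderedCoefficients", vStar = swappedV, swapped = TRUE,
                ratios = r2, fallback = TRUE)
        else
            new("OrderedCoefficients", vStar = V, swapped = FALSE,
                ratios = r1, fallback = TRUE)
    }
}

#' Per-pixel pigment concentrations
#'
#' Inverts the mixing model on the full original region: per pixel,
#' \eqn{c = (V^*)^{-1} H} with \eqn{H = (\ln B - \ln R,\; \ln G - \ln R)}
#' and the baseline irradiance term taken as zero.  Note the split at the
#' heart of the method: \eqn{V} is estimated from the selected / clustered
#' subsample, but synthesis always uses every pixel of the region.
#'
#' @param ordering an [OrderedCoefficients-class] (or a plain 2x2 matrix
#'   taken as \eqn{V^*}).
#' @param image the original [SkinImage-class] region.
#' @return H x W x 2 array: layer 1 melanin, layer 2 hemoglobin.
#' @export
pigmentConcentrations <- function(ordering, image) {
    vStar <- if (is(ordering, "OrderedCoefficients")) ordering@vStar
        else ordering
    stopIfNot(abs(det(vStar)) >= 1e-10, "V* is numerically singular")
    lds <- channelDifferences(image)
    cmat <- lds@data %*% t(solve(vStar))  # n x 2, raster order
    h <- lds@regionDim[1L]; w <- lds@regionDim[2L]
    out <- array(0, c(h, w, 2L))
    out[, , 1L] <- matrix(cmat[, 1L], h, w, byrow = TRUE)
    out[, , 2L] <- matrix(cmat[, 2L], h, w, byrow = TRUE)
    out
}

#' Synthesize the melanin and hemoglobin images
#'
#' Rebuilds each pigment's image by keeping only its contribution to the
#' log channel differences:
#' \deqn{L_m = \exp(V^* \mathrm{diag}(1,0)\, c + (H_R^{\log}, H_R^{\log})^T)}
#' and analogously with \eqn{\mathrm{diag}(0,1)} for hemoglobin.  Row 1 of
#' \eqn{V^*} feeds the B channel and row 2 the G channel (the (B-R, G-R)
#' ordering of the observables); the R channel is copied bit-identically
#' from the input.  On the log-difference scale the two pigment images add
#' back exactly to the original observables, which is the defining identity
#' of the decomposition.  Channel values above 1 are clipped (counted in
#' the `clipped` slot).
#'
#' @param ordering an [OrderedCoefficients-class].
#' @param concentrations H x W x 2 array from [pigmentConcentrations()].
#' @param image the original [SkinImage-class].
#' @return a [PigmentMaps-class].
#' @export
synthesizePigmentImages <- function(ordering, concentrations, image) {
    stopifnot(is(ordering, "OrderedCoefficients"), is(image, "SkinImage"))
    vStar <- ordering@vStar
    d <- dim(image@pixels)
    stopIfNot(all(dim(concentrations)[1:2] == d[1:2]),
        "concentration maps do not match the image")
    lnR <- log(image@pixels[, , 1L])
    build <- function(col, cmap) {
        px <- array(0, d)
        px[, , 1L] <- image@pixels[, , 1L]
        px[, , 3L] <- exp(vStar[1L, col] * cmap + lnR)  # B channel
        px[, , 2L] <- exp(vStar[2L, col] * cmap + lnR)  # G channel
        px
    }
    mel <- build(1L, concentrations[, , 1L])
    hem <- build(2L, concentrations[, , 2L])
    nClip <- sum(mel[, , 2:3] > 1) + sum(hem[, , 2:3] > 1)
    mel[mel > 1] <- 1
    hem[hem > 1] <- 1
    new("PigmentMaps",
        concentrations = concentrations,
        melanin = new("SkinImage", pixels = mel, bitDepth = image@bitDepth,
            rescale = 1),
        hemoglobin = new("SkinImage", pixels = hem,
            bitDepth = image@bitDepth, rescale = 1),
        ordering = ordering, clipped = as.integer(nClip))
}

#' Write pigment maps to disk
#'
#' Writes the melanin and hemoglobin images (8-bit PNG and 16-bit TIFF),
#' the concentration maps as 32-bit float TIFFs (min-max scaled, with the
#' scaling recorded in the metadata), and the ordered coefficient matrix as
#' JSON.
#'
#' @param maps a [PigmentMaps-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the files written.
#' @export
writePigmentMaps <- function(maps, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- c(melanin = file.path(dir, "melanin.png"),
        melanin16 = file.path(dir, "melanin.tif"),
        hemoglobin = file.path(dir, "hemoglobin.png"),
        hemoglobin16 = file.path(dir, "hemoglobin.tif"),
        cm = file.path(dir, "concentration_m.tif"),
        ch = file.path(dir, "concentration_h.tif"),
        meta = file.path(dir, "vstar.json"))
    png::writePNG(maps@melanin@pixels, files[["melanin"]])
    tiff::writeTIFF(maps@melanin@pixels, files[["melanin16"]],
        bits.per.sample = 16L)
    png::writePNG(maps@hemoglobin@pixels, files[["hemoglobin"]])
    tiff::writeTIFF(maps@hemoglobin@pixels, files[["hemoglobin16"]],
        bits.per.sample = 16L)
    ranges <- list()
    for (j in 1:2) {
        cmap <- maps@concentrations[, , j]
        rg <- range(cmap)
        scaled <- if (diff(rg) > 0) (cmap - rg[1L]) / diff(rg) else cmap * 0
        tiff::writeTIFF(scaled, files[[c("cm", "ch")[j]]],
            bits.per.sample = 32L)
        ranges[[c("m", "h")[j]]] <- rg
    }
    jsonlite::write_json(
        list(vStar = maps@ordering@vStar, swapped = maps@ordering@swapped,
            ratios = maps@ordering@ratios, clipped = maps@clipped,
            concentrationRanges = ranges),
        files[["meta"]], auto_unbox = TRUE, digits = NA)
    invisible(files)
}

#' @rdname accessors
#' @export
setMethod("melaninImage", "PigmentMaps", function(object) object@melanin)

#' @rdname accessors
#' @export
setMethod("hemoglobinImage", "PigmentMaps",
    function(object) object@hemoglobin)

#' @rdname accessors
#' @export
setMethod("concentrationMaps", "PigmentMaps", function(object) {
    list(cM = object@concentrations[, , 1L],
         cH = object@concentrations[, , 2L])
})

setMethod("show", "OrderedCoefficients", function(object) {
    cat("OrderedCoefficients (swapped =", object@swapped,
        if (object@fallback) ", fallback order" else "", "):\n")
    v <- object@vStar
    dimnames(v) <- list(c("B-R", "G-R"), c("melanin", "hemoglobin"))
    print(signif(v, 4L))
    cat("  ratios (v21/v11, v22/v12):",
        signif(object@ratios, 4L), "\n")
})

setMethod("show", "PigmentMaps", function(object) {
    d <- dim(object@concentrations)
    cat("PigmentMaps:", d[1L], "x", d[2L],
        "; clipped channel values:", object@clipped, "\n")
})
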