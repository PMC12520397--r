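#' Load an RGB skin image
#'
#' Reads a PNG or TIFF image, normalizes intensities to (0, 1] by the
#' bit-depth maximum and clamps exact zeros to half a code value
#' (\eqn{1/(2 \cdot \mathrm{maxcode})}) so that logarithms stay finite.
#' An optional rectangular region crops the image at load time.
#'
#' @param path path to a 3-channel PNG or TIFF file (an alpha channel, if
#'   present, is dropped).
#' @param region optional integer vector `c(row, col, height, width)`
#'   (1-based top-left corner) selecting a sub-rectangle.
#' @param bitDepth origin bit depth (8 or 16); if `NULL`, sniffed from the
#'   file header.
#'
#' @return a [SkinImage-class].
#' @export
loadSkinImage <- function(path, region = NULL, bitDepth = NULL) {
    stopIfNot(file.exists(path), paste("no such file:", path))
    ext <- tolower(tools::file_ext(path))
    if (ext == "png") {
        px <- png::readPNG(path)
        if (is.null(bitDepth)) bitDepth <- pngBitDepth(path)
    } else if (ext %in% c("tif", "tiff")) {
        px <- tiff::readTIFF(path, info = TRUE)
        if (is.null(bitDepth)) {
            bps <- attr(px, "bits.per.sample")
            bitDepth <- if (is.null(bps)) 8L else as.integer(bps)
        }
    } else stop("unsupported image format: ", ext, call. = FALSE)
    if (length(dim(px)) != 3L || dim(px)[3L] < 3L)
        stop("input must be a 3-channel RGB image", call. = FALSE)
    px <- px[, , 1:3, drop = FALSE]
    maxCode <- 2^bitDepth - 1
    px[px <= 0] <- 1 / (2 * maxCode)
    px[px > 1] <- 1
    img <- new("SkinImage", pixels = px, bitDepth = as.integer(bitDepth),
        rescale = 1)
    if (!is.null(region)) img <- cropImage(img, region) else img
}

# Bit depth from the PNG IHDR chunk (byte 25 of the file).
pngBitDepth <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- readBin(con, "raw", 25L)
    as.integer(hdr[25L])
}

#' @describeIn loadSkinImage crop a loaded image to a rectangular region.
#' @param image a [SkinImage-class].
#' @export
cropImage <- function(image, region) {
    stopifnot(is(image, "SkinImage"))
    stopIfNot(length(region) == 4L && all(region >= 1),
        "region must be c(row, col, height, width), 1-based")
    d <- dim(image@pixels)
    r0 <- region[1L]; c0 <- region[2L]; h <- region[3L]; w <- region[4L]
    stopIfNot(r0 + h - 1 <= d[1L] && c0 + w - 1 <= d[2L],
        "region extends outside the image")
    new("SkinImage",
        pixels = image@pixels[r0:(r0 + h - 1), c0:(c0 + w - 1), ,
            drop = FALSE],
        bitDepth = image@bitDepth, rescale = image@rescale)
}

#' Per-pixel log channel differences
#'
#' Converts an RGB image to the two-channel optical-density observation
#' matrix: per pixel, \eqn{(\ln B - \ln R,\; \ln G - \ln R)}.  Any
#' multiplicative factor common to the three channels -- shading, exposure,
#' the renderer's rescale -- cancels exactly in these differences, which is
#' why the pipeline works in them.  Rows follow the raster (row-major) order
#' of the region.
#'
#' @param image a [SkinImage-class].
#' @param region optional `c(row, col, height, width)` sub-rectangle.
#' @return a [LogDiffSamples-class].
#' @examples
#' img <- renderSkinImage(simulateScene(32, 32, seed = 1))
#' lds <- channelDifferences(img)
#' head(logDiffs(lds))
#' @export
channelDifferences <- function(image, region = NULL) {
    stopifnot(is(image, "SkinImage"))
    if (!is.null(region)) image <- cropImage(image, region)
    p <- image@pixels
    h <- dim(p)[1L]; w <- dim(p)[2L]
    # raster (row-major) order: pixel index i <-> (row, col) with
    # i = (row-1)*w + col; R stores column-major, so transpose.
    lnR <- as.vector(t(log(p[, , 1L])))
    lnG <- as.vector(t(log(p[, , 2L])))
    lnB <- as.vector(t(log(p[, , 3L])))
    data <- cbind(dBR = lnB - lnR, dGR = lnG - lnR)
    coords <- cbind(
        row = rep(seq_len(h), each = w),
        col = rep(seq_len(w), times = h))
    new("LogDiffSamples", data = data, coords = coords,
        regionDim = c(h, w))
}

#' @rdname accessors
#' @export
setMethod("logDiffs", "LogDiffSamples", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("pixelCoords", "LogDiffSamples", function(object) object@coords)

#' @rdname accessors
#' @export
setMethod("pixelValues", "SkinImage", function(object) object@pixels)

#' Export log-difference samples as a data.frame
#'
#' @param x a [LogDiffSamples-class].
#' @param row.names,optional,... passed through (unused).
#' @return data.frame with columns row, col, dBR, dGR.
#' @export
as.data.frame.LogDiffSamples <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
    data.frame(row = x@coords[, 1L], col = x@coords[, 2L],
        dBR = x@data[, 1L], dGR = x@data[, 2L])
}

setMethod("show", "LogDiffSamples", function(object) {
    cat("LogDiffSamples:", nrow(object@data), "pixels from a",
        object@regionDim[1L], "x", object@regionDim[2L], "region\n")
    cat("  dBR range:", signif(range(object@data[, 1L]), 4L), "\n")
    cat("  dGR range:", signif(range(object@data[, 2L]), 4L), "\n")
})
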