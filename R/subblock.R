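#' Partition a region into q x q sub-blocks
#'
#' Tiles the region with non-overlapping `q` x `q` blocks in raster order;
#' partial tiles at the right and bottom borders are discarded, so the count
#' is `floor(H/q) * floor(W/q)`.
#'
#' @param regionDim integer `c(height, width)`.
#' @param q block side length in pixels.
#' @return data.frame with columns blockId, row, col (1-based top-left
#'   pixel of each block).
#' @examples
#' nrow(partitionBlocks(c(600, 300), 5))  # 7200
#' @export
partitionBlocks <- function(regionDim, q) {
    h <- regionDim[1L]; w <- regionDim[2L]
    stopIfNot(q >= 1, "q must be at least 1")
    stopIfNot(q <= min(h, w), "q exceeds the region's smaller side")
    nr <- h %/% q
    nc <- w %/% q
    data.frame(
        blockId = seq_len(nr * nc),
        row = rep((seq_len(nr) - 1L) * q + 1L, each = nc),
        col = rep((seq_len(nc) - 1L) * q + 1L, times = nr))
}

#' Score sub-blocks by mean absolute channel differences
#'
#' For each block, computes the mean of the (B-R) and (G-R) log differences
#' over the block's pixels and the block score
#' \deqn{d_{B,G-R} = |\bar{d}_{B-R}| + |\bar{d}_{G-R}|.}
#' Blocks with small scores have nearly equal channels -- the regime in
#' which residual shading errors dominate the observables -- so they are the
#' ones selection discards.
#'
#' @param samples a [LogDiffSamples-class] covering the region.
#' @param origins block origins from [partitionBlocks()].
#' @param q block side length.
#' @return data.frame with columns blockId, row, col, dBarBR, dBarGR, dBGR.
#' @export
scoreBlocks <- function(samples, origins, q) {
    stopifnot(is(samples, "LogDiffSamples"))
    bid <- sampleBlockIds(samples, q)
    keep <- !is.na(bid)
    mBR <- rowsum(samples@data[keep, 1L], bid[keep]) / q^2
    mGR <- rowsum(samples@data[keep, 2L], bid[keep]) / q^2
    ord <- as.integer(rownames(mBR))
    out <- origins
    out$dBarBR <- NA_real_
    out$dBarGR <- NA_real_
    out$dBarBR[ord] <- mBR[, 1L]
    out$dBarGR[ord] <- mGR[, 1L]
    out$dBGR <- abs(out$dBarBR) + abs(out$dBarGR)
    out
}

# Map each sample to its block id (NA for pixels in discarded border tiles).
sampleBlockIds <- function(samples, q) {
    h <- samples@regionDim[1L]; w <- samples@regionDim[2L]
    nr <- h %/% q; nc <- w %/% q
    br <- (samples@coords[, 1L] - 1L) %/% q
    bc <- (samples@coords[, 2L] - 1L) %/% q
    id <- br * nc + bc + 1L
    id[br >= nr | bc >= nc] <- NA_integer_
    id
}

#' Select the top-scoring sub-blocks
#'
#' Retains the `ceiling(fraction * N)` blocks with the largest
#' \eqn{d_{B,G-R}} scores (ties broken by lower blockId, i.e. raster order)
#' and rebuilds the ICA input by concatenating their pixels, blocks in
#' raster order and pixels in raster order within each block.
#'
#' @param samples the full-region [LogDiffSamples-class].
#' @param scores data.frame from [scoreBlocks()].
#' @param fraction retained block fraction in (0, 1]; values outside the
#'   empirically recommended 0.2--0.3 band trigger a warning.
#' @param q block side length.
#' @return a [SelectionResult-class].
#' @examples
#' img <- renderSkinImage(simulateScene(40, 40, seed = 2))
#' lds <- channelDifferences(img)
#' org <- partitionBlocks(c(40, 40), 5)
#' sel <- selectBlocks(lds, scoreBlocks(lds, org, 5), 0.25, 5)
#' length(sel@blockIds)
#' @export
selectBlocks <- function(samples, scores, fraction = 0.25, q = 5L) {
    stopIfNot(fraction > 0 && fraction <= 1, "fraction must be in (0, 1]")
    if (fraction < 0.2 || fraction > 0.3)
        warning("fraction outside the recommended 0.2-0.3 range")
    n <- nrow(scores)
    nSel <- ceiling(fraction * n)
    stopIfNot(nSel >= 1, "fraction selects no blocks")
    ord <- order(-scores$dBGR, scores$blockId)
    sel <- sort(scores$blockId[ord[seq_len(nSel)]])
    bid <- sampleBlockIds(samples, q)
    keep <- which(bid %in% sel)
    # global raster order within each block is preserved by a stable sort
    # on block id, so samples come out block-by-block, raster within block.
    keep <- keep[order(bid[keep], keep)]
    subSamples <- new("LogDiffSamples",
        data = samples@data[keep, , drop = FALSE],
        coords = samples@coords[keep, , drop = FALSE],
        regionDim = samples@regionDim)
    scores$selected <- scores$blockId %in% sel
    new("SelectionResult", blockIds = as.integer(sel), samples = subSamples,
        scores = scores, fraction = fraction, q = as.integer(q))
}

#' One-call sub-block selection
#'
#' Convenience wrapper running [partitionBlocks()], [scoreBlocks()] and
#' [selectBlocks()] with the defaults q = 5 and fraction = 0.25.
#'
#' @inheritParams selectBlocks
#' @param q block side; values outside 3--8 trigger a warning.
#' @return a [SelectionResult-class].
#' @export
subblockSelect <- function(samples, q = 5L, fraction = 0.25) {
    if (q < 3 || q > 8) warning("q outside the recommended 3-8 range")
    origins <- partitionBlocks(samples@regionDim, q)
    selectBlocks(samples, scoreBlocks(samples, origins, q), fraction, q)
}

#' @rdname accessors
#' @export
setMethod("blockScores", "SelectionResult", function(object) object@scores)

#' @rdname accessors
#' @export
setMethod("selectedSamples", "SelectionResult",
    function(object) object@samples)

#' Write block scores to CSV
#'
#' @param selection a [SelectionResult-class].
#' @param path output CSV path.
#' @export
writeBlockScores <- function(selection, path) {
    utils::write.csv(selection@scores, path, row.names = FALSE)
    invisible(path)
}

setMethod("show", "SelectionResult", function(object) {
    cat("SelectionResult: retained", length(object@blockIds), "of",
        nrow(object@scores), "blocks (q =", object@q,
        ", fraction =", object@fraction, ")\n")
    cat("  pixels retained:", nrow(object@samples@data), "\n")
})
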