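#' @import methods
NULL

#' SkinScene: a synthetic skin scene with known ground truth
#'
#' Container for a forward-simulated patch of skin: the two chromophore
#' concentration fields, a multiplicative shading field (stored on the log
#' scale), the per-channel pigment coefficients and the baseline log
#' irradiance per channel.  The per-pixel log color of the rendered image is
#' \deqn{\log C_i = -v_m(i)\,c_m - v_h(i)\,c_h + \log p + \bar{E}_i^{\log}}
#' for channel \eqn{i \in \{R,G,B\}}.
#'
#' @slot cM numeric matrix, melanin concentration field (arbitrary units,
#'   nonnegative).
#' @slot cH numeric matrix, hemoglobin concentration field (nonnegative).
#' @slot shadingLog numeric matrix, \eqn{\log p(x,y)}; zero means uniform
#'   illumination.
#' @slot vChannel 3x2 numeric matrix of per-channel pigment coefficients;
#'   rows R, G, B; columns melanin, hemoglobin.
#' @slot eBarLog length-3 numeric, baseline log incident irradiance (R,G,B).
#' @slot seed integer scalar (NA if none), the seed the scene was built with.
#'
#' @seealso [simulateScene()], [renderSkinImage()], [trueCoefficients()]
#' @export
setClass("SkinScene",
    representation(
        cM = "matrix", cH = "matrix", shadingLog = "matrix",
        vChannel = "matrix", eBarLog = "numeric", seed = "integer"
    )
)

setValidity("SkinScene", function(object) {
    msg <- character()
    d <- dim(object@cM)
    if (!identical(d, dim(object@cH)) || !identical(d, dim(object@shadingLog)))
        msg <- c(msg, "cM, cH and shadingLog must share dimensions")
    if (any(object@cM < 0) || any(object@cH < 0))
        msg <- c(msg, "concentration fields must be nonnegative")
    if (!all(is.finite(object@shadingLog)))
        msg <- c(msg, "shadingLog must be finite")
    if (!identical(dim(object@vChannel), c(3L, 2L)))
        msg <- c(msg, "vChannel must be 3x2 (rows R,G,B; columns m,h)")
    if (length(object@eBarLog) != 3L)
        msg <- c(msg, "eBarLog must have length 3")
    if (length(msg)) msg else TRUE
})

#' SkinImage: an RGB intensity image in (0, 1]
#'
#' @slot pixels H x W x 3 numeric array of channel intensities in (0, 1]
#'   (channels ordered R, G, B).
#' @slot bitDepth integer, the bit depth of the originating file (8 or 16);
#'   16 for rendered scenes.
#' @slot rescale numeric, the single global factor applied to bring rendered
#'   intensities into (0, 1] (1 for loaded images).  A global factor cancels
#'   in the log channel differences, so the observables are unaffected.
#'
#' @export
setClass("SkinImage",
    representation(pixels = "array", bitDepth = "integer", rescale = "numeric")
)

setValidity("SkinImage", function(object) {
    p <- object@pixels
    if (length(dim(p)) != 3L || dim(p)[3L] != 3L)
        return("pixels must be an H x W x 3 array")
    if (!all(is.finite(p)) || any(p <= 0) || any(p > 1))
        return("intensities must lie in (0, 1]")
    TRUE
})

#' LogDiffSamples: per-pixel log channel differences
#'
#' The ICA observation matrix: one row per pixel, column 1 is
#' \eqn{\ln B - \ln R}, column 2 is \eqn{\ln G - \ln R}.  Rows follow the
#' raster (row-major) order of the source region; this order matters
#' downstream because local clustering seeds its centers along it.
#'
#' @slot data n x 2 numeric matrix of (B-R, G-R) log differences.
#' @slot coords n x 2 integer matrix of 1-based (row, col) pixel positions.
#' @slot regionDim integer length-2, (height, width) of the source region.
#'
#' @export
setClass("LogDiffSamples",
    representation(data = "matrix", coords = "matrix", regionDim = "integer")
)

setValidity("LogDiffSamples", function(object) {
    if (ncol(object@data) != 2L) return("data must have 2 columns")
    if (!all(is.finite(object@data))) return("log differences must be finite")
    if (nrow(object@coords) != nrow(object@data))
        return("coords must have one row per sample")
    TRUE
})

#' SelectionResult: the outcome of sub-block selection
#'
#' @slot blockIds integer, ids (raster order, 1-based) of the retained
#'   blocks, ascending.
#' @slot samples [LogDiffSamples-class] concatenating the pixels of the
#'   retained blocks (block raster order, raster order within block).
#' @slot scores data.frame of per-block scores: blockId, row, col, dBarBR,
#'   dBarGR, dBGR, selected.
#' @slot fraction numeric, the retained block fraction requested.
#' @slot q integer, block side length.
#'
#' @export
setClass("SelectionResult",
    representation(
        blockIds = "integer", samples = "LogDiffSamples",
        scores = "data.frame", fraction = "numeric", q = "integer"
    )
)

#' ClusterState: local clustering assignment and centers
#'
#' @slot centers k x 2 numeric matrix of cluster centers in whitened space.
#' @slot labels integer length-n assignment (1-based center index).
#' @slot k integer, number of centers.
#' @slot r integer, neighbor search radius in center-index units.
#' @slot iterations integer, assign/update rounds performed.
#' @slot changedFraction numeric, fraction of labels changed in the last
#'   round.
#' @slot converged logical, whether the <1% label-change rule was met.
#'
#' @export
setClass("ClusterState",
    representation(
        centers = "matrix", labels = "integer", k = "integer", r = "integer",
        iterations = "integer", changedFraction = "numeric",
        converged = "logical"
    )
)

setValidity("ClusterState", function(object) {
    if (length(object@labels) &&
        (min(object@labels) < 1L || max(object@labels) > object@k))
        return("labels must lie in [1, k]")
    if (nrow(object@centers) != object@k) return("centers must be k x 2")
    TRUE
})

#' FeatureSet: per-cluster sampled feature points
#'
#' @slot points p x 2 numeric matrix of selected whitened samples.
#' @slot sourceIndices integer, rows of the original sample matrix the
#'   points came from.
#' @slot m integer, requested points per cluster.
#' @slot seed integer, sampling seed (NA if none).
#'
#' @export
setClass("FeatureSet",
    representation(
        points = "matrix", sourceIndices = "integer", m = "integer",
        seed = "integer"
    )
)

#' WhitenedData: centered and whitened samples
#'
#' @slot Z n x 2 whitened samples (identity sample covariance).
#' @slot whitening 2x2 whitening matrix \eqn{\Lambda^{-1/2} U^T}.
#' @slot dewhitening 2x2 inverse \eqn{U \Lambda^{1/2}}.
#' @slot mean length-2 subtracted column means.
#'
#' @export
setClass("WhitenedData",
    representation(
        Z = "matrix", whitening = "matrix", dewhitening = "matrix",
        mean = "numeric"
    )
)

#' SeparationResult: FastICA unmixing outcome
#'
#' @slot W 2x2 separation matrix (rows are the unit unmixing vectors in
#'   whitened space).
#' @slot V 2x2 nonnegative pigment coefficient matrix, columns unit-norm.
#' @slot converged logical, TRUE iff every component met the tolerance
#'   within the iteration budget.
#' @slot compConverged logical length-2, per-component convergence.
#' @slot iterations integer length-2, fixed-point iterations per component.
#' @slot seed integer, initialisation seed (NA if none).
#'
#' @export
setClass("SeparationResult",
    representation(
        W = "matrix", V = "matrix", converged = "logical",
        compConverged = "logical", iterations = "integer", seed = "integer"
    )
)

#' OrderedCoefficients: V with columns identified as melanin / hemoglobin
#'
#' @slot vStar 2x2 matrix, column 1 melanin, column 2 hemoglobin.
#' @slot swapped logical, whether the input columns were exchanged.
#' @slot ratios numeric length-2, (v21/v11, v22/v12) as evaluated for the
#'   chosen order.
#' @slot fallback logical, TRUE when neither order satisfied the ratio
#'   conditions and the closest order was kept.
#'
#' @export
setClass("OrderedCoefficients",
    representation(
        vStar = "matrix", swapped = "logical", ratios = "numeric",
        fallback = "logical"
    )
)

#' PigmentMaps: synthesized pigment images and concentration fields
#'
#' @slot concentrations H x W x 2 array, per-pixel melanin (layer 1) and
#'   hemoglobin (layer 2) concentrations (relative units; sign/scale fixed
#'   only up to the ICA ambiguity).
#' @slot melanin [SkinImage-class], the melanin image (shares the input's R
#'   channel exactly).
#' @slot hemoglobin [SkinImage-class], the hemoglobin image.
#' @slot ordering [OrderedCoefficients-class] used for synthesis.
#' @slot clipped integer, number of channel values clipped into (0, 1].
#'
#' @export
setClass("PigmentMaps",
    representation(
        concentrations = "array", melanin = "SkinImage",
        hemoglobin = "SkinImage", ordering = "OrderedCoefficients",
        clipped = "integer"
    )
)
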