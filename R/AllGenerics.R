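#' Accessor generics
#'
#' Small accessors for the package's S4 containers; use these rather than
#' reaching into slots.
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("concentrationMaps",
    function(object) standardGeneric("concentrationMaps"))

#' @rdname accessors
#' @export
setGeneric("shadingField", function(object) standardGeneric("shadingField"))

#' @rdname accessors
#' @export
setGeneric("trueCoefficients",
    function(object) standardGeneric("trueCoefficients"))

#' @rdname accessors
#' @export
setGeneric("pixelValues", function(object) standardGeneric("pixelValues"))

#' @rdname accessors
#' @export
setGeneric("logDiffs", function(object) standardGeneric("logDiffs"))

#' @rdname accessors
#' @export
setGeneric("pixelCoords", function(object) standardGeneric("pixelCoords"))

#' @rdname accessors
#' @export
setGeneric("blockScores", function(object) standardGeneric("blockScores"))

#' @rdname accessors
#' @export
setGeneric("selectedSamples",
    function(object) standardGeneric("selectedSamples"))

#' @rdname accessors
#' @export
setGeneric("clusterCenters", function(object) standardGeneric("clusterCenters"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("featurePoints", function(object) standardGeneric("featurePoints"))

#' @rdname accessors
#' @export
setGeneric("whitenedSamples",
    function(object) standardGeneric("whitenedSamples"))

#' @rdname accessors
#' @export
setGeneric("separationMatrix",
    function(object) standardGeneric("separationMatrix"))

#' @rdname accessors
#' @export
setGeneric("pigmentCoefficients",
    function(object) standardGeneric("pigmentCoefficients"))

#' @rdname accessors
#' @export
setGeneric("melaninImage", function(object) standardGeneric("melaninImage"))

#' @rdname accessors
#' @export
setGeneric("hemoglobinImage",
    function(object) standardGeneric("hemoglobinImage"))
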