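#' @name hatpress-accessors
#' @title Accessors for hatpress S4 objects
#' @description Slot access goes through these accessors; the slots are an
#'   implementation detail.
#' @param x,object an object of the appropriate class
#' @return the accessed component
NULL

#' @rdname hatpress-accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname hatpress-accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname hatpress-accessors
#' @export
setGeneric("kinshipMatrix", function(x) standardGeneric("kinshipMatrix"))

#' @rdname hatpress-accessors
#' @export
setGeneric("normalizationFactor",
    function(x) standardGeneric("normalizationFactor"))

#' @rdname hatpress-accessors
#' @export
setGeneric("eigenVectors", function(x) standardGeneric("eigenVectors"))

#' @rdname hatpress-accessors
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))

#' @rdname hatpress-accessors
#' @export
setGeneric("fixedEffects", function(x) standardGeneric("fixedEffects"))

#' @rdname hatpress-accessors
#' @export
setGeneric("varianceComponents",
    function(x) standardGeneric("varianceComponents"))

#' @rdname hatpress-accessors
#' @export
setGeneric("varianceRatio", function(x) standardGeneric("varianceRatio"))

#' @rdname hatpress-accessors
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))

#' @rdname hatpress-accessors
#' @export
setGeneric("blup", function(x) standardGeneric("blup"))

#' @rdname hatpress-accessors
#' @export
setGeneric("centeredPhenotypes",
    function(x) standardGeneric("centeredPhenotypes"))

#' @rdname hatpress-accessors
#' @export
setGeneric("modelFit", function(x) standardGeneric("modelFit"))

#' @rdname hatpress-accessors
#' @export
setGeneric("foldIndices", function(x) standardGeneric("foldIndices"))

#' @rdname hatpress-accessors
#' @export
setGeneric("press", function(x) standardGeneric("press"))

#' @rdname hatpress-accessors
#' @export
setGeneric("totalSS", function(x) standardGeneric("totalSS"))

#' @rdname hatpress-accessors
#' @export
setGeneric("predictability", function(x) standardGeneric("predictability"))

#' @rdname hatpress-accessors
#' @export
setGeneric("predictedResiduals",
    function(x) standardGeneric("predictedResiduals"))
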