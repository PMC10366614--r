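#' @name accessors
#' @title Accessors for manifoldFC objects
#' @description Small accessor generics used across the package instead of
#'   direct slot access.
#' @param object an object of the relevant class.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("nRois", function(object) standardGeneric("nRois"))
#' @rdname accessors
#' @export
setGeneric("nAcquisitions", function(object) standardGeneric("nAcquisitions"))
#' @rdname accessors
#' @export
setGeneric("trSeconds", function(object) standardGeneric("trSeconds"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("roiNames", function(object) standardGeneric("roiNames"))
#' @rdname accessors
#' @export
setGeneric("scheduleEvents", function(object) standardGeneric("scheduleEvents"))
#' @rdname accessors
#' @export
setGeneric("connectionIndex", function(object) standardGeneric("connectionIndex"))
#' @rdname accessors
#' @export
setGeneric("windowStarts", function(object) standardGeneric("windowStarts"))
#' @rdname accessors
#' @export
setGeneric("windowLabels", function(object) standardGeneric("windowLabels"))
#' @rdname accessors
#' @export
setGeneric("windowSpec", function(object) standardGeneric("windowSpec"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setGeneric("tvfcValues", function(object) standardGeneric("tvfcValues"))
#' @rdname accessors
#' @export
setGeneric("embeddingCoords", function(object) standardGeneric("embeddingCoords"))
#' @rdname accessors
#' @export
setGeneric("embeddingMethod", function(object) standardGeneric("embeddingMethod"))
#' @rdname accessors
#' @export
setGeneric("windowData", function(object) standardGeneric("windowData"))
#' @rdname accessors
#' @export
setGeneric("diagnostics", function(object) standardGeneric("diagnostics"))
#' @rdname accessors
#' @export
setGeneric("graphWeights", function(object) standardGeneric("graphWeights"))
#' @rdname accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))
#' @rdname accessors
#' @export
setGeneric("idValue", function(object) standardGeneric("idValue"))
#' @rdname accessors
#' @export
setGeneric("localIdValues", function(object) standardGeneric("localIdValues"))
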