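#' @rdname pixels
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname extentMM
#' @export
setGeneric("extentMM", function(x) standardGeneric("extentMM"))

#' @rdname pixelSizeMM
#' @export
setGeneric("pixelSizeMM", function(x) standardGeneric("pixelSizeMM"))

#' @rdname areaMM2
#' @export
setGeneric("areaMM2", function(x) standardGeneric("areaMM2"))

#' @rdname eyeID
#' @export
setGeneric("eyeID", function(x) standardGeneric("eyeID"))

#' @rdname eyeID
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @rdname eyeID
#' @export
setGeneric("laterality", function(x) standardGeneric("laterality"))
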