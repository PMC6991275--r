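#' Pixel grid of a field image
#'
#' @param x a [FieldImage] derivative.
#' @return The underlying H x W matrix (numeric for images and responses,
#'   logical for masks).
#' @name pixels
#' @aliases pixels,FieldImage-method
#' @export
setMethod("pixels", "FieldImage", function(x) x@pixels)

#' Physical extent of the imaged field
#'
#' @param x a [FieldImage] or [WindowGrid].
#' @return numeric(2): field (width, height) in mm.
#' @name extentMM
#' @export
setMethod("extentMM", "FieldImage", function(x) x@extentMM)

#' @rdname extentMM
#' @export
setMethod("extentMM", "WindowGrid", function(x) x@extentMM)

#' Pixel size in mm
#'
#' @param x a [FieldImage] derivative.
#' @return numeric(2): pixel (width, height) in mm, i.e. extent over grid
#'   dimension. 12 mm over 500 samples gives 0.024 mm pixels.
#' @name pixelSizeMM
#' @export
setMethod("pixelSizeMM", "FieldImage", function(x)
    c(x@extentMM[1] / ncol(x@pixels), x@extentMM[2] / nrow(x@pixels)))

#' Physical area of a binary mask
#'
#' @param x a [BinaryMask].
#' @return Area of the `TRUE` pixels in mm^2 (pixel count times pixel area).
#' @name areaMM2
#' @export
setMethod("areaMM2", "BinaryMask", function(x) {
    ps <- pixelSizeMM(x)
    sum(x@pixels) * ps[1] * ps[2]
})

#' Identifiers of an angiogram
#'
#' @param x an [Angiogram].
#' @return `eyeID`/`subjectID`: character scalar; `laterality`: one of
#'   `"OD"`, `"OS"`, `"unknown"`.
#' @name eyeID
#' @export
setMethod("eyeID", "Angiogram", function(x) x@eyeID)

#' @rdname eyeID
#' @export
setMethod("subjectID", "Angiogram", function(x) x@subjectID)

#' @rdname eyeID
#' @export
setMethod("laterality", "Angiogram", function(x) x@laterality)

setMethod("show", "Angiogram", function(object) {
    d <- dim(object@pixels)
    cat(sprintf("Angiogram '%s' (%s): %d x %d px over %.3g x %.3g mm\n",
                object@eyeID, object@laterality, d[1], d[2],
                object@extentMM[1], object@extentMM[2]))
    cat(sprintf("  intensity range [%.3f, %.3f], pixel %.4g x %.4g mm\n",
                min(object@pixels), max(object@pixels),
                pixelSizeMM(object)[1], pixelSizeMM(object)[2]))
})

setMethod("show", "BinaryMask", function(object) {
    d <- dim(object@pixels)
    cat(sprintf("BinaryMask: %d x %d px over %.3g x %.3g mm; %d TRUE (%.2f%%), %.3f mm^2\n",
                d[1], d[2], object@extentMM[1], object@extentMM[2],
                sum(object@pixels), 100 * mean(object@pixels), areaMM2(object)))
})

setMethod("show", "VesselnessResponse", function(object) {
    d <- dim(object@pixels)
    cat(sprintf("VesselnessResponse: %d x %d px; %d orientations, Hessian scales {%s} px\n",
                d[1], d[2], object@nOrientations,
                paste(object@scalesPx, collapse = ", ")))
})

setMethod("show", "SegmentationResult", function(object) {
    cat("SegmentationResult\n")
    for (s in c("largeVessel", "capillary", "lowSignal", "exclusion"))
        cat(sprintf("  %-12s %6.2f%% of field\n", s,
                    100 * mean(slot(object, s)@pixels)))
})

setMethod("show", "WindowGrid", function(object) {
    cat(sprintf("WindowGrid: %d windows of %.3g mm at %.3g mm steps over %.3g x %.3g mm\n",
                nrow(object@windows), object@windowMM, object@stepMM,
                object@extentMM[1], object@extentMM[2]))
})

setMethod("show", "PhantomConfig", function(object) {
    cat(sprintf("PhantomConfig: %d x %d px / %.3g x %.3g mm, %d vessel trees, fill %.2f\n",
                object@gridPx[1], object@gridPx[2], object@extentMM[1],
                object@extentMM[2], object@nVesselTrees,
                object@capillaryFillFraction))
    cat(sprintf("  dropout: %d explicit + %d random patches (ecc bias %.2g); speckle sigma %.3g; seed %d\n",
                nrow(object@dropoutPatches), object@nDropoutPatches,
                object@eccentricityBias, object@speckleSigma, object@seed))
})

#' Construct a BinaryMask
#'
#' @param pixels logical matrix (numeric input is coerced by `> 0.5`).
#' @param extentMM numeric(2), field (width, height) mm.
#' @return A [BinaryMask].
#' @export
binaryMask <- function(pixels, extentMM) {
    if (!is.logical(pixels)) pixels <- pixels > 0.5
    new("BinaryMask", pixels = pixels, extentMM = as.numeric(extentMM))
}

#' Construct filter parameters for the large-vessel enhancement
#'
#' See [FilterParams] for the meaning and defaults of every argument.
#'
#' @param gaborWavelengthsPx,gaborOrientations,hessianScalesPx,combineRule
#'   see [FilterParams].
#' @param binarizeRule,fixedThreshold,minVesselAreaMM2 see [FilterParams].
#' @return A validated [FilterParams] object.
#' @export
filterParams <- function(gaborWavelengthsPx = c(6, 10, 16),
                         gaborOrientations = 12L,
                         hessianScalesPx = c(2, 4, 8),
                         combineRule = c("max", "product"),
                         binarizeRule = c("otsu", "fixed"),
                         fixedThreshold = NA_real_,
                         minVesselAreaMM2 = 0.01) {
    new("FilterParams",
        gaborWavelengthsPx = as.numeric(gaborWavelengthsPx),
        gaborOrientations = as.integer(gaborOrientations),
        hessianScalesPx = as.numeric(hessianScalesPx),
        combineRule = match.arg(combineRule),
        binarizeRule = match.arg(binarizeRule),
        fixedThreshold = as.numeric(fixedThreshold),
        minVesselAreaMM2 = as.numeric(minVesselAreaMM2))
}

#' Construct parameters for capillary segmentation and low-signal masking
#'
#' See [CapillaryParams] for the meaning and defaults of every argument; the
#' 0.35 threshold factor is the empirical fraction of the large-vessel mean
#' intensity that separates perfused capillaries from background.
#'
#' @param thresholdFactor,minVesselPxPerWindow,voteRule see [CapillaryParams].
#' @param lowSignalQuantile,lowSignalBlockMM,lowSignalRelFloor see
#'   [CapillaryParams].
#' @return A validated [CapillaryParams] object.
#' @export
capillaryParams <- function(thresholdFactor = 0.35,
                            minVesselPxPerWindow = 50L,
                            voteRule = c("majority", "any"),
                            lowSignalQuantile = 0.05,
                            lowSignalBlockMM = 0.6,
                            lowSignalRelFloor = 0.5) {
    new("CapillaryParams",
        thresholdFactor = as.numeric(thresholdFactor),
        minVesselPxPerWindow = as.integer(minVesselPxPerWindow),
        voteRule = match.arg(voteRule),
        lowSignalQuantile = as.numeric(lowSignalQuantile),
        lowSignalBlockMM = as.numeric(lowSignalBlockMM),
        lowSignalRelFloor = as.numeric(lowSignalRelFloor))
}
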