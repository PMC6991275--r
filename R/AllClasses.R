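#' @import methods
NULL

.validExtent <- function(extent) {
    if (length(extent) != 2L || !is.numeric(extent) || any(!is.finite(extent)) ||
        any(extent <= 0))
        return("extentMM must be two strictly positive finite numbers (width, height) in mm")
    TRUE
}

#' Field images: intensity or mask grids with a physical extent
#'
#' `FieldImage` is the virtual parent of every pixel grid in the package. The
#' grid is an H x W matrix whose rows run top to bottom (y) and whose columns
#' run left to right (x); `extentMM` gives the physical size of the imaged
#' field as (width, height) in millimetres. Pixel centres sit at
#' ((j - 0.5) * width/W, (i - 0.5) * height/H) mm for 1-based indices (i, j).
#'
#' @slot pixels matrix of intensities or logicals.
#' @slot extentMM numeric(2), field (width, height) in mm.
#' @name FieldImage-class
#' @aliases FieldImage
#' @exportClass FieldImage
setClass("FieldImage",
    representation("VIRTUAL", pixels = "matrix", extentMM = "numeric"))

#' En-face angiogram with physical metadata
#'
#' An `Angiogram` holds a maximum-projection en-face OCTA intensity image
#' normalised to [0, 1], together with the physical field size and the eye's
#' identifiers. The canonical wide-field geometry is a 12 x 12 mm field
#' sampled on a 500 x 500 grid (24 um pixels).
#'
#' @slot pixels numeric matrix in [0, 1].
#' @slot extentMM numeric(2), (width, height) mm.
#' @slot eyeID character scalar identifying the eye.
#' @slot subjectID character scalar identifying the subject (eyes cluster
#'   within subjects for the bootstrap statistics).
#' @slot group character scalar, cohort group label (may be `NA`).
#' @slot laterality one of `"OD"`, `"OS"`, `"unknown"`.
#' @seealso [readAngiogram()], [enhanceVessels()], [generatePhantom()]
#' @exportClass Angiogram
setClass("Angiogram", contains = "FieldImage",
    representation(eyeID = "character", subjectID = "character",
                   group = "character", laterality = "character"),
    prototype(eyeID = "eye", subjectID = NA_character_,
              group = NA_character_, laterality = "unknown"))

setValidity("Angiogram", function(object) {
    p <- object@pixels
    msg <- .validExtent(object@extentMM)
    if (!isTRUE(msg)) return(msg)
    if (nrow(p) < 16L || ncol(p) < 16L)
        return("angiogram grid must be at least 16 x 16 pixels")
    if (!is.numeric(p) || anyNA(p) || any(!is.finite(p)))
        return("angiogram intensities must be finite and non-missing")
    if (min(p) < 0 || max(p) > 1)
        return("angiogram intensities must lie in [0, 1]")
    if (!object@laterality %in% c("OD", "OS", "unknown"))
        return("laterality must be 'OD', 'OS' or 'unknown'")
    TRUE
})

#' Structural (non-angiographic) en-face image
#'
#' The structural projection paired with an [Angiogram]; used only to flag
#' low-OCT-signal areas that must not be scored as nonperfusion.
#'
#' @slot pixels numeric matrix in [0, 1].
#' @slot extentMM numeric(2) mm.
#' @seealso [lowSignalMask()]
#' @exportClass StructuralImage
setClass("StructuralImage", contains = "FieldImage")

setValidity("StructuralImage", function(object) {
    msg <- .validExtent(object@extentMM)
    if (!isTRUE(msg)) return(msg)
    p <- object@pixels
    if (!is.numeric(p) || anyNA(p) || any(!is.finite(p)) || min(p) < 0 || max(p) > 1)
        return("structural intensities must be finite and in [0, 1]")
    TRUE
})

#' Binary mask aligned to a field image
#'
#' A logical grid with the same shape and physical extent as the image it
#' annotates. The physical area of any subset is the count of `TRUE` pixels
#' times the pixel area in mm^2.
#'
#' @slot pixels logical matrix.
#' @slot extentMM numeric(2) mm.
#' @seealso [areaMM2()], [readMask()], [writeMask()]
#' @exportClass BinaryMask
setClass("BinaryMask", contains = "FieldImage")

setValidity("BinaryMask", function(object) {
    msg <- .validExtent(object@extentMM)
    if (!isTRUE(msg)) return(msg)
    if (!is.logical(object@pixels) || anyNA(object@pixels))
        return("mask pixels must be logical and non-missing")
    TRUE
})

#' Vesselness response map
#'
#' Output of the combined Gabor / Hessian large-vessel enhancement: a per-pixel
#' tubularity score normalised to [0, 1].
#'
#' @slot pixels numeric matrix in [0, 1].
#' @slot extentMM numeric(2) mm.
#' @slot scalesPx Hessian scales (pixels) used.
#' @slot nOrientations number of Gabor orientations used.
#' @seealso [enhanceVessels()], [segmentLargeVessels()]
#' @exportClass VesselnessResponse
setClass("VesselnessResponse", contains = "FieldImage",
    representation(scalesPx = "numeric", nOrientations = "integer"))

setValidity("VesselnessResponse", function(object) {
    msg <- .validExtent(object@extentMM)
    if (!isTRUE(msg)) return(msg)
    p <- object@pixels
    if (anyNA(p) || any(!is.finite(p)) || min(p) < 0 || max(p) > 1)
        return("response values must be finite and in [0, 1]")
    TRUE
})

#' Parameters of the large-vessel enhancement filter
#'
#' Defaults target vessels roughly 4-12 px wide, i.e. the calibre of the major
#' arcades at 24 um sampling: Gabor wavelengths {6, 10, 16} px over 12 evenly
#' spaced orientations (15 degrees apart), Frangi-style Hessian scales
#' {2, 4, 8} px, the two normalised responses combined by pixelwise `max`,
#' binarisation by Otsu's threshold on the combined response, and removal of
#' connected specks below 0.01 mm^2 so that capillary fragments never enter
#' the large-vessel class.
#'
#' @slot gaborWavelengthsPx Gabor carrier wavelengths, pixels.
#' @slot gaborOrientations number of evenly spaced orientations.
#' @slot hessianScalesPx Gaussian scales for the Hessian vesselness, pixels.
#' @slot combineRule `"max"` or `"product"`.
#' @slot binarizeRule `"otsu"` or `"fixed"`.
#' @slot fixedThreshold threshold in [0, 1] used when `binarizeRule = "fixed"`.
#' @slot minVesselAreaMM2 minimum component area kept in the vessel mask, mm^2.
#' @seealso [filterParams()], [enhanceVessels()]
#' @exportClass FilterParams
setClass("FilterParams",
    representation(gaborWavelengthsPx = "numeric", gaborOrientations = "integer",
                   hessianScalesPx = "numeric", combineRule = "character",
                   binarizeRule = "character", fixedThreshold = "numeric",
                   minVesselAreaMM2 = "numeric"),
    prototype(gaborWavelengthsPx = c(6, 10, 16), gaborOrientations = 12L,
              hessianScalesPx = c(2, 4, 8), combineRule = "max",
              binarizeRule = "otsu", fixedThreshold = NA_real_,
              minVesselAreaMM2 = 0.01))

setValidity("FilterParams", function(object) {
    if (length(object@gaborWavelengthsPx) == 0L || any(object@gaborWavelengthsPx <= 0))
        return("gaborWavelengthsPx must be a nonempty positive vector")
    if (length(object@hessianScalesPx) == 0L || any(object@hessianScalesPx <= 0))
        return("hessianScalesPx must be a nonempty positive vector")
    if (object@gaborOrientations < 1L)
        return("gaborOrientations must be >= 1")
    if (!object@combineRule %in% c("max", "product"))
        return("combineRule must be 'max' or 'product'")
    if (!object@binarizeRule %in% c("otsu", "fixed"))
        return("binarizeRule must be 'otsu' or 'fixed'")
    if (object@binarizeRule == "fixed" &&
        (is.na(object@fixedThreshold) || object@fixedThreshold < 0 ||
         object@fixedThreshold > 1))
        return("fixedThreshold must be in [0, 1] when binarizeRule = 'fixed'")
    if (object@minVesselAreaMM2 < 0)
        return("minVesselAreaMM2 must be >= 0")
    TRUE
})

#' Parameters of the sliding-window capillary segmentation
#'
#' The adaptive threshold in each sliding window is `thresholdFactor` (0.35)
#' times the mean angiogram intensity over the large-vessel pixels in that
#' window; windows holding fewer than `minVesselPxPerWindow` vessel pixels
#' fall back to the global large-vessel mean. Overlapping windows each cast a
#' binary vote per pixel; `voteRule` resolves them (majority, ties perfused).
#'
#' @slot thresholdFactor fraction of the large-vessel mean intensity, in (0, 1).
#' @slot minVesselPxPerWindow fallback trigger for vessel-poor windows.
#' @slot voteRule `"majority"` or `"any"`.
#' @slot lowSignalQuantile lower-tail quantile of local structural means
#'   flagged as low signal, in (0, 1).
#' @slot lowSignalBlockMM side of the local averaging block, mm.
#' @slot lowSignalRelFloor additional guard: a block is only flagged if its
#'   mean is also below this fraction of the whole-image mean, so that
#'   artifact-free images yield an empty low-signal mask.
#' @seealso [capillaryParams()], [segmentCapillaries()], [lowSignalMask()]
#' @exportClass CapillaryParams
setClass("CapillaryParams",
    representation(thresholdFactor = "numeric", minVesselPxPerWindow = "integer",
                   voteRule = "character", lowSignalQuantile = "numeric",
                   lowSignalBlockMM = "numeric", lowSignalRelFloor = "numeric"),
    prototype(thresholdFactor = 0.35, minVesselPxPerWindow = 50L,
              voteRule = "majority", lowSignalQuantile = 0.05,
              lowSignalBlockMM = 0.6, lowSignalRelFloor = 0.5))

setValidity("CapillaryParams", function(object) {
    if (object@thresholdFactor <= 0 || object@thresholdFactor >= 1)
        return("thresholdFactor must be in (0, 1)")
    if (object@lowSignalQuantile <= 0 || object@lowSignalQuantile >= 1)
        return("lowSignalQuantile must be in (0, 1)")
    if (!object@voteRule %in% c("majority", "any"))
        return("voteRule must be 'majority' or 'any'")
    if (object@lowSignalBlockMM <= 0)
        return("lowSignalBlockMM must be > 0")
    TRUE
})

#' Sliding-window grid over the imaged field
#'
#' Row-major list of rectangular pixel windows produced by
#' [buildWindowGrid()]. With the canonical 3 mm window and 1.5 mm step on a
#' 12 mm field there are 7 offsets per axis, hence 49 windows, and interior
#' pixels are covered by exactly 4 windows.
#'
#' @slot windowMM window side, mm.
#' @slot stepMM stride, mm.
#' @slot windows integer matrix with columns `y0, y1, x0, x1` (1-based,
#'   inclusive pixel ranges), one row per window in row-major order.
#' @slot dimPx integer(2), (rows, cols) of the underlying grid.
#' @slot extentMM numeric(2) mm.
#' @exportClass WindowGrid
setClass("WindowGrid",
    representation(windowMM = "numeric", stepMM = "numeric",
                   windows = "matrix", dimPx = "integer", extentMM = "numeric"))

#' Aligned segmentation masks for one eye
#'
#' Bundles the pairwise-aligned binary masks the downstream metrics need:
#' large vessels, capillaries (disjoint from the vessels by construction),
#' low-signal artifact pixels, and manual exclusions (foveal avascular zone
#' and optic disc). Perfusion is the union of the first two.
#'
#' @slot largeVessel,capillary,lowSignal,exclusion [BinaryMask] objects on a
#'   common grid.
#' @seealso [segmentEye()], [nonperfusionMap()], [computeMetrics()]
#' @exportClass SegmentationResult
setClass("SegmentationResult",
    representation(largeVessel = "BinaryMask", capillary = "BinaryMask",
                   lowSignal = "BinaryMask", exclusion = "BinaryMask"))

setValidity("SegmentationResult", function(object) {
    d <- dim(object@largeVessel@pixels)
    for (s in c("capillary", "lowSignal", "exclusion")) {
        if (!identical(dim(slot(object, s)@pixels), d))
            return(sprintf("mask '%s' is not aligned to the large-vessel mask", s))
    }
    if (any(object@largeVessel@pixels & object@capillary@pixels))
        return("large-vessel and capillary masks must be disjoint")
    TRUE
})

#' Configuration of the synthetic wide-field angiogram generator
#'
#' Defaults emulate the canonical acquisition: a 12 x 12 mm field on a
#' 500 x 500 grid, bright tubular large vessels (8 trees, 4-12 px wide) over
#' a dimmer perfused capillary mesh filling 55% of the extravascular area,
#' multiplicative log-normal speckle, and optional capillary-dropout disks
#' and low-OCT-signal patches. A single integer seed fixes every draw.
#'
#' @slot extentMM numeric(2) mm.
#' @slot gridPx integer(2), (rows, cols).
#' @slot nVesselTrees number of large-vessel trees.
#' @slot vesselWidthPxRange numeric(2), root calibre range in px.
#' @slot capillaryFillFraction target perfused fraction of non-vessel area.
#' @slot dropoutPatches matrix with columns `x_mm, y_mm, radius_mm`
#'   (0 rows for none); explicit patch placement.
#' @slot nDropoutPatches,dropoutRadiusRangeMM random patch placement used when
#'   `dropoutPatches` has no rows and `nDropoutPatches > 0`.
#' @slot eccentricityBias >= 0; exponent of the radial acceptance weight
#'   (d/d_max)^bias used when placing random patches: 0 samples uniformly,
#'   larger values concentrate dropout toward the field periphery.
#' @slot speckleSigma log-normal sigma of the multiplicative speckle.
#' @slot lowSignalPatches matrix with columns `x_mm, y_mm, radius_mm`.
#' @slot seed integer seed.
#' @seealso [phantomConfig()], [generatePhantom()]
#' @exportClass PhantomConfig
setClass("PhantomConfig",
    representation(extentMM = "numeric", gridPx = "integer",
                   nVesselTrees = "integer", vesselWidthPxRange = "numeric",
                   capillaryFillFraction = "numeric", dropoutPatches = "matrix",
                   nDropoutPatches = "integer", dropoutRadiusRangeMM = "numeric",
                   eccentricityBias = "numeric", speckleSigma = "numeric",
                   lowSignalPatches = "matrix", seed = "integer"),
    prototype(extentMM = c(12, 12), gridPx = c(500L, 500L), nVesselTrees = 8L,
              vesselWidthPxRange = c(4, 12), capillaryFillFraction = 0.55,
              dropoutPatches = matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("x_mm", "y_mm", "radius_mm"))),
              nDropoutPatches = 0L, dropoutRadiusRangeMM = c(0.5, 1.2),
              eccentricityBias = 0, speckleSigma = 0.15,
              lowSignalPatches = matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("x_mm", "y_mm", "radius_mm"))),
              seed = 1L))

setValidity("PhantomConfig", function(object) {
    msg <- .validExtent(object@extentMM)
    if (!isTRUE(msg)) return(msg)
    if (object@capillaryFillFraction < 0 || object@capillaryFillFraction > 1)
        return("capillaryFillFraction must be in [0, 1]")
    if (any(object@gridPx < 32L))
        return("gridPx must be at least 32 x 32")
    if (ncol(object@dropoutPatches) != 3L || ncol(object@lowSignalPatches) != 3L)
        return("patch matrices need columns x_mm, y_mm, radius_mm")
    if (object@eccentricityBias < 0) return("eccentricityBias must be >= 0")
    if (object@speckleSigma < 0) return("speckleSigma must be >= 0")
    TRUE
})

#' Ground truth attached to a synthetic phantom
#'
#' Exact masks from which the phantom image was rendered, plus the metric
#' table implied by those masks under the same regional definitions the
#' pipeline uses. Large-vessel and capillary truths are disjoint, and the
#' dropout truth is contained in the unperfused area.
#'
#' @slot lvTruth,capillaryTruth,dropoutTruth,lowSignalTruth [BinaryMask]s.
#' @slot designedMetrics data.frame of per-region metrics derived from the
#'   truth masks (see [computeMetrics()] for the schema).
#' @exportClass PhantomTruth
setClass("PhantomTruth",
    representation(lvTruth = "BinaryMask", capillaryTruth = "BinaryMask",
                   dropoutTruth = "BinaryMask", lowSignalTruth = "BinaryMask",
                   designedMetrics = "data.frame"))

setValidity("PhantomTruth", function(object) {
    if (any(object@lvTruth@pixels & object@capillaryTruth@pixels))
        return("vessel and capillary truths must be disjoint")
    perfused <- object@lvTruth@pixels | object@capillaryTruth@pixels
    if (any(object@dropoutTruth@pixels & perfused))
        return("dropout truth must lie in the unperfused area")
    TRUE
})
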