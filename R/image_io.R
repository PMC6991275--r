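## Raster I/O with physical metadata.
##
## Rasters are grayscale PNG or TIFF; physical metadata (field extent, eye and
## subject identifiers) travels in a JSON sidecar with the same basename,
## because TIFF/PNG tag dialects are unreliable across writers. Intensities
## are normalised by the container bit depth (what png/tiff readers return),
## never by the observed maximum: the 0.35 capillary threshold references
## measured vessel intensity and must not be confounded by a per-image
## contrast stretch.

.sidecarPath <- function(path) paste0(sub("\\.[A-Za-z]+$", "", path), ".json")

.readRaster <- function(path) {
    if (!file.exists(path))
        stop("raster file not found: ", path, call. = FALSE)
    ext <- tolower(sub(".*\\.", "", path))
    px <- switch(ext,
        png = png::readPNG(path),
        tif = ,
        tiff = tiff::readTIFF(path),
        stop("unsupported raster format '.", ext, "' for ", path, call. = FALSE))
    if (length(dim(px)) == 3L) {
        if (dim(px)[3] %in% c(2L, 4L)) # drop alpha
            px <- px[, , -dim(px)[3], drop = FALSE]
        if (dim(px)[3] == 1L) {
            px <- px[, , 1]
        } else if (all(px[, , 1] == px[, , 2]) && all(px[, , 1] == px[, , 3])) {
            px <- px[, , 1]
        } else {
            stop("raster is not grayscale: ", path, call. = FALSE)
        }
    }
    if (anyNA(px) || any(!is.finite(px)))
        stop("raster contains missing or non-finite samples: ", path,
             call. = FALSE)
    px
}

.readSidecar <- function(path, metadataPath) {
    if (is.null(metadataPath)) metadataPath <- .sidecarPath(path)
    if (!file.exists(metadataPath))
        stop("metadata sidecar not found for ", path, " (expected ",
             metadataPath, "); extent_mm cannot be defaulted", call. = FALSE)
    meta <- jsonlite::read_json(metadataPath, simplifyVector = TRUE)
    if (is.null(meta$extent_mm) || length(meta$extent_mm) != 2L)
        stop("metadata ", metadataPath,
             " must supply extent_mm as [width, height]", call. = FALSE)
    meta
}

#' Read an en-face angiogram with its metadata sidecar
#'
#' Reads a grayscale PNG/TIFF raster, rescaled to [0, 1] by the file's bit
#' depth, and attaches the physical extent and identifiers from a JSON
#' sidecar of the form
#' `{"extent_mm": [w, h], "eye_id": ..., "subject_id": ..., "group": ...,
#' "laterality": ...}`. The sidecar is mandatory: a missing physical extent
#' is a configuration error, never a silent default.
#'
#' @param path raster file (`.png`, `.tif`, `.tiff`).
#' @param metadataPath JSON sidecar; defaults to `path` with a `.json`
#'   extension.
#' @return An [Angiogram].
#' @examples
#' ph <- generatePhantom(phantomConfig(gridPx = c(64, 64), seed = 1))
#' td <- tempfile(); dir.create(td)
#' writeAngiogram(ph$angiogram, file.path(td, "eye.tif"))
#' img <- readAngiogram(file.path(td, "eye.tif"))
#' pixelSizeMM(img)
#' @export
readAngiogram <- function(path, metadataPath = NULL) {
    px <- .readRaster(path)
    meta <- .readSidecar(path, metadataPath)
    new("Angiogram", pixels = px, extentMM = as.numeric(meta$extent_mm),
        eyeID = as.character(meta$eye_id %||% basename(path)),
        subjectID = as.character(meta$subject_id %||% NA_character_),
        group = as.character(meta$group %||% NA_character_),
        laterality = as.character(meta$laterality %||% "unknown"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read the structural image paired with an angiogram
#'
#' @inheritParams readAngiogram
#' @return A [StructuralImage].
#' @export
readStructural <- function(path, metadataPath = NULL) {
    px <- .readRaster(path)
    meta <- .readSidecar(path, metadataPath)
    new("StructuralImage", pixels = px, extentMM = as.numeric(meta$extent_mm))
}

#' Write an angiogram or structural image as a 32-bit float TIFF
#'
#' Float TIFF keeps the round trip lossless; a JSON sidecar with the physical
#' metadata is written alongside.
#'
#' @param img an [Angiogram] or [StructuralImage].
#' @param path output `.tif`/`.tiff` path.
#' @return `path`, invisibly.
#' @export
writeAngiogram <- function(img, path) {
    tiff::writeTIFF(img@pixels, path, bits.per.sample = 32L)
    meta <- list(extent_mm = img@extentMM)
    if (is(img, "Angiogram"))
        meta <- c(meta, list(eye_id = img@eyeID, subject_id = img@subjectID,
                             group = img@group, laterality = img@laterality))
    jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' Read and write binary masks as 0/255 PNG
#'
#' Masks are stored single-channel with 0 = background, 255 = mask; the
#' physical extent travels in the JSON sidecar. The round trip preserves
#' every pixel.
#'
#' @param mask a [BinaryMask].
#' @param path PNG path.
#' @param metadataPath optional sidecar path (defaults to the raster basename
#'   with `.json`).
#' @return `writeMask`: `path` invisibly; `readMask`: a [BinaryMask].
#' @export
writeMask <- function(mask, path) {
    png::writePNG(ifelse(mask@pixels, 1, 0), path)
    jsonlite::write_json(list(extent_mm = mask@extentMM), .sidecarPath(path),
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path, metadataPath = NULL) {
    px <- .readRaster(path)
    meta <- .readSidecar(path, metadataPath)
    binaryMask(px > 0.5, as.numeric(meta$extent_mm))
}

#' Write and read the per-eye, per-region metrics table
#'
#' One CSV row per (eye, region) with columns `eye_id, subject_id, group,
#' region, TPD_pct, CPD_pct, LVD_pct, CDD_pct` (values in percent). Written
#' at full double precision so a write/read round trip is lossless to well
#' below 1e-9.
#'
#' @param records data.frame of metric records (see [computeMetrics()]).
#' @param path CSV path.
#' @return `writeMetricsTable`: `path` invisibly; `readMetricsTable`: the
#'   data.frame.
#' @export
writeMetricsTable <- function(records, path) {
    if (NROW(records) == 0L)
        stop("records must be nonempty", call. = FALSE)
    need <- c("eye_id", "subject_id", "group", "region",
              "TPD_pct", "CPD_pct", "LVD_pct", "CDD_pct")
    miss <- setdiff(need, names(records))
    if (length(miss))
        stop("records lack columns: ", paste(miss, collapse = ", "),
             call. = FALSE)
    out <- records[need]
    for (v in c("TPD_pct", "CPD_pct", "LVD_pct", "CDD_pct"))
        out[[v]] <- sprintf("%.17g", out[[v]])
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    invisible(path)
}

#' @rdname writeMetricsTable
#' @export
readMetricsTable <- function(path) {
    if (!file.exists(path))
        stop("metrics table not found: ", path, call. = FALSE)
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                    colClasses = c(eye_id = "character",
                                   subject_id = "character",
                                   group = "character", region = "character"))
}
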