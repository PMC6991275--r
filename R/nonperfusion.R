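## Nonperfusion and capillary-dropout detection. The perfusion map (large
## vessels plus capillaries) is inverted so nonperfusion is 1; connected
## intercapillary components strictly larger than 0.36 mm^2 are capillary
## dropout, everything smaller is normal intercapillary space. The foveal
## avascular zone and the optic disc are physiologically or anatomically
## capillary-free and are excluded via manual masks.

#' Assemble a SegmentationResult from aligned masks
#'
#' Low-signal and exclusion pixels are removed from the vessel and capillary
#' masks here, so every downstream consumer sees masks that already honour
#' the artifact filtering.
#'
#' @param largeVessel,capillary [BinaryMask]s from the segmentation steps.
#' @param lowSignal optional low-signal [BinaryMask] (default empty).
#' @param exclusion optional manual exclusion [BinaryMask] (FAZ and/or optic
#'   disc; default empty).
#' @return A [SegmentationResult].
#' @export
segmentationResult <- function(largeVessel, capillary, lowSignal = NULL,
                               exclusion = NULL) {
    d <- dim(largeVessel@pixels); ext <- largeVessel@extentMM
    emptyMask <- function() binaryMask(matrix(FALSE, d[1], d[2]), ext)
    if (is.null(lowSignal)) lowSignal <- emptyMask()
    if (is.null(exclusion)) exclusion <- emptyMask()
    drop <- lowSignal@pixels | exclusion@pixels
    new("SegmentationResult",
        largeVessel = binaryMask(largeVessel@pixels & !drop, ext),
        capillary = binaryMask(capillary@pixels & !largeVessel@pixels & !drop,
                               ext),
        lowSignal = lowSignal, exclusion = exclusion)
}

#' Invert the perfusion map
#'
#' Nonperfusion is the complement of the perfused pixels (large vessels and
#' capillaries) within the valid area: low-signal pixels carry no perfusion
#' information and are not part of the map.
#'
#' @param seg a [SegmentationResult].
#' @return A [BinaryMask] with `TRUE` on nonperfused valid pixels.
#' @export
nonperfusionMap <- function(seg) {
    stopifnot(is(seg, "SegmentationResult"))
    perf <- seg@largeVessel@pixels | seg@capillary@pixels
    binaryMask(!perf & !seg@lowSignal@pixels, seg@largeVessel@extentMM)
}

#' Detect capillary-dropout regions
#'
#' Labels the connected components of the nonperfusion map (8-connected by
#' default), removes components touching the manual FAZ/optic-disc masks
#' (whole-component removal by default, avoiding ring residue around the
#' FAZ; `mode = "remove_pixels"` subtracts the masks before labelling), and
#' keeps components whose physical area strictly exceeds `minAreaMM2`
#' (0.36 mm^2): at 24 um pixels the 625-px component (exactly 0.36 mm^2) is
#' rejected and a 626-px component kept. Border-touching components are
#' retained and flagged, since peripheral dropout is the signal of interest.
#'
#' @param npmap nonperfusion [BinaryMask] (see [nonperfusionMap()]).
#' @param faz,disc optional manual exclusion [BinaryMask]s.
#' @param minAreaMM2 strict area threshold, mm^2.
#' @param connectivity 8 (default) or 4.
#' @param mode `"remove_component"` or `"remove_pixels"`.
#' @param keepBorder keep components touching the field border (default
#'   `TRUE`).
#' @return data.frame with one row per dropout region, sorted by descending
#'   area: `label, pixel_count, area_mm2, centroid_x_mm, centroid_y_mm,
#'   touches_border`. The relabelled component matrix is attached as
#'   attribute `"labels"` and the extent as `"extentMM"`, so the regions can
#'   be rasterised again with [dropoutMask()].
#' @export
detectDropout <- function(npmap, faz = NULL, disc = NULL, minAreaMM2 = 0.36,
                          connectivity = 8L,
                          mode = c("remove_component", "remove_pixels"),
                          keepBorder = TRUE) {
    stopifnot(is(npmap, "BinaryMask"))
    mode <- match.arg(mode)
    ps <- pixelSizeMM(npmap)
    if (any(!is.finite(ps)) || any(ps <= 0))
        stop("pixel size could not be derived from the mask extent",
             call. = FALSE)
    np <- npmap@pixels
    excl <- matrix(FALSE, nrow(np), ncol(np))
    if (!is.null(faz)) excl <- excl | faz@pixels
    if (!is.null(disc)) excl <- excl | disc@pixels
    if (mode == "remove_pixels") np <- np & !excl
    lab <- labelComponents(np, connectivity)
    nlab <- max(lab)
    emptyResult <- function() {
        out <- data.frame(label = integer(0), pixel_count = integer(0),
                          area_mm2 = numeric(0), centroid_x_mm = numeric(0),
                          centroid_y_mm = numeric(0),
                          touches_border = logical(0))
        attr(out, "labels") <- matrix(0L, nrow(np), ncol(np))
        attr(out, "extentMM") <- npmap@extentMM
        out
    }
    if (nlab == 0L) return(emptyResult())
    if (mode == "remove_component" && any(excl)) {
        bad <- unique(lab[excl & lab > 0L])
        if (length(bad)) {
            lab[lab %in% bad] <- 0L
            nlab <- max(lab)
            if (nlab == 0L) return(emptyResult())
        }
    }
    cnt <- .componentCounts(lab)
    pxArea <- ps[1] * ps[2]
    keep <- which(cnt * pxArea > minAreaMM2)        # strictly more than
    if (keepBorder == FALSE) {
        border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                           lab[, ncol(lab)]))
        keep <- setdiff(keep, border[border > 0L])
    }
    if (length(keep) == 0L) return(emptyResult())
    idx <- which(lab > 0L & matrix(lab %in% keep, nrow(lab), ncol(lab)))
    labKept <- lab
    labKept[!(labKept %in% keep)] <- 0L
    ij <- arrayInd(idx, dim(lab))
    lv <- labKept[idx]
    cx <- tapply((ij[, 2] - 0.5) * ps[1], lv, mean)
    cy <- tapply((ij[, 1] - 0.5) * ps[2], lv, mean)
    onBorder <- tapply(ij[, 1] == 1L | ij[, 1] == nrow(lab) |
                       ij[, 2] == 1L | ij[, 2] == ncol(lab), lv, any)
    labsOut <- as.integer(names(cx))
    out <- data.frame(label = labsOut, pixel_count = cnt[labsOut],
                      area_mm2 = cnt[labsOut] * pxArea,
                      centroid_x_mm = as.numeric(cx),
                      centroid_y_mm = as.numeric(cy),
                      touches_border = as.logical(onBorder))
    out <- out[order(-out$area_mm2, out$label), , drop = FALSE]
    rownames(out) <- NULL
    ## relabel compactly in the sorted order
    remap <- integer(max(labsOut))
    remap[out$label] <- seq_len(nrow(out))
    fg <- labKept > 0L
    labKept[fg] <- remap[labKept[fg]]
    out$label <- seq_len(nrow(out))
    attr(out, "labels") <- labKept
    attr(out, "extentMM") <- npmap@extentMM
    out
}

#' Rasterise dropout regions into a mask
#'
#' @param regions the data.frame returned by [detectDropout()].
#' @param labels optional subset of region labels to keep (default all).
#' @return A [BinaryMask]: the union of the member pixels of the selected
#'   regions. Re-detecting on this mask returns the identical region set.
#' @export
dropoutMask <- function(regions, labels = regions$label) {
    lab <- attr(regions, "labels")
    if (is.null(lab))
        stop("regions must come from detectDropout()", call. = FALSE)
    binaryMask(matrix(lab %in% labels[labels > 0L], nrow(lab), ncol(lab)),
               attr(regions, "extentMM"))
}
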