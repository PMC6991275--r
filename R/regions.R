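## Regional scheme and the four perfusion metrics. Two independent region
## schemes cover the full field: (i) the wide field split into a centred
## central square (default 6 x 6 mm) and the remaining square annulus, and
## (ii) a uniform block grid (default 5 x 5, i.e. 2.4 mm blocks on a 12 mm
## field). Region membership is decided per pixel centre, so the 25 blocks
## partition the wide field exactly and block metrics reassemble the
## wide-field metric by area weighting.

#' Build the region registry for one field
#'
#' Returns 28 regions for the default geometry: `wide`, `central6`,
#' `annulus`, and `block_r_c` for r, c in 0..4 (row-major from the top-left
#' block). Each region carries its full mask and a valid mask with
#' low-signal and manual exclusion pixels removed; metric denominators use
#' the valid mask.
#'
#' @param extentMM numeric(2) mm.
#' @param dimPx integer(2), grid (rows, cols).
#' @param centralMM side of the central square, mm (default 6).
#' @param blockGrid blocks per axis (default 5).
#' @param exclusion,lowSignal optional [BinaryMask]s removed from the valid
#'   area.
#' @return Named list of regions; each element is a list with `name`,
#'   `mask` (logical matrix), `validMask`, `areaMM2` (valid area) and
#'   `nominalAreaMM2`.
#' @examples
#' regs <- buildRegions(c(12, 12), c(100L, 100L))
#' regs$annulus$nominalAreaMM2  # 108
#' @export
buildRegions <- function(extentMM, dimPx, centralMM = 6, blockGrid = 5L,
                         exclusion = NULL, lowSignal = NULL) {
    extentMM <- as.numeric(extentMM); dimPx <- as.integer(dimPx)
    if (centralMM >= min(extentMM))
        stop("central square (", centralMM, " mm) must be smaller than the field",
             call. = FALSE)
    H <- dimPx[1]; W <- dimPx[2]
    psx <- extentMM[1] / W; psy <- extentMM[2] / H
    cx <- (seq_len(W) - 0.5) * psx
    cy <- (seq_len(H) - 0.5) * psy
    inv <- matrix(TRUE, H, W)
    if (!is.null(lowSignal)) inv <- inv & !lowSignal@pixels
    if (!is.null(exclusion)) inv <- inv & !exclusion@pixels
    pxArea <- psx * psy
    mk <- function(name, mask, nominal) {
        valid <- mask & inv
        list(name = name, mask = mask, validMask = valid,
             areaMM2 = sum(valid) * pxArea, nominalAreaMM2 = nominal)
    }
    wide <- matrix(TRUE, H, W)
    lo <- (extentMM - centralMM) / 2
    hi <- lo + centralMM
    central <- outer(cy >= lo[2] & cy < hi[2], cx >= lo[1] & cx < hi[1], "&")
    regions <- list(
        wide = mk("wide", wide, prod(extentMM)),
        central6 = mk("central6", central, centralMM^2),
        annulus = mk("annulus", wide & !central,
                     prod(extentMM) - centralMM^2))
    bw <- extentMM[1] / blockGrid; bh <- extentMM[2] / blockGrid
    colIdx <- pmin(blockGrid - 1L, floor(cx / bw))
    rowIdx <- pmin(blockGrid - 1L, floor(cy / bh))
    for (r in 0:(blockGrid - 1L)) for (cc in 0:(blockGrid - 1L)) {
        nm <- sprintf("block_%d_%d", r, cc)
        regions[[nm]] <- mk(nm, outer(rowIdx == r, colIdx == cc, "&"),
                            bw * bh)
    }
    regions
}

#' Compute the four perfusion metrics over one region
#'
#' All four metrics are class area per valid imaged area, in percent:
#' total perfusion density (TPD, vessels plus capillaries), capillary
#' perfusion density (CPD), large vessel density (LVD) and capillary dropout
#' density (CDD). Low-signal and manual exclusion pixels are excluded from
#' numerator and denominator alike, and because the capillary and vessel
#' classes are disjoint the identity TPD = CPD + LVD holds exactly.
#'
#' @param seg a [SegmentationResult].
#' @param dropout dropout [BinaryMask] (see [dropoutMask()]); `NULL` for
#'   none.
#' @param region one element of [buildRegions()].
#' @param eyeID,subjectID,group identifiers copied into the record.
#' @return One-row data.frame: `eye_id, subject_id, group, region,
#'   TPD_pct, CPD_pct, LVD_pct, CDD_pct, valid_area_mm2, valid` (`valid` is
#'   `FALSE` with `NA` metrics when the region has no valid area).
#' @export
computeMetrics <- function(seg, dropout, region, eyeID = "eye",
                           subjectID = NA_character_, group = NA_character_) {
    stopifnot(is(seg, "SegmentationResult"))
    valid <- region$validMask
    denom <- sum(valid)
    rec <- data.frame(eye_id = eyeID, subject_id = subjectID, group = group,
                      region = region$name, TPD_pct = NA_real_,
                      CPD_pct = NA_real_, LVD_pct = NA_real_,
                      CDD_pct = NA_real_, valid_area_mm2 = 0,
                      valid = FALSE, stringsAsFactors = FALSE)
    if (denom == 0L) {
        message("region '", region$name, "' has zero valid area; record flagged invalid")
        return(rec)
    }
    lv <- seg@largeVessel@pixels; cap <- seg@capillary@pixels
    dp <- if (is.null(dropout)) FALSE else dropout@pixels
    rec$LVD_pct <- 100 * sum(lv & valid) / denom
    rec$CPD_pct <- 100 * sum(cap & valid) / denom
    rec$TPD_pct <- 100 * sum((lv | cap) & valid) / denom
    rec$CDD_pct <- if (is.null(dropout)) 0 else 100 * sum(dp & valid) / denom
    ps <- pixelSizeMM(seg@largeVessel)
    rec$valid_area_mm2 <- denom * ps[1] * ps[2]
    rec$valid <- TRUE
    rec
}

#' Compute metrics over every region in a registry
#'
#' @inheritParams computeMetrics
#' @param regions the list returned by [buildRegions()].
#' @return data.frame with one row per region (28 for the default
#'   geometry).
#' @export
computeAllMetrics <- function(seg, dropout, regions, eyeID = "eye",
                              subjectID = NA_character_,
                              group = NA_character_) {
    out <- do.call(rbind, lapply(regions, computeMetrics, seg = seg,
                                 dropout = dropout, eyeID = eyeID,
                                 subjectID = subjectID, group = group))
    rownames(out) <- NULL
    out
}

#' Relative perfusion change per block between two groups
#'
#' For each of the `blockGrid^2` blocks, the relative change of the mean
#' metric of the target group against the reference group:
#' (mean_target - mean_reference) / mean_reference. A zero reference mean
#' gives `NA` for that cell.
#'
#' @param records metric data.frame holding `block_r_c` rows for many eyes
#'   (the schema of [computeAllMetrics()]).
#' @param targetGroup,referenceGroup group labels.
#' @param metric metric column (default `"CPD_pct"`).
#' @param blockGrid blocks per axis (default 5).
#' @return `blockGrid` x `blockGrid` numeric matrix (rows top to bottom).
#' @export
blockHeatmap <- function(records, targetGroup, referenceGroup,
                         metric = "CPD_pct", blockGrid = 5L) {
    out <- matrix(NA_real_, blockGrid, blockGrid)
    for (r in 0:(blockGrid - 1L)) for (cc in 0:(blockGrid - 1L)) {
        nm <- sprintf("block_%d_%d", r, cc)
        sel <- records$region == nm
        tg <- records[[metric]][sel & records$group == targetGroup]
        rf <- records[[metric]][sel & records$group == referenceGroup]
        if (!length(tg) || !length(rf)) next
        mr <- mean(rf, na.rm = TRUE)
        if (is.na(mr) || mr == 0) next
        out[r + 1L, cc + 1L] <- (mean(tg, na.rm = TRUE) - mr) / mr
    }
    out
}
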