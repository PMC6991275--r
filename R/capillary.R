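## Sliding-window adaptive capillary segmentation. The threshold in each
## 3 x 3 mm window is 0.35 of the mean angiogram intensity over the
## large-vessel pixels it contains, so the capillary cutoff tracks the local
## signal level; windows overlap (1.5 mm step) and vote per pixel to avoid
## tiling seams.

#' Build the sliding-window grid over the field
#'
#' Window offsets run from 0 in steps of `stepMM` while the window fits the
#' field; if the final offset does not reach the border, one border-flush
#' window per axis is appended (for the canonical 12 / 3 / 1.5 geometry this
#' never fires). A pixel belongs to a window when its centre falls inside
#' the window's half-open mm interval, so with window = 2 x step every
#' interior pixel is covered by exactly four windows. Windows are ordered
#' row-major.
#'
#' @param extentMM numeric(2), field (width, height) mm.
#' @param dimPx integer(2), grid (rows, cols).
#' @param windowMM window side in mm (default 3).
#' @param stepMM stride in mm (default 1.5).
#' @return A [WindowGrid].
#' @examples
#' g <- buildWindowGrid(c(12, 12), c(500L, 500L))
#' nrow(g@windows)  # 49
#' @export
buildWindowGrid <- function(extentMM, dimPx, windowMM = 3, stepMM = 1.5) {
    extentMM <- as.numeric(extentMM); dimPx <- as.integer(dimPx)
    if (windowMM > min(extentMM) + 1e-9)
        stop("window (", windowMM, " mm) larger than the field", call. = FALSE)
    if (stepMM <= 0) stop("stepMM must be > 0", call. = FALSE)
    axisRanges <- function(extent, n) {
        offs <- seq(0, extent - windowMM + 1e-9, by = stepMM)
        if (max(offs) < extent - windowMM - 1e-9)
            offs <- c(offs, extent - windowMM)
        centers <- (seq_len(n) - 0.5) * extent / n
        t(vapply(offs, function(o) {
            hi <- o + windowMM
            sel <- if (hi >= extent - 1e-9)
                centers >= o - 1e-9
            else
                centers >= o - 1e-9 & centers < hi - 1e-9
            range(which(sel))
        }, numeric(2)))
    }
    ry <- axisRanges(extentMM[2], dimPx[1])   # rows follow height
    rx <- axisRanges(extentMM[1], dimPx[2])
    win <- do.call(rbind, lapply(seq_len(nrow(ry)), function(i)
        cbind(y0 = ry[i, 1], y1 = ry[i, 2], x0 = rx[, 1], x1 = rx[, 2])))
    storage.mode(win) <- "integer"
    new("WindowGrid", windowMM = windowMM, stepMM = stepMM, windows = win,
        dimPx = dimPx, extentMM = extentMM)
}

.windowStats <- function(p, lv, grid, params) {
    globalMean <- mean(p[lv])
    w <- grid@windows
    t(vapply(seq_len(nrow(w)), function(i) {
        ys <- w[i, 1]:w[i, 2]; xs <- w[i, 3]:w[i, 4]
        lvw <- lv[ys, xs]
        n <- sum(lvw)
        m <- if (n >= params@minVesselPxPerWindow) mean(p[ys, xs][lvw])
             else globalMean
        c(nLvPx = n, lvMean = m, threshold = params@thresholdFactor * m)
    }, numeric(3)))
}

#' Per-window capillary thresholds (audit table)
#'
#' @inheritParams segmentCapillaries
#' @return data.frame with one row per window: pixel bounds, large-vessel
#'   pixel count, the vessel mean used (global fallback when the window
#'   holds fewer than `minVesselPxPerWindow` vessel pixels) and the
#'   resulting threshold.
#' @export
windowThresholds <- function(img, lvMask, grid, params = capillaryParams()) {
    st <- .windowStats(img@pixels, lvMask@pixels, grid, params)
    data.frame(window = seq_len(nrow(grid@windows)), grid@windows, st)
}

#' Segment perfused capillaries with the sliding-window adaptive threshold
#'
#' In each window the threshold is `thresholdFactor` (0.35) times the mean
#' angiogram intensity over the large-vessel pixels in the window (global
#' large-vessel mean when the window is vessel-poor). Every window votes
#' `intensity >= threshold` for the pixels it covers; the final label is the
#' majority of covering windows (ties perfused) or, under
#' `voteRule = "any"`, a single positive vote. Large-vessel pixels are then
#' removed so the capillary and large-vessel classes are disjoint by
#' construction and total perfusion density decomposes exactly as
#' TPD = CPD + LVD.
#'
#' @param img an [Angiogram].
#' @param lvMask large-vessel [BinaryMask] aligned to `img`.
#' @param grid a [WindowGrid] (default: canonical 3 mm / 1.5 mm grid).
#' @param params a [CapillaryParams].
#' @return A [BinaryMask] of capillary pixels, disjoint from `lvMask`.
#' @export
segmentCapillaries <- function(img, lvMask,
                               grid = buildWindowGrid(extentMM(img),
                                                      dim(pixels(img))),
                               params = capillaryParams()) {
    stopifnot(is(img, "Angiogram"), is(lvMask, "BinaryMask"))
    p <- img@pixels; lv <- lvMask@pixels
    if (!identical(dim(p), dim(lv)))
        stop("large-vessel mask is not aligned to the angiogram", call. = FALSE)
    if (!any(lv))
        stop("large-vessel mask is empty: the adaptive threshold references ",
             "vessel intensity; segment vessels first or binarise with a ",
             "fixed threshold", call. = FALSE)
    st <- .windowStats(p, lv, grid, params)
    cover <- matrix(0L, nrow(p), ncol(p))
    pass <- matrix(0L, nrow(p), ncol(p))
    w <- grid@windows
    for (i in seq_len(nrow(w))) {
        ys <- w[i, 1]:w[i, 2]; xs <- w[i, 3]:w[i, 4]
        cover[ys, xs] <- cover[ys, xs] + 1L
        pass[ys, xs] <- pass[ys, xs] + (p[ys, xs] >= st[i, "threshold"])
    }
    final <- switch(params@voteRule,
                    majority = 2L * pass >= cover,
                    any = pass >= 1L)
    binaryMask(final & !lv, img@extentMM)
}

#' Flag low-OCT-signal areas from the structural image
#'
#' Nonperfusion cannot be scored where the OCT signal itself is lost, so
#' pixels whose local mean structural intensity (averaged over a
#' `lowSignalBlockMM` block) falls in the lower `lowSignalQuantile` tail of
#' the image's block means -- and below `lowSignalRelFloor` times the image
#' mean, so that artifact-free images yield an empty mask -- are flagged.
#' Flagged pixels are excluded from every downstream mask and from all area
#' denominators.
#'
#' @param struct a [StructuralImage].
#' @param params a [CapillaryParams].
#' @return A [BinaryMask] of low-signal pixels (possibly empty).
#' @export
lowSignalMask <- function(struct, params = capillaryParams()) {
    stopifnot(is(struct, "StructuralImage"))
    p <- struct@pixels
    ps <- pixelSizeMM(struct)
    k <- max(3L, round(params@lowSignalBlockMM / ps[1]))
    if (k %% 2L == 0L) k <- k + 1L
    local <- .conv(p, matrix(1 / (k * k), k, k))
    thr <- stats::quantile(local, params@lowSignalQuantile, names = FALSE)
    flag <- local <= thr & local < params@lowSignalRelFloor * mean(local)
    binaryMask(flag, struct@extentMM)
}
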