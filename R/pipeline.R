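## One-call orchestration of the per-eye pipeline: vessel enhancement ->
## large-vessel mask -> sliding-window capillaries -> low-signal filtering
## -> nonperfusion inversion -> dropout rule -> regional metrics. Every
## stage is deterministic, so a fixed configuration reproduces every mask
## and table bit for bit.

#' Segment one eye end to end
#'
#' Runs the full segmentation chain on an angiogram, optionally filtering
#' low-signal artifacts from the paired structural image and excluding
#' manual FAZ/optic-disc masks from the dropout calculation. When no
#' structural image is supplied the low-signal step is skipped with a
#' warning and the QC summary records the skip.
#'
#' @param angiogram an [Angiogram].
#' @param structural optional [StructuralImage] paired with the angiogram.
#' @param faz,disc optional manual exclusion [BinaryMask]s.
#' @param fparams [FilterParams] for vessel enhancement/binarisation.
#' @param cparams [CapillaryParams] for capillary segmentation and
#'   low-signal masking.
#' @param connectivity component connectivity for dropout detection.
#' @return List: `seg` ([SegmentationResult]), `dropoutRegions`
#'   (data.frame from [detectDropout()]), `dropoutMask` ([BinaryMask]),
#'   `nonperfusion` ([BinaryMask]) and `qc` (vessel coverage, low-signal
#'   fraction, dropout count and flags).
#' @export
segmentEye <- function(angiogram, structural = NULL, faz = NULL, disc = NULL,
                       fparams = filterParams(), cparams = capillaryParams(),
                       connectivity = 8L) {
    stopifnot(is(angiogram, "Angiogram"))
    resp <- enhanceVessels(angiogram, fparams)
    lv <- segmentLargeVessels(resp, angiogram, fparams)
    lowSig <- NULL
    if (is.null(structural)) {
        warning("no structural image supplied: low-signal filtering skipped",
                call. = FALSE)
    } else {
        lowSig <- lowSignalMask(structural, cparams)
    }
    grid <- buildWindowGrid(angiogram@extentMM, dim(angiogram@pixels))
    cap <- segmentCapillaries(angiogram, lv, grid, cparams)
    excl <- NULL
    if (!is.null(faz) || !is.null(disc)) {
        d <- dim(angiogram@pixels)
        ex <- matrix(FALSE, d[1], d[2])
        if (!is.null(faz)) ex <- ex | faz@pixels
        if (!is.null(disc)) ex <- ex | disc@pixels
        excl <- binaryMask(ex, angiogram@extentMM)
    }
    seg <- segmentationResult(lv, cap, lowSignal = lowSig, exclusion = excl)
    np <- nonperfusionMap(seg)
    regions <- detectDropout(np, faz = faz, disc = disc,
                             connectivity = connectivity)
    dmask <- dropoutMask(regions)
    qc <- list(eye_id = angiogram@eyeID,
               vessel_fraction = mean(seg@largeVessel@pixels),
               capillary_fraction = mean(seg@capillary@pixels),
               low_signal_fraction = mean(seg@lowSignal@pixels),
               low_signal_skipped = is.null(structural),
               n_dropout_regions = nrow(regions))
    list(seg = seg, dropoutRegions = regions, dropoutMask = dmask,
         nonperfusion = np, qc = qc)
}

#' Segment one eye and compute its regional metrics
#'
#' Convenience wrapper around [segmentEye()], [buildRegions()] and
#' [computeAllMetrics()]: returns the 28-row regional metric table for the
#' default geometry together with the segmentation artifacts.
#'
#' @inheritParams segmentEye
#' @param centralMM,blockGrid regional geometry (defaults 6 mm and 5).
#' @return List: everything [segmentEye()] returns plus `metrics` (the
#'   per-region data.frame).
#' @export
processEye <- function(angiogram, structural = NULL, faz = NULL, disc = NULL,
                       fparams = filterParams(), cparams = capillaryParams(),
                       connectivity = 8L, centralMM = 6, blockGrid = 5L) {
    res <- segmentEye(angiogram, structural, faz = faz, disc = disc,
                      fparams = fparams, cparams = cparams,
                      connectivity = connectivity)
    excl <- res$seg@exclusion
    if (!any(excl@pixels)) excl <- NULL
    regions <- buildRegions(angiogram@extentMM, dim(angiogram@pixels),
                            centralMM = centralMM, blockGrid = blockGrid,
                            exclusion = excl, lowSignal = res$seg@lowSignal)
    res$metrics <- computeAllMetrics(res$seg, res$dropoutMask, regions,
                                     eyeID = angiogram@eyeID,
                                     subjectID = angiogram@subjectID,
                                     group = angiogram@group)
    res
}

#' Test-retest repeatability (ICC) from paired scans
#'
#' @param pairs data.frame with columns `subject_id`, `scan` (1 or 2) and
#'   the metric columns; exactly two rows per subject. Unpaired subjects
#'   are excluded with a warning.
#' @param metrics metric column names.
#' @return data.frame with one [iccTwoWay()] row per metric.
#' @export
runRepeatability <- function(pairs,
                             metrics = c("TPD_pct", "CPD_pct", "LVD_pct",
                                         "CDD_pct")) {
    cnt <- table(pairs$subject_id)
    good <- names(cnt)[cnt == 2L]
    if (length(good) < length(cnt))
        warning(sum(cnt != 2L), " subject(s) without a scan pair excluded")
    pairs <- pairs[pairs$subject_id %in% good, ]
    do.call(rbind, lapply(metrics, function(m) {
        wide <- cbind(pairs[[m]][pairs$scan == 1][order(pairs$subject_id[pairs$scan == 1])],
                      pairs[[m]][pairs$scan == 2][order(pairs$subject_id[pairs$scan == 2])])
        iccTwoWay(wide, metric = m)
    }))
}
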