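## Synthetic wide-field angiogram phantoms with exact ground truth.
##
## The generator renders the image properties the pipeline assumes: bright
## tubular large vessels (random-walk tubes entering from the border and
## tapering toward the centre) over a dimmer perfused capillary mesh, with
## optional capillary-dropout disks, low-OCT-signal patches and
## multiplicative log-normal speckle (decorrelation angiograms are
## speckle-dominated). The capillary texture is built as a closed cellular
## mesh -- the dilated boundary set of smoothed-noise level cells -- so the
## unperfused background decomposes into small intercapillary cells, as it
## does in a real angiogram, instead of one percolating component.

#' Construct a phantom configuration
#'
#' See [PhantomConfig] for the meaning and defaults of every field.
#'
#' @param extentMM,gridPx,nVesselTrees,vesselWidthPxRange see
#'   [PhantomConfig].
#' @param capillaryFillFraction,dropoutPatches,nDropoutPatches see
#'   [PhantomConfig].
#' @param dropoutRadiusRangeMM,eccentricityBias,speckleSigma see
#'   [PhantomConfig].
#' @param lowSignalPatches,seed see [PhantomConfig].
#' @return A validated [PhantomConfig].
#' @export
phantomConfig <- function(extentMM = c(12, 12), gridPx = c(500L, 500L),
                          nVesselTrees = 8L, vesselWidthPxRange = c(4, 12),
                          capillaryFillFraction = 0.55,
                          dropoutPatches = NULL, nDropoutPatches = 0L,
                          dropoutRadiusRangeMM = c(0.5, 1.2),
                          eccentricityBias = 0, speckleSigma = 0.15,
                          lowSignalPatches = NULL, seed = 1L) {
    emptyPatches <- matrix(numeric(0), 0, 3,
                           dimnames = list(NULL, c("x_mm", "y_mm", "radius_mm")))
    asPatches <- function(p) {
        if (is.null(p) || NROW(p) == 0L) return(emptyPatches)
        p <- matrix(as.numeric(p), ncol = 3,
                    dimnames = list(NULL, c("x_mm", "y_mm", "radius_mm")))
        p
    }
    new("PhantomConfig", extentMM = as.numeric(extentMM),
        gridPx = as.integer(gridPx), nVesselTrees = as.integer(nVesselTrees),
        vesselWidthPxRange = as.numeric(vesselWidthPxRange),
        capillaryFillFraction = as.numeric(capillaryFillFraction),
        dropoutPatches = asPatches(dropoutPatches),
        nDropoutPatches = as.integer(nDropoutPatches),
        dropoutRadiusRangeMM = as.numeric(dropoutRadiusRangeMM),
        eccentricityBias = as.numeric(eccentricityBias),
        speckleSigma = as.numeric(speckleSigma),
        lowSignalPatches = asPatches(lowSignalPatches),
        seed = as.integer(seed))
}

.diskOffsets <- function(r) {
    ri <- ceiling(r)
    g <- seq(-ri, ri)
    ij <- expand.grid(dy = g, dx = g)
    ij[ij$dy^2 + ij$dx^2 <= r^2, , drop = FALSE]
}

.stampDisk <- function(mask, i, j, r) {
    off <- .diskOffsets(r)
    ii <- i + off$dy; jj <- j + off$dx
    ok <- ii >= 1L & ii <= nrow(mask) & jj >= 1L & jj <= ncol(mask)
    mask[cbind(ii[ok], jj[ok])] <- TRUE
    mask
}

.diskMaskMM <- function(dimPx, extentMM, x_mm, y_mm, r_mm) {
    cx <- (seq_len(dimPx[2]) - 0.5) * extentMM[1] / dimPx[2]
    cy <- (seq_len(dimPx[1]) - 0.5) * extentMM[2] / dimPx[1]
    outer((cy - y_mm)^2, (cx - x_mm)^2, "+") <= r_mm^2
}

## Random-walk vessel tubes entering from the border, tapering toward the
## centre, each with one thinner side branch.
.drawVesselTrees <- function(H, W, n, widthRange) {
    mask <- matrix(FALSE, H, W)
    walk <- function(i, j, ang, w0, L) {
        m <- matrix(FALSE, H, W)
        for (s in seq_len(L)) {
            ang <- ang + stats::rnorm(1, 0, 0.05)
            ## gentle steering toward the field centre keeps tubes in frame
            tc <- atan2(H / 2 - i, W / 2 - j)
            d <- atan2(sin(tc - ang), cos(tc - ang))
            ang <- ang + 0.015 * d
            i <- i + sin(ang); j <- j + cos(ang)
            if (i < -5 || i > H + 5 || j < -5 || j > W + 5) break
            r <- (w0 / 2) * (1 - 0.6 * s / L)
            if (s %% 2L == 0L)
                m <- .stampDisk(m, round(i), round(j), r)
        }
        list(mask = m, i = i, j = j)
    }
    for (t in seq_len(n)) {
        side <- sample.int(4L, 1L)
        pos <- switch(side,
            c(1, stats::runif(1, 1, W), pi / 2),        # top, heading down
            c(H, stats::runif(1, 1, W), -pi / 2),       # bottom, heading up
            c(stats::runif(1, 1, H), 1, 0),             # left, heading right
            c(stats::runif(1, 1, H), W, pi))            # right, heading left
        ang <- pos[3] + stats::runif(1, -0.5, 0.5)
        w0 <- stats::runif(1, widthRange[1], widthRange[2])
        L <- round(0.7 * min(H, W))
        tr <- walk(pos[1], pos[2], ang, w0, L)
        mask <- mask | tr$mask
        ## one side branch from a point partway along the parent
        bs <- round(stats::runif(1, 0.3, 0.6) * L)
        br <- walk(pos[1] + bs * 0.5 * sin(ang), pos[2] + bs * 0.5 * cos(ang),
                   ang + sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.1),
                   0.7 * w0, round(L / 2))
        mask <- mask | br$mask
    }
    mask
}

## Cellular capillary mesh hitting a target fill fraction outside vessels.
## The cell scale is physical (cellSigmaMM) so intercapillary spaces keep a
## realistic area regardless of the sampling grid; 0.053 mm gives ~0.25 mm
## cells, well below the 0.36 mm^2 dropout cutoff.
.capillaryMesh <- function(H, W, lv, fillFraction, pxMM,
                           cellSigmaMM = 0.053) {
    edgeOf <- function(cells) {
        edge <- matrix(FALSE, H, W)
        edge[-H, ] <- edge[-H, ] | (cells[-H, ] != cells[-1, ])
        edge[-1, ] <- edge[-1, ] | (cells[-1, ] != cells[-H, ])
        edge[, -W] <- edge[, -W] | (cells[, -W] != cells[, -1])
        edge[, -1] <- edge[, -1] | (cells[, -1] != cells[, -W])
        edge
    }
    ## Two independent contour webs at different scales: a single median
    ## level set of smoothed noise has elongated percolating phases whose
    ## interiors can exceed the 0.36 mm^2 cutoff; superimposing a coarser
    ## web chops them into compact intercapillary cells, as in a real
    ## capillary bed.
    webAt <- function(sigmaPx) {
        sm <- EBImage::imageData(EBImage::gblur(
            matrix(stats::runif(H * W), H, W), sigma = sigmaPx))
        edgeOf(sm > stats::median(sm))
    }
    s1 <- max(1.8, cellSigmaMM / pxMM)
    edge <- webAt(s1) | webAt(2 * s1)
    ## dilate the mesh to the target fraction via the distance transform;
    ## the jitter breaks the ties of the discrete distance values so the
    ## realized fraction matches the target closely
    d <- EBImage::imageData(EBImage::distmap(1 - edge))
    d <- d + matrix(stats::runif(H * W, 0, 0.35), H, W)
    outside <- !lv
    thr <- stats::quantile(d[outside], fillFraction, names = FALSE)
    (d <= thr) & outside
}

.applySpeckle <- function(img, sigma) {
    if (sigma <= 0) return(img)
    n <- length(img)
    sp <- exp(stats::rnorm(n, 0, sigma) - sigma^2 / 2)
    pmin(pmax(img * matrix(sp, nrow(img), ncol(img)), 0), 1)
}

.drawPatches <- function(cfg) {
    if (nrow(cfg@dropoutPatches) > 0L) return(cfg@dropoutPatches)
    if (cfg@nDropoutPatches == 0L)
        return(cfg@dropoutPatches)
    ext <- cfg@extentMM
    ctr <- ext / 2
    dmax <- sqrt(sum(ctr^2))
    out <- matrix(NA_real_, cfg@nDropoutPatches, 3,
                  dimnames = list(NULL, c("x_mm", "y_mm", "radius_mm")))
    for (k in seq_len(cfg@nDropoutPatches)) {
        r <- stats::runif(1, cfg@dropoutRadiusRangeMM[1],
                          cfg@dropoutRadiusRangeMM[2])
        repeat {
            x <- stats::runif(1, r, ext[1] - r)
            y <- stats::runif(1, r, ext[2] - r)
            ## radial acceptance weight (d/dmax)^bias: 0 = uniform, larger
            ## exponents concentrate patches toward the periphery
            tt <- sqrt(sum((c(x, y) - ctr)^2)) / dmax
            if (stats::runif(1) <= tt^cfg@eccentricityBias) break
        }
        out[k, ] <- c(x, y, r)
    }
    out
}

#' Generate a synthetic wide-field angiogram with exact ground truth
#'
#' Renders an angiogram/structural pair from the configuration: vessel trees
#' at intensity ~0.9 and the capillary mesh at ~0.5 over a 0.05 background,
#' a light 0.4 px blur for band-limited optics, dropout disks that erase the
#' capillary mesh (never the large vessels), low-signal patches that darken
#' both images, and multiplicative speckle. The ground-truth dropout mask is
#' derived from the truth perfusion masks by the same component rule the
#' pipeline applies (8-connected intercapillary components strictly above
#' 0.36 mm^2), so designed and measured dropout quantify the same geometric
#' object. The same seed reproduces every output bit for bit.
#'
#' @param cfg a [PhantomConfig].
#' @return List with elements `angiogram` ([Angiogram]), `structural`
#'   ([StructuralImage]), `truth` ([PhantomTruth]), `noiseless` (the
#'   speckle-free rendered matrix, used by [rescanPhantom()]) and `patches`
#'   (the dropout disks actually placed).
#' @examples
#' ph <- generatePhantom(phantomConfig(gridPx = c(128, 128), seed = 7,
#'                                     nDropoutPatches = 2L))
#' ph$truth@designedMetrics[1, c("TPD_pct", "CPD_pct", "LVD_pct", "CDD_pct")]
#' @export
generatePhantom <- function(cfg) {
    stopifnot(is(cfg, "PhantomConfig"))
    if (cfg@capillaryFillFraction > 1)
        stop("capillaryFillFraction > 1 is infeasible", call. = FALSE)
    set.seed(cfg@seed)
    H <- cfg@gridPx[1]; W <- cfg@gridPx[2]
    ext <- cfg@extentMM
    lv <- .drawVesselTrees(H, W, cfg@nVesselTrees, cfg@vesselWidthPxRange)
    cap <- .capillaryMesh(H, W, lv, cfg@capillaryFillFraction, ext[1] / W)
    patches <- .drawPatches(cfg)
    for (k in seq_len(nrow(patches)))
        cap <- cap & !.diskMaskMM(c(H, W), ext, patches[k, 1], patches[k, 2],
                                  patches[k, 3])
    ls <- matrix(FALSE, H, W)
    for (k in seq_len(nrow(cfg@lowSignalPatches)))
        ls <- ls | .diskMaskMM(c(H, W), ext, cfg@lowSignalPatches[k, 1],
                               cfg@lowSignalPatches[k, 2],
                               cfg@lowSignalPatches[k, 3])
    ## render
    img <- matrix(0.05, H, W)
    img[cap] <- 0.5
    img[lv] <- 0.9
    img <- EBImage::imageData(EBImage::gblur(img, sigma = 0.4))
    img[ls] <- img[ls] * 0.08
    img <- pmin(pmax(img, 0), 1)
    noiseless <- img
    img <- .applySpeckle(img, cfg@speckleSigma)
    struct <- matrix(0.85, H, W) + matrix(stats::runif(H * W, -0.03, 0.03),
                                          H, W)
    struct[ls] <- 0.05
    struct <- pmin(pmax(struct, 0), 1)
    ## truth masks and the metrics they imply
    lvMask <- binaryMask(lv & !ls, ext)
    capMask <- binaryMask(cap & !ls & !lv, ext)
    lsMask <- binaryMask(ls, ext)
    segTruth <- segmentationResult(lvMask, capMask, lowSignal = lsMask)
    npTruth <- nonperfusionMap(segTruth)
    dropRegions <- detectDropout(npTruth)
    dropMask <- dropoutMask(dropRegions)
    regions <- buildRegions(ext, c(H, W), lowSignal = lsMask)
    designed <- computeAllMetrics(segTruth, dropMask, regions,
                                  eyeID = sprintf("phantom_seed%d", cfg@seed))
    angio <- new("Angiogram", pixels = img, extentMM = ext,
                 eyeID = sprintf("phantom_seed%d", cfg@seed),
                 laterality = "unknown")
    truth <- new("PhantomTruth", lvTruth = lvMask, capillaryTruth = capMask,
                 dropoutTruth = dropMask, lowSignalTruth = lsMask,
                 designedMetrics = designed)
    list(angiogram = angio,
         structural = new("StructuralImage", pixels = struct, extentMM = ext),
         truth = truth, noiseless = noiseless, patches = patches)
}

#' Re-scan a phantom: same anatomy, fresh speckle
#'
#' Emulates an immediate repeat acquisition of the same eye: the noiseless
#' render is kept and only the multiplicative speckle is redrawn.
#'
#' @param phantom the list returned by [generatePhantom()].
#' @param seed integer seed for the new speckle draw.
#' @param speckleSigma log-normal sigma (default 0.15).
#' @return An [Angiogram] of the repeat scan.
#' @export
rescanPhantom <- function(phantom, seed, speckleSigma = 0.15) {
    set.seed(seed)
    img <- .applySpeckle(phantom$noiseless, speckleSigma)
    a <- phantom$angiogram
    new("Angiogram", pixels = img, extentMM = a@extentMM,
        eyeID = paste0(a@eyeID, "_rescan"), subjectID = a@subjectID,
        group = a@group, laterality = a@laterality)
}

#' Generate a synthetic cohort of phantom eyes
#'
#' Draws `nSubjects` subjects per group with `eyesPerSubject` eyes each.
#' Eyes within a subject share an additive random effect on the capillary
#' fill fraction (truncated normal, SD `subjectSdFill`), inducing the
#' intra-subject correlation the clustered bootstrap is designed for. Group
#' severity is encoded in the group configurations, typically by a
#' nondecreasing number of dropout patches.
#'
#' @param groupConfigs named list of [PhantomConfig]s in severity order
#'   (e.g. control, noDR, mildNPDR, modsevNPDR).
#' @param nSubjects subjects per group (>= 2).
#' @param eyesPerSubject eyes per subject (default 2).
#' @param seed master seed; per-eye seeds are derived from it.
#' @param subjectSdFill SD of the subject effect on fill fraction
#'   (default 0.03).
#' @param runPipeline also run the full segmentation pipeline per eye and
#'   return pipeline-derived metrics (slower; default `FALSE`).
#' @param outDir optional directory: eyes and truth masks are written
#'   through the raster I/O layer and a manifest CSV is produced.
#' @return List with `manifest` (one row per eye), `truthMetrics`
#'   (region-level metrics from the truth masks) and `pipelineMetrics`
#'   (`NULL` unless `runPipeline`).
#' @export
generateCohort <- function(groupConfigs, nSubjects, eyesPerSubject = 2L,
                           seed = 1L, subjectSdFill = 0.03,
                           runPipeline = FALSE, outDir = NULL) {
    stopifnot(is.list(groupConfigs), length(groupConfigs) >= 1L,
              !is.null(names(groupConfigs)))
    if (nSubjects < 2L)
        stop("need at least 2 subjects per group for downstream statistics",
             call. = FALSE)
    set.seed(seed)
    nEyes <- length(groupConfigs) * nSubjects * eyesPerSubject
    eyeSeeds <- sample.int(.Machine$integer.max - 1L, nEyes)
    manifest <- NULL; truthMetrics <- NULL; pipeMetrics <- NULL
    k <- 0L
    for (g in names(groupConfigs)) {
        baseCfg <- groupConfigs[[g]]
        for (s in seq_len(nSubjects)) {
            subj <- sprintf("%s_s%02d", g, s)
            offset <- max(-2 * subjectSdFill,
                          min(2 * subjectSdFill,
                              stats::rnorm(1, 0, subjectSdFill)))
            for (e in seq_len(eyesPerSubject)) {
                k <- k + 1L
                cfg <- baseCfg
                cfg@seed <- eyeSeeds[k]
                cfg@capillaryFillFraction <-
                    min(1, max(0, baseCfg@capillaryFillFraction + offset))
                ph <- generatePhantom(cfg)
                eye <- sprintf("%s_e%d", subj, e)
                tm <- ph$truth@designedMetrics
                tm$eye_id <- eye; tm$subject_id <- subj; tm$group <- g
                truthMetrics <- rbind(truthMetrics, tm)
                manifest <- rbind(manifest, data.frame(
                    eye_id = eye, subject_id = subj, group = g,
                    seed = eyeSeeds[k], stringsAsFactors = FALSE))
                if (runPipeline) {
                    pm <- processEye(ph$angiogram, ph$structural)$metrics
                    pm$eye_id <- eye; pm$subject_id <- subj; pm$group <- g
                    pipeMetrics <- rbind(pipeMetrics, pm)
                }
                if (!is.null(outDir)) {
                    a <- ph$angiogram
                    a@eyeID <- eye; a@subjectID <- subj; a@group <- g
                    writeAngiogram(a, file.path(outDir,
                                                paste0(eye, "_angio.tif")))
                    writeAngiogram(ph$structural,
                                   file.path(outDir,
                                             paste0(eye, "_struct.tif")))
                }
            }
        }
    }
    rownames(truthMetrics) <- NULL
    if (!is.null(pipeMetrics)) rownames(pipeMetrics) <- NULL
    if (!is.null(outDir))
        utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                         row.names = FALSE)
    list(manifest = manifest, truthMetrics = truthMetrics,
         pipelineMetrics = pipeMetrics)
}
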