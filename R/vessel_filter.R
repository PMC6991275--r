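## Large-vessel enhancement: a combined Gabor and Hessian (Frangi-style)
## tubularity filter followed by thresholding. Both branches are normalised
## to [0, 1] before combination so neither dominates by scale, and both are
## signed for bright-on-dark ridges (angiogram polarity): the even Gabor
## response is clipped at zero and only negative-second-eigenvalue Hessian
## responses are counted.

.minmax01 <- function(m) {
    lo <- min(m); hi <- max(m)
    if (hi - lo <= 1e-9 * max(abs(hi), abs(lo), 1)) # constant map guard
        return(matrix(0, nrow(m), ncol(m)))
    (m - lo) / (hi - lo)
}

.conv <- function(img, kernel) {
    ## crop oversized kernels symmetrically so small images stay usable
    crop <- function(k, d, n) {
        if (k <= n) return(NULL)
        hs <- (if (n %% 2L == 0L) n - 1L else n - 2L) %/% 2L
        ctr <- (k + 1L) %/% 2L
        (ctr - hs):(ctr + hs)
    }
    ri <- crop(nrow(kernel), 1, nrow(img))
    ci <- crop(ncol(kernel), 2, ncol(img))
    if (!is.null(ri)) kernel <- kernel[ri, , drop = FALSE]
    if (!is.null(ci)) kernel <- kernel[, ci, drop = FALSE]
    EBImage::imageData(EBImage::filter2(img, kernel, boundary = "replicate"))
}

## Zero-DC even-phase Gabor kernel; bright bars along orientation theta give
## a positive centre response. sigma = 0.56 * wavelength is the one-octave
## bandwidth choice; gamma < 1 elongates the envelope along the bar.
.gaborKernel <- function(wavelengthPx, theta, gamma = 0.5, sigmaFactor = 0.56) {
    sigma <- sigmaFactor * wavelengthPx
    hs <- ceiling(2.5 * sigma / gamma)
    g <- seq(-hs, hs)
    x <- outer(rep(1, length(g)), g)   # column coordinate
    y <- outer(g, rep(1, length(g)))   # row coordinate
    xr <- x * cos(theta) + y * sin(theta)
    yr <- -x * sin(theta) + y * cos(theta)
    env <- exp(-(xr^2 + (gamma * yr)^2) / (2 * sigma^2))
    carrier <- cos(2 * pi * xr / wavelengthPx)
    k <- env * carrier
    k - env * (sum(k) / sum(env))      # remove DC within the envelope
}

## Scale-normalised Gaussian-derivative kernels for the Hessian at scale s.
.hessianKernels <- function(sigma) {
    hs <- ceiling(3 * sigma)
    g <- seq(-hs, hs)
    x <- outer(rep(1, length(g)), g)
    y <- outer(g, rep(1, length(g)))
    G <- exp(-(x^2 + y^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
    list(xx = sigma^2 * ((x^2 - sigma^2) / sigma^4) * G,
         yy = sigma^2 * ((y^2 - sigma^2) / sigma^4) * G,
         xy = sigma^2 * (x * y / sigma^4) * G)
}

.frangiVesselness <- function(img, sigma, beta = 0.5) {
    k <- .hessianKernels(sigma)
    Lxx <- .conv(img, k$xx); Lyy <- .conv(img, k$yy); Lxy <- .conv(img, k$xy)
    half <- (Lxx + Lyy) / 2
    disc <- sqrt(((Lxx - Lyy) / 2)^2 + Lxy^2)
    e1 <- half + disc; e2 <- half - disc
    swap <- abs(e1) > abs(e2)              # lambda2 = larger magnitude
    l1 <- ifelse(swap, e2, e1)
    l2 <- ifelse(swap, e1, e2)
    S2 <- l1^2 + l2^2
    c2 <- max(S2) / 4                      # c = max(S)/2, adaptive per scale
    if (c2 <= 0) return(matrix(0, nrow(img), ncol(img)))
    Rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
    v <- exp(-Rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * c2)))
    v[l2 >= 0] <- 0                        # bright ridges only
    v
}

#' Enhance large retinal vessels with a combined Gabor/Hessian filter
#'
#' Computes two tubularity maps -- the maximum over orientations and
#' wavelengths of an even-phase, zero-DC Gabor bank, and the maximum over
#' scales of a Frangi-style Hessian vesselness -- each min-max normalised to
#' [0, 1], then combines them per pixel by the rule in `params` (default
#' `max`). No orientation is privileged: rotating the input by 90 degrees
#' rotates the response. A constant image yields an all-zero response.
#'
#' @param img an [Angiogram].
#' @param params a [FilterParams].
#' @return A [VesselnessResponse].
#' @examples
#' ph <- generatePhantom(phantomConfig(gridPx = c(96, 96), seed = 3))
#' resp <- enhanceVessels(ph$angiogram)
#' range(pixels(resp))
#' @export
enhanceVessels <- function(img, params = filterParams()) {
    stopifnot(is(img, "Angiogram"), is(params, "FilterParams"))
    p <- img@pixels
    thetas <- (seq_len(params@gaborOrientations) - 1L) * pi /
        params@gaborOrientations
    gab <- matrix(0, nrow(p), ncol(p))
    for (lam in params@gaborWavelengthsPx)
        for (th in thetas)
            gab <- pmax(gab, pmax(.conv(p, .gaborKernel(lam, th)), 0))
    gab <- .minmax01(gab)
    hes <- matrix(0, nrow(p), ncol(p))
    for (s in params@hessianScalesPx)
        hes <- pmax(hes, .frangiVesselness(p, s))
    hes <- .minmax01(hes)
    resp <- switch(params@combineRule,
                   max = pmax(gab, hes),
                   product = gab * hes)
    new("VesselnessResponse", pixels = resp, extentMM = img@extentMM,
        scalesPx = params@hessianScalesPx,
        nOrientations = params@gaborOrientations)
}

#' Binarise the vesselness response into a large-vessel mask
#'
#' Thresholds the combined response (Otsu's method on the response histogram
#' by default, or a fixed threshold for reproducibility pinning), constrains
#' the mask to pixels brighter than the image median (vessels are bright in
#' an angiogram), and removes connected specks smaller than
#' `minVesselAreaMM2` so capillary fragments never enter the large-vessel
#' class. An all-zero response yields an empty mask with a message.
#'
#' @param resp the [VesselnessResponse] computed on `img`.
#' @param img the source [Angiogram].
#' @param params a [FilterParams].
#' @return A [BinaryMask] of large-vessel pixels.
#' @export
segmentLargeVessels <- function(resp, img, params = filterParams()) {
    stopifnot(is(resp, "VesselnessResponse"), is(img, "Angiogram"))
    r <- resp@pixels
    if (max(r) == 0) {
        message("vesselness response is identically zero; returning empty mask")
        return(binaryMask(matrix(FALSE, nrow(r), ncol(r)), img@extentMM))
    }
    thr <- if (params@binarizeRule == "fixed") params@fixedThreshold
           else EBImage::otsu(EBImage::Image(r), range = c(0, 1))
    mask <- r >= thr
    mask <- mask & (img@pixels > stats::median(img@pixels))
    ps <- pixelSizeMM(img)
    minPx <- ceiling(params@minVesselAreaMM2 / (ps[1] * ps[2]))
    if (minPx > 1L) mask <- .dropSmallComponents(mask, minPx)
    binaryMask(mask, img@extentMM)
}
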