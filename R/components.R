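## Connected-component labelling on binary grids.
##
## EBImage::bwlabel provides fast 4-connected labelling; 8-connectivity is
## obtained by merging 4-connected labels that touch diagonally with a small
## union-find over label ids. Diagonal gaps between visually continuous
## nonperfusion patches merge under 8-connectivity, which is the package
## default for dropout detection.

#' Label connected components of a binary grid
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of the same shape: 0 for background, 1..n for the
#'   components (labels are compact but otherwise arbitrary).
#' @export
labelComponents <- function(mask, connectivity = 8L) {
    stopifnot(is.matrix(mask))
    if (!is.logical(mask)) mask <- mask > 0.5
    lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
    storage.mode(lab) <- "integer"
    nlab <- max(lab)
    if (connectivity == 4L || nlab <= 1L) return(lab)
    if (connectivity != 8L) stop("connectivity must be 4 or 8", call. = FALSE)
    nr <- nrow(lab); nc <- ncol(lab)
    ## diagonally adjacent, differently labelled foreground pairs
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # \ diagonal
    a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # / diagonal
    keep1 <- a1 > 0L & b1 > 0L & a1 != b1
    keep2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                          cbind(a2[keep2], b2[keep2])))
    if (nrow(pairs) == 0L) return(lab)
    parent <- seq_len(nlab)
    findRoot <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    for (r in seq_len(nrow(pairs))) {
        ra <- findRoot(pairs[r, 1]); rb <- findRoot(pairs[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(nlab), findRoot, integer(1))
    compact <- match(root, sort(unique(root)))
    out <- lab
    fg <- lab > 0L
    out[fg] <- compact[lab[fg]]
    out
}

## pixel counts per label (1..max), excluding background
.componentCounts <- function(lab) {
    if (max(lab) == 0L) return(integer(0))
    tabulate(lab[lab > 0L], nbins = max(lab))
}

## drop components whose pixel count is below minPx (strictly)
.dropSmallComponents <- function(mask, minPx, connectivity = 8L) {
    lab <- labelComponents(mask, connectivity)
    if (max(lab) == 0L) return(mask)
    cnt <- .componentCounts(lab)
    keep <- which(cnt >= minPx)
    matrix(lab %in% keep, nrow(mask), ncol(mask))
}
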