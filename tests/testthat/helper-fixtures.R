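# Shared fixtures built in code. Small geometric images with known masks,
# plus independent brute-force oracles used across test files.

# straight bright tube of given width (px) through the image centre, at
# angle theta (radians), on a dark background
tubeImage <- function(n = 96, widthPx = 8, theta = 0, fg = 0.9, bg = 0.05,
                      extent = c(12, 12)) {
  cx <- (seq_len(n) - 0.5) - n / 2
  x <- outer(rep(1, n), cx)
  y <- outer(cx, rep(1, n))
  d <- abs(-x * sin(theta) + y * cos(theta))   # distance to tube axis
  px <- ifelse(d <= widthPx / 2, fg, bg)
  new("Angiogram", pixels = px, extentMM = extent, eyeID = "tube")
}

tubeTruth <- function(n = 96, widthPx = 8, theta = 0) {
  cx <- (seq_len(n) - 0.5) - n / 2
  x <- outer(rep(1, n), cx)
  y <- outer(cx, rep(1, n))
  abs(-x * sin(theta) + y * cos(theta)) <= widthPx / 2
}

# brute-force flood-fill component labelling (queue-based), the oracle for
# labelComponents()
floodLabel <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), 1)
    lab[i, j] <- cur
    while (nrow(queue) > 0L) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(nb))) {
        ii <- p[1] + nb[k, 1]; jj <- p[2] + nb[k, 2]
        if (ii >= 1L && ii <= H && jj >= 1L && jj <= W &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  lab
}

# partition-equivalence of two labelings
sameLabeling <- function(a, b) {
  if (max(a) != max(b)) return(FALSE)
  fg <- a > 0L
  if (!identical(fg, b > 0L)) return(FALSE)
  all(tapply(b[fg], a[fg], function(v) length(unique(v))) == 1L)
}

diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# cohort table of per-eye values with subject clustering:
# x = sqrt(rho) * subject effect + sqrt(1 - rho) * eye noise + group shift
simClusteredTable <- function(nSubj = 30, eyes = 2, rho = 0.5,
                              shifts = c(A = 0, B = 0)) {
  rows <- NULL
  for (g in names(shifts)) {
    subj <- rnorm(nSubj)
    for (s in seq_len(nSubj)) {
      x <- shifts[[g]] + sqrt(rho) * subj[s] +
        sqrt(1 - rho) * rnorm(eyes)
      rows <- rbind(rows, data.frame(
        eye_id = sprintf("%s%02d_%d", g, s, seq_len(eyes)),
        subject_id = sprintf("%s%02d", g, s), group = g, value = x))
    }
  }
  rows
}
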