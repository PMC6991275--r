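# Independent oracles: brute-force ANOVA mean squares for the ICC, a
# stand-alone step-up implementation for BH, exhaustive pair counting for
# the AUC, and a placement-value computation for the DeLong variance.

iccOracle <- function(m) {
  # two-way ANOVA mean squares via aov, then the absolute-agreement
  # single-measure formula
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  MSR <- tab["subj", "Mean Sq"]; MSC <- tab["rater", "Mean Sq"]
  MSE <- tab["Residuals", "Mean Sq"]
  n <- nrow(m); k <- ncol(m)
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

bhOracle <- function(p) {
  m <- length(p); o <- order(p)
  adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  out <- numeric(m); out[o] <- adj
  out
}

aucOracle <- function(scores, labels, caseLevel, positiveLow = TRUE) {
  cases <- scores[labels == caseLevel]
  ctrls <- scores[labels != caseLevel]
  tot <- 0
  for (ca in cases) for (co in ctrls)
    tot <- tot + if (positiveLow) (co > ca) + 0.5 * (co == ca)
                 else (ca > co) + 0.5 * (ca == co)
  tot / (length(cases) * length(ctrls))
}

# DeLong variance of auc1 - auc2 from placement values
delongOracle <- function(s1, s2, labels, caseLevel, positiveLow = TRUE) {
  placements <- function(s) {
    # orient so higher = more diseased
    if (positiveLow) s <- -s
    x <- s[labels == caseLevel]; y <- s[labels != caseLevel]
    m <- length(x); n <- length(y)
    V10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), 0)
    V01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), 0)
    list(auc = mean(V10), V10 = V10, V01 = V01, m = m, n = n)
  }
  p1 <- placements(s1); p2 <- placements(s2)
  s10 <- stats::cov(cbind(p1$V10, p2$V10))
  s01 <- stats::cov(cbind(p1$V01, p2$V01))
  S <- s10 / p1$m + s01 / p1$n
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  z <- (p1$auc - p2$auc) / sqrt(v)
  list(delta = p1$auc - p2$auc, p = 2 * stats::pnorm(-abs(z)))
}

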