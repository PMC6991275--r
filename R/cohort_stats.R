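## Cohort statistics: test-retest ICC, z-normalised group contrasts by
## subject-clustered bootstrap with Benjamini-Hochberg correction, linear
## orthogonal trend contrasts, and ROC/AUC with DeLong comparison of
## correlated curves. Eyes cluster within subjects, so every bootstrap
## resamples subjects and carries both of a subject's eyes together.

#' Two-way random-effects intraclass correlation (absolute agreement,
#' single measurement)
#'
#' Computes ICC(A,1) from the two-way ANOVA mean squares of an
#' n-subjects x k-ratings matrix (k = 2 repeated scans for test-retest):
#' ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n), with MSR the
#' between-subject, MSC the between-rating and MSE the residual mean
#' square. Bands follow the 0.50 / 0.75 / 0.90 cutpoints (poor, moderate,
#' good, excellent), values exactly at a cutpoint falling in the lower
#' band.
#'
#' @param data numeric matrix, n subjects x k repeated measurements, no
#'   missing cells, n >= 3.
#' @param metric optional metric name carried into the result.
#' @return data.frame: `metric, icc, band, n_subjects, n_ratings`. Zero
#'   total variance yields `NA` ICC with band `"undefined"`.
#' @export
iccTwoWay <- function(data, metric = NA_character_) {
    data <- as.matrix(data)
    if (anyNA(data)) stop("ICC input must have no missing cells", call. = FALSE)
    n <- nrow(data); k <- ncol(data)
    if (n < 3L) stop("ICC needs at least 3 subjects", call. = FALSE)
    if (k < 2L) stop("ICC needs at least 2 repeated measurements", call. = FALSE)
    grand <- mean(data)
    rowm <- rowMeans(data); colm <- colMeans(data)
    SSR <- k * sum((rowm - grand)^2)
    SSC <- n * sum((colm - grand)^2)
    SST <- sum((data - grand)^2)
    SSE <- SST - SSR - SSC
    MSR <- SSR / (n - 1); MSC <- SSC / (k - 1)
    MSE <- SSE / ((n - 1) * (k - 1))
    denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
    if (SST <= .Machine$double.eps * n * k) {
        return(data.frame(metric = metric, icc = NA_real_,
                          band = "undefined", n_subjects = n, n_ratings = k,
                          stringsAsFactors = FALSE))
    }
    icc <- (MSR - MSE) / denom
    band <- if (icc <= 0.50) "poor" else if (icc <= 0.75) "moderate"
            else if (icc <= 0.90) "good" else "excellent"
    data.frame(metric = metric, icc = icc, band = band, n_subjects = n,
               n_ratings = k, stringsAsFactors = FALSE)
}

#' z-normalize a metric across all eyes of a cohort table
#'
#' Subtracts the mean and divides by the SD computed over every eye in the
#' table (all groups pooled), so contrasts of different parameters are
#' comparable in SD units.
#'
#' @param x numeric vector of per-eye values.
#' @return Numeric vector with mean 0 and SD 1.
#' @export
zNormalize <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
        stop("cannot z-normalize: SD is zero", call. = FALSE)
    (x - mean(x)) / s
}

## subject-level resampling engine: resamples subjects with replacement
## within each group and returns the replicate statistic vector.
## groupList: named list of per-group lists with subjSum, subjCnt
## (per-subject sum and eye count of the z-scored metric). statFun maps the
## vector of per-group replicate means to the statistic. Each group draws
## from its own RNG substream keyed by (seed, group name), so the replicate
## set is invariant to the order in which groups are listed.
.groupSeed <- function(seed, name) {
    u <- utf8ToInt(name)
    (as.integer(seed) + sum(u * seq_along(u)) * 131L) %% 2147483647L
}

.clusterBoot <- function(groupList, statFun, B, seed) {
    ns <- vapply(groupList, function(g) length(g$subjSum), integer(1))
    means <- matrix(NA_real_, length(groupList), B)
    for (gi in seq_along(groupList)) {
        g <- groupList[[gi]]
        set.seed(.groupSeed(seed, names(groupList)[gi]))
        idx <- matrix(sample.int(ns[gi], ns[gi] * B, replace = TRUE),
                      ns[gi], B)
        means[gi, ] <- colSums(matrix(g$subjSum[idx], ns[gi], B)) /
            colSums(matrix(g$subjCnt[idx], ns[gi], B))
    }
    apply(means, 2, statFun)
}

.groupSummaries <- function(values, subjects, groups, levels) {
    names(levels) <- levels
    lapply(levels, function(g) {
        sel <- groups == g
        s <- split(values[sel], subjects[sel])
        list(subjSum = vapply(s, sum, numeric(1)),
             subjCnt = vapply(s, length, numeric(1)),
             mean = mean(values[sel]))
    })
}

.bootP <- function(reps, B) {
    ## two-sided percentile p with (count + 1)/(B + 1) continuity correction
    min(1, 2 * min((sum(reps <= 0) + 1) / (B + 1),
                   (sum(reps >= 0) + 1) / (B + 1)))
}

#' Subject-clustered bootstrap contrast of a metric between two groups
#'
#' z-normalises the metric over all eyes in the table, then bootstraps the
#' group mean difference (A - B, in SD units) by resampling subjects -- not
#' eyes -- with replacement within each group, carrying every eye of a
#' resampled subject. The 95% CI is percentile (2.5, 97.5) and the
#' two-sided p-value uses the (count + 1)/(B + 1) continuity correction so
#' finite replicates never yield p = 0. Deterministic under a fixed seed.
#'
#' @param table metric data.frame with columns `subject_id`, `group` and
#'   the metric column (typically one region's rows of a cohort table).
#' @param metric metric column name, e.g. `"CPD_pct"`.
#' @param groupA,groupB group labels to contrast (A - B).
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param normalize z-normalise across all eyes first (default `TRUE`).
#' @return data.frame: `metric, comparison, diff_sd_units, ci_lo, ci_hi,
#'   p_raw, n_replicates, seed`.
#' @export
clusterBootstrapDiff <- function(table, metric, groupA, groupB, B = 1000L,
                                 seed = 1L, normalize = TRUE) {
    stopifnot(all(c("subject_id", "group", metric) %in% names(table)))
    spanning <- tapply(table$group, table$subject_id,
                       function(g) length(unique(g)))
    if (any(spanning > 1L))
        stop("subjects must not span groups", call. = FALSE)
    vals <- table[[metric]]
    if (normalize) vals <- zNormalize(vals)
    sel <- table$group %in% c(groupA, groupB)
    if (!any(table$group == groupA) || !any(table$group == groupB))
        stop("both groups must be present in the table", call. = FALSE)
    gl <- .groupSummaries(vals[sel], table$subject_id[sel], table$group[sel],
                          c(groupA, groupB))
    if (any(vapply(gl, function(g) length(g$subjSum), integer(1)) < 2L))
        warning("a group has a single subject: resampling is degenerate")
    obs <- gl[[1]]$mean - gl[[2]]$mean
    reps <- .clusterBoot(gl, function(m) m[1] - m[2], B, seed)
    ci <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
    data.frame(metric = metric,
               comparison = paste(groupA, "vs", groupB),
               diff_sd_units = obs, ci_lo = ci[1], ci_hi = ci[2],
               p_raw = .bootP(reps, B), n_replicates = B, seed = seed,
               stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Controls the false discovery rate across a family of p-values; the
#' adjusted values are monotone in rank and never below the raw values.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bhAdjust <- function(p) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]", call. = FALSE)
    stats::p.adjust(p, method = "BH")
}

#' Linear orthogonal trend contrast across ordered groups
#'
#' Tests for a monotone trend of the (z-normalised) metric across ordered
#' severity groups using the orthogonal linear contrast of the group means
#' (coefficients -1, 0, 1 for three groups; -3, -1, 1, 3 for four). The
#' reference distribution comes from the same subject-clustered bootstrap
#' engine as the pairwise contrasts, honouring the eye clustering.
#'
#' @param table metric data.frame (see [clusterBootstrapDiff()]).
#' @param metric metric column name.
#' @param orderedGroups character vector of >= 3 group labels, in order.
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param normalize z-normalise across all eyes first (default `TRUE`).
#' @return data.frame: `metric, contrast, p_trend, n_replicates, seed`.
#' @export
linearTrendTest <- function(table, metric, orderedGroups, B = 1000L,
                            seed = 1L, normalize = TRUE) {
    k <- length(orderedGroups)
    if (k < 3L) stop("trend test needs at least 3 ordered groups",
                     call. = FALSE)
    coef <- 2 * (seq_len(k) - (k + 1) / 2)
    if (k %% 2L == 1L) coef <- coef / 2        # -1,0,1 / -3,-1,1,3 / ...
    vals <- table[[metric]]
    if (normalize) vals <- zNormalize(vals)
    sel <- table$group %in% orderedGroups
    gl <- .groupSummaries(vals[sel], table$subject_id[sel], table$group[sel],
                          orderedGroups)
    obs <- sum(coef * vapply(gl, `[[`, numeric(1), "mean"))
    reps <- .clusterBoot(gl, function(m) sum(coef * m), B, seed)
    data.frame(metric = metric, contrast = obs, p_trend = .bootP(reps, B),
               n_replicates = B, seed = seed, stringsAsFactors = FALSE)
}

.rocObj <- function(scores, labels, caseLevel, positiveLow) {
    labels <- as.character(labels)
    lev <- unique(labels)
    if (length(lev) != 2L)
        stop("labels must contain exactly two classes", call. = FALSE)
    controlLevel <- setdiff(lev, caseLevel)
    if (length(controlLevel) != 1L)
        stop("caseLevel '", caseLevel, "' not found in labels", call. = FALSE)
    ## declared polarity: with positiveLow, lower scores indicate disease,
    ## i.e. controls score higher than cases
    direction <- if (positiveLow) ">" else "<"
    pROC::roc(response = factor(labels, levels = c(controlLevel, caseLevel)),
              predictor = as.numeric(scores), direction = direction,
              levels = c(controlLevel, caseLevel), quiet = TRUE)
}

#' ROC AUC with DeLong confidence interval
#'
#' AUC is the Mann-Whitney two-sample statistic (ties counted one half);
#' the 95% CI uses the DeLong variance with a normal approximation, clipped
#' to [0, 1]. The score polarity is declared, never auto-flipped: with
#' `positiveLow = TRUE` (the default, matching perfusion metrics) lower
#' scores indicate disease.
#'
#' @param scores numeric per-eye scores.
#' @param labels two-class labels, same length.
#' @param caseLevel label value of the diseased class.
#' @param positiveLow `TRUE` if low scores indicate disease.
#' @return data.frame: `auc, ci_lo, ci_hi, n_cases, n_controls`.
#' @export
rocAuc <- function(scores, labels, caseLevel, positiveLow = TRUE) {
    r <- .rocObj(scores, labels, caseLevel, positiveLow)
    ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
    data.frame(auc = as.numeric(pROC::auc(r)),
               ci_lo = max(0, ci[1]), ci_hi = min(1, ci[3]),
               n_cases = sum(as.character(labels) == caseLevel),
               n_controls = sum(as.character(labels) != caseLevel))
}

#' Compare two correlated AUCs by the DeLong test
#'
#' Both score vectors must be measured on the same eyes (paired design);
#' the test uses per-observation placement values and a two-sided normal
#' reference. Eyes are treated as independent observations, as the
#' standard algorithm does.
#'
#' @param scores1,scores2 numeric score vectors on the same eyes.
#' @param labels two-class labels.
#' @param caseLevel label value of the diseased class.
#' @param positiveLow `TRUE` if low scores indicate disease.
#' @return data.frame: `auc1, auc2, delta, p_delong` plus the DeLong 95%
#'   CIs of both AUCs.
#' @export
delongCompare <- function(scores1, scores2, labels, caseLevel,
                          positiveLow = TRUE) {
    if (length(scores1) != length(scores2) ||
        length(scores1) != length(labels))
        stop("scores1, scores2 and labels must have equal length",
             call. = FALSE)
    r1 <- .rocObj(scores1, labels, caseLevel, positiveLow)
    r2 <- .rocObj(scores2, labels, caseLevel, positiveLow)
    tst <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
    a1 <- rocAuc(scores1, labels, caseLevel, positiveLow)
    a2 <- rocAuc(scores2, labels, caseLevel, positiveLow)
    data.frame(auc1 = a1$auc, auc1_lo = a1$ci_lo, auc1_hi = a1$ci_hi,
               auc2 = a2$auc, auc2_lo = a2$ci_lo, auc2_hi = a2$ci_hi,
               delta = a1$auc - a2$auc,
               p_delong = as.numeric(tst$p.value))
}

#' Full comparison grid for one region's cohort table
#'
#' Runs [clusterBootstrapDiff()] for every metric x comparison cell,
#' adjusts the whole family with [bhAdjust()] (mirroring FDR control across
#' vascular parameters and severity-group combinations), and appends the
#' linear trend p per metric across the ordered groups.
#'
#' @param table one region's metric rows (columns `subject_id, group` plus
#'   the metric columns).
#' @param metrics metric column names (default the four densities).
#' @param comparisons list of `c(groupA, groupB)` pairs.
#' @param trendGroups ordered groups for the trend test (>= 3), or `NULL`
#'   to skip.
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @return List with `comparisons` (one row per cell incl. `p_adj`) and
#'   `trend` (one row per metric, or `NULL`).
#' @export
runGroupComparisons <- function(table,
                                metrics = c("TPD_pct", "CPD_pct", "LVD_pct",
                                            "CDD_pct"),
                                comparisons, trendGroups = NULL, B = 1000L,
                                seed = 1L) {
    rows <- list()
    i <- 0L
    for (m in metrics) for (cp in comparisons) {
        i <- i + 1L
        rows[[length(rows) + 1L]] <-
            clusterBootstrapDiff(table, m, cp[1], cp[2], B = B,
                                 seed = seed + i)
    }
    grid <- do.call(rbind, rows)
    grid$p_adj <- bhAdjust(grid$p_raw)
    trend <- NULL
    if (!is.null(trendGroups)) {
        trend <- do.call(rbind, lapply(seq_along(metrics), function(j)
            linearTrendTest(table, metrics[j], trendGroups, B = B,
                            seed = seed + 1000L + j)))
    }
    list(comparisons = grid, trend = trend)
}

#' Group mean/SD summary of a cohort table
#'
#' @param table metric data.frame with a `group` column.
#' @param metrics metric column names.
#' @param groups group order (default: order of appearance).
#' @return data.frame with one row per group x metric: `group, metric,
#'   mean, sd, n_eyes`.
#' @export
cohortSummary <- function(table,
                          metrics = c("TPD_pct", "CPD_pct", "LVD_pct",
                                      "CDD_pct"),
                          groups = unique(table$group)) {
    out <- expand.grid(group = groups, metric = metrics,
                       stringsAsFactors = FALSE)
    out$mean <- NA_real_; out$sd <- NA_real_; out$n_eyes <- NA_integer_
    for (i in seq_len(nrow(out))) {
        v <- table[[out$metric[i]]][table$group == out$group[i]]
        out$mean[i] <- mean(v); out$sd[i] <- stats::sd(v)
        out$n_eyes[i] <- length(v)
    }
    out
}
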