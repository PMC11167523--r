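# Group comparisons (Wilcoxon rank-sum with an exact enumeration path),
# display sorting of traces by k-means, and mean +/- SD summaries.

# Exact null distribution of the group-A rank sum by enumeration of all
# choose(n, nA) rank assignments (no ties).
.ranksumExactP <- function(W, nA, n) {
    sums <- colSums(combn(n, nA))
    pLe <- mean(sums <= W + 1e-9)
    pGe <- mean(sums >= W - 1e-9)
    min(1, 2 * min(pLe, pGe))
}

#' Wilcoxon rank-sum test for two unpaired groups
#'
#' Midranks are used for ties. With 12 or fewer observations in total and
#' no ties the two-sided p-value is exact (full enumeration of rank
#' assignments, doubling the smaller tail); otherwise a normal
#' approximation with tie correction and continuity correction is used.
#' The method actually applied is reported in the result.
#'
#' @param a,b numeric vectors, per-fish values of the two groups.
#' @param metric label carried into the result.
#' @param exactMax largest total sample size for the exact path.
#' @return A [GroupComparison][GroupComparison-class]; the statistic is
#'   the rank sum of group `a`.
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))   # exact p = 0.1
#' @export
wilcoxonRankSum <- function(a, b, metric = "metric", exactMax = 12L) {
    a <- as.numeric(a); b <- as.numeric(b)
    if (!length(a) || !length(b)) stop("both groups must be non-empty")
    nA <- length(a); nB <- length(b); n <- nA + nB
    pooled <- c(a, b)
    rk <- rank(pooled)            # midranks
    W <- sum(rk[seq_len(nA)])
    ties <- any(duplicated(pooled))
    degenerate <- length(unique(pooled)) == 1L
    if (degenerate) {
        p <- 1
        method <- "degenerate (all values identical)"
    } else if (!ties && n <= exactMax) {
        p <- .ranksumExactP(W, nA, n)
        method <- "exact enumeration"
    } else {
        mu <- nA * (n + 1) / 2
        tieTab <- table(pooled)
        tieCorr <- sum(tieTab^3 - tieTab) / (n * (n - 1))
        sigma2 <- nA * nB / 12 * ((n + 1) - tieCorr)
        z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
        p <- min(1, 2 * pnorm(-abs(z)))
        method <- "normal approximation (continuity and tie corrected)"
    }
    stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
             if (p < 0.05) "*" else "ns"
    new("GroupComparison", metric = metric, groupA = a, groupB = b,
        statistic = W, pValue = p, method = method, stars = stars,
        degenerate = degenerate,
        summary = summarizeScatter(list(A = a, B = b)))
}

#' Mean and standard deviation per group
#'
#' The scatterplot summary: per group mean, SD (n - 1 denominator) and n.
#' Groups of size 1 report `NA` SD and are flagged.
#'
#' @param values named list of numeric vectors, one per group.
#' @return data.frame with columns `group, n, mean, sd, flagged`.
#' @export
summarizeScatter <- function(values) {
    if (!is.list(values)) values <- list(values)
    if (is.null(names(values)))
        names(values) <- paste0("group", seq_along(values))
    do.call(rbind, lapply(names(values), function(g) {
        v <- values[[g]]
        if (!length(v)) stop("empty group: ", g)
        data.frame(group = g, n = length(v), mean = mean(v),
                   sd = if (length(v) > 1) sd(v) else NA_real_,
                   flagged = length(v) == 1L)
    }))
}

# k-means++ style seeding: first centre uniform, next centres with
# probability proportional to squared distance to the nearest centre.
.kmeansPlusPlusInit <- function(X, k) {
    n <- nrow(X)
    centers <- matrix(NA_real_, k, ncol(X))
    idx <- sample.int(n, 1)
    centers[1, ] <- X[idx, ]
    if (k > 1) {
        d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
        for (j in 2:k) {
            prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
            idx <- sample.int(n, 1, prob = prob)
            centers[j, ] <- X[idx, ]
            d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
        }
    }
    centers
}

#' Sort traces by k-means clustering for display
#'
#' Clusters the dF/F traces with k-means (k-means++-style seeding, Lloyd
#' iterations, fixed iteration cap), orders clusters by decreasing mean
#' centroid activity and cells within a cluster by increasing distance to
#' their centroid. Deterministic for a given seed; display only.
#'
#' @param dff a [TraceMatrix()] (or plain matrix) of traces.
#' @param k number of clusters.
#' @param seed RNG seed for the initialization.
#' @param iterMax Lloyd iteration cap.
#' @return List with `order` (display permutation of cells) and `cluster`
#'   (per-cell cluster labels, relabelled in display order).
#' @export
kmeansSort <- function(dff, k = 10, seed = 1L, iterMax = 100L) {
    X <- if (is(dff, "TraceMatrix")) traceValues(dff) else as.matrix(dff)
    if (k > nrow(X)) stop("k must not exceed the number of cells")
    if (ncol(X) < 2L) stop("need at least 2 timepoints")
    set.seed(seed)
    km <- suppressWarnings(
        kmeans(X, centers = .kmeansPlusPlusInit(X, k),
               iter.max = iterMax, algorithm = "Lloyd"))
    clOrder <- order(-rowMeans(km$centers))
    newLab <- match(km$cluster, clOrder)
    d2c <- rowSums((X - km$centers[km$cluster, , drop = FALSE])^2)
    ord <- order(newLab, d2c)
    list(order = ord, cluster = newLab)
}
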