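#' @importFrom BiocGenerics estimateSizeFactors
#' @export
BiocGenerics::estimateSizeFactors

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features of the ratio
#' of its count to the feature's geometric mean across samples, using only
#' features with a nonzero count in every sample; factors are then rescaled
#' to have geometric mean 1.  When no feature is nonzero in all samples the
#' function falls back to total-count ratios with a warning.  Implemented as
#' a method on the [BiocGenerics::estimateSizeFactors()] generic for plain
#' count matrices (and data.frames).
#'
#' @param object feature x sample matrix of non-negative counts.
#' @param ... ignored.
#' @return Named numeric vector of size factors (geometric mean 1).
#' @rdname estimateSizeFactors-matrix
#' @export
setMethod("estimateSizeFactors", "matrix", function(object, ...) {
    .sizeFactorsMedianRatios(object)
})

#' @rdname estimateSizeFactors-matrix
#' @export
setMethod("estimateSizeFactors", "data.frame", function(object, ...) {
    .sizeFactorsMedianRatios(as.matrix(object))
})

.sizeFactorsMedianRatios <- function(counts) {
    counts <- as.matrix(counts)
    logGeo <- rowMeans(log(counts))
    use <- is.finite(logGeo)
    if (!any(use)) {
        warning("no feature nonzero in all samples; using total-count ratios")
        sf <- colSums(counts)
    } else {
        sf <- apply(counts[use, , drop = FALSE], 2L, function(x)
            exp(stats::median(log(x) - logGeo[use])))
    }
    sf <- sf / exp(mean(log(sf)))
    stats::setNames(sf, colnames(counts))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement:
#' `q_(i) = min_{j >= i} ( m * p_(j) / j )`, capped at 1.
#'
#' @param p numeric vector of p-values in `[0,1]` (NAs propagate).
#' @return Adjusted q-values in the original order.
#' @export
bhAdjust <- function(p) {
    q <- rep(NA_real_, length(p))
    ok <- which(!is.na(p))
    if (length(ok) == 0L) return(q)
    pv <- p[ok]
    m <- length(pv)
    o <- order(pv, decreasing = TRUE)
    q[ok[o]] <- pmin(1, cummin(m / (m:1) * pv[o]))
    q
}

#' Negative-binomial Wald test for WT vs mutant RNA-seq
#'
#' A defined, self-contained NB test in the DESeq family: counts are
#' normalised by median-of-ratios size factors; per-gene dispersion is
#' estimated by method of moments (`var = mu + disp * mu^2`) on the
#' normalised counts and shrunk (arithmetically, weighted by residual
#' degrees of freedom against `priorDf`) toward a trend over genes of
#' similar expression (`dispersionMode = "trended"`, 20 baseMean bins) or
#' toward the pooled mean dispersion (`"pooled"`); the log2 fold change is
#' computed from normalised condition means with a pseudocount of 0.5; its
#' standard error comes from the NB delta method; the Wald statistic is
#' referred to the standard normal, two-sided.
#'
#' Genes with zero counts in both conditions get `p = 1` and `log2FC = 0`
#' and are flagged in the `allZero` column.
#'
#' @param counts feature x sample integer matrix.
#' @param condition factor/character per sample, with levels WT and mutant;
#'   the first level (or `"WT"` if present) is the reference.
#' @param sizeFactors optional precomputed size factors.
#' @param dispersionMode `"trended"` (default) or `"pooled"`.
#' @param priorDf weight (in pseudo-degrees-of-freedom) of the dispersion
#'   trend relative to the per-gene estimate (default 10).
#' @param fold,alpha thresholds passed to [classifyDE()] for the `call`
#'   column.
#' @return `data.frame` with `feature_id`, `baseMean`, `log2FC`, `se`,
#'   `stat`, `p`, `q`, `call`, `allZero`.
#' @export
nbWaldTest <- function(counts, condition, sizeFactors = NULL,
                       dispersionMode = c("trended", "pooled"),
                       priorDf = 10, fold = 1.5, alpha = 0.05) {
    dispersionMode <- match.arg(dispersionMode)
    counts <- as.matrix(counts)
    condition <- as.character(condition)
    lev <- unique(condition)
    if (length(lev) != 2L) stop("exactly two conditions required")
    ref <- if ("WT" %in% lev) "WT" else lev[1]
    altLev <- setdiff(lev, ref)
    if (min(table(condition)) < 2L)
        stop("at least two replicates per condition required")
    if (is.null(sizeFactors)) sizeFactors <- estimateSizeFactors(counts)
    norm <- sweep(counts, 2L, sizeFactors, "/")
    iW <- which(condition == ref)
    iM <- which(condition == altLev)
    nW <- length(iW); nM <- length(iM)
    muW <- rowMeans(norm[, iW, drop = FALSE])
    muM <- rowMeans(norm[, iM, drop = FALSE])
    baseMean <- (muW + muM) / 2
    # method-of-moments dispersion from pooled within-condition variance
    vW <- apply(norm[, iW, drop = FALSE], 1L, stats::var)
    vM <- apply(norm[, iM, drop = FALSE], 1L, stats::var)
    s2 <- ((nW - 1) * vW + (nM - 1) * vM) / (nW + nM - 2)
    muBar <- pmax(baseMean, 1e-8)
    # raw estimates are noisy and strongly right-skewed at few replicates;
    # the trend is an arithmetic (not log-scale) bin mean so that genes whose
    # sample variance falls below the Poisson floor do not drag it to zero
    dispRaw <- pmax((s2 - muBar) / muBar^2, 0)
    dispRaw <- pmin(dispRaw, 10)
    expressed <- baseMean > 0
    if (dispersionMode == "pooled") {
        trend <- rep(mean(dispRaw[expressed]), nrow(counts))
    } else {
        trend <- rep(NA_real_, nrow(counts))
        idx <- which(expressed)
        nb <- max(1L, min(20L, floor(length(idx) / 25)))
        bins <- cut(rank(baseMean[idx], ties.method = "first"),
                    breaks = nb, labels = FALSE)
        binMean <- tapply(dispRaw[idx], bins, mean)
        trend[idx] <- binMean[as.character(bins)]
        trend[!expressed] <- mean(dispRaw[expressed])
    }
    df <- nW + nM - 2
    w <- df / (df + priorDf)
    disp <- pmax(w * dispRaw + (1 - w) * trend, 1e-8)
    # delta-method SE of the log2 ratio of normalised means
    varMuW <- vapply(seq_len(nrow(counts)), function(g)
        sum(muW[g] / sizeFactors[iW] + disp[g] * muW[g]^2) / nW^2, 0)
    varMuM <- vapply(seq_len(nrow(counts)), function(g)
        sum(muM[g] / sizeFactors[iM] + disp[g] * muM[g]^2) / nM^2, 0)
    pc <- 0.5
    log2FC <- log2((muM + pc) / (muW + pc))
    se <- sqrt(varMuW / (muW + pc)^2 + varMuM / (muM + pc)^2) / log(2)
    stat <- ifelse(se > 0, log2FC / se, 0)
    p <- 2 * stats::pnorm(-abs(stat))
    allZero <- muW == 0 & muM == 0
    p[allZero] <- 1
    log2FC[allZero] <- 0
    res <- data.frame(feature_id = rownames(counts), baseMean = baseMean,
                      log2FC = log2FC, se = se, stat = stat, p = p,
                      q = bhAdjust(p), row.names = NULL)
    res$call <- classifyDE(res$log2FC, res$p, fold = fold, alpha = alpha)
    res$allZero <- allZero
    res
}

#' Call differential expression at a fold/p threshold
#'
#' `up` requires `2^log2FC > fold` and `p < alpha`; `down` is symmetric;
#' everything else (including exactly `fold`, the bound being strict) is
#' `unchanged`.  Defaults reproduce the >1.5-fold, p < 0.05 convention.
#'
#' @param log2FC,p vectors from the test.
#' @param fold fold-change bound, strict (default 1.5).
#' @param alpha p-value bound, strict (default 0.05).
#' @return Character vector of `"up"`, `"down"`, `"unchanged"`.
#' @export
classifyDE <- function(log2FC, p, fold = 1.5, alpha = 0.05) {
    out <- rep("unchanged", length(log2FC))
    out[2^log2FC > fold & p < alpha] <- "up"
    out[2^(-log2FC) > fold & p < alpha] <- "down"
    out
}

#' Tally differential-expression calls by feature class
#'
#' For each call direction, counts features per class and reports
#' round-half-up integer percentages of the direction's total.
#'
#' @param calls named character vector (or `DEResult` data.frame with
#'   `feature_id` and `call`) of `up`/`down`/`unchanged` calls.
#' @param fclass named character vector of feature classes, or a
#'   [GenomeAnnotation-class].
#' @return `data.frame` with `direction`, `fclass`, `count`, `pct`.
#' @examples
#' calls <- rep(c("down"), 445)
#' cls <- rep(c("ncRNA", "mRNA", "intergenic", "snoRNA"),
#'            c(159, 147, 135, 4))
#' names(calls) <- names(cls) <- paste0("g", seq_along(cls))
#' tallyClasses(calls, cls)  # 36% / 33% / 30% / 1%
#' @export
tallyClasses <- function(calls, fclass) {
    if (is.data.frame(calls))
        calls <- stats::setNames(calls$call, calls$feature_id)
    if (is(fclass, "GenomeAnnotation")) fclass <- featureClass(fclass)
    out <- list()
    for (dir in c("up", "down")) {
        ids <- names(calls)[calls == dir]
        if (length(ids) == 0L) next
        cls <- fclass[ids]
        tab <- sort(table(cls), decreasing = TRUE)
        out[[dir]] <- data.frame(direction = dir, fclass = names(tab),
                                 count = as.integer(tab),
                                 pct = roundHalfUp(100 * as.integer(tab) /
                                                       length(ids)))
    }
    if (length(out) == 0L)
        return(data.frame(direction = character(), fclass = character(),
                          count = integer(), pct = numeric()))
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a query gene list
#' and a gene set within a universe: `p = P(X >= k)` with `N = |universe|`,
#' `K = |set|`, `n = |query|`, `k = |overlap|`.
#'
#' @param queryIds,setIds,universeIds character vectors of gene ids; query
#'   and set must be subsets of the universe.
#' @param setId label for the output row.
#' @return One-row `data.frame` with `set_id`, `k`, `n`, `K`, `N`, `p`.
#' @export
hypergeomEnrichment <- function(queryIds, setIds, universeIds,
                                setId = "set") {
    universeIds <- unique(universeIds)
    if (length(universeIds) == 0L) stop("empty universe")
    queryIds <- unique(queryIds); setIds <- unique(setIds)
    if (!all(queryIds %in% universeIds) || !all(setIds %in% universeIds))
        stop("query and set must be subsets of the universe")
    N <- length(universeIds); K <- length(setIds); n <- length(queryIds)
    k <- length(intersect(queryIds, setIds))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = setId, k = k, n = n, K = K, N = N, p = p)
}
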