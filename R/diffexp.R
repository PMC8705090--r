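## Negative-binomial two-group differential expression:
## median-of-ratios normalization, moment dispersion, Wald test.

#' Construct a differential-expression configuration
#'
#' @param alpha Significance level on raw p-values (default 0.05).
#' @param lfcMin Minimum |log2 fold change| for calling; 0 for miR/isomiR
#'   matrices, 1 for gene-level matrices.
#' @param minTotalCount Features with total raw count below this across
#'   the contrast samples are flagged filtered and not tested.
#' @param dispersionFloor Lower bound on the moment dispersion estimate.
#' @return A [DEConfig-class] object.
#' @export
deConfig <- function(alpha = 0.05, lfcMin = 0, minTotalCount = 10L,
                     dispersionFloor = 1e-8) {
    new("DEConfig", alpha = alpha, lfcMin = lfcMin,
        minTotalCount = as.integer(minTotalCount),
        dispersionFloor = dispersionFloor)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median ratio of a
#' sample's counts to the geometric-mean pseudo-reference, over features
#' with strictly positive counts in every sample, then rescaled to
#' geometric mean 1.
#'
#' @param counts Count matrix (features x samples) or
#'   SummarizedExperiment.
#' @return Named positive numeric vector, one factor per sample.
#' @export
medianRatioSizeFactors <- function(counts) {
    m <- .asCountMatrix(counts)
    pos <- rowSums(m > 0) == ncol(m)
    if (!any(pos))
        stop("no feature has positive counts in every sample; ",
             "pre-filter the matrix before normalization")
    lm_ <- log(m[pos, , drop = FALSE])
    ref <- rowMeans(lm_)
    sf <- exp(apply(lm_ - ref, 2L, stats::median))
    sf <- sf / exp(mean(log(sf)))
    stats::setNames(sf, colnames(m))
}

.designGroups <- function(design) {
    if (is.data.frame(design)) {
        stopifnot(all(c("sample", "group") %in% colnames(design)))
        stats::setNames(as.character(design$group),
                        as.character(design$sample))
    } else if (!is.null(names(design))) {
        stats::setNames(as.character(design), names(design))
    } else stop("design must be a data.frame(sample, group) or a named vector")
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' For each feature: counts are normalized by [medianRatioSizeFactors()];
#' the NB dispersion is estimated by method of moments on normalized
#' counts, pooled across the two groups and floored; the log2 fold change
#' is computed from the normalized group means (a 0.5 pseudo-count guards
#' the ratio whenever a group mean is exactly zero);
#' its standard error comes from the NB delta method; and the Wald
#' statistic `log2FC / se` is referred to a t distribution with
#' `n1 + n2 - 2` degrees of freedom (two-sided). A Benjamini-Hochberg
#' adjusted p-value is reported alongside but not used for calling.
#'
#' @param counts Count matrix (features x samples) or
#'   SummarizedExperiment.
#' @param design data.frame with columns `sample`, `group`, or a named
#'   group vector.
#' @param contrast Length-2 character vector `c(test, reference)`.
#' @param config A [DEConfig-class].
#' @return data.frame with columns `feature`, `baseMean`, `log2FC`, `se`,
#'   `wald`, `p`, `padj`, `filtered`. Filtered features carry NA
#'   statistics and `filtered = TRUE`.
#' @export
nbWaldTest <- function(counts, design, contrast,
                       config = deConfig()) {
    m <- .asCountMatrix(counts)
    grp <- .designGroups(design)
    stopifnot(length(contrast) == 2L)
    test <- contrast[1L]; ref <- contrast[2L]
    keep <- names(grp)[grp %in% c(test, ref)]
    keep <- intersect(colnames(m), keep)
    grp <- grp[keep]
    i1 <- keep[grp == test]; i0 <- keep[grp == ref]
    if (length(i1) < 2L || length(i0) < 2L)
        stop("each contrast group needs at least two samples")
    m <- m[, c(i1, i0), drop = FALSE]

    filtered <- rowSums(m) < config@minTotalCount
    if (all(filtered))
        stop("all features filtered; contrast is degenerate")
    sf <- medianRatioSizeFactors(m[!filtered, , drop = FALSE])
    q <- sweep(m, 2L, sf, "/")
    q1 <- q[, i1, drop = FALSE]; q0 <- q[, i0, drop = FALSE]
    n1 <- length(i1); n0 <- length(i0)
    m1 <- rowMeans(q1); m0 <- rowMeans(q0)

    ## moment dispersion, pooled across groups:
    ## within a group, Var(q_ij) = mu/sf_j + alpha*mu^2, so
    ## alpha_g = (s2_g - m_g * mean(1/sf_g)) / m_g^2
    c1 <- mean(1 / sf[i1]); c0 <- mean(1 / sf[i0])
    s21 <- apply(q1, 1L, stats::var)
    s20 <- apply(q0, 1L, stats::var)
    a1 <- ifelse(m1 > 0, (s21 - m1 * c1) / m1^2, NA_real_)
    a0 <- ifelse(m0 > 0, (s20 - m0 * c0) / m0^2, NA_real_)
    w1 <- ifelse(is.na(a1), 0, n1 - 1L)
    w0 <- ifelse(is.na(a0), 0, n0 - 1L)
    a1[is.na(a1)] <- 0; a0[is.na(a0)] <- 0
    denom <- w1 + w0
    alpha <- ifelse(denom > 0, (w1 * a1 + w0 * a0) / denom, 0)
    alpha <- pmax(alpha, config@dispersionFloor)

    ## delta-method se of the log2 ratio under the NB model; the 0.5
    ## pseudo-count enters only when a group mean is zero, so that the
    ## estimate is exactly invariant to rescaling a sample's column
    v1 <- (m1 * sum(1 / sf[i1]) + n1 * alpha * m1^2) / n1^2
    v0 <- (m0 * sum(1 / sf[i0]) + n0 * alpha * m0^2) / n0^2
    pseudo <- ifelse(m1 == 0 | m0 == 0, 0.5, 0)
    lfc <- log2((m1 + pseudo) / (m0 + pseudo))
    se <- sqrt(v1 / (m1 + pseudo)^2 + v0 / (m0 + pseudo)^2) / log(2)
    wald <- ifelse(se > 0, lfc / se, 0)
    df <- n1 + n0 - 2L
    p <- 2 * stats::pt(-abs(wald), df = df)

    out <- data.frame(
        feature = rownames(m), baseMean = rowMeans(q),
        log2FC = lfc, se = se, wald = wald, p = p,
        padj = NA_real_, filtered = filtered,
        row.names = NULL, stringsAsFactors = FALSE)
    out$log2FC[filtered] <- NA_real_
    out$se[filtered] <- NA_real_
    out$wald[filtered] <- NA_real_
    out$p[filtered] <- NA_real_
    out$padj[!filtered] <- stats::p.adjust(out$p[!filtered], "BH")
    out
}

#' Call differentially expressed features
#'
#' Keeps tested features with `p < alpha` and `|log2FC| >= lfcMin`
#' (raw p-values, matching common practice of reporting unadjusted
#' significance for small cohorts), and annotates the direction of
#' change.
#'
#' @param records data.frame from [nbWaldTest()].
#' @param config A [DEConfig-class].
#' @return Subset of `records` with an added `direction` column
#'   (`"up"`/`"down"`).
#' @export
callDE <- function(records, config = deConfig()) {
    keep <- !records$filtered & !is.na(records$p) &
        records$p < config@alpha & abs(records$log2FC) >= config@lfcMin
    out <- records[keep, , drop = FALSE]
    out$direction <- ifelse(out$log2FC >= 0, "up", "down")
    rownames(out) <- NULL
    out
}

#' Write a differential-expression table as TSV
#'
#' @param records data.frame from [nbWaldTest()] or [callDE()].
#' @param path Output path.
#' @export
writeDETable <- function(records, path) {
    records <- records[order(records$feature), , drop = FALSE]
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
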