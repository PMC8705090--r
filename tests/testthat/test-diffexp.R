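mkSamples <- function(n = 6L, groups = c("A", "B")) {
    data.frame(sample = sprintf("s%02d", seq_len(2L * n)),
               group = rep(groups, each = n), stringsAsFactors = FALSE)
}

test_that("median-of-ratios size factors behave under symmetry and scaling", {
    m <- matrix(rep(c(10L, 50L, 200L, 1000L), 3), ncol = 3,
                dimnames = list(paste0("f", 1:4), paste0("s", 1:3)))
    expect_equal(unname(medianRatioSizeFactors(m)), rep(1, 3))

    m2 <- m; m2[, 2] <- m2[, 2] * 2L
    sf <- medianRatioSizeFactors(m2)
    expect_equal(unname(sf[2] / sf[1]), 2)
    expect_equal(unname(sf[2] / sf[3]), 2)
    expect_equal(exp(mean(log(sf))), 1)

    expect_error(medianRatioSizeFactors(
        matrix(c(0L, 1L, 1L, 0L), 2, 2,
               dimnames = list(c("a", "b"), c("x", "y")))),
        "pre-filter")
})

test_that("size factors recover a planted 1:2:4 depth gradient", {
    samples <- mkSamples()
    set.seed(1)
    mu <- setNames(exp(stats::rnorm(5000, log(200), 1)),
                   sprintf("f%04d", 1:5000))
    depth <- setNames(rep(c(1, 2, 4), each = 4), samples$sample)
    m <- simulateCounts(mu, samples, testGroup = "B", dispersion = 0.1,
                        sizeFactors = depth, seed = 77)
    sf <- medianRatioSizeFactors(m)
    rel <- sf / depth
    rel <- rel / exp(mean(log(rel)))
    expect_true(all(abs(rel - 1) < 0.05))
})

test_that("size factors match the DESeq2 median-of-ratios oracle", {
    skip_if_not_installed("DESeq2")
    samples <- mkSamples(3L)
    set.seed(4)
    mu <- setNames(exp(stats::rnorm(400, log(100), 1)), paste0("f", 1:400))
    m <- simulateCounts(mu, samples, testGroup = "B", dispersion = 0.1,
                        sizeFactors = setNames(runif(6, 0.5, 2),
                                               samples$sample),
                        seed = 5)
    sf <- medianRatioSizeFactors(m)
    oracle <- DESeq2::estimateSizeFactorsForMatrix(m)
    oracle <- oracle / exp(mean(log(oracle)))
    expect_equal(unname(sf), unname(oracle), tolerance = 1e-8)
})

test_that("a feature with identical counts in all samples has log2FC == 0", {
    samples <- mkSamples(3L)
    m <- matrix(rep(c(100L, 40L, 700L), 6), ncol = 6,
                dimnames = list(paste0("f", 1:3), samples$sample))
    rec <- nbWaldTest(m, samples, contrast = c("B", "A"))
    expect_identical(unname(rec$log2FC), rep(0, 3))
    expect_true(all(rec$p == 1))
})

test_that("log2FC is invariant to rescaling a sample and antisymmetric in the contrast", {
    samples <- mkSamples()
    set.seed(9)
    mu <- setNames(exp(stats::rnorm(300, log(150), 0.8)), paste0("f", 1:300))
    lfc <- setNames(rep(c(1.5, -1.5), 20), names(mu)[1:40])
    m <- simulateCounts(mu, samples, lfc = lfc, testGroup = "B",
                        dispersion = 0.1, seed = 10)
    rec <- nbWaldTest(m, samples, contrast = c("B", "A"))

    m2 <- m; m2[, 3] <- m2[, 3] * 7L
    rec2 <- nbWaldTest(m2, samples, contrast = c("B", "A"))
    expect_equal(rec2$log2FC, rec$log2FC, tolerance = 1e-9)

    rev_ <- nbWaldTest(m, samples, contrast = c("A", "B"))
    expect_equal(rev_$log2FC, -rec$log2FC, tolerance = 1e-12)
    expect_equal(rev_$p, rec$p, tolerance = 1e-12)
})

test_that("low-count features are flagged filtered, not tested", {
    samples <- mkSamples(2L)
    m <- rbind(f1 = rep(300L, 4), f2 = c(1L, 0L, 2L, 1L))
    colnames(m) <- samples$sample
    rec <- nbWaldTest(m, samples, contrast = c("B", "A"))
    expect_true(rec$filtered[rec$feature == "f2"])
    expect_true(is.na(rec$p[rec$feature == "f2"]))
    expect_error(nbWaldTest(m[2, , drop = FALSE], samples,
                            contrast = c("B", "A")),
                 "degenerate")
    expect_error(nbWaldTest(m, samples[1:3, ], contrast = c("B", "A")),
                 "two samples")
})

test_that("planted fold changes are recovered with small bias across the grid", {
    samples <- mkSamples()
    for (l in c(0, 1, 2)) for (d in c(0.05, 0.2)) {
        mu <- setNames(rep(500, 600), sprintf("g%04d", 1:600))
        planted <- setNames(rep(c(l, -l), 30), names(mu)[1:60])
        m <- simulateCounts(mu, samples, lfc = planted, testGroup = "B",
                            dispersion = d,
                            seed = 7000L + l * 10L + as.integer(d * 100))
        rec <- nbWaldTest(m, samples, contrast = c("B", "A"))
        est <- rec$log2FC[match(names(planted), rec$feature)]
        bias <- mean(est * ifelse(planted >= 0, 1, -1)) - l
        expect_lt(abs(bias), 0.1)
    }
})

test_that("DE calling applies the p and fold-change thresholds with direction", {
    rec <- data.frame(
        feature = c("a", "b", "c", "d"),
        baseMean = 100, log2FC = c(1.2, 0.6, 3.0, -1.4),
        se = 0.3, wald = 4,
        p = c(0.049, 0.049, 0.051, 0.001),
        padj = NA_real_, filtered = FALSE)
    cfg <- deConfig(lfcMin = 1)
    de <- callDE(rec, cfg)
    expect_identical(de$feature, c("a", "d"))
    expect_identical(de$direction, c("up", "down"))
    de0 <- callDE(rec, deConfig(lfcMin = 0))
    expect_true(all(c("a", "b", "d") %in% de0$feature))
    expect_false("c" %in% de0$feature)
})
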