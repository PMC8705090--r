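test_that("target filtering keeps the inclusive score-80 boundary", {
    t <- data.frame(regulator = "miR-27b-3p", gene = c("A", "B", "C"),
                    score = c(80.0, 79.9, 95))
    kept <- filterTargets(t)
    expect_setequal(kept$gene, c("A", "C"))
    t$score[1] <- 101
    expect_error(filterTargets(t), "0, 100")
})

test_that("pairing joins DE regulators and DE genes by sign product", {
    mirDE <- data.frame(feature = c("miR-449c-5p_t_+1_-1", "miR-92a-3p"),
                        log2FC = c(2.5, 1.1))
    geneDE <- data.frame(feature = c("MYCN", "TWIST1"),
                         log2FC = c(-1.8, 1.2))
    targets <- data.frame(
        regulator = c("miR-449c-5p_t_+1_-1", "miR-92a-3p", "miR-92a-3p"),
        gene = c("MYCN", "TWIST1", "NOTDE1"), score = c(98, 90, 85))
    pairs <- pairDE(mirDE, geneDE, targets)
    expect_identical(nrow(pairs), 2L)
    expect_identical(
        pairs$klass[pairs$regulator == "miR-449c-5p_t_+1_-1"], "negative")
    expect_identical(pairs$klass[pairs$regulator == "miR-92a-3p"],
                     "positive")
    expect_false("NOTDE1" %in% pairs$gene)
    # conservation: negative + positive == target pairs with both sides DE
    expect_identical(sum(pairs$klass == "negative") +
                     sum(pairs$klass == "positive"), 2L)
})

test_that("seed-unshifted variants inherit parent targets; 5'-shifted do not", {
    mirDE <- data.frame(
        feature = c("miR-27b-3p_t_0_-1",        # same seed as parent
                    "miR-27b-3p_nont_0_+1_A",   # same seed
                    "miR-27b-3p_t_+1_0"),       # shifted seed
        log2FC = c(2, 2, 2))
    geneDE <- data.frame(feature = "EYA4", log2FC = -1.5)
    targets <- data.frame(regulator = "miR-27b-3p", gene = "EYA4",
                          score = 92)
    pairs <- pairDE(mirDE, geneDE, targets)
    expect_setequal(pairs$regulator,
                    c("miR-27b-3p_t_0_-1", "miR-27b-3p_nont_0_+1_A"))
    # a 5'-isomiR pairs only through rows of its own
    own <- rbind(targets, data.frame(regulator = "miR-27b-3p_t_+1_0",
                                     gene = "EYA4", score = 88))
    pairs2 <- pairDE(mirDE, geneDE, own)
    expect_true("miR-27b-3p_t_+1_0" %in% pairs2$regulator)
    # inheritance can be disabled
    expect_identical(nrow(pairDE(mirDE, geneDE, targets,
                                 inheritSeedMatched = FALSE)), 0L)
})

test_that("the curated receptive-endometrium table has 18 multi-target genes", {
    pairs <- receptivePairsTable()
    counts <- multiTargetGenes(pairs)
    multi <- counts[counts$nRegulators >= 2, ]
    expect_identical(nrow(multi), 18L)
    expect_identical(counts$nRegulators[counts$gene == "MYCN"], 2L)
    mycn <- sort(unique(pairs$regulator[pairs$gene == "MYCN"]))
    expect_identical(mycn, c("let-7g-5p", "miR-449c-5p_t_+1_-1"))
    expect_identical(counts$nRegulators[counts$gene == "FUT9"], 4L)

    disjoint <- data.frame(regulator = c("a-5p", "b-5p"),
                           gene = c("G1", "G2"))
    m2 <- multiTargetGenes(disjoint)
    expect_identical(nrow(m2[m2$nRegulators >= 2, ]), 0L)
})

test_that("TF regulations expand to every DE member of the family", {
    regs <- data.frame(tf = c("MYCN", "MYCN"),
                       mir_family = c("miR-92a", "miR-345"),
                       direction = c("activate", "repress"),
                       literature_curated = c(TRUE, TRUE))
    de <- c("miR-92a-3p_nont_0_+2_AA", "miR-92a-3p", "miR-449c-5p_t_0_-2")
    edges <- expandTFRegulations(regs, de)
    expect_setequal(edges$feature[edges$tf == "MYCN"],
                    c("miR-92a-3p_nont_0_+2_AA", "miR-92a-3p"))
    # non-curated records are ignored by default
    regs$literature_curated <- FALSE
    expect_identical(nrow(expandTFRegulations(regs, de)), 0L)
    expect_identical(nrow(expandTFRegulations(regs, character())), 0L)
    expect_error(expandTFRegulations(
        data.frame(tf = "X", mir_family = "y", direction = "unknown",
                   literature_curated = TRUE),
        "bad_name_t_0_0"))
})

test_that("the circuit wires negative pairs and expanded TF edges", {
    pairs <- data.frame(
        regulator = c("miR-449c-5p_t_+1_-1", "miR-92a-3p_nont_0_+2_AA",
                      "miR-92a-3p_nont_0_+2_AA"),
        gene = c("MYCN", "TWIST1", "IRS2"),
        regulatorLFC = c(2.5, -1.4, -1.4),
        geneLFC = c(-1.8, 1.2, 1.2),
        klass = "negative")
    tfEdges <- data.frame(
        tf = c("MYCN", "MYCN"),
        feature = c("miR-92a-3p_nont_0_+2_AA", "miR-92a-3p_t_0_-1"))
    circ <- buildCircuit(pairs, tfEdges, deTFGenes = c("MYCN", "TWIST1"))
    nodes <- circuitNodes(circ)
    edges <- circuitEdges(circ)
    expect_true(hasPath(circ, c("MYCN", "miR-92a-3p", "TWIST1")))
    expect_identical(nodes$type[nodes$name == "MYCN"], "TF")
    # two miR-92a features collapse into one family node, multiplicity 2
    expect_identical(nodes$multiplicity[nodes$name == "miR-92a-3p"], 2L)
    # no edge is invented: every edge traces back to an input relation
    famOf <- function(f) sub("-([35]p).*$", "-\\1", f)
    tg <- edges[edges$type == "mir_targets_gene", ]
    expect_true(all(paste(tg$src, tg$dst) %in%
                    paste(famOf(pairs$regulator), pairs$gene)))
    te <- edges[edges$type == "tf_regulates_mir", ]
    expect_true(all(paste(te$src, te$dst) %in%
                    paste(tfEdges$tf, famOf(tfEdges$feature))))

    onlyTF <- buildCircuit(pairs[0, ], tfEdges)
    expect_true(all(circuitEdges(onlyTF)$type == "tf_regulates_mir"))

    d <- withr::local_tempdir()
    writeCircuit(circ, dotPath = file.path(d, "c.dot"),
                 edgesPath = file.path(d, "c.tsv"))
    dot <- readLines(file.path(d, "c.dot"))
    expect_true(any(grepl("MYCN.*miR-92a-3p", dot)))
    back <- utils::read.delim(file.path(d, "c.tsv"))
    expect_identical(nrow(back), nrow(edges))
})

test_that("set comparison partitions exactly", {
    cs <- compareSets(c("x", "y"), c("y", "z"))
    expect_identical(cs$shared, "y")
    expect_identical(cs$only_a, "x")
    expect_identical(cs$only_b, "z")
    expect_identical(unname(attr(cs, "counts")), c(1L, 1L, 1L))
    expect_identical(compareSets(c("a", "b"), c("a", "b"))$only_a,
                     character(0))
    expect_identical(compareSets("a", "b")$shared, character(0))
})
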