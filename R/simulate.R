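## Seeded synthetic-data generators. Every emitted file is a pure function
## of (configuration, seed); ground-truth tables accompany each output so
## the classifier, the DE test and the pairing stage can all be checked
## against planted values.

.sampleSeq <- function(n, alphabet = c("A", "C", "G", "U")) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Generate a random miR reference
#'
#' Random precursors carrying one or two non-overlapping mature arms of
#' 19-25 nt (the canonical mature-miR length range), separated and
#' flanked by 4-8 nt of G/C-only sequence. Because every base outside an
#' arm is G or C, an A/U tail on a simulated read can never be templated,
#' and reads extending past an arm end remain classifiable.
#'
#' @param nPrecursors Number of precursors.
#' @param seed Mandatory RNG seed.
#' @param armLengthRange,flankRange Integer length-2 ranges (nt).
#' @param twoArmFraction Fraction of precursors carrying both arms.
#' @return A [MiRReferenceSet-class].
#' @export
makeReference <- function(nPrecursors = 6L, seed,
                          armLengthRange = c(19L, 25L),
                          flankRange = c(4L, 8L),
                          twoArmFraction = 0.5) {
    stopifnot(!missing(seed))
    set.seed(seed)
    gc_ <- c("C", "G")
    seqs <- character(nPrecursors)
    arms <- list()
    names(seqs) <- sprintf("sim-pre-%02d", seq_len(nPrecursors))
    for (i in seq_len(nPrecursors)) {
        two <- stats::runif(1) < twoArmFraction
        nArms <- if (two) 2L else 1L
        flank5 <- .sampleSeq(sample(flankRange[1L]:flankRange[2L], 1L), gc_)
        parts <- flank5
        pos <- nchar(flank5)
        armRows <- list()
        labels <- if (nArms == 2L) c("5p", "3p")
                  else sample(c("5p", "3p"), 1L)
        for (lab in labels) {
            repeat {
                armSeq <- .sampleSeq(
                    sample(armLengthRange[1L]:armLengthRange[2L], 1L))
                ## distinct first two bases keep single-offset variants of
                ## the same arm from aligning ambiguously
                if (substr(armSeq, 1L, 1L) != substr(armSeq, 2L, 2L))
                    break
            }
            parts <- c(parts, armSeq)
            armRows[[lab]] <- data.frame(
                name = sprintf("sim-miR-%02d-%s", i, lab),
                precursor_id = names(seqs)[i],
                start = pos, end = pos + nchar(armSeq), arm = lab,
                stringsAsFactors = FALSE)
            pos <- pos + nchar(armSeq)
            spacer <- .sampleSeq(
                sample(flankRange[1L]:flankRange[2L], 1L), gc_)
            parts <- c(parts, spacer)
            pos <- pos + nchar(spacer)
        }
        seqs[i] <- paste(parts, collapse = "")
        arms[[i]] <- do.call(rbind, armRows)
    }
    .newReferenceSet(seqs, do.call(rbind, arms))
}

#' Default isomiR composition profile
#'
#' Relative abundances of the variant classes emitted per arm: the
#' reference form dominates, templated end variants within +/-1 nt come
#' next, and non-templated tails are adenine-heavy (A, 2A, 3A, with minor
#' U and AU), mirroring the composition typical of mammalian small-RNA
#' libraries. Weights sum to 1.
#'
#' @return data.frame with columns `offset5`, `offset3t` (templated 3'
#'   displacement), `tail`, `weight`.
#' @export
defaultIsoProfile <- function() {
    p <- data.frame(
        offset5 = c(0L, 1L, -1L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L),
        offset3t = c(0L, 0L, 0L, 1L, -1L, -1L, 0L, 0L, 0L, 0L, 0L),
        tail = c("", "", "", "", "", "", "A", "AA", "AAA", "U", "AU"),
        weight = c(0.50, 0.08, 0.02, 0.10, 0.10, 0.05,
                   0.08, 0.03, 0.01, 0.02, 0.01),
        stringsAsFactors = FALSE)
    stopifnot(abs(sum(p$weight) - 1) < 1e-9)
    p
}

.variantName <- function(arm, offset5, offset3t, tail) {
    nameCall(list(parent = arm, offset5 = offset5,
                  offset3 = offset3t + nchar(tail), tail = tail))
}

.variantSeq <- function(precursor, start, end, offset5, offset3t, tail) {
    paste0(substring(precursor, start + offset5 + 1L, end + offset3t),
           tail)
}

#' Simulate grouped small-RNA libraries with planted isomiR composition
#'
#' For every (arm, variant, sample), a copy number is drawn from
#' NB(mu, dispersion) with `mu = baseMean * weight * 2^lfc(group)` and
#' variance `mu + dispersion * mu^2`; with `noise = FALSE` the copy
#' number is `round(mu)` exactly, so quantification can be checked
#' against the truth table bit for bit. Reads are the exact sequences
#' implied by (arm, offsets, tail), written as DNA-letter FASTQ with
#' constant qualities.
#'
#' @param refset A [MiRReferenceSet-class] (e.g. from [makeReference()]).
#' @param samples data.frame with columns `sample`, `group`.
#' @param armParams data.frame with columns `arm`, `baseMean`; optional
#'   per-group planted effects in `lfcTable`.
#' @param lfcTable Optional data.frame (`arm`, `group`, `lfc`); missing
#'   combinations mean lfc 0 (the reference group should not appear).
#' @param profile Variant composition, see [defaultIsoProfile()].
#' @param dispersion NB dispersion of copy numbers.
#' @param noise Draw NB noise (TRUE) or emit deterministic rounded means.
#' @param outDir Directory for FASTQ files (created if absent).
#' @param seed Mandatory RNG seed.
#' @return list with `manifest` (sample, path), `truth` (sample, name,
#'   arm, category, count) and `lfcTable`.
#' @export
simulateReads <- function(refset, samples, armParams,
                          lfcTable = NULL,
                          profile = defaultIsoProfile(),
                          dispersion = 0.1, noise = TRUE,
                          outDir, seed) {
    stopifnot(!missing(seed), !missing(outDir))
    set.seed(seed)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    arms <- as.data.frame(refset@arms)
    stopifnot(all(armParams$arm %in% arms$name))
    pre <- as.character(refset@precursors)
    lfcOf <- function(arm, group) {
        if (is.null(lfcTable)) return(0)
        hit <- lfcTable$arm == arm & lfcTable$group == group
        if (any(hit)) lfcTable$lfc[hit][1L] else 0
    }
    truth <- list()
    manifest <- data.frame(sample = samples$sample,
                           path = file.path(outDir,
                               paste0(samples$sample, ".fastq")),
                           stringsAsFactors = FALSE)
    for (k in seq_len(nrow(samples))) {
        smp <- samples$sample[k]; grpk <- samples$group[k]
        seqsOut <- character(); idsOut <- character()
        rows <- list()
        for (j in seq_len(nrow(armParams))) {
            armName <- armParams$arm[j]
            ai <- match(armName, arms$name)
            prec <- pre[[arms$precursor_id[ai]]]
            lfc <- lfcOf(armName, grpk)
            for (v in seq_len(nrow(profile))) {
                mu <- armParams$baseMean[j] * profile$weight[v] * 2^lfc
                cnt <- if (!noise) as.integer(round(mu))
                       else if (dispersion > 0)
                           stats::rnbinom(1L, mu = mu,
                                          size = 1 / dispersion)
                       else stats::rpois(1L, mu)
                if (cnt <= 0L) next
                sq <- .variantSeq(prec, arms$start[ai], arms$end[ai],
                                  profile$offset5[v], profile$offset3t[v],
                                  profile$tail[v])
                nm <- .variantName(armName, profile$offset5[v],
                                   profile$offset3t[v], profile$tail[v])
                seqsOut <- c(seqsOut, rep(sq, cnt))
                rows[[length(rows) + 1L]] <- data.frame(
                    sample = smp, name = nm, arm = armName,
                    category = .categoryOf(profile$offset5[v],
                        profile$offset3t[v] + nchar(profile$tail[v]),
                        profile$tail[v]),
                    count = cnt, lfc = lfc, stringsAsFactors = FALSE)
            }
        }
        truth[[k]] <- if (length(rows)) do.call(rbind, rows) else NULL
        dna <- gsub("U", "T", seqsOut, fixed = TRUE)
        ids <- sprintf("%s_read_%06d", smp, seq_along(dna))
        .writeFastq(dna, ids, manifest$path[k])
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    list(manifest = manifest, truth = truth, lfcTable = lfcTable)
}

.writeFastq <- function(dna, ids, path) {
    if (length(dna) == 0L) {
        file.create(path)
        return(invisible(path))
    }
    qual <- Biostrings::PhredQuality(
        vapply(nchar(dna), function(n) strrep("I", n), ""))
    set <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(dna), qual)
    names(set) <- ids
    Biostrings::writeQualityScaledXStringSet(set, path)
    invisible(path)
}

#' Simulate grouped NB count matrices (miR features or genes)
#'
#' Direct count-level simulator used by the statistical recovery checks:
#' counts are NB(mu, dispersion) with `mu = baseMean * sizeFactor *
#' 2^lfc(group)` and variance `mu + dispersion * mu^2`.
#'
#' @param featureMeans Named numeric vector of base means.
#' @param samples data.frame with columns `sample`, `group`.
#' @param lfc Named numeric vector of planted log2 fold changes applied
#'   in `testGroup` (features absent default to 0).
#' @param testGroup Group receiving the effect.
#' @param dispersion NB dispersion.
#' @param sizeFactors Optional named per-sample depth multipliers.
#' @param seed Mandatory RNG seed.
#' @return Integer count matrix, features x samples.
#' @export
simulateCounts <- function(featureMeans, samples, lfc = numeric(),
                           testGroup, dispersion = 0.1,
                           sizeFactors = NULL, seed) {
    stopifnot(!missing(seed))
    set.seed(seed)
    nF <- length(featureMeans); nS <- nrow(samples)
    if (is.null(sizeFactors))
        sizeFactors <- stats::setNames(rep(1, nS), samples$sample)
    effect <- rep(0, nF)
    names(effect) <- names(featureMeans)
    if (length(lfc)) effect[names(lfc)] <- lfc
    m <- matrix(0L, nF, nS,
                dimnames = list(names(featureMeans), samples$sample))
    for (k in seq_len(nS)) {
        isTest <- samples$group[k] == testGroup
        mu <- featureMeans * sizeFactors[samples$sample[k]] *
            2^(if (isTest) effect else 0)
        m[, k] <- stats::rnbinom(nF, mu = mu, size = 1 / dispersion)
    }
    m
}

#' Simulate a full coupled study: reads, gene counts, target/TF tables
#'
#' Emits every input the pipeline consumes, with planted structure:
#' small-RNA libraries with planted arm-level fold changes and the
#' default isomiR composition; a gene count matrix in which each planted
#' anti-correlated (regulator, gene) pair receives a gene fold change
#' opposite in sign to its regulator family's; a target table scoring
#' planted pairs >= 80 and decoys < 80; and a TF table carrying a
#' planted two-step motif (a DE TF gene that is targeted by one DE family
#' and regulates another DE family, which in turn targets a second DE TF
#' gene) for circuit checks.
#'
#' @param outDir Output directory (created).
#' @param seed Mandatory RNG seed.
#' @param nPrecursors Number of reference precursors.
#' @param nPerGroup Samples per group.
#' @param groups Length-2 character vector `c(reference, test)`.
#' @param armBaseMean Mean copy number of an arm's variant ensemble.
#' @param armLfc Magnitude of planted arm fold changes.
#' @param nGenes Number of background genes.
#' @param nPlantedPairs Planted anti-correlated (regulator, gene) pairs.
#' @param geneLfc Magnitude of planted gene fold changes.
#' @param dispersion NB dispersion for both data types.
#' @param noise Passed to [simulateReads()].
#' @return list with all file paths, the truth tables and the planted
#'   pair/motif descriptions.
#' @export
simulateStudy <- function(outDir, seed, nPrecursors = 6L, nPerGroup = 6L,
                          groups = c("P", "hCG9"), armBaseMean = 300,
                          armLfc = 2, nGenes = 200L, nPlantedPairs = 10L,
                          geneLfc = 2, dispersion = 0.1, noise = TRUE) {
    stopifnot(!missing(seed), length(groups) == 2L)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    refGroup <- groups[1L]; testGroup <- groups[2L]
    refset <- makeReference(nPrecursors, seed = seed)
    writeReference(refset, file.path(outDir, "reference.fa"),
                   file.path(outDir, "reference_coords.tsv"))
    armsAll <- armNames(refset)

    set.seed(seed + 1L)
    samples <- data.frame(
        sample = sprintf("%s_%d", rep(groups, each = nPerGroup),
                         rep(seq_len(nPerGroup), 2L)),
        group = rep(groups, each = nPerGroup),
        stringsAsFactors = FALSE)
    ## plant four DE arms: two up, two down in the test group
    nDE <- min(4L, length(armsAll))
    deArms <- sample(armsAll, nDE)
    lfcs <- rep(c(armLfc, -armLfc), length.out = nDE)
    lfcTable <- data.frame(arm = deArms, group = testGroup, lfc = lfcs,
                           stringsAsFactors = FALSE)
    armParams <- data.frame(arm = armsAll,
        baseMean = armBaseMean * exp(stats::rnorm(length(armsAll), 0, 0.3)),
        stringsAsFactors = FALSE)
    reads <- simulateReads(refset, samples, armParams,
                           lfcTable = lfcTable, dispersion = dispersion,
                           noise = noise, outDir = file.path(outDir, "fastq"),
                           seed = seed + 2L)
    utils::write.table(reads$manifest,
                       file.path(outDir, "fastq_manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(samples, file.path(outDir, "mir_design.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(reads$truth, file.path(outDir, "mir_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    ## gene side: planted anti-correlated pairs keyed to the DE arms'
    ## reference features (the most abundant variant of each family)
    set.seed(seed + 3L)
    genes <- sprintf("GENE%04d", seq_len(nGenes))
    tf1 <- "TFGENE1"; tf2 <- "TFGENE2"
    genes <- c(genes, tf1, tf2)
    featureMeans <- stats::setNames(
        500 * exp(stats::rnorm(length(genes), 0, 0.4)), genes)
    upArm <- deArms[lfcs > 0][1L]
    downArm <- deArms[lfcs < 0][1L]
    regFeatures <- deArms           # refseq canonical names == arm names
    plantedGenes <- genes[seq_len(nPlantedPairs)]
    planted <- data.frame(
        regulator = rep(regFeatures, length.out = nPlantedPairs),
        gene = plantedGenes, stringsAsFactors = FALSE)
    planted$regulatorLFC <- lfcTable$lfc[match(planted$regulator,
                                               lfcTable$arm)]
    planted$geneLFC <- -sign(planted$regulatorLFC) * geneLfc
    ## planted TF motif: tf1 targeted by the up family (tf1 down),
    ## tf1 regulates the down family, which targets tf2 (tf2 up)
    motif <- data.frame(regulator = c(upArm, downArm),
                        gene = c(tf1, tf2),
                        regulatorLFC = c(armLfc, -armLfc),
                        geneLFC = c(-geneLfc, geneLfc),
                        stringsAsFactors = FALSE)
    plantedAll <- rbind(planted, motif)
    geneLfcVec <- stats::setNames(plantedAll$geneLFC, plantedAll$gene)
    geneCounts <- simulateCounts(featureMeans, samples, lfc = geneLfcVec,
                                 testGroup = testGroup,
                                 dispersion = dispersion / 2,
                                 seed = seed + 4L)
    writeCountMatrix(geneCounts, file.path(outDir, "gene_counts.tsv"))
    utils::write.table(samples, file.path(outDir, "gene_design.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    ## target table: planted rows score >= 80, decoys < 80
    set.seed(seed + 5L)
    nDecoys <- min(30L, length(setdiff(genes, plantedAll$gene)))
    decoyGenes <- sample(setdiff(genes, plantedAll$gene), nDecoys)
    decoys <- data.frame(
        regulator = sample(regFeatures, nDecoys, replace = TRUE),
        gene = decoyGenes,
        score = stats::runif(nDecoys, 40, 79.9), stringsAsFactors = FALSE)
    targets <- rbind(
        data.frame(regulator = plantedAll$regulator,
                   gene = plantedAll$gene,
                   score = stats::runif(nrow(plantedAll), 80, 100),
                   stringsAsFactors = FALSE),
        decoys)
    targets <- targets[order(targets$regulator, targets$gene), ,
                       drop = FALSE]
    utils::write.table(targets, file.path(outDir, "targets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    tfTable <- data.frame(
        tf = c(tf1, tf1),
        mir_family = c(.armFamily(downArm), .armFamily(upArm)),
        direction = c("activate", "unknown"),
        literature_curated = c(TRUE, FALSE),
        stringsAsFactors = FALSE)
    utils::write.table(tfTable, file.path(outDir, "tf_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(plantedAll, file.path(outDir, "pair_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    list(outDir = outDir, refset = refset,
         reference = file.path(outDir, c("reference.fa",
                                         "reference_coords.tsv")),
         manifest = file.path(outDir, "fastq_manifest.tsv"),
         mirDesign = file.path(outDir, "mir_design.tsv"),
         geneCounts = file.path(outDir, "gene_counts.tsv"),
         geneDesign = file.path(outDir, "gene_design.tsv"),
         targets = file.path(outDir, "targets.tsv"),
         tfTable = file.path(outDir, "tf_table.tsv"),
         samples = samples, groups = groups,
         mirTruth = reads$truth, lfcTable = lfcTable,
         plantedPairs = plantedAll,
         motif = list(tf1 = tf1, tf2 = tf2,
                      upFamily = .armFamily(upArm),
                      downFamily = .armFamily(downArm),
                      upArm = upArm, downArm = downArm))
}
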