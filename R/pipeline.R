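## Pipeline orchestration: YAML config, subcommands, deterministic TSV
## outputs. The CLI entry point (inst/scripts/isomirpipe) is a thin
## wrapper over pipelineMain(); every stage is equally usable from R.

.logmsg <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
}

.cfgGet <- function(config, ...) {
    keys <- c(...)
    node <- config
    for (k in keys) {
        if (is.null(node[[k]]))
            stop("missing config key: ", paste(keys, collapse = "."))
        node <- node[[k]]
    }
    node
}

.cfgPath <- function(config, ...) {
    p <- .cfgGet(config, ...)
    base <- attr(config, "dir")
    if (!is.null(base) && !grepl("^(/|[A-Za-z]:)", p))
        p <- file.path(base, p)
    p
}

#' Read a pipeline configuration file
#'
#' YAML with sections `reference` (fasta, coords), `reads` (manifest),
#' `mir` (design), `genes` (counts, design), `integration` (targets,
#' tf_table, min_score), `contrasts` (list of `[test, reference]`
#' pairs), `classifier`, `de_mir`, `de_gene`, `simulate`, plus top-level
#' `out_dir` and `seed`. Relative paths are resolved against the config
#' file's directory.
#'
#' @param path Path to the YAML file.
#' @return The config list (with the base directory attached).
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path))
        stop("config file not found: ", path)
    config <- yaml::read_yaml(path)
    attr(config, "dir") <- dirname(normalizePath(path))
    config
}

.classifierFromConfig <- function(config) {
    cc <- config$classifier
    if (is.null(cc)) return(classifierConfig())
    classifierConfig(
        maxOffset = cc$max_offset %||% 5L,
        maxTail = cc$max_tail %||% 3L,
        minReadLen = cc$min_read_len %||% 16L,
        maxReadLen = cc$max_read_len %||% 28L)
}

.deFromConfig <- function(config, section, lfcDefault) {
    dc <- config[[section]]
    deConfig(alpha = dc$alpha %||% 0.05,
             lfcMin = dc$lfc_min %||% lfcDefault,
             minTotalCount = dc$min_total_count %||% 10L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.outDir <- function(config) {
    d <- .cfgPath(config, "out_dir")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
}

.contrastTag <- function(ct) paste0(ct[1L], "_vs_", ct[2L])

.cmdBuildRef <- function(config) {
    ref <- loadReference(.cfgPath(config, "reference", "fasta"),
                         .cfgPath(config, "reference", "coords"))
    out <- .outDir(config)
    writeReference(ref, file.path(out, "reference.fa"),
                   file.path(out, "reference_coords.tsv"))
    .logmsg("build-ref", "validated %d precursors / %d arms",
            length(precursors(ref)), nrow(matureArms(ref)))
    0L
}

.cmdSimulate <- function(config) {
    sc <- config$simulate %||% list()
    seed <- config$seed %||% stop("missing config key: seed")
    out <- .outDir(config)
    res <- simulateStudy(outDir = out, seed = as.integer(seed),
        nPrecursors = sc$n_precursors %||% 6L,
        nPerGroup = sc$n_per_group %||% 6L,
        groups = unlist(sc$groups %||% list("P", "hCG9")),
        nGenes = sc$n_genes %||% 200L,
        nPlantedPairs = sc$n_planted_pairs %||% 10L)
    .logmsg("simulate", "wrote study to %s (%d samples, %d planted pairs)",
            out, nrow(res$samples), nrow(res$plantedPairs))
    0L
}

.cmdClassify <- function(config) {
    ref <- loadReference(.cfgPath(config, "reference", "fasta"),
                         .cfgPath(config, "reference", "coords"))
    manifest <- utils::read.delim(.cfgPath(config, "reads", "manifest"),
                                  stringsAsFactors = FALSE)
    base <- attr(config, "dir")
    rel <- !grepl("^(/|[A-Za-z]:)", manifest$path)
    manifest$path[rel] <- file.path(base, manifest$path[rel])
    se <- quantifyReads(manifest, ref, .classifierFromConfig(config))
    out <- .outDir(config)
    writeCountMatrix(se, file.path(out, "mir_counts.tsv"))
    writeUnassignedReport(se, file.path(out, "unassigned.tsv"))
    .logmsg("classify", "%d samples in, %d features out, %d unassigned reads",
            nrow(manifest), nrow(se),
            sum(S4Vectors::metadata(se)$unassigned$count))
    0L
}

.cmdDE <- function(config, what = c("mir", "gene")) {
    out <- .outDir(config)
    contrasts <- .cfgGet(config, "contrasts")
    for (w in what) {
        if (w == "mir") {
            counts <- readCountMatrix(file.path(out, "mir_counts.tsv"))
            design <- utils::read.delim(.cfgPath(config, "mir", "design"),
                                        stringsAsFactors = FALSE)
            dc <- .deFromConfig(config, "de_mir", 0)
        } else {
            counts <- readCountMatrix(.cfgPath(config, "genes", "counts"))
            design <- utils::read.delim(.cfgPath(config, "genes", "design"),
                                        stringsAsFactors = FALSE)
            dc <- .deFromConfig(config, "de_gene", 1)
        }
        for (ct in contrasts) {
            ct <- unlist(ct)
            rec <- nbWaldTest(counts, design, contrast = ct, config = dc)
            de <- callDE(rec, dc)
            tag <- .contrastTag(ct)
            writeDETable(rec, file.path(out,
                sprintf("de_%s_%s.tsv", w, tag)))
            writeDETable(de, file.path(out,
                sprintf("de_%s_%s_called.tsv", w, tag)))
            .logmsg("de", "%s %s: %d tested, %d called DE", w, tag,
                    sum(!rec$filtered), nrow(de))
        }
    }
    0L
}

.cmdPair <- function(config) {
    out <- .outDir(config)
    minScore <- config$integration$min_score %||% 80
    targets <- filterTargets(
        utils::read.delim(.cfgPath(config, "integration", "targets"),
                          stringsAsFactors = FALSE),
        minScore = minScore)
    for (ct in .cfgGet(config, "contrasts")) {
        tag <- .contrastTag(unlist(ct))
        mirDE <- utils::read.delim(
            file.path(out, sprintf("de_mir_%s_called.tsv", tag)),
            stringsAsFactors = FALSE)
        geneDE <- utils::read.delim(
            file.path(out, sprintf("de_gene_%s_called.tsv", tag)),
            stringsAsFactors = FALSE)
        pairs <- pairDE(mirDE, geneDE, targets)
        utils::write.table(pairs,
            file.path(out, sprintf("pairs_%s.tsv", tag)),
            sep = "\t", quote = FALSE, row.names = FALSE)
        .logmsg("pair", "%s: %d negative, %d positive pairs", tag,
                sum(pairs$klass == "negative"),
                sum(pairs$klass == "positive"))
    }
    0L
}

.cmdCircuit <- function(config) {
    out <- .outDir(config)
    tf <- utils::read.delim(.cfgPath(config, "integration", "tf_table"),
                            stringsAsFactors = FALSE)
    for (ct in .cfgGet(config, "contrasts")) {
        tag <- .contrastTag(unlist(ct))
        pairs <- utils::read.delim(
            file.path(out, sprintf("pairs_%s.tsv", tag)),
            stringsAsFactors = FALSE)
        mirDE <- utils::read.delim(
            file.path(out, sprintf("de_mir_%s_called.tsv", tag)),
            stringsAsFactors = FALSE)
        geneDE <- utils::read.delim(
            file.path(out, sprintf("de_gene_%s_called.tsv", tag)),
            stringsAsFactors = FALSE)
        tfEdges <- expandTFRegulations(tf, mirDE$feature)
        deTF <- intersect(unique(tf$tf), geneDE$feature)
        circ <- buildCircuit(pairs, tfEdges, deTFGenes = deTF)
        writeCircuit(circ,
                     dotPath = file.path(out,
                         sprintf("circuit_%s.dot", tag)),
                     edgesPath = file.path(out,
                         sprintf("circuit_%s_edges.tsv", tag)))
        .logmsg("circuit", "%s: %d nodes, %d edges", tag,
                nrow(circuitNodes(circ)), nrow(circuitEdges(circ)))
    }
    0L
}

.USAGE <- paste(
    "usage: isomirpipe <subcommand> --config <file> [options]",
    "subcommands: build-ref simulate classify de pair circuit run-all",
    "options: --seed N --alpha A --lfc-min L --min-score S --version",
    sep = "\n")

.parseArgs <- function(args) {
    flags <- list()
    positional <- character()
    i <- 1L
    while (i <= length(args)) {
        a <- args[i]
        if (a == "--version") {
            flags$version <- TRUE
        } else if (grepl("^--", a)) {
            key <- sub("^--", "", a)
            if (i == length(args) || grepl("^--", args[i + 1L]))
                stop("flag ", a, " needs a value")
            flags[[gsub("-", "_", key)]] <- args[i + 1L]
            i <- i + 1L
        } else positional <- c(positional, a)
        i <- i + 1L
    }
    list(flags = flags, positional = positional)
}

#' Command-line pipeline driver
#'
#' Dispatches the subcommands `build-ref`, `simulate`, `classify`, `de`,
#' `pair`, `circuit` and `run-all` (classify, then miR and gene DE for
#' every configured contrast, then pairing, then circuit assembly). Log
#' lines go to stderr; results are written only to files under the
#' configured output directory, with deterministic lexicographic row
#' ordering. Returns (rather than calls) the exit status so it can be
#' driven from tests; the installed `isomirpipe` script forwards the
#' status to `quit()`.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status: 0 on success, 1 on a validation/run
#'   error, 2 on a usage error.
#' @examples
#' pipelineMain(c("--version"))
#' @export
pipelineMain <- function(args = commandArgs(trailingOnly = TRUE)) {
    parsed <- tryCatch(.parseArgs(args), error = function(e) e)
    if (inherits(parsed, "error")) {
        message(conditionMessage(parsed)); message(.USAGE)
        return(2L)
    }
    if (isTRUE(parsed$flags$version)) {
        message("isomirpipe ",
                as.character(utils::packageVersion("isomiRpipe")))
        return(0L)
    }
    if (length(parsed$positional) != 1L) {
        message(.USAGE)
        return(2L)
    }
    sub <- parsed$positional
    known <- c("build-ref", "simulate", "classify", "de", "pair",
               "circuit", "run-all")
    if (!sub %in% known) {
        message("unknown subcommand: ", sub); message(.USAGE)
        return(2L)
    }
    status <- tryCatch({
        if (is.null(parsed$flags$config))
            stop("missing required flag --config")
        config <- readPipelineConfig(parsed$flags$config)
        fl <- parsed$flags
        if (!is.null(fl$seed)) config$seed <- as.integer(fl$seed)
        if (!is.null(fl$alpha)) {
            config$de_mir$alpha <- as.numeric(fl$alpha)
            config$de_gene$alpha <- as.numeric(fl$alpha)
        }
        if (!is.null(fl$lfc_min))
            config$de_gene$lfc_min <- as.numeric(fl$lfc_min)
        if (!is.null(fl$min_score))
            config$integration$min_score <- as.numeric(fl$min_score)
        switch(sub,
            "build-ref" = .cmdBuildRef(config),
            "simulate" = .cmdSimulate(config),
            "classify" = .cmdClassify(config),
            "de" = .cmdDE(config),
            "pair" = .cmdPair(config),
            "circuit" = .cmdCircuit(config),
            "run-all" = {
                .cmdClassify(config)
                .cmdDE(config)
                .cmdPair(config)
                .cmdCircuit(config)
                0L
            })
    }, error = function(e) {
        message("error: ", conditionMessage(e))
        1L
    })
    as.integer(status)
}
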