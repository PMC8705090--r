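## Quantification: collapse FASTQ reads, classify unique sequences, and
## accumulate copy numbers into a feature x sample count matrix.

#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
NULL

.readFastqSeqs <- function(path) {
    if (!file.exists(path))
        stop("FASTQ file not found: ", path)
    set <- tryCatch(
        Biostrings::readBStringSet(path, format = "fastq"),
        error = function(e) {
            if (grepl("no lines|empty", conditionMessage(e),
                      ignore.case = TRUE))
                return(Biostrings::BStringSet())
            stop("failed to read FASTQ '", path, "': ",
                 conditionMessage(e))
        })
    .normalizeRNA(as.character(set))
}

#' Quantify isomiRs from FASTQ libraries
#'
#' Collapses identical read sequences per sample, classifies each distinct
#' sequence once with [classifyRead()] semantics, and accumulates copy
#' numbers under the canonical isomiR names. Unassigned reads are tallied
#' per reason code. Each distinct assigned sequence contributes its copies
#' to exactly one canonical name (deterministic tie-break), never
#' fractionally.
#'
#' @param manifest A data.frame with columns `sample` and `path` (FASTQ,
#'   gzip allowed), or a named character vector of paths (names =
#'   samples). Sample names must be unique.
#' @param refset A [MiRReferenceSet-class].
#' @param config A [ClassifierConfig-class].
#' @return A [SummarizedExperiment::SummarizedExperiment] with integer
#'   assay `"counts"` (features x samples, rows sorted lexicographically),
#'   `rowData` holding the parsed name fields, and
#'   `metadata(x)$unassigned` a data.frame (sample, reason, count).
#' @export
quantifyReads <- function(manifest, refset, config = classifierConfig()) {
    if (is.character(manifest))
        manifest <- data.frame(sample = names(manifest), path = manifest,
                               stringsAsFactors = FALSE)
    stopifnot(all(c("sample", "path") %in% colnames(manifest)))
    if (anyDuplicated(manifest$sample))
        stop("sample names must be unique")
    samples <- as.character(manifest$sample)

    perSample <- vector("list", length(samples))
    unassigned <- list()
    classCache <- new.env(parent = emptyenv())
    preRawList <- .precursorRawList(refset)
    arms <- as.data.frame(refset@arms)

    for (k in seq_along(samples)) {
        seqs <- .readFastqSeqs(manifest$path[k])
        if (length(seqs) == 0L) {
            warning("empty FASTQ for sample '", samples[k], "'")
            perSample[[k]] <- integer(0)
            next
        }
        tab <- table(seqs)
        uniq <- names(tab)
        counts <- as.integer(tab)
        names_out <- character(length(uniq))
        reasons <- character(length(uniq))
        for (i in seq_along(uniq)) {
            key <- uniq[i]
            hit <- classCache[[key]]
            if (is.null(hit)) {
                n <- nchar(key)
                if (n < config@minReadLen || n > config@maxReadLen) {
                    hit <- list(assigned = FALSE, reason = "length")
                } else {
                    hit <- .classifyOne(key, preRawList, arms, config)
                }
                classCache[[key]] <- hit
            }
            if (isTRUE(hit$assigned)) names_out[i] <- hit$name
            else reasons[i] <- hit$reason
        }
        ok <- nzchar(names_out)
        if (any(ok)) {
            agg <- tapply(counts[ok], names_out[ok], sum)
            perSample[[k]] <- stats::setNames(as.integer(agg), names(agg))
        } else perSample[[k]] <- integer(0)
        if (any(!ok)) {
            ragg <- tapply(counts[!ok], reasons[!ok], sum)
            unassigned[[samples[k]]] <- data.frame(
                sample = samples[k], reason = names(ragg),
                count = as.integer(ragg), stringsAsFactors = FALSE)
        }
    }

    feats <- sort(unique(unlist(lapply(perSample, names))))
    mat <- matrix(0L, nrow = length(feats), ncol = length(samples),
                  dimnames = list(feats, samples))
    for (k in seq_along(samples)) {
        v <- perSample[[k]]
        if (length(v)) mat[names(v), k] <- v
    }
    un <- if (length(unassigned)) do.call(rbind, unname(unassigned))
          else data.frame(sample = character(), reason = character(),
                          count = integer(), stringsAsFactors = FALSE)
    rownames(un) <- NULL
    rd <- if (length(feats)) S4Vectors::DataFrame(.parseNames(feats))
          else S4Vectors::DataFrame(name = character())
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = mat), rowData = rd)
    S4Vectors::metadata(se)$unassigned <- un
    se
}

.asCountMatrix <- function(x) {
    if (methods::is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x, "counts")
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    if (any(m < 0) || any(m != round(m)))
        stop("count matrix must contain non-negative integers")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
        stop("count matrix needs unique feature names")
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
        stop("count matrix needs unique sample names")
    m
}

#' Write / read a count matrix as TSV
#'
#' Tab-separated, features in rows, header `feature<TAB>sample...`, rows in
#' lexicographic feature order.
#'
#' @param x A count matrix or SummarizedExperiment with a `counts` assay.
#' @param path Output (input) path.
#' @return `writeCountMatrix`: invisibly the path; `readCountMatrix`: an
#'   integer matrix.
#' @export
writeCountMatrix <- function(x, path) {
    m <- .asCountMatrix(x)
    m <- m[order(rownames(m)), , drop = FALSE]
    df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeCountMatrix
#' @export
readCountMatrix <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (colnames(df)[1L] != "feature")
        stop("count matrix TSV must start with a 'feature' column")
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$feature
    storage.mode(m) <- "integer"
    m
}

#' Per-class distribution of isomiR features
#'
#' Tabulates how many distinct features (not reads) of each class —
#' refseq, iso5, iso3, iso5_3, nontemplate — are present, and their
#' percentage of the subset; a per-sequence-class accounting.
#'
#' @param x A SummarizedExperiment/matrix with canonical feature names, or
#'   a character vector of canonical names.
#' @param features Optional subset of feature names to tabulate.
#' @return A data.frame with columns `category`, `n`, `percent`
#'   (percentages sum to 100).
#' @export
typeDistribution <- function(x, features = NULL) {
    nm <- if (is.character(x)) x
          else rownames(.asCountMatrix(x))
    if (!is.null(features)) {
        missing <- setdiff(features, nm)
        if (length(missing))
            stop("features not present: ", missing[1L])
        nm <- intersect(nm, features)
    }
    if (length(nm) == 0L)
        stop("empty feature subset")
    cats <- vapply(nm, function(n) parseName(n)$category, "")
    n <- vapply(.CATEGORIES, function(cc) sum(cats == cc), 0L)
    data.frame(category = .CATEGORIES, n = as.integer(n),
               percent = 100 * as.numeric(n) / length(nm),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Write the unassigned-read report of a quantification
#'
#' @param se SummarizedExperiment from [quantifyReads()].
#' @param path Output TSV path (sample, reason, count).
#' @export
writeUnassignedReport <- function(se, path) {
    un <- S4Vectors::metadata(se)$unassigned
    un <- un[order(un$sample, un$reason), , drop = FALSE]
    utils::write.table(un, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
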