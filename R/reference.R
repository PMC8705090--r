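## Reference database: precursor hairpins + mature-arm coordinates.
## Coordinates are 0-based half-open everywhere (files and API), the
## convention of BED-style genomics tooling.

.normalizeRNA <- function(x) {
    x <- toupper(x)
    gsub("T", "U", x, fixed = TRUE)
}

.newReferenceSet <- function(sequences, arms) {
    pre <- Biostrings::RNAStringSet(sequences)
    arms <- S4Vectors::DataFrame(
        name = as.character(arms$name),
        precursor_id = as.character(arms$precursor_id),
        start = as.integer(arms$start),
        end = as.integer(arms$end),
        arm = as.character(arms$arm))
    rownames(arms) <- arms$name
    new("MiRReferenceSet", precursors = pre, arms = arms)
}

#' Load a miR reference from FASTA plus an arm-coordinate table
#'
#' Reads precursor hairpins from FASTA (DNA or RNA; `T` is normalized to
#' `U`) and mature-arm locations from a tab-separated table with header
#' columns `precursor_id`, `mature_name`, `start`, `end`, `arm`.
#' Coordinates are 0-based half-open intervals on the precursor.
#'
#' @param hairpinFasta Path to the precursor FASTA (gzip allowed).
#' @param coordsTable Path to the TSV arm-coordinate table.
#' @return A [MiRReferenceSet-class] object.
#' @examples
#' d <- tempfile(); dir.create(d)
#' writeReference(fixtureReference(), file.path(d, "ref.fa"),
#'                file.path(d, "coords.tsv"))
#' ref <- loadReference(file.path(d, "ref.fa"), file.path(d, "coords.tsv"))
#' armNames(ref)
#' @export
loadReference <- function(hairpinFasta, coordsTable) {
    seqs <- Biostrings::readBStringSet(hairpinFasta)
    sq <- .normalizeRNA(as.character(seqs))
    names(sq) <- sub("\\s.*$", "", names(seqs))
    if (any(grepl("[^ACGU]", sq)))
        stop("precursor FASTA contains non-nucleotide characters")
    tab <- utils::read.delim(coordsTable, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    req <- c("precursor_id", "mature_name", "start", "end", "arm")
    if (!all(req %in% colnames(tab)))
        stop("coords table must have columns: ", paste(req, collapse = ", "))
    unknown <- which(!(tab$precursor_id %in% names(sq)))
    if (length(unknown))
        stop(sprintf("unknown precursor id '%s' in coords row %d",
                     tab$precursor_id[unknown[1L]], unknown[1L]))
    plen <- nchar(sq)[match(tab$precursor_id, names(sq))]
    oob <- which(tab$start < 0L | tab$start >= tab$end | tab$end > plen)
    if (length(oob))
        stop(sprintf("coordinates out of bounds in coords row %d (%s)",
                     oob[1L], tab$mature_name[oob[1L]]))
    if (anyDuplicated(tab$mature_name))
        stop("duplicate mature name: ",
             tab$mature_name[duplicated(tab$mature_name)][1L])
    .newReferenceSet(sq, data.frame(
        name = tab$mature_name, precursor_id = tab$precursor_id,
        start = tab$start, end = tab$end, arm = tab$arm))
}

#' Write a reference set back to FASTA + coordinate TSV
#'
#' Inverse of [loadReference()]; sequences and coordinates round-trip
#' bit-exactly.
#'
#' @param refset A [MiRReferenceSet-class].
#' @param hairpinFasta,coordsTable Output paths.
#' @return Invisibly, the two paths.
#' @export
writeReference <- function(refset, hairpinFasta, coordsTable) {
    Biostrings::writeXStringSet(refset@precursors, filepath = hairpinFasta)
    arms <- as.data.frame(refset@arms)
    out <- data.frame(precursor_id = arms$precursor_id,
                      mature_name = arms$name,
                      start = arms$start, end = arms$end, arm = arms$arm)
    utils::write.table(out, coordsTable, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(hairpinFasta, coordsTable))
}

#' @describeIn MiRReferenceSet-class Precursor hairpin sequences.
#' @param x A `MiRReferenceSet`.
#' @export
precursors <- function(x) x@precursors

#' @describeIn MiRReferenceSet-class Mature-arm coordinate table.
#' @export
matureArms <- function(x) x@arms

#' @describeIn MiRReferenceSet-class Names of all mature arms.
#' @export
armNames <- function(x) x@arms$name

#' Mature-arm sequence(s) derived from the precursor
#'
#' @param refset A [MiRReferenceSet-class].
#' @param name Arm name(s); default all arms.
#' @return Named character vector of RNA arm sequences.
#' @export
armSequence <- function(refset, name = armNames(refset)) {
    arms <- refset@arms
    idx <- match(name, arms$name)
    if (anyNA(idx))
        stop("unknown arm name: ", name[is.na(idx)][1L])
    sq <- as.character(refset@precursors)[
        match(arms$precursor_id[idx], names(refset@precursors))]
    out <- substring(sq, arms$start[idx] + 1L, arms$end[idx])
    names(out) <- name
    out
}

setMethod("show", "MiRReferenceSet", function(object) {
    cat(sprintf("MiRReferenceSet: %d precursors, %d mature arms\n",
                length(object@precursors), nrow(object@arms)))
    if (nrow(object@arms))
        cat("  arms:", paste(utils::head(object@arms$name, 6L),
                             collapse = ", "),
            if (nrow(object@arms) > 6L) "..." else "", "\n")
})

## Mature arms with sequences printed in the endometrial-receptivity study;
## each is embedded in a synthetic precursor with G/C-only 4-nt flanks so
## that A/U tails can never be templated.
.FIXTURE_ARMS <- c(
    "let-7g-5p"   = "CUGUACAGGCCACUGCCUUGC",
    "miR-10b-5p"  = "UACCCUGUAGAACCGAAUUUGUG",
    "miR-27b-3p"  = "UUCACAGUGGCUAAGUUCUGC",
    "miR-141-3p"  = "UAACACUGUCUGGUAAAGAUGG",
    "miR-199a-5p" = "CCCAGUGUUCAGACUACCUGUUC",
    "miR-486-5p"  = "UCCUGUACUGAGCUGCCCCGAG")

#' Built-in reference fixture of six mature arms
#'
#' A deterministic [MiRReferenceSet-class] containing six well-known human
#' mature miRs (let-7g-5p, miR-10b-5p, miR-27b-3p, miR-141-3p, miR-199a-5p,
#' miR-486-5p), each embedded in a synthetic precursor with 4-nt G/C flanks.
#' Because the flanks contain no A or U, adenine/uridine 3' tails on reads
#' against this fixture are guaranteed to be non-templated. The arm
#' sequences are real; the precursors are synthetic scaffolds.
#'
#' @return A [MiRReferenceSet-class].
#' @examples
#' armSequence(fixtureReference(), "miR-27b-3p")
#' @export
fixtureReference <- function() {
    arm <- .FIXTURE_ARMS
    pre_id <- paste0("syn-pre-", names(arm))
    sequences <- paste0("GCGG", arm, "CGGC")
    names(sequences) <- pre_id
    armlab <- ifelse(grepl("-5p$", names(arm)), "5p", "3p")
    .newReferenceSet(sequences, data.frame(
        name = names(arm), precursor_id = pre_id,
        start = 4L, end = 4L + nchar(arm), arm = armlab))
}

#' Convert a miRBase-style GFF3 annotation to an arm-coordinate TSV
#'
#' Thin converter for genome-coordinate GFF3 files in which `miRNA`
#' features carry a `Derives_from` attribute pointing at their
#' `miRNA_primary_transcript`. Arm positions are re-expressed relative to
#' the parent precursor (strand-aware) as 0-based half-open intervals, the
#' interchange format consumed by [loadReference()].
#'
#' @param gff3Path Input GFF3 path.
#' @param coordsTable Output TSV path.
#' @return Invisibly, the coords data.frame that was written.
#' @export
gff3ToCoordsTable <- function(gff3Path, coordsTable) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
        stop("gff3ToCoordsTable requires the rtracklayer package")
    gr <- rtracklayer::import(gff3Path)
    md <- S4Vectors::mcols(gr)
    is_pre <- md$type == "miRNA_primary_transcript"
    is_mat <- md$type == "miRNA"
    pre <- gr[is_pre]
    mat <- gr[is_mat]
    pid <- as.character(S4Vectors::mcols(pre)$ID)
    names(pre) <- pid
    dfrom <- as.character(S4Vectors::mcols(mat)$Derives_from)
    idx <- match(dfrom, pid)
    if (anyNA(idx))
        stop("miRNA feature with Derives_from not matching any precursor")
    p <- pre[idx]
    minus <- as.character(BiocGenerics::strand(p)) == "-"
    start0 <- ifelse(minus,
        BiocGenerics::end(p) - BiocGenerics::end(mat),
        BiocGenerics::start(mat) - BiocGenerics::start(p))
    end0 <- start0 + BiocGenerics::width(mat)
    nm <- as.character(S4Vectors::mcols(mat)$Name)
    armlab <- ifelse(grepl("-3p$", nm), "3p", "5p")
    nmp <- as.character(S4Vectors::mcols(p)$Name)
    out <- data.frame(precursor_id = nmp, mature_name = nm,
                      start = as.integer(start0), end = as.integer(end0),
                      arm = armlab)
    out <- out[order(out$precursor_id, out$start), , drop = FALSE]
    utils::write.table(out, coordsTable, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(out)
}
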