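#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom Biostrings RNAStringSet readBStringSet writeXStringSet width
NULL

#' Reference set of miR precursors and mature arms
#'
#' Holds miRBase-like reference data: precursor hairpin sequences (RNA
#' alphabet) and the mature 5p/3p arms located inside them by 0-based
#' half-open coordinates. All isomiR classification is performed against an
#' object of this class.
#'
#' @slot precursors A named [Biostrings::RNAStringSet] of hairpin sequences.
#' @slot arms A [S4Vectors::DataFrame] with columns `name`, `precursor_id`,
#'   `start` (0-based inclusive), `end` (exclusive) and `arm` (`"5p"` or
#'   `"3p"`), one row per mature arm.
#'
#' @section Invariants:
#' Precursor sequences are non-empty and strictly over A/C/G/U; every arm
#' lies within its precursor; a precursor carries at most two arms whose
#' intervals do not overlap; arm names are unique.
#'
#' @seealso [loadReference()], [fixtureReference()], [makeReference()]
#' @export
setClass("MiRReferenceSet",
    representation(precursors = "RNAStringSet", arms = "DataFrame"))

setValidity("MiRReferenceSet", function(object) {
    pre <- object@precursors
    arms <- object@arms
    if (is.null(names(pre)) || anyDuplicated(names(pre)))
        return("precursors must have unique names")
    seqs <- as.character(pre)
    if (any(nchar(seqs) == 0L))
        return("precursor sequences must be non-empty")
    if (any(grepl("[^ACGU]", seqs)))
        return("precursor sequences must be uppercase RNA over {A,C,G,U}")
    req <- c("name", "precursor_id", "start", "end", "arm")
    if (!all(req %in% colnames(arms)))
        return(paste("arms must have columns:", paste(req, collapse = ", ")))
    if (nrow(arms) == 0L)
        return(TRUE)
    if (anyDuplicated(arms$name))
        return("duplicate mature name")
    if (!all(arms$precursor_id %in% names(pre)))
        return("arm refers to unknown precursor id")
    if (!all(arms$arm %in% c("5p", "3p")))
        return("arm label must be '5p' or '3p'")
    plen <- nchar(seqs)[match(arms$precursor_id, names(pre))]
    if (any(arms$start < 0L) || any(arms$start >= arms$end) ||
        any(arms$end > plen))
        return("coordinates out of bounds")
    for (pid in unique(arms$precursor_id)) {
        sub <- arms[arms$precursor_id == pid, , drop = FALSE]
        if (nrow(sub) > 2L)
            return(sprintf("precursor '%s' carries more than two arms", pid))
        if (nrow(sub) == 2L) {
            sub <- sub[order(sub$start), , drop = FALSE]
            if (sub$end[1L] > sub$start[2L])
                return(sprintf("overlapping arms on precursor '%s'", pid))
        }
    }
    TRUE
})

#' Classifier configuration
#'
#' Bounds for isomiR classification: the maximum absolute 5' and (templated)
#' 3' end offset in nucleotides, the maximum length of a non-templated 3'
#' tail, and the admissible read-length window.
#'
#' @slot maxOffset integer, window for |5' offset| and |templated 3' offset|.
#' @slot maxTail integer, maximum non-templated 3' suffix length.
#' @slot minReadLen,maxReadLen integer read-length bounds.
#' @export
setClass("ClassifierConfig",
    representation(maxOffset = "integer", maxTail = "integer",
                   minReadLen = "integer", maxReadLen = "integer"))

setValidity("ClassifierConfig", function(object) {
    v <- c(object@maxOffset, object@maxTail, object@minReadLen,
           object@maxReadLen)
    if (length(v) != 4L || any(is.na(v)) || any(v <= 0L))
        return("all classifier bounds must be positive integers")
    if (object@minReadLen > object@maxReadLen)
        return("minReadLen must not exceed maxReadLen")
    TRUE
})

#' Differential-expression configuration
#'
#' @slot alpha numeric significance level on raw p-values.
#' @slot lfcMin numeric minimum |log2 fold change| for calling (0 for
#'   miR/isomiR matrices, 1 for gene matrices).
#' @slot minTotalCount integer; features whose total raw count across the
#'   contrast samples falls below this are flagged `filtered` and not tested.
#' @slot dispersionFloor numeric lower bound for the moment dispersion.
#' @export
setClass("DEConfig",
    representation(alpha = "numeric", lfcMin = "numeric",
                   minTotalCount = "integer", dispersionFloor = "numeric"))

setValidity("DEConfig", function(object) {
    if (object@alpha <= 0 || object@alpha >= 1)
        return("alpha must lie in (0, 1)")
    if (object@lfcMin < 0)
        return("lfcMin must be non-negative")
    if (object@minTotalCount < 0L)
        return("minTotalCount must be non-negative")
    if (object@dispersionFloor <= 0)
        return("dispersionFloor must be positive")
    TRUE
})

#' TF-miR/isomiR-gene regulatory circuit
#'
#' A typed directed graph with node types `TF`, `mir_family` and `gene`, and
#' edge types `tf_regulates_mir` and `mir_targets_gene`. isomiR features are
#' collapsed into family nodes labelled by their parent mature arm; the
#' number of collapsed features is recorded as the node multiplicity.
#'
#' @slot nodes data.frame with columns `name`, `type`, `multiplicity`.
#' @slot edges data.frame with columns `src`, `dst`, `type`.
#' @seealso [buildCircuit()], [writeCircuit()]
#' @export
setClass("RegulatoryCircuit",
    representation(nodes = "data.frame", edges = "data.frame"))

setValidity("RegulatoryCircuit", function(object) {
    nd <- object@nodes
    ed <- object@edges
    if (!all(c("name", "type", "multiplicity") %in% colnames(nd)))
        return("nodes must have columns name, type, multiplicity")
    if (!all(c("src", "dst", "type") %in% colnames(ed)))
        return("edges must have columns src, dst, type")
    if (anyDuplicated(nd$name))
        return("duplicate node names")
    if (!all(nd$type %in% c("TF", "mir_family", "gene")))
        return("unknown node type")
    if (!all(ed$type %in% c("tf_regulates_mir", "mir_targets_gene")))
        return("unknown edge type")
    if (nrow(ed) > 0L && !all(c(ed$src, ed$dst) %in% nd$name))
        return("edge endpoint missing from node table")
    bad <- ed$type == "mir_targets_gene" &
        ed$dst %in% nd$name[nd$type == "mir_family"]
    if (any(bad))
        return("mir_targets_gene edge may not point at a mir node")
    TRUE
})
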