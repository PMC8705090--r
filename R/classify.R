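## isomiR classification by end offsets and non-templated 3' tails.
##
## Conventions (derived from the canonical-name grammar):
##   offset5 = read 5' start - arm 5' start (precursor coordinates);
##             positive = trimmed at the 5' end, negative = extended.
##   offset3 = read 3' end (tail included) - arm 3' end;
##             positive = longer at the 3' end.
## The templated portion of a read is its longest prefix matching the
## precursor exactly and contiguously (maximal-prefix rule), so a declared
## tail never starts with the next templated base unless the match already
## reached the precursor's end.

.CATEGORIES <- c("refseq", "iso5", "iso3", "iso5_3", "nontemplate")

#' Construct a classifier configuration
#'
#' @param maxOffset Window (nt) for the absolute 5' offset and for the
#'   absolute templated 3' displacement. The total 3' offset of a tailed
#'   variant may therefore reach `maxOffset + maxTail`.
#' @param maxTail Maximum non-templated 3' suffix length (nt); mono- to
#'   tri-nucleotide tails (A, 2A, 3A ...) are the biologically common case.
#' @param minReadLen,maxReadLen Admissible read lengths (nt).
#' @return A [ClassifierConfig-class] object.
#' @export
classifierConfig <- function(maxOffset = 5L, maxTail = 3L,
                             minReadLen = 16L, maxReadLen = 28L) {
    new("ClassifierConfig", maxOffset = as.integer(maxOffset),
        maxTail = as.integer(maxTail), minReadLen = as.integer(minReadLen),
        maxReadLen = as.integer(maxReadLen))
}

.fmtOffset <- function(x) {
    ifelse(x > 0L, paste0("+", x), as.character(x))
}

.categoryOf <- function(offset5, offset3, tail) {
    if (nzchar(tail)) return("nontemplate")
    if (offset5 == 0L && offset3 == 0L) return("refseq")
    if (offset5 != 0L && offset3 != 0L) return("iso5_3")
    if (offset5 != 0L) return("iso5")
    "iso3"
}

#' Canonical isomiR name for a classified call
#'
#' Reference reads keep the bare arm name; templated variants are named
#' `"{parent}_t_{o5}_{o3}"` and tailed variants
#' `"{parent}_nont_{o5}_{o3}_{tail}"`, with offsets carrying an explicit
#' sign for non-zero values (`+1`, `-2`, bare `0`).
#'
#' @param call A call as returned by [classifyRead()] (a list with fields
#'   `parent`, `offset5`, `offset3`, `tail`), or a one-row data.frame.
#' @return The canonical name string.
#' @examples
#' nameCall(list(parent = "miR-449c-5p", offset5 = 0L, offset3 = -2L,
#'               tail = ""))
#' @export
nameCall <- function(call) {
    call <- as.list(call)
    o5 <- as.integer(call$offset5)
    o3 <- as.integer(call$offset3)
    tail <- if (is.null(call$tail)) "" else call$tail
    if (nzchar(tail))
        return(paste0(call$parent, "_nont_", .fmtOffset(o5), "_",
                      .fmtOffset(o3), "_", tail))
    if (o5 == 0L && o3 == 0L)
        return(call$parent)
    paste0(call$parent, "_t_", .fmtOffset(o5), "_", .fmtOffset(o3))
}

.OFFSET_RX <- "(0|[+][1-9][0-9]*|-[1-9][0-9]*)"

#' Parse a canonical isomiR name back into its fields
#'
#' Exact inverse of [nameCall()] on its output grammar.
#'
#' @param name A canonical name string.
#' @return A list with fields `parent`, `category`, `offset5`, `offset3`,
#'   `tail`.
#' @examples
#' parseName("miR-30d-5p_t_+1_+2")
#' @export
parseName <- function(name) {
    stopifnot(is.character(name), length(name) == 1L)
    rx_t <- paste0("^(.*)_t_", .OFFSET_RX, "_", .OFFSET_RX, "$")
    rx_n <- paste0("^(.*)_nont_", .OFFSET_RX, "_", .OFFSET_RX, "_([ACGU]+)$")
    if (grepl(rx_t, name)) {
        m <- regmatches(name, regexec(rx_t, name))[[1L]]
        o5 <- as.integer(m[3L]); o3 <- as.integer(m[4L])
        if (o5 == 0L && o3 == 0L)
            stop("malformed isomiR name '", name,
                 "': templated variant with zero offsets")
        return(list(parent = m[2L], category = .categoryOf(o5, o3, ""),
                    offset5 = o5, offset3 = o3, tail = ""))
    }
    if (grepl(rx_n, name)) {
        m <- regmatches(name, regexec(rx_n, name))[[1L]]
        return(list(parent = m[2L], category = "nontemplate",
                    offset5 = as.integer(m[3L]), offset3 = as.integer(m[4L]),
                    tail = m[5L]))
    }
    ## reject names that look like variant names with an unknown type token
    ## or malformed offsets rather than silently treating them as refseq
    if (grepl("_[A-Za-z0-9]+_[+-]?[0-9]+_[+-]?[0-9]+(_[A-Za-z]+)?$", name)) {
        bad <- regexpr("_[A-Za-z0-9]+_[+-]?[0-9]+_", name)
        stop(sprintf("malformed isomiR name '%s' at position %d", name,
                     as.integer(bad)))
    }
    list(parent = name, category = "refseq", offset5 = 0L, offset3 = 0L,
         tail = "")
}

.parseNames <- function(names) {
    out <- lapply(names, parseName)
    data.frame(name = names,
               parent = vapply(out, `[[`, "", "parent"),
               category = vapply(out, `[[`, "", "category"),
               offset5 = vapply(out, `[[`, 0L, "offset5"),
               offset3 = vapply(out, `[[`, 0L, "offset3"),
               tail = vapply(out, `[[`, "", "tail"),
               stringsAsFactors = FALSE)
}

## Longest common prefix length of read and precursor starting at 0-based
## precursor position s, working on raw byte vectors.
.lcp <- function(preRaw, s, readRaw) {
    n <- min(length(readRaw), length(preRaw) - s)
    if (n <= 0L) return(0L)
    cmp <- preRaw[(s + 1L):(s + n)] == readRaw[seq_len(n)]
    if (all(cmp)) return(n)
    which.min(cmp) - 1L
}

## Core single-read classifier over pre-extracted raw sequences.
## Returns a list(assigned, reason | parent, category, offset5, offset3,
## tail, name).
.classifyOne <- function(read, preRawList, arms, cfg) {
    readRaw <- charToRaw(read)
    rl <- length(readRaw)
    best <- NULL
    bestKey <- NULL
    sawTailTooLong <- FALSE
    sawOffset <- FALSE
    for (i in seq_len(nrow(arms))) {
        preRaw <- preRawList[[arms$precursor_id[i]]]
        a_start <- arms$start[i]
        a_end <- arms$end[i]
        s_lo <- max(0L, a_start - cfg@maxOffset)
        s_hi <- min(length(preRaw) - 1L, a_start + cfg@maxOffset)
        if (s_lo > s_hi) next
        for (s in s_lo:s_hi) {
            L <- .lcp(preRaw, s, readRaw)
            if (L == 0L) next
            e <- s + L
            tailLen <- rl - L
            if (abs(e - a_end) > cfg@maxOffset) {
                sawOffset <- TRUE
                next
            }
            if (tailLen > cfg@maxTail) {
                sawTailTooLong <- TRUE
                next
            }
            o5 <- s - a_start
            o3 <- (s + rl) - a_end
            key <- list(-L, abs(o5) + abs(o3), tailLen, arms$name[i])
            if (is.null(best) || .keyLess(key, bestKey)) {
                tail <- if (tailLen > 0L)
                    rawToChar(readRaw[(L + 1L):rl]) else ""
                best <- list(parent = arms$name[i], offset5 = o5,
                             offset3 = o3, tail = tail)
                bestKey <- key
            }
        }
    }
    if (is.null(best)) {
        reason <- if (sawTailTooLong) "tail_too_long"
                  else if (sawOffset) "offset_too_large" else "no_match"
        return(list(assigned = FALSE, reason = reason))
    }
    cat_ <- .categoryOf(best$offset5, best$offset3, best$tail)
    c(list(assigned = TRUE), best, list(category = cat_,
      name = nameCall(best)))
}

.keyLess <- function(a, b) {
    for (k in 1:3) {
        if (a[[k]] < b[[k]]) return(TRUE)
        if (a[[k]] > b[[k]]) return(FALSE)
    }
    a[[4L]] < b[[4L]]
}

.precursorRawList <- function(refset) {
    sq <- as.character(refset@precursors)
    out <- lapply(sq, charToRaw)
    names(out) <- names(refset@precursors)
    out
}

#' Classify one read against the reference arms
#'
#' Finds the longest read prefix matching a precursor exactly and
#' contiguously, starting within `maxOffset` of an arm's 5' start and
#' ending (templated portion) within `maxOffset` of the arm's 3' end; any
#' unmatched suffix up to `maxTail` nt is the non-templated tail. Among
#' admissible placements the call is chosen deterministically: longest
#' templated match, then smallest |offset5| + |offset3|, then shortest
#' tail, then lexicographically smallest parent name.
#'
#' @param read RNA (or DNA; `T` is converted) read sequence.
#' @param refset A [MiRReferenceSet-class].
#' @param config A [ClassifierConfig-class].
#' @return A list: either `assigned = TRUE` with fields `parent`,
#'   `category` (one of refseq/iso5/iso3/iso5_3/nontemplate), `offset5`,
#'   `offset3`, `tail`, `name`; or `assigned = FALSE` with a `reason` code
#'   (`length`, `no_match`, `offset_too_large`, `tail_too_long`).
#' @examples
#' classifyRead("UCACAGUGGCUAAGUUCUGC", fixtureReference())$name
#' @export
classifyRead <- function(read, refset, config = classifierConfig()) {
    stopifnot(is.character(read), length(read) == 1L)
    read <- .normalizeRNA(read)
    if (grepl("[^ACGU]", read))
        stop("read contains characters outside {A,C,G,U}")
    n <- nchar(read)
    if (n < config@minReadLen || n > config@maxReadLen)
        return(list(assigned = FALSE, reason = "length"))
    arms <- as.data.frame(refset@arms)
    .classifyOne(read, .precursorRawList(refset), arms, config)
}

#' Classify a vector of reads
#'
#' Vectorized wrapper around the single-read classifier; reads outside the
#' length window are reported unassigned with reason `length` rather than
#' erroring.
#'
#' @inheritParams classifyRead
#' @param reads Character vector of read sequences.
#' @return A data.frame with one row per read: `read`, `assigned`,
#'   `reason`, `parent`, `category`, `offset5`, `offset3`, `tail`, `name`.
#' @export
classifyReads <- function(reads, refset, config = classifierConfig()) {
    reads <- .normalizeRNA(reads)
    bad <- grepl("[^ACGU]", reads)
    if (any(bad))
        stop("read contains characters outside {A,C,G,U}: ",
             reads[bad][1L])
    preRawList <- .precursorRawList(refset)
    arms <- as.data.frame(refset@arms)
    n <- nchar(reads)
    out <- data.frame(read = reads, assigned = FALSE, reason = "",
                      parent = NA_character_, category = NA_character_,
                      offset5 = NA_integer_, offset3 = NA_integer_,
                      tail = NA_character_, name = NA_character_,
                      stringsAsFactors = FALSE)
    for (i in seq_along(reads)) {
        if (n[i] < config@minReadLen || n[i] > config@maxReadLen) {
            out$reason[i] <- "length"
            next
        }
        res <- .classifyOne(reads[i], preRawList, arms, config)
        if (isTRUE(res$assigned)) {
            out$assigned[i] <- TRUE
            out$parent[i] <- res$parent
            out$category[i] <- res$category
            out$offset5[i] <- res$offset5
            out$offset3[i] <- res$offset3
            out$tail[i] <- res$tail
            out$name[i] <- res$name
        } else {
            out$reason[i] <- res$reason
        }
    }
    out
}

#' Seed region of a mature sequence
#'
#' The seed is the 7-mer at positions 2-8 (1-based) of the mature
#' sequence, the primary determinant of target recognition.
#'
#' @param sequence RNA string of length >= 8.
#' @return The 7-nt seed string.
#' @examples
#' seedOf("UUCACAGUGGCUAAGUUCUGC")
#' @export
seedOf <- function(sequence) {
    sequence <- .normalizeRNA(sequence)
    if (nchar(sequence) < 8L)
        stop("sequence shorter than 8 nt has no defined seed")
    substr(sequence, 2L, 8L)
}

#' Does a call (or canonical name) carry a shifted seed?
#'
#' A 5' end offset moves positions 2-8 and therefore re-targets the
#' variant; 3'-only and tailed variants keep the parent's seed.
#'
#' @param call A call list from [classifyRead()], or a canonical name
#'   string (parsed with [parseName()]).
#' @return Logical.
#' @export
isSeedShifted <- function(call) {
    if (is.character(call))
        call <- parseName(call)
    as.integer(call$offset5) != 0L
}
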