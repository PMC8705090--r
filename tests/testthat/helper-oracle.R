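# Brute-force classification oracle: enumerate every (arm, start,
# templated-length, tail) split admissible under the offset/tail windows
# and the maximal-prefix rule, then apply the documented tie-break.
# Deliberately written with plain substring comparisons, independent of
# the package's incremental matcher.
oracleClassify <- function(read, refset, cfg = classifierConfig()) {
    n <- nchar(read)
    if (n < cfg@minReadLen || n > cfg@maxReadLen)
        return(list(assigned = FALSE, reason = "length"))
    arms <- as.data.frame(matureArms(refset))
    pre <- as.character(precursors(refset))
    best <- NULL
    bestKey <- NULL
    less <- function(a, b) {
        for (k in seq_along(a)) {
            if (a[k] < b[k]) return(TRUE)
            if (a[k] > b[k]) return(FALSE)
        }
        FALSE
    }
    for (i in seq_len(nrow(arms))) {
        p <- pre[[arms$precursor_id[i]]]
        pl <- nchar(p)
        for (s in 0:(pl - 1L)) {
            if (abs(s - arms$start[i]) > cfg@maxOffset) next
            for (m in seq_len(n)) {
                e <- s + m
                if (e > pl) break
                if (substr(p, s + 1L, e) != substr(read, 1L, m)) next
                tl <- n - m
                if (tl > cfg@maxTail) next
                if (abs(e - arms$end[i]) > cfg@maxOffset) next
                tail <- substr(read, m + 1L, n)
                if (tl > 0L && e < pl &&
                    substr(p, e + 1L, e + 1L) == substr(tail, 1L, 1L))
                    next  # not a maximal templated prefix
                o5 <- s - arms$start[i]
                o3 <- s + n - arms$end[i]
                key <- c(-m, abs(o5) + abs(o3), tl)
                cand <- list(parent = arms$name[i], offset5 = o5,
                             offset3 = o3, tail = tail)
                if (is.null(best) || less(key, bestKey) ||
                    (!less(bestKey, key) && cand$parent < best$parent)) {
                    best <- cand
                    bestKey <- key
                }
            }
        }
    }
    if (is.null(best)) return(list(assigned = FALSE))
    best$assigned <- TRUE
    best$name <- nameCall(best)
    best
}

# Random reads enriched for classifiable structure: derived from an arm
# with random end offsets and a random (possibly templated-looking) tail,
# plus a share of fully random sequences.
randomReadFor <- function(refset, cfg = classifierConfig()) {
    arms <- as.data.frame(matureArms(refset))
    pre <- as.character(precursors(refset))
    if (runif(1) < 0.15)
        return(paste(sample(c("A", "C", "G", "U"), sample(16:28, 1),
                            replace = TRUE), collapse = ""))
    i <- sample(nrow(arms), 1L)
    p <- pre[[arms$precursor_id[i]]]
    o5 <- sample(-(cfg@maxOffset + 1L):(cfg@maxOffset + 1L), 1L)
    o3 <- sample(-(cfg@maxOffset + 1L):(cfg@maxOffset + 1L), 1L)
    s <- max(0L, arms$start[i] + o5)
    e <- min(nchar(p), arms$end[i] + o3)
    if (e - s < 8L) return(randomReadFor(refset, cfg))
    core <- substr(p, s + 1L, e)
    tail <- paste(sample(c("A", "U", "C", "G"),
                         sample(0:(cfg@maxTail + 2L), 1L,
                                prob = c(0.4, 0.25, 0.15, 0.1, 0.06, 0.04)),
                         replace = TRUE), collapse = "")
    paste0(core, tail)
}

writeTestFastq <- function(seqs, path) {
    dna <- gsub("U", "T", seqs, fixed = TRUE)
    lines <- unlist(lapply(seq_along(dna), function(i)
        c(paste0("@r", i), dna[i], "+", strrep("I", nchar(dna[i])))))
    writeLines(lines, path)
    path
}
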